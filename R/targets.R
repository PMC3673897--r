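# penalty for an (miRNA base, target base) pair, antiparallel:
# Watson-Crick 0, G:U wobble 0.5, otherwise mismatch 1
pair_penalty_lookup <- function() {
  pen <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
  pen["A", "T"] <- 0; pen["T", "A"] <- 0
  pen["G", "C"] <- 0; pen["C", "G"] <- 0
  pen["G", "T"] <- 0.5   # G (miRNA) : U (target)
  pen["T", "G"] <- 0.5   # U (miRNA) : G (target)
  pen
}

position_weights <- function(L, double_from = 2, double_to = 13) {
  w <- rep(1, L)
  w[double_from:min(double_to, L)] <- 2
  w
}

#' Complementarity score of a miRNA against a candidate target site
#'
#' Plant-convention penalty sum: the site is written 5' to 3' on the
#' transcript and aligned antiparallel to the miRNA, so miRNA position j
#' pairs site position L - j + 1. Penalties are 1 per mismatch, 0.5 per G:U
#' wobble and 2 per gap, doubled at miRNA positions 2-13 counted from the
#' miRNA 5' end. The default alignment is gap-free; `allow_gap = TRUE`
#' additionally tries every single-gap placement (a one-base bulge on either
#' strand) and returns the best alignment.
#'
#' @param mirna_seq miRNA sequence, 5' to 3'
#' @param site_seq candidate site, 5' to 3' on the transcript; length must
#'   equal the miRNA length (gap-free) or differ by one (single gap)
#' @param allow_gap permit one gap
#' @return list with `score`, `mismatch_pos`, `wobble_pos` (miRNA
#'   positions), and `gap` (0 or 1)
#' @export
pair_score <- function(mirna_seq, site_seq, allow_gap = FALSE) {
  m <- dna_norm(mirna_seq); s <- dna_norm(site_seq)
  assert_dna(c(m, s), "pair_score input")
  L <- nchar(m); Ls <- nchar(s)
  mv <- strsplit(m, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  pen <- pair_penalty_lookup()

  score_gapfree <- function(mv, sv) {
    L <- length(mv)
    w <- position_weights(L)
    p <- vapply(seq_len(L), function(j) pen[mv[j], sv[L - j + 1]], numeric(1))
    list(score = sum(w * p),
         mismatch_pos = which(p == 1), wobble_pos = which(p == 0.5))
  }

  if (Ls == L) {
    res <- score_gapfree(mv, sv)
    res$gap <- 0L
    if (!allow_gap) return(res)
    return(res)
  }
  if (!allow_gap || abs(Ls - L) != 1) {
    stop("site length must equal miRNA length (or differ by 1 with allow_gap)",
         call. = FALSE)
  }
  w <- position_weights(L)
  best <- NULL
  if (Ls == L + 1) {
    # extra target base: bulge in the target, unpaired opposite a gap in the miRNA
    for (g in seq_len(Ls)) {           # target position left unpaired (5'->3')
      sv2 <- sv[-g]
      r <- score_gapfree(mv, sv2)
      # gap penalty doubled when the bulge sits inside the 2-13 pairing zone
      j_adj <- L - min(g, L) + 1
      gp <- 2 * ifelse(j_adj >= 2 && j_adj <= 13, 2, 1)
      r$score <- r$score + gp
      r$gap <- 1L
      if (is.null(best) || r$score < best$score) best <- r
    }
  } else {
    # missing target base: one miRNA position left unpaired
    for (g in seq_len(L)) {
      mv2 <- mv[-g]
      p <- vapply(seq_along(mv2), function(j) {
        jj <- if (j < g) j else j + 1L
        pen[mv[jj], sv[length(sv) - j + 1]]
      }, numeric(1))
      w2 <- w[-g]
      gp <- 2 * ifelse(g >= 2 && g <= 13, 2, 1)
      r <- list(score = sum(w2 * p) + gp,
                mismatch_pos = which(p == 1), wobble_pos = which(p == 0.5),
                gap = 1L)
      if (is.null(best) || r$score < best$score) best <- r
    }
  }
  best
}

# vectorised gap-free scan of one miRNA over one transcript; returns a
# data.frame of all start positions with total score and 10/11 pairing flag
scan_transcript <- function(mirna_seq, transcript_seq) {
  m <- dna_norm(mirna_seq)
  t_ <- dna_norm(transcript_seq)
  L <- nchar(m)
  N <- nchar(t_) - L + 1
  if (N < 1) {
    return(data.frame(site_start = integer(), score = numeric(),
                      wc_10_11 = logical()))
  }
  mv <- strsplit(m, "")[[1]]
  tv <- strsplit(t_, "")[[1]]
  pen <- pair_penalty_lookup()
  w <- position_weights(L)
  starts <- seq_len(N)
  score <- numeric(N)
  wc10 <- wc11 <- logical(N)
  for (j in seq_len(L)) {
    sb <- tv[starts + (L - j)]
    pj <- pen[cbind(mv[j], sb)]
    score <- score + w[j] * pj
    if (j == 10) wc10 <- pj == 0
    if (j == 11) wc11 <- pj == 0
  }
  data.frame(site_start = starts, score = score, wc_10_11 = wc10 & wc11)
}

#' Degradome read preparation
#'
#' Trims the 3' adapter, keeps high-quality inserts of at least 18 nt and
#' retains the 20-21 nt tags; removes polyN tags (any single base above 70%
#' of the tag); normalises counts to reads per 10 million (RP10M) of clean
#' reads; and maps tags to the transcriptome by exact match, recording
#' 5'-end positions.
#'
#' @param reads FASTQ path, data.frame from [read_fastq()], or character
#'   vector of read sequences
#' @param adapter3 3' adapter sequence
#' @param transcriptome named character vector of transcript sequences
#' @param keep_len retained tag lengths (default 20:21)
#' @param polyn_frac single-base fraction above which a tag is polyN
#' @return list with `tags` (sequence, count, rp10m), `hits` (sequence,
#'   transcript, pos of the tag 5' end, 1-based), and `stats`
#' @export
degradome_prep <- function(reads, adapter3, transcriptome,
                           keep_len = 20:21, polyn_frac = 0.7) {
  if (length(transcriptome) == 0) stop("empty transcriptome", call. = FALSE)
  cleaned <- clean_reads(reads, adapter3, min_len = 18, max_len = 40)
  clean_total <- cleaned$stats[["clean"]]
  tags <- cleaned$tags[nchar(cleaned$tags) %in% keep_len]
  tab <- table(tags)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    base_frac <- vapply(df$sequence, function(s) {
      v <- strsplit(s, "")[[1]]
      max(table(v)) / length(v)
    }, numeric(1), USE.NAMES = FALSE)
    polyn <- base_frac > polyn_frac
    df <- df[!polyn, , drop = FALSE]
  } else polyn <- logical(0)
  df$rp10m <- if (clean_total > 0) df$count / clean_total * 1e7 else NA_real_

  hits <- list()
  txs <- Biostrings::DNAStringSet(dna_norm(transcriptome))
  for (i in seq_len(nrow(df))) {
    m <- Biostrings::vmatchPattern(df$sequence[i], txs)
    n_per <- S4Vectors::elementNROWS(m)
    if (sum(n_per) == 0) next
    hits[[length(hits) + 1]] <- data.frame(
      sequence = df$sequence[i],
      transcript = rep(names(txs), n_per),
      pos = unlist(IRanges::start(m)),
      stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(sequence = character(), transcript = character(),
               pos = integer(), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  rownames(df) <- NULL
  list(tags = df, hits = hits,
       stats = c(cleaned$stats, kept_20_21 = length(tags),
                 polyn_removed = sum(polyn), unique_tags = nrow(df),
                 mapped_unique_tags = length(unique(hits$sequence))))
}

#' Locate a cleavage position within a transcript model
#'
#' @param position transcript coordinate(s), 1-based
#' @param cds_start,cds_end CDS bounds (1-based inclusive); NA gives
#'   `"unknown"`
#' @return character vector over {5UTR, CDS, 3UTR, unknown}
#' @export
locate_site <- function(position, cds_start, cds_end) {
  ifelse(is.na(cds_start) | is.na(cds_end), "unknown",
         ifelse(position < cds_start, "5UTR",
                ifelse(position <= cds_end, "CDS", "3UTR")))
}

#' Proportion of cleavage sites per transcript region
#'
#' @param regions character vector of site regions (from [locate_site()])
#' @param digits decimal places for the percentage (default 1)
#' @return data.frame with `region`, `n`, `pct` (percent of sites with a
#'   known region, rounded half-up)
#' @export
region_proportions <- function(regions, digits = 1) {
  known <- regions[regions != "unknown"]
  tab <- table(factor(known, levels = c("5UTR", "CDS", "3UTR")))
  data.frame(region = names(tab), n = as.integer(tab),
             pct = pct(as.integer(tab), length(known), digits),
             row.names = NULL)
}

#' Call miRNA targets
#'
#' Scans every transcript for gap-free sites with complementarity score at
#' most `max_score` and perfect Watson-Crick pairing at miRNA positions 10
#' and 11. In degradome mode a hit additionally requires at least one
#' degradome tag whose mapped 5' end equals the transcript position pairing
#' miRNA nucleotide 10 (the cleavage position, site_end - 9 for a gap-free
#' site); that position's RP10M is reported.
#'
#' @param mirnas data.frame with columns `name` and `sequence`, or a named
#'   character vector of mature sequences
#' @param transcriptome named character vector of transcript sequences
#' @param degradome result of [degradome_prep()], or NULL for
#'   computational-only prediction
#' @param cds optional data.frame with `transcript`, `cds_start`, `cds_end`
#' @param max_score maximum alignment score (inclusive, default 7)
#' @return data.frame of TargetHits: `mirna`, `transcript`, `site_start`,
#'   `site_end`, `score`, `cleavage_pos`, `rp10m` (NA in predicted mode),
#'   `region`, `mode`
#' @export
call_targets <- function(mirnas, transcriptome, degradome = NULL, cds = NULL,
                         max_score = 7) {
  if (!is.data.frame(mirnas)) {
    mirnas <- data.frame(name = names(mirnas), sequence = as.character(mirnas),
                         stringsAsFactors = FALSE)
  }
  mode <- if (is.null(degradome)) "predicted" else "degradome"
  deg_signal <- NULL
  if (!is.null(degradome)) {
    h <- degradome$hits
    if (nrow(h)) {
      h$rp10m <- degradome$tags$rp10m[match(h$sequence, degradome$tags$sequence)]
      deg_signal <- stats::aggregate(rp10m ~ transcript + pos, data = h, FUN = sum)
    } else {
      deg_signal <- data.frame(transcript = character(), pos = integer(),
                               rp10m = numeric())
    }
  }
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    L <- nchar(mirnas$sequence[i])
    for (tx in names(transcriptome)) {
      sc <- scan_transcript(mirnas$sequence[i], transcriptome[[tx]])
      sc <- sc[sc$score <= max_score & sc$wc_10_11, , drop = FALSE]
      if (nrow(sc) == 0) next
      sc$site_end <- sc$site_start + L - 1L
      sc$cleavage_pos <- sc$site_end - 9L
      sc$rp10m <- NA_real_
      if (mode == "degradome") {
        key <- paste(tx, sc$cleavage_pos)
        sig <- deg_signal$rp10m[match(key, paste(deg_signal$transcript,
                                                 deg_signal$pos))]
        sc$rp10m <- sig
        sc <- sc[!is.na(sig) & sig > 0, , drop = FALSE]
        if (nrow(sc) == 0) next
      }
      sc$mirna <- mirnas$name[i]
      sc$transcript <- tx
      out[[length(out) + 1]] <- sc
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(site_start = integer(), score = numeric(), wc_10_11 = logical(),
               site_end = integer(), cleavage_pos = integer(), rp10m = numeric(),
               mirna = character(), transcript = character(),
               stringsAsFactors = FALSE)
  hits$region <- if (!is.null(cds) && nrow(hits)) {
    j <- match(hits$transcript, cds$transcript)
    locate_site(hits$cleavage_pos, cds$cds_start[j], cds$cds_end[j])
  } else rep("unknown", nrow(hits))
  hits$mode <- rep(mode, nrow(hits))
  hits <- hits[, c("mirna", "transcript", "site_start", "site_end", "score",
                   "cleavage_pos", "rp10m", "region", "mode")]
  rownames(hits) <- NULL
  hits
}

#' Computational-only target prediction
#'
#' Same scoring and position-10/11 pairing requirement as degradome calling,
#' without the degradome-support requirement.
#'
#' @inheritParams call_targets
#' @return TargetHit data.frame with `mode = "predicted"`
#' @export
predict_targets <- function(mirnas, transcriptome, cds = NULL, max_score = 7) {
  call_targets(mirnas, transcriptome, degradome = NULL, cds = cds,
               max_score = max_score)
}

#' Detect target-mimic sites
#'
#' A mimic pairs the miRNA well on both flanks but carries a 2-4 nt
#' insertion bulge in the target strand between the bases pairing miRNA
#' positions k and k+1 (k in 9-11, i.e. the bulge sits opposite the 9-12
#' cleavage region), which blocks cleavage and disqualifies the site from
#' target calling. Spans that also contain a cleavable gap-free site are not
#' reported: there the bulge is not what prevents cleavage.
#'
#' @param noncoding_seq candidate RNA sequence
#' @param mirna_seq mature miRNA sequence
#' @param bulge_len bulge sizes to consider (default 2:4)
#' @param split_positions miRNA positions after which the bulge may sit
#' @param mimic_max_score maximum summed flank score (default 7)
#' @return data.frame of mimic sites: `site_start`, `site_end`,
#'   `bulge_after` (miRNA position), `bulge_len`, `score`
#' @export
detect_mimic <- function(noncoding_seq, mirna_seq, bulge_len = 2:4,
                         split_positions = 9:11, mimic_max_score = 7) {
  s <- dna_norm(noncoding_seq)
  m <- dna_norm(mirna_seq)
  L <- nchar(m)
  mv <- strsplit(m, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  pen <- pair_penalty_lookup()
  w <- position_weights(L)
  out <- list()
  for (b in bulge_len) {
    span <- L + b
    N <- nchar(s) - span + 1
    if (N < 1) next
    for (k in split_positions) {
      score <- numeric(N)
      for (j in seq_len(L)) {
        off <- L - j + ifelse(j <= k, b, 0L)
        sb <- sv[seq_len(N) + off]
        score <- score + w[j] * pen[cbind(mv[j], sb)]
      }
      hit <- which(score <= mimic_max_score)
      if (length(hit)) {
        out[[length(out) + 1]] <- data.frame(
          site_start = hit, site_end = hit + span - 1L,
          bulge_after = k, bulge_len = b, score = score[hit])
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(site_start = integer(), site_end = integer(),
               bulge_after = integer(), bulge_len = integer(),
               score = numeric())
  # a span that also harbours a cleavable gap-free site is a target, not a
  # mimic: the bulge must be what blocks cleavage
  if (nrow(res)) {
    cl <- scan_transcript(m, s)
    cl <- cl[cl$score <= mimic_max_score & cl$wc_10_11, , drop = FALSE]
    if (nrow(cl)) {
      cl_end <- cl$site_start + L - 1L
      keep <- vapply(seq_len(nrow(res)), function(i) {
        !any(res$site_start[i] <= cl_end & cl$site_start <= res$site_end[i])
      }, logical(1))
      res <- res[keep, , drop = FALSE]
    }
  }
  rownames(res) <- NULL
  res[order(res$site_start, res$bulge_after, res$bulge_len), , drop = FALSE]
}
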