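#' Extract candidate precursor windows around a mapped tag
#'
#' For each locus three windows are proposed: the locus extended `flank`
#' bases upstream, extended downstream, and centred (half the flank on each
#' side), all clipped at chromosome ends. Sequences are reported 5' to 3' on
#' the tag's strand.
#'
#' @param locus list or one-row data.frame with `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive)
#' @param genome named character vector or `DNAStringSet`
#' @param flank flanking length in bases (default 200)
#' @return data.frame with columns `window`, `chrom`, `start`, `end`,
#'   `strand`, `seq`
#' @export
extract_windows <- function(locus, genome, flank = 200) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(dna_norm(genome))
  chrom <- as.character(locus$chrom)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom, call. = FALSE)
  len <- Biostrings::width(genome[chrom])
  if (locus$start < 1 || locus$end > len) {
    stop("locus outside chromosome bounds", call. = FALSE)
  }
  half <- floor(flank / 2)
  starts <- pmax(1L, c(locus$start - flank, locus$start, locus$start - half))
  ends <- pmin(len, c(locus$end, locus$end + flank, locus$end + half))
  seqs <- as.character(Biostrings::extractAt(
    genome[[chrom]], IRanges::IRanges(starts, ends)))
  if (locus$strand == "-") seqs <- revcomp(seqs)
  data.frame(window = c("upstream", "downstream", "centered"),
             chrom = chrom, start = starts, end = ends,
             strand = locus$strand, seq = seqs, stringsAsFactors = FALSE)
}

#' Duplex statistics for a mature tag inside a folded precursor
#'
#' Infers the star (miRNA*) span as the pairing partner of the mature with
#' the canonical 2-nt 3' overhang, and counts paired bases within the mature
#' span. Candidates whose mature spans the terminal loop (pairing partners
#' on both sides or inside the mature itself) are rejected.
#'
#' @param precursor_seq precursor sequence (5' to 3')
#' @param structure matching dot-bracket string
#' @param mature_start,mature_end 1-based mature coordinates within the
#'   precursor
#' @return list with `star_start`, `star_end`, `star_seq`, `matched_pairs`,
#'   `size_diff`, `arm` (5p/3p) and `reject` (NA when usable, otherwise
#'   `"loop_spanning"` or `"no_duplex"`)
#' @export
duplex_stats <- function(precursor_seq, structure, mature_start, mature_end) {
  stopifnot(nchar(precursor_seq) == nchar(structure),
            mature_start >= 1, mature_end <= nchar(precursor_seq),
            mature_start < mature_end)
  p <- pairing_table(structure)
  m <- mature_start:mature_end
  partners <- p[m]
  paired <- partners > 0
  out <- list(star_start = NA_integer_, star_end = NA_integer_,
              star_seq = NA_character_, matched_pairs = sum(paired),
              size_diff = NA_integer_, arm = NA_character_, reject = NA_character_)
  if (!any(paired)) {
    out$reject <- "no_duplex"
    return(out)
  }
  inside <- partners[paired] >= mature_start & partners[paired] <= mature_end
  up <- partners[paired] < mature_start
  down <- partners[paired] > mature_end
  if (any(inside) || (any(up) && any(down))) {
    out$reject <- "loop_spanning"
    return(out)
  }
  # canonical duplex: star pairs mature[1 .. len-2], with a 2-nt 3' overhang
  idx <- m[paired]
  j1 <- idx[1]                               # 5'-most paired mature position
  core <- idx[idx <= mature_end - 2]
  j2 <- if (length(core)) core[length(core)] else idx[length(idx)]
  star_start <- min(p[j2], p[j1])
  star_end <- min(max(p[j1], p[j2]) + 2L, nchar(precursor_seq))
  out$star_start <- star_start
  out$star_end <- star_end
  out$star_seq <- substr(precursor_seq, star_start, star_end)
  out$size_diff <- abs((mature_end - mature_start + 1L) -
                         (star_end - star_start + 1L))
  out$arm <- if (mature_start < star_start) "5p" else "3p"
  out
}

#' Default discovery thresholds
#'
#' All thresholds of the seven-criterion miRNA definition, configurable.
#' `max_mfe` is applied to the folding engine's kcal/mol output; the
#' abundance rule is inclusive (at least `min_tpm`) while the energy rule is
#' strict (strictly below `max_mfe`).
#'
#' @param min_tpm minimum TPM in any library (criterion 1, default 100)
#' @param arm_ratio_mode `"detect"` (criterion 2 passes whenever both arms
#'   are detected, the literal reading of the 5p/3p-or-3p/5p ratio rule,
#'   since max(a/b, b/a) >= 1 > 0.9) or `"min_over_max"` (requires
#'   min(a,b)/max(a,b) > `arm_ratio`)
#' @param arm_ratio balance threshold used by `min_over_max` mode
#' @param mature_len mature length window (criterion 3, default 20-24 nt)
#' @param max_mfe precursor MFE must be strictly below this (criterion 4,
#'   default -37 kcal/mol)
#' @param min_mfei MFEI must be strictly above this (criterion 5, 0.85)
#' @param min_matched_pairs duplex pairs must exceed this (default 16)
#' @param max_size_diff mature/star length difference cap (default 4 nt)
#' @param flank precursor window flank (default 200 nt)
#' @param max_loci_per_tag cap on loci examined per tag (default 20)
#' @param classifier_hook optional function(candidate row) -> logical,
#'   criterion 7; the default accepts every candidate
#' @return list of thresholds
#' @export
discovery_config <- function(min_tpm = 100, arm_ratio_mode = c("detect", "min_over_max"),
                             arm_ratio = 0.9, mature_len = c(20, 24),
                             max_mfe = -37, min_mfei = 0.85,
                             min_matched_pairs = 16, max_size_diff = 4,
                             flank = 200, max_loci_per_tag = 20,
                             classifier_hook = NULL) {
  list(min_tpm = min_tpm, arm_ratio_mode = match.arg(arm_ratio_mode),
       arm_ratio = arm_ratio, mature_len = mature_len, max_mfe = max_mfe,
       min_mfei = min_mfei, min_matched_pairs = min_matched_pairs,
       max_size_diff = max_size_diff, flank = flank,
       max_loci_per_tag = max_loci_per_tag, classifier_hook = classifier_hook)
}

#' Apply the seven miRNA criteria to a candidate
#'
#' @param candidate list/one-row data.frame with fields `mfe`, `mfei`,
#'   `mature_len`, `single_stem` (logical), `star_detected` (logical),
#'   `arm_balance` (min/max TPM ratio of the two arms, NA when the star is
#'   undetected)
#' @param tpm numeric vector of the mature's TPM across libraries
#' @param config thresholds from [discovery_config()]
#' @return named logical vector `c1..c7` plus `pass`
#' @export
apply_criteria <- function(candidate, tpm, config = discovery_config()) {
  if (length(tpm) == 0 || all(is.na(tpm))) stop("missing expression", call. = FALSE)
  c1 <- max(tpm, na.rm = TRUE) >= config$min_tpm
  c2 <- if (config$arm_ratio_mode == "detect") {
    isTRUE(candidate$star_detected)
  } else {
    isTRUE(candidate$star_detected) &&
      !is.na(candidate$arm_balance) && candidate$arm_balance > config$arm_ratio
  }
  c3 <- candidate$mature_len >= config$mature_len[1] &&
    candidate$mature_len <= config$mature_len[2]
  c4 <- !is.na(candidate$mfe) && candidate$mfe < config$max_mfe
  c5 <- !is.na(candidate$mfei) && candidate$mfei > config$min_mfei
  c6 <- isTRUE(candidate$single_stem)
  c7 <- if (is.null(config$classifier_hook)) TRUE else
    isTRUE(config$classifier_hook(candidate))
  flags <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6, c7 = c7)
  c(flags, pass = all(flags))
}

#' Classify a mature sequence by conservation against a reference catalog
#'
#' An exact same-species catalog match is `known`. Otherwise a family is
#' assigned when the mature matches any family member of equal length with
#' at most `max_mismatch` substitutions (no indels); the class is
#' `conserved` when that family has a member outside the legumes,
#' `less_conserved` when it is legume-only, and `novel` when no family can
#' be assigned.
#'
#' @param mature mature sequence
#' @param catalog data.frame with columns `mature_seq`, `species`, `family`,
#'   `name`
#' @param species the study species code (default `"gma"`)
#' @param legume_species species codes counted as legumes
#' @param max_mismatch substitution tolerance for family assignment
#' @return list with `class` (known/conserved/less_conserved/novel),
#'   `family` (or NA) and `name` (catalog name for known matches, else NA)
#' @export
classify_conservation <- function(mature, catalog, species = "gma",
                                  legume_species = c("gma", "mtr", "pvu",
                                                     "lja", "aip", "vun"),
                                  max_mismatch = 3) {
  mature <- dna_norm(mature)
  if (is.null(catalog) || nrow(catalog) == 0) {
    warning("empty reference catalog: all candidates classed novel")
    return(list(class = "novel", family = NA_character_, name = NA_character_))
  }
  cat_seq <- dna_norm(catalog$mature_seq)
  exact <- which(cat_seq == mature & catalog$species == species)
  if (length(exact)) {
    i <- exact[1]
    return(list(class = "known", family = catalog$family[i],
                name = catalog$name[i]))
  }
  same_len <- which(nchar(cat_seq) == nchar(mature))
  if (length(same_len)) {
    mm <- vapply(cat_seq[same_len], function(s) {
      sum(strsplit(s, "")[[1]] != strsplit(mature, "")[[1]])
    }, numeric(1), USE.NAMES = FALSE)
    ok <- same_len[mm <= max_mismatch]
    if (length(ok)) {
      fam <- catalog$family[ok[which.min(mm[mm <= max_mismatch])]]
      fam_species <- unique(catalog$species[catalog$family == fam])
      cls <- if (any(!fam_species %in% legume_species)) "conserved" else "less_conserved"
      return(list(class = cls, family = fam, name = NA_character_))
    }
  }
  list(class = "novel", family = NA_character_, name = NA_character_)
}

tag_tpm_matrix <- function(tags, clean_reads) {
  cc <- count_columns(tags)
  stopifnot(all(cc %in% names(clean_reads)))
  m <- as.matrix(tags[, cc, drop = FALSE])
  sweep(m, 2, as.numeric(clean_reads[cc]), "/") * 1e6
}

#' Discover miRNAs from collapsed tags
#'
#' End-to-end discovery: map tags, drop structural-RNA and exonic tags,
#' extract and fold precursor windows around the remaining loci, infer the
#' miRNA* duplex, and apply the seven criteria. Overlapping windows that
#' yield the same mature collapse to the best-MFEI candidate.
#'
#' @param tags collapsed tag data.frame from [collapse_tags()]
#' @param index a [build_index()] genome index
#' @param annotation annotation `GRanges` (see [categorize_tags()])
#' @param clean_reads named numeric vector of clean-read totals per library
#'   (names matching the tag count columns)
#' @param reference_catalog optional conservation reference (see
#'   [classify_conservation()]); NULL skips conservation classing
#' @param config thresholds from [discovery_config()]
#' @return data.frame of candidates with structure statistics, per-criterion
#'   flags `c1..c7`, `pass`, conservation class and per-library TPM
#' @export
discover_mirnas <- function(tags, index, annotation, clean_reads,
                            reference_catalog = NULL,
                            config = discovery_config()) {
  empty <- candidate_skeleton(count_columns(tags))
  if (nrow(tags) == 0) return(empty)
  tpm <- tag_tpm_matrix(tags, clean_reads)
  max_tpm <- apply(tpm, 1, max)
  len_ok <- tags$length >= config$mature_len[1] & tags$length <= config$mature_len[2]
  pre <- tags$sequence[len_ok & max_tpm >= config$min_tpm]
  if (length(pre) == 0) return(empty)

  loci <- map_tags(pre, index)
  if (nrow(loci) == 0) return(empty)
  cats <- categorize_tags(loci, annotation)
  keep_cat <- cats$tag[cats$category %in% c("known_miRNA", "intron", "unannotated")]
  loci <- loci[loci$tag %in% keep_cat, , drop = FALSE]
  if (nrow(loci) == 0) return(empty)
  loci <- do.call(rbind, lapply(split(loci, loci$tag), utils::head,
                                config$max_loci_per_tag))

  # windows for every (tag, locus)
  win_list <- lapply(seq_len(nrow(loci)), function(i) {
    w <- extract_windows(loci[i, ], index$genome, config$flank)
    w$tag <- loci$tag[i]
    w$locus_start <- loci$start[i]
    w$locus_end <- loci$end[i]
    w
  })
  wins <- do.call(rbind, win_list)
  folded <- fold(unique(wins$seq))
  fidx <- match(wins$seq, folded$seq)
  wins$structure <- folded$structure[fidx]
  wins$mfe <- folded$mfe[fidx]

  # first pass: locate the mature/star duplex inside each folded window and
  # excise the precursor (duplex plus a short pad); the precursor is then
  # refolded and all criteria are computed on the refold
  pad <- 10L
  pre_rows <- lapply(seq_len(nrow(wins)), function(i) {
    w <- wins[i, ]
    mstart <- if (w$strand == "+") w$locus_start - w$start + 1L else
      w$end - w$locus_end + 1L
    mend <- mstart + (w$locus_end - w$locus_start)
    ds <- duplex_stats(w$seq, w$structure, mstart, mend)
    if (!is.na(ds$reject)) return(NULL)
    ps <- max(1L, min(mstart, ds$star_start) - pad)
    pe <- min(nchar(w$seq), max(mend, ds$star_end) + pad)
    w$pre_seq <- substr(w$seq, ps, pe)
    w$m_in_pre <- mstart - ps + 1L
    if (w$strand == "+") {
      w$pre_gstart <- w$start + ps - 1L
      w$pre_gend <- w$start + pe - 1L
    } else {
      w$pre_gstart <- w$end - pe + 1L
      w$pre_gend <- w$end - ps + 1L
    }
    w
  })
  pre <- do.call(rbind, pre_rows)
  if (is.null(pre) || nrow(pre) == 0) return(empty)

  refolded <- fold(unique(pre$pre_seq))
  ridx <- match(pre$pre_seq, refolded$seq)
  pre$pre_structure <- refolded$structure[ridx]
  pre$pre_mfe <- refolded$mfe[ridx]

  rows <- lapply(seq_len(nrow(pre)), function(i) {
    w <- pre[i, ]
    mstart <- w$m_in_pre
    mend <- mstart + (w$locus_end - w$locus_start)
    ds <- duplex_stats(w$pre_seq, w$pre_structure, mstart, mend)
    if (!is.na(ds$reject)) return(NULL)
    data.frame(tag = w$tag, chrom = w$chrom, start = w$pre_gstart,
               end = w$pre_gend, strand = w$strand, window = w$window,
               precursor_seq = w$pre_seq, structure = w$pre_structure,
               mfe = w$pre_mfe,
               mfei = compute_mfei(w$pre_mfe, w$pre_seq),
               gc_pct = gc_percent(w$pre_seq),
               single_stem = is_single_stem(w$pre_structure),
               mature_start = mstart, mature_end = mend,
               star_seq = ds$star_seq, matched_pairs = ds$matched_pairs,
               size_diff = ds$size_diff, arm = ds$arm,
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  if (is.null(cand) || nrow(cand) == 0) return(empty)

  # duplex prefilter (pairs strictly exceeding the minimum, bounded size gap)
  cand <- cand[cand$matched_pairs > config$min_matched_pairs &
                 cand$size_diff <= config$max_size_diff, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  # best window per (tag, locus); then dedupe same-mature overlapping precursors
  key <- paste(cand$tag, cand$chrom, cand$strand,
               ifelse(cand$strand == "+",
                      cand$start + cand$mature_start - 1L,
                      cand$end - cand$mature_end + 1L))
  cand <- do.call(rbind, lapply(split(cand, key), function(g) {
    g[order(-g$single_stem, -g$mfei), ][1, , drop = FALSE]
  }))
  cand <- dedupe_overlapping(cand)

  # expression, star detection, criteria
  cc <- count_columns(tags)
  seq_idx <- match(cand$tag, tags$sequence)
  tpm_rows <- tpm[seq_idx, , drop = FALSE]
  counts_total <- rowSums(tags[, cc, drop = FALSE])
  names(counts_total) <- tags$sequence
  star_tot <- counts_total[cand$star_seq]
  star_tot[is.na(star_tot)] <- 0
  mature_tot <- counts_total[cand$tag]
  cand$star_detected <- star_tot > 0
  cand$arm_balance <- ifelse(star_tot > 0,
                             pmin(mature_tot, star_tot) / pmax(mature_tot, star_tot),
                             NA_real_)
  cand$mature_len <- nchar(cand$tag)

  flags <- t(vapply(seq_len(nrow(cand)), function(i) {
    apply_criteria(cand[i, ], tpm_rows[i, ], config)
  }, logical(8)))
  flags <- as.data.frame(flags)
  cand <- cbind(cand, flags)

  # conservation
  cons <- lapply(cand$tag, function(m) {
    if (is.null(reference_catalog)) {
      list(class = NA_character_, family = NA_character_, name = NA_character_)
    } else classify_conservation(m, reference_catalog)
  })
  cand$conservation <- vapply(cons, `[[`, character(1), "class")
  cand$family <- vapply(cons, `[[`, character(1), "family")
  known_name <- vapply(cons, `[[`, character(1), "name")

  ord <- order(cand$chrom, cand$start)
  cand <- cand[ord, , drop = FALSE]
  known_name <- known_name[ord]
  cand$name <- ifelse(!is.na(known_name), known_name,
                      sprintf("miRcand_%03d", seq_len(nrow(cand))))
  tpm_out <- as.data.frame(tpm[match(cand$tag, tags$sequence), , drop = FALSE])
  names(tpm_out) <- paste0("tpm_", tolower(cc))
  cand <- cbind(cand, tpm_out)
  names(cand)[names(cand) == "tag"] <- "sequence"
  rownames(cand) <- NULL
  cand
}

candidate_skeleton <- function(libs) {
  df <- data.frame(sequence = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   window = character(), precursor_seq = character(),
                   structure = character(), mfe = numeric(), mfei = numeric(),
                   gc_pct = numeric(), single_stem = logical(),
                   mature_start = integer(), mature_end = integer(),
                   star_seq = character(), matched_pairs = integer(),
                   size_diff = integer(), arm = character(),
                   star_detected = logical(), arm_balance = numeric(),
                   mature_len = integer(),
                   c1 = logical(), c2 = logical(), c3 = logical(),
                   c4 = logical(), c5 = logical(), c6 = logical(),
                   c7 = logical(), pass = logical(),
                   conservation = character(), family = character(),
                   name = character(), stringsAsFactors = FALSE)
  for (l in libs) df[[paste0("tpm_", tolower(l))]] <- numeric()
  df
}

# same mature sequence at overlapping precursor coordinates -> keep best MFEI
dedupe_overlapping <- function(cand) {
  if (nrow(cand) <= 1) return(cand)
  keep <- rep(TRUE, nrow(cand))
  ord <- order(-cand$mfei)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(ord)[-seq_len(a)]) {
      j <- ord[b]
      if (!keep[j]) next
      if (cand$tag[i] == cand$tag[j] && cand$chrom[i] == cand$chrom[j] &&
          cand$strand[i] == cand$strand[j] &&
          cand$start[i] <= cand$end[j] && cand$start[j] <= cand$end[i]) {
        keep[j] <- FALSE
      }
    }
  }
  cand[keep, , drop = FALSE]
}
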