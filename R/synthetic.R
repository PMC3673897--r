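#' Simulation design for a planted-truth small RNA study
#'
#' Encodes the study layout being emulated: four small RNA libraries
#' (leaf/root under +Pi/-Pi), planted hairpin loci whose mature tags carry
#' designed abundances (constitutive, tissue-specific with true zeros,
#' Pi-induced and Pi-repressed), a degradome whose tags mark planted
#' cleavage positions, and 2-kb promoters with planted cis-elements.
#'
#' @param seed integer RNG seed; every downstream generator derives its
#'   stream from it
#' @param genome_length total genome size in bases (default 60000)
#' @param n_hairpins number of planted miRNA hairpin loci (default 12)
#' @param n_decoy_loci number of decoy loci (rRNA/tRNA-like repeats, exonic
#'   regions) producing background tags (default 12)
#' @param mature_length_range mature tag length bounds, within [18, 31]
#' @param library_depths named reads-per-library vector (HPL, LPL, HPR, LPR)
#' @param expression designed true-TPM matrix, one row per hairpin, columns
#'   HPL/LPL/HPR/LPR; NULL uses [default_expression_design()]
#' @param dispersion negative-binomial overdispersion of tag counts; 0 gives
#'   Poisson sampling
#' @param adapter3 3' adapter ligated to every read
#' @param n_targets number of planted target transcripts
#' @param n_promoter_motifs planted cis-elements per promoter
#' @param background_scale 0-1 multiplier on the background read budget
#'   (1 fills each library to its depth; 0 is the noiseless limit)
#' @param star_fraction expected star-tag reads as a fraction of mature
#'   reads
#' @param degradome_background background degradome tags as a fraction of
#'   planted signal tags (0 = noiseless)
#' @param read_length raw read length (default 49)
#' @return an object of class `simulation_design`
#' @export
simulation_design <- function(seed = 1, genome_length = 60000, n_hairpins = 12,
                              n_decoy_loci = 12, mature_length_range = c(20, 24),
                              library_depths = c(HPL = 2e5, LPL = 2e5,
                                                 HPR = 2e5, LPR = 2e5),
                              expression = NULL, dispersion = 0.05,
                              adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                              n_targets = 8, n_promoter_motifs = 3,
                              background_scale = 1, star_fraction = 0.1,
                              degradome_background = 0.2, read_length = 49) {
  stopifnot(all(library_depths > 0),
            mature_length_range[1] >= 18, mature_length_range[2] <= 31,
            mature_length_range[1] <= mature_length_range[2],
            dispersion >= 0, background_scale >= 0, background_scale <= 1)
  libs <- c("HPL", "LPL", "HPR", "LPR")
  if (!all(libs %in% names(library_depths))) {
    stop("library_depths must be named HPL, LPL, HPR, LPR", call. = FALSE)
  }
  if (is.null(expression)) expression <- default_expression_design(n_hairpins)
  expression <- as.matrix(expression[, libs, drop = FALSE])
  if (nrow(expression) != n_hairpins) {
    stop("expression matrix must have one row per hairpin", call. = FALSE)
  }
  if (any(expression < 0)) stop("expression must be non-negative", call. = FALSE)
  if (any(colSums(expression) > 1e6)) {
    stop("designed TPM exceeds 10^6 in some library", call. = FALSE)
  }
  assert_dna(adapter3, "adapter3")
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 n_hairpins = n_hairpins, n_decoy_loci = n_decoy_loci,
                 mature_length_range = mature_length_range,
                 library_depths = library_depths[libs],
                 expression = expression, dispersion = dispersion,
                 adapter3 = dna_norm(adapter3), n_targets = n_targets,
                 n_promoter_motifs = n_promoter_motifs,
                 background_scale = background_scale,
                 star_fraction = star_fraction,
                 degradome_background = degradome_background,
                 read_length = read_length),
            class = "simulation_design")
}

#' Default designed expression archetypes
#'
#' Cycles through twelve archetypes emulating the expression patterns seen
#' in a phosphate-starvation study: constitutive, leaf-/root-specific (true
#' zeros), Pi-induced and Pi-repressed in one or both tissues, and a
#' root-specific -Pi-only pattern. Designed fold changes are at least
#' fourfold (|log2fc| >= 2) and specific/responsive baselines stay well
#' above the 100-TPM discovery floor so that desk-scale library depths
#' recover the planted classes.
#'
#' @param n number of planted miRNAs
#' @return matrix with columns HPL, LPL, HPR, LPR
#' @export
default_expression_design <- function(n) {
  arch <- rbind(
    constitutive_high = c(2500, 2500, 2200, 2200),
    constitutive_mid = c(1200, 1200, 1400, 1400),
    leaf_specific = c(900, 900, 0, 0),
    root_specific = c(0, 0, 900, 900),
    leaf_induced = c(300, 1500, 800, 800),
    root_induced = c(800, 800, 300, 1500),
    both_induced = c(300, 1400, 350, 1600),
    leaf_repressed = c(1500, 300, 800, 800),
    root_repressed = c(800, 800, 1500, 300),
    unchanged_low = c(800, 800, 850, 850),
    leaf_specific_induced = c(300, 1400, 0, 0),
    root_specific_lowPi = c(0, 0, 0, 900))
  colnames(arch) <- c("HPL", "LPL", "HPR", "LPR")
  if (n == 0) return(arch[0, , drop = FALSE])
  m <- arch[rep_len(seq_len(nrow(arch)), n), , drop = FALSE]
  rownames(m) <- sprintf("mir%02d", seq_len(n))
  m
}

# concrete hairpin construction: near-perfect stem (12-nt extensions on both
# sides of the mature, two designed mismatches opposite interior mature
# positions so the stem is not a perfect inverted repeat), low-pairing A/C
# loop
build_hairpin <- function(mature, arm, ext = 12, loop_len = 15,
                          n_mismatch = 2) {
  loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE), collapse = "")
  # GC-rich extensions keep the excised precursor's stem strongly stable
  # (< -37 kcal/mol) even for AT-rich matures
  if (arm == "5p") {
    stemA <- paste0(random_dna(ext, gc = 0.8), mature)
  } else {
    stemB <- paste0(mature, random_dna(ext, gc = 0.8))
    stemA <- revcomp(stemB)
  }
  stemB <- revcomp(stemA)
  precursor <- paste0(stemA, loop, stemB)
  sl <- nchar(stemA)
  total <- nchar(precursor)
  if (arm == "5p") {
    mstart <- ext + 1L
  } else {
    mstart <- sl + loop_len + 1L
  }
  mend <- mstart + nchar(mature) - 1L

  # unpair n_mismatch interior mature positions by mutating the partner base
  broken <- integer(0)
  mm_pos <- mstart + c(4L, 14L, 8L)[seq_len(n_mismatch)]
  for (pos in mm_pos) {
    q <- total - pos + 1L
    b <- substr(precursor, pos, pos)
    forbidden <- c(chartr("ACGT", "TGCA", b),
                   if (b == "G") "T", if (b == "T") "G",
                   substr(precursor, q, q))
    x <- setdiff(c("A", "C", "G", "T"), forbidden)[1]
    substr(precursor, q, q) <- x
    broken <- c(broken, min(pos, q))
  }
  v <- rep(".", total)
  stem_idx <- setdiff(seq_len(sl), broken)
  v[stem_idx] <- "("
  v[total - stem_idx + 1L] <- ")"
  structure_designed <- paste(v, collapse = "")

  ds <- duplex_stats(precursor, structure_designed, mstart, mend)
  list(precursor = precursor, structure = structure_designed,
       mature_start = mstart, mature_end = mend, star_seq = ds$star_seq)
}

#' Generate a synthetic genome with planted hairpins and decoy loci
#'
#' Embeds `n_hairpins` stem-loop precursors (perfect stems, so the designed
#' duplex has well over 16 matched pairs and a strongly negative MFE) and
#' decoy loci (rRNA/tRNA-like repeats, exons) in random background sequence.
#' Deterministic for a fixed design seed.
#'
#' @param design a [simulation_design()]
#' @return list with `genome` (named character vector), `annotation`
#'   (`GRanges` with `type` and `ID`), and `truth` (list with
#'   `planted_mirnas` data.frame carrying designed TPM and intended
#'   response/tissue classes)
#' @export
generate_genome <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(derive_seed(design$seed, 1))
  n_items <- design$n_hairpins + design$n_decoy_loci
  slot <- if (n_items > 0) floor(design$genome_length / n_items) else design$genome_length
  if (n_items > 0 && slot < 400) {
    stop("genome_length too small to host the requested loci", call. = FALSE)
  }

  lens <- if (design$n_hairpins > 0) {
    sample(seq(design$mature_length_range[1], design$mature_length_range[2]),
           design$n_hairpins, replace = TRUE)
  } else integer(0)
  matures <- character(0)
  while (length(matures) < design$n_hairpins) {
    cand <- random_dna(lens[length(matures) + 1])
    gc <- gc_percent(cand)
    if (gc >= 40 && gc <= 65 && !cand %in% matures) {
      matures <- c(matures, cand)
    }
  }
  arms <- rep_len(c("5p", "3p"), design$n_hairpins)
  strands <- rep_len(c("+", "-"), design$n_hairpins)
  hairpins <- lapply(seq_len(design$n_hairpins), function(i) {
    build_hairpin(matures[i], arms[i])
  })

  decoy_types <- rep_len(c("rRNA", "tRNA", "exon", "snRNA", "snoRNA"),
                         max(design$n_decoy_loci, 1))[seq_len(design$n_decoy_loci)]
  decoys <- vapply(decoy_types, function(tp) {
    if (tp %in% c("rRNA", "tRNA")) {
      strrep(random_dna(8), 15)            # repeat-like structural locus
    } else {
      random_dna(if (tp == "exon") 300 else 150)
    }
  }, character(1), USE.NAMES = FALSE)

  genome <- random_dna(design$genome_length)
  items <- c(lapply(seq_along(hairpins), function(i) {
    seq <- hairpins[[i]]$precursor
    if (strands[i] == "-") seq <- revcomp(seq)
    list(kind = "hairpin", i = i, seq = seq)
  }), lapply(seq_along(decoys), function(i) {
    list(kind = "decoy", i = i, seq = decoys[i])
  }))

  starts <- integer(length(items))
  gvec <- genome
  for (k in seq_along(items)) {
    s <- (k - 1L) * slot + 11L
    seq <- items[[k]]$seq
    if (s + nchar(seq) - 1 > design$genome_length) {
      stop("genome_length too small to host the requested loci", call. = FALSE)
    }
    substr(gvec, s, s + nchar(seq) - 1) <- seq
    starts[k] <- s
  }
  genome <- c(chr1 = gvec)

  mirna_rows <- lapply(seq_along(hairpins), function(i) {
    hp <- hairpins[[i]]
    s <- starts[i]
    e <- s + nchar(hp$precursor) - 1L
    if (strands[i] == "+") {
      mstart <- s + hp$mature_start - 1L
      mend <- s + hp$mature_end - 1L
    } else {
      mend <- e - hp$mature_start + 1L
      mstart <- e - hp$mature_end + 1L
    }
    data.frame(id = rownames(design$expression)[i], mature_seq = matures[i],
               star_seq = hp$star_seq, arm = arms[i], chrom = "chr1",
               strand = strands[i], pre_start = s, pre_end = e,
               mat_start = mstart, mat_end = mend,
               precursor_seq = hp$precursor, stringsAsFactors = FALSE)
  })
  planted <- if (length(mirna_rows)) do.call(rbind, mirna_rows) else
    data.frame(id = character(), mature_seq = character(), star_seq = character(),
               arm = character(), chrom = character(), strand = character(),
               pre_start = integer(), pre_end = integer(), mat_start = integer(),
               mat_end = integer(), precursor_seq = character(),
               stringsAsFactors = FALSE)
  if (nrow(planted)) {
    expr <- design$expression
    planted$tpm_hpl <- expr[, "HPL"]; planted$tpm_lpl <- expr[, "LPL"]
    planted$tpm_hpr <- expr[, "HPR"]; planted$tpm_lpr <- expr[, "LPR"]
    rep_ <- reported_tpm(expr)
    planted$response_leaf <- classify_response(log2(rep_[, "LPL"] / rep_[, "HPL"]))
    planted$response_root <- classify_response(log2(rep_[, "LPR"] / rep_[, "HPR"]))
    planted$tissue_highPi <- ifelse(expr[, "HPL"] > 0 & expr[, "HPR"] == 0, "leaf",
                                    ifelse(expr[, "HPR"] > 0 & expr[, "HPL"] == 0,
                                           "root", "none"))
    planted$tissue_lowPi <- ifelse(expr[, "LPL"] > 0 & expr[, "LPR"] == 0, "leaf",
                                   ifelse(expr[, "LPR"] > 0 & expr[, "LPL"] == 0,
                                          "root", "none"))
  }

  dec_idx <- which(vapply(items, function(x) x$kind == "decoy", logical(1)))
  ann <- data.frame(
    chrom = "chr1",
    start = c(planted$pre_start, starts[dec_idx]),
    end = c(planted$pre_end,
            starts[dec_idx] + nchar(decoys) - 1L),
    strand = c(planted$strand, rep("+", length(dec_idx))),
    type = c(rep("miRNA_primary_transcript", nrow(planted)), decoy_types),
    ID = c(planted$id, sprintf("decoy%02d", seq_along(dec_idx))),
    stringsAsFactors = FALSE)
  annotation <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$start, ann$end), strand = ann$strand,
    type = ann$type, ID = ann$ID)

  list(genome = genome, annotation = annotation,
       truth = list(planted_mirnas = planted), design = design)
}

#' Generate a transcriptome with planted miRNA target sites
#'
#' Builds `n_targets` transcripts each carrying one near-perfect
#' complementary site for a planted miRNA (cycled), a few background-only
#' transcripts, and one non-coding mimic transcript whose site pairs the
#' first planted miRNA perfectly except for a 3-nt bulge between the bases
#' pairing miRNA positions 10 and 11. Cleavage positions are site_end - 9.
#'
#' @param design a [simulation_design()]
#' @param truth truth list from [generate_genome()]
#' @param n_background background-only transcripts (default 3)
#' @return list with `transcriptome` (named character), `cds` (data.frame),
#'   and `truth` extended with `planted_targets` and `planted_mimics`
#' @export
generate_transcriptome <- function(design, truth, n_background = 3) {
  set.seed(derive_seed(design$seed, 2))
  planted <- truth$planted_mirnas
  if (nrow(planted) == 0 && design$n_targets > 0) {
    stop("no planted miRNAs to target", call. = FALSE)
  }
  tx_len <- 1200L
  cds_start <- 151L
  cds_end <- 1050L
  regions <- rep_len(c("CDS", "CDS", "CDS", "5UTR", "CDS", "3UTR"),
                     max(design$n_targets, 1))[seq_len(design$n_targets)]
  txs <- character(0); cds <- list(); tgt <- list()
  for (i in seq_len(design$n_targets)) {
    mi <- ((i - 1) %% nrow(planted)) + 1
    m <- planted$mature_seq[mi]
    L <- nchar(m)
    site <- revcomp(m)
    if (i %% 3 == 0) {
      # one mismatch opposite miRNA position 15 (outside the doubled zone,
      # score 1 or 2) for variety
      pos <- L - 15 + 1
      cur <- substr(site, pos, pos)
      repl <- setdiff(c("A", "C", "G", "T"),
                      c(cur, revcomp(substr(m, 15, 15)),
                        chartr("ACGT", "TGCA", substr(m, 15, 15))))[1]
      substr(site, pos, pos) <- repl
    }
    site_start <- switch(regions[i],
                         "5UTR" = 60L,
                         "CDS" = 380L + 40L * (i %% 5),
                         "3UTR" = 1080L)
    seq <- random_dna(tx_len)
    substr(seq, site_start, site_start + L - 1) <- site
    id <- sprintf("tx%02d", i)
    txs[id] <- seq
    cds[[id]] <- data.frame(transcript = id, cds_start = cds_start,
                            cds_end = cds_end, stringsAsFactors = FALSE)
    tgt[[id]] <- data.frame(mirna = planted$id[mi], transcript = id,
                            site_start = site_start,
                            site_end = site_start + L - 1L,
                            cleavage_pos = site_start + L - 10L,
                            region = locate_site(site_start + L - 10L,
                                                 cds_start, cds_end),
                            stringsAsFactors = FALSE)
  }
  for (b in seq_len(n_background)) {
    id <- sprintf("bg%02d", b)
    txs[id] <- random_dna(tx_len)
    cds[[id]] <- data.frame(transcript = id, cds_start = cds_start,
                            cds_end = cds_end, stringsAsFactors = FALSE)
  }
  mimics <- NULL
  if (nrow(planted)) {
    m <- planted$mature_seq[1]
    L <- nchar(m)
    rc <- revcomp(m)
    bulge <- random_dna(3)
    mimic_site <- paste0(substr(rc, 1, L - 10), bulge, substr(rc, L - 9, L))
    seq <- random_dna(600)
    mstart <- 200L
    substr(seq, mstart, mstart + nchar(mimic_site) - 1) <- mimic_site
    txs[["mimic01"]] <- seq
    cds[["mimic01"]] <- data.frame(transcript = "mimic01",
                                   cds_start = NA_integer_,
                                   cds_end = NA_integer_,
                                   stringsAsFactors = FALSE)
    mimics <- data.frame(mirna = planted$id[1], transcript = "mimic01",
                         site_start = mstart,
                         site_end = mstart + nchar(mimic_site) - 1L,
                         bulge_len = 3L, stringsAsFactors = FALSE)
  }
  truth$planted_targets <- if (length(tgt)) do.call(rbind, c(tgt, make.row.names = FALSE)) else
    data.frame(mirna = character(), transcript = character(),
               site_start = integer(), site_end = integer(),
               cleavage_pos = integer(), region = character(),
               stringsAsFactors = FALSE)
  truth$planted_mimics <- mimics
  list(transcriptome = txs,
       cds = do.call(rbind, c(cds, make.row.names = FALSE)),
       truth = truth)
}

sample_counts <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion <= 1e-12) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# assemble raw reads: insert + adapter + junk pad, truncated to read length
assemble_reads <- function(inserts, adapter3, read_length) {
  if (length(inserts) == 0) return(character(0))
  pads <- random_dna(rep(read_length, 64))
  pad <- pads[sample.int(64, length(inserts), replace = TRUE)]
  substr(paste0(inserts, adapter3, pad), 1, read_length)
}

#' Simulate the four small RNA libraries
#'
#' Per-library mature (and star) tag counts are drawn negative-binomially
#' around depth x TPM / 10^6 (Poisson when dispersion is 0); a designed TPM
#' of zero yields exactly zero reads. Background reads fill the library to
#' its depth (scaled by `background_scale`): decoy-locus fragments, random
#' inserts, plus small fractions of too-short inserts, adapter-free reads
#' and N-containing reads to exercise the cleaning counters. Reads carry the
#' 3' adapter and a junk tail; deterministic per design seed.
#'
#' @param design a [simulation_design()]
#' @param truth truth list from [generate_genome()]
#' @param genome named character vector (for decoy fragments)
#' @param annotation decoy annotation `GRanges`
#' @return named list of data.frames (columns `seq`, `qual`), one per
#'   library
#' @export
simulate_small_rna_libraries <- function(design, truth, genome, annotation) {
  planted <- truth$planted_mirnas
  decoy <- annotation[annotation$type != "miRNA_primary_transcript"]
  decoy_seqs <- if (length(decoy)) {
    vapply(seq_along(decoy), function(i) {
      substr(genome[[as.character(GenomicRanges::seqnames(decoy[i]))]],
             GenomicRanges::start(decoy[i]), GenomicRanges::end(decoy[i]))
    }, character(1))
  } else character(0)

  libs <- names(design$library_depths)
  out <- list()
  for (li in seq_along(libs)) {
    lib <- libs[li]
    set.seed(derive_seed(design$seed, 10 + li))
    depth <- design$library_depths[[lib]]
    tpm <- if (nrow(planted)) planted[[paste0("tpm_", tolower(lib))]] else numeric(0)
    mu <- depth * tpm / 1e6
    n_mat <- sample_counts(mu, design$dispersion)
    n_mat[tpm == 0] <- 0L
    n_star <- sample_counts(design$star_fraction * mu, design$dispersion)
    n_star[tpm == 0] <- 0L

    budget <- max(0, round(design$background_scale *
                             (depth - sum(n_mat) - sum(n_star))))
    n_decoy <- if (length(decoy_seqs)) round(0.6 * budget) else 0
    n_rand <- budget - n_decoy
    n_short <- round(0.02 * budget)
    n_noad <- round(0.01 * budget)
    n_lowq <- round(0.005 * budget)

    inserts <- c(rep(planted$mature_seq, n_mat), rep(planted$star_seq, n_star))
    if (n_decoy > 0) {
      src <- sample(decoy_seqs, n_decoy, replace = TRUE)
      len <- sample(18:28, n_decoy, replace = TRUE)
      pos <- vapply(seq_len(n_decoy), function(i) {
        sample.int(nchar(src[i]) - len[i] + 1L, 1)
      }, integer(1))
      frag <- substr(src, pos, pos + len - 1L)
      flip <- sample(c(TRUE, FALSE), n_decoy, replace = TRUE)
      frag[flip] <- revcomp(frag[flip])
      inserts <- c(inserts, frag)
    }
    if (n_rand > 0) inserts <- c(inserts, random_dna(sample(18:28, n_rand,
                                                            replace = TRUE)))
    if (n_short > 0) inserts <- c(inserts, random_dna(sample(8:17, n_short,
                                                             replace = TRUE)))
    reads <- assemble_reads(inserts, design$adapter3, design$read_length)
    if (n_noad > 0) reads <- c(reads, random_dna(rep(design$read_length, n_noad)))
    if (n_lowq > 0) {
      lowq <- assemble_reads(random_dna(rep(21, n_lowq)), design$adapter3,
                             design$read_length)
      substr(lowq, 5, 5) <- "N"
      reads <- c(reads, lowq)
    }
    reads <- reads[sample.int(length(reads))]
    out[[lib]] <- data.frame(seq = reads,
                             qual = strrep("I", nchar(reads)),
                             stringsAsFactors = FALSE)
  }
  out
}

#' Simulate a degradome library
#'
#' For every planted target, 20-21 nt tags whose 5' end equals the planted
#' cleavage position; background tags from uniform random transcript
#' positions in proportion `degradome_background`. Deterministic per seed.
#'
#' @param design a [simulation_design()]
#' @param truth truth list containing `planted_targets`
#' @param transcriptome named character vector
#' @param signal_depth expected tag count per planted cleavage site
#' @return data.frame of reads (`seq`, `qual`)
#' @export
simulate_degradome <- function(design, truth, transcriptome,
                               signal_depth = 50) {
  set.seed(derive_seed(design$seed, 30))
  tg <- truth$planted_targets
  tags <- character(0)
  for (i in seq_len(nrow(tg))) {
    tx <- transcriptome[[tg$transcript[i]]]
    len <- if (i %% 2 == 0) 20L else 21L
    if (tg$cleavage_pos[i] + len - 1L > nchar(tx)) {
      stop("cleavage position outside transcript", call. = FALSE)
    }
    tag <- substr(tx, tg$cleavage_pos[i], tg$cleavage_pos[i] + len - 1L)
    n <- stats::rpois(1, signal_depth)
    tags <- c(tags, rep(tag, n))
  }
  n_bg <- round(design$degradome_background * length(tags))
  if (n_bg > 0) {
    tx_ids <- sample(names(transcriptome), n_bg, replace = TRUE)
    len <- sample(20:21, n_bg, replace = TRUE)
    bg <- vapply(seq_len(n_bg), function(i) {
      s <- transcriptome[[tx_ids[i]]]
      p <- sample.int(nchar(s) - len[i] + 1L, 1)
      substr(s, p, p + len[i] - 1L)
    }, character(1))
    # a few polyN tags so the polyN filter is exercised
    tags <- c(tags, bg, rep(strrep("A", 15) %+% random_dna(5), 3))
  }
  reads <- assemble_reads(tags, design$adapter3, design$read_length)
  reads <- reads[sample.int(length(reads))]
  data.frame(seq = reads, qual = strrep("I", nchar(reads)),
             stringsAsFactors = FALSE)
}

`%+%` <- function(a, b) paste0(a, b)

concretize_iupac <- function(pattern) {
  amb <- list(M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
              S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
              V = c("A", "C", "G"), H = c("A", "C", "T"),
              D = c("A", "G", "T"), B = c("C", "G", "T"),
              N = c("A", "C", "G", "T"))
  v <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(v, function(ch) {
    if (ch %in% c("A", "C", "G", "T")) ch else sample(amb[[ch]], 1)
  }, character(1)), collapse = "")
}

# resample any motif-matching span until the sequence is motif-free
motif_free_sequence <- function(len, motif_table, max_iter = 100) {
  seq <- random_dna(len)
  for (it in seq_len(max_iter)) {
    hits <- scan_motifs(seq, motif_table)
    if (nrow(hits) == 0) return(seq)
    for (i in seq_len(nrow(hits))) {
      e <- len - hits$offset[i] + 1L
      s <- e - nchar(hits$match[i]) + 1L
      substr(seq, s, e) <- random_dna(e - s + 1L)
    }
  }
  stop("could not generate a motif-free background", call. = FALSE)
}

#' Plant cis-elements into 2-kb promoters
#'
#' Each planted miRNA gene receives a motif-free 2000-base promoter
#' (rejection-sampled against the motif table) into which
#' `n_promoter_motifs` elements are planted at recorded offsets and strands.
#' Induced genes draw preferentially from the phosphate-signalling elements
#' (P1BS-rich) and repressed genes from the PHO/NIT2 pool, so planted
#' element densities mirror the induced/repressed contrast.
#'
#' @param design a [simulation_design()]
#' @param truth truth list with `planted_mirnas`
#' @param motif_table motif definitions (default [default_motif_table()])
#' @param promoter_length promoter size (default 2000)
#' @return list with `promoters` (named character vector) and `truth`
#'   extended with `planted_motifs`
#' @export
plant_promoters <- function(design, truth, motif_table = default_motif_table(),
                            promoter_length = 2000) {
  set.seed(derive_seed(design$seed, 40))
  if (any(nchar(motif_table$pattern) > promoter_length)) {
    stop("motif longer than promoter", call. = FALSE)
  }
  planted <- truth$planted_mirnas
  promoters <- character(0)
  rows <- list()
  for (i in seq_len(nrow(planted))) {
    induced <- any(c(planted$response_leaf[i], planted$response_root[i]) ==
                     "induced")
    repressed <- any(c(planted$response_leaf[i], planted$response_root[i]) ==
                       "repressed")
    pool <- if (induced) c("P1BS", "P1BS", "W-box", "TATA-box", "TC")
    else if (repressed) c("PHO", "NIT2", "TATA-box")
    else c("W-box", "TATA-box", "TSS")
    pool <- intersect(pool, motif_table$name)
    n <- design$n_promoter_motifs
    if (n == 0) {
      promoters[[planted$id[i]]] <- motif_free_sequence(promoter_length,
                                                        motif_table)
      next
    }
    for (attempt in 1:20) {
      seq <- motif_free_sequence(promoter_length, motif_table)
      els <- sample(pool, n, replace = TRUE)
      offs <- integer(0)
      while (length(offs) < n) {
        o <- sample(50:(promoter_length - 50), 1)
        if (all(abs(o - offs) > 30)) offs <- c(offs, o)
      }
      strands <- ifelse(motif_table$strands[match(els, motif_table$name)] ==
                          "sense", "+", sample(c("+", "-"), n, replace = TRUE))
      matches <- character(n)
      for (j in seq_len(n)) {
        pat <- motif_table$pattern[match(els[j], motif_table$name)]
        conc <- concretize_iupac(pat)
        matches[j] <- conc
        e <- promoter_length - offs[j] + 1L
        s <- e - nchar(conc) + 1L
        ins <- if (strands[j] == "+") conc else revcomp(conc)
        substr(seq, s, e) <- ins
      }
      # palindromic IUPAC patterns (e.g. the P1BS) match both strands over
      # the same span, so compare unique (element, offset) pairs
      found <- unique(scan_motifs(seq, motif_table)[, c("element", "offset")])
      if (setequal(paste(found$element, found$offset),
                   paste(els, offs))) break
      if (attempt == 20) stop("failed to plant promoter motifs cleanly",
                              call. = FALSE)
    }
    promoters[[planted$id[i]]] <- seq
    rows[[i]] <- data.frame(gene = planted$id[i], element = els,
                            offset = offs, strand = strands, match = matches,
                            stringsAsFactors = FALSE)
  }
  truth$planted_motifs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), element = character(), offset = integer(),
               strand = character(), match = character(),
               stringsAsFactors = FALSE)
  list(promoters = promoters, truth = truth)
}

#' Run the full simulation, optionally writing all artefacts to disk
#'
#' @param design a [simulation_design()]
#' @param out_dir optional directory; when given, writes genome FASTA,
#'   annotation GFF3, per-library FASTQ, degradome FASTQ, transcriptome
#'   FASTA + CDS TSV, promoter FASTA and truth-table TSVs
#' @param motif_table motif definitions for promoter planting
#' @return list with `genome`, `annotation`, `reads` (per library),
#'   `degradome_reads`, `transcriptome`, `cds`, `promoters`, `truth`,
#'   `design`
#' @export
simulate_all <- function(design, out_dir = NULL,
                         motif_table = default_motif_table()) {
  g <- generate_genome(design)
  tx <- generate_transcriptome(design, g$truth)
  reads <- simulate_small_rna_libraries(design, tx$truth, g$genome,
                                        g$annotation)
  deg <- simulate_degradome(design, tx$truth, tx$transcriptome)
  pr <- plant_promoters(design, tx$truth, motif_table)
  sim <- list(genome = g$genome, annotation = g$annotation, reads = reads,
              degradome_reads = deg, transcriptome = tx$transcriptome,
              cds = tx$cds, promoters = pr$promoters, truth = pr$truth,
              design = design)
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              fp("genome.fa"))
  rtracklayer::export(sim$annotation, fp("annotation.gff3"), format = "gff3")
  for (lib in names(sim$reads)) {
    write_fastq(sim$reads[[lib]]$seq, fp(paste0(lib, ".fastq")))
  }
  write_fastq(sim$degradome_reads$seq, fp("degradome.fastq"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$transcriptome),
                              fp("transcripts.fa"))
  utils::write.table(sim$cds, fp("cds.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(sim$promoters)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$promoters),
                                fp("promoters.fa"))
  }
  for (nm in names(sim$truth)) {
    tt <- sim$truth[[nm]]
    if (is.data.frame(tt)) {
      utils::write.table(tt, fp(paste0("truth_", nm, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  invisible(out_dir)
}
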