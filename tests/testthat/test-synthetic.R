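test_that("design invariants are validated", {
  expect_error(simulation_design(mature_length_range = c(16, 24)))
  expect_error(simulation_design(library_depths = c(HPL = 0, LPL = 1, HPR = 1,
                                                    LPR = 1)))
  expect_error(simulation_design(n_hairpins = 2,
                                 expression = matrix(2e6, 2, 4,
                                                     dimnames = list(NULL,
                                                                     c("HPL", "LPL", "HPR", "LPR")))),
               "10\\^6")
  expect_error(generate_genome(simulation_design(genome_length = 2000,
                                                 n_hairpins = 10)),
               "too small")
})

test_that("generation is deterministic for a fixed seed", {
  d <- noiseless_design(9, n_hairpins = 3)
  s1 <- simulate_all(d)
  s2 <- simulate_all(d)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$reads$HPL$seq, s2$reads$HPL$seq)
  expect_identical(s1$degradome_reads$seq, s2$degradome_reads$seq)
  expect_identical(s1$promoters, s2$promoters)
  # and FASTQ files round-trip byte-identically
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1); write_simulation(s2, d2)
  expect_identical(readLines(file.path(d1, "HPL.fastq")),
                   readLines(file.path(d2, "HPL.fastq")))
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted precursors satisfy the discovery criteria when folded", {
  d <- noiseless_design(31, n_hairpins = 6)
  g <- generate_genome(d)
  tr <- g$truth$planted_mirnas
  f <- fold(tr$precursor_seq)
  expect_true(all(is_single_stem(f$structure)))
  expect_true(all(f$mfe < -37))
  expect_true(all(compute_mfei(f$mfe, tr$precursor_seq) > 0.85))
  for (i in seq_len(nrow(tr))) {
    mstart <- if (tr$strand[i] == "+") tr$mat_start[i] - tr$pre_start[i] + 1L
    else tr$pre_end[i] - tr$mat_end[i] + 1L
    ds <- duplex_stats(tr$precursor_seq[i], f$structure[i], mstart,
                       mstart + nchar(tr$mature_seq[i]) - 1L)
    expect_true(is.na(ds$reject))
    expect_gt(ds$matched_pairs, 16)
    expect_lte(ds$size_diff, 4)
  }
})

test_that("a designed zero stays a true zero in the reads", {
  d <- noiseless_design(41)
  sim <- simulate_all(d)
  tr <- sim$truth$planted_mirnas
  zero_rows <- which(tr$tpm_hpr == 0)
  expect_gt(length(zero_rows), 0)
  for (i in zero_rows) {
    expect_false(any(grepl(tr$mature_seq[i], sim$reads$HPR$seq, fixed = TRUE)))
  }
})

test_that("with zero dispersion counts fall in the Poisson 99% band", {
  expr <- matrix(c(500, 500, 500, 500), 1,
                 dimnames = list("mir01", c("HPL", "LPL", "HPR", "LPR")))
  d <- simulation_design(seed = 6, n_hairpins = 1, n_decoy_loci = 2,
                         genome_length = 20000, expression = expr,
                         library_depths = c(HPL = 1e5, LPL = 1e5, HPR = 1e5,
                                            LPR = 1e5),
                         dispersion = 0, background_scale = 0, n_targets = 1)
  g <- generate_genome(d)
  reads <- simulate_small_rna_libraries(d, g$truth, g$genome, g$annotation)
  mu <- 1e5 * 500 / 1e6
  band <- qpois(c(0.005, 0.995), mu)
  for (lib in names(reads)) {
    n <- sum(grepl(g$truth$planted_mirnas$mature_seq[1], reads[[lib]]$seq,
                   fixed = TRUE))
    expect_gte(n, band[1])
    expect_lte(n, band[2])
  }
})

test_that("degradome tags start at planted cleavage positions", {
  sim <- simulate_all(noiseless_design(51))
  tt <- sim$truth$planted_targets
  # truth convention: cleavage opposite miRNA nt 10, i.e. site_end - 9
  expect_equal(tt$cleavage_pos, tt$site_end - 9L)
  deg <- degradome_prep(sim$degradome_reads, sim$design$adapter3,
                        sim$transcriptome)
  for (i in seq_len(nrow(tt))) {
    on_tx <- deg$hits[deg$hits$transcript == tt$transcript[i], ]
    counts <- deg$tags$count[match(on_tx$sequence, deg$tags$sequence)]
    dominant <- on_tx$pos[which.max(counts)]
    expect_equal(dominant, tt$cleavage_pos[i])
  }
  # cleavage position beyond the transcript end raises a generation error
  bad_truth <- sim$truth
  bad_truth$planted_targets$cleavage_pos[1] <- 5000L
  expect_error(simulate_degradome(sim$design, bad_truth, sim$transcriptome),
               "outside transcript")
})

test_that("background degradome tags never dominate a signal-free transcript", {
  d <- noiseless_design(61)
  d$degradome_background <- 0.5
  sim <- simulate_all(d)
  deg <- degradome_prep(sim$degradome_reads, d$adapter3, sim$transcriptome)
  bg_tx <- grep("^bg", names(sim$transcriptome), value = TRUE)
  h <- deg$hits[deg$hits$transcript %in% bg_tx, ]
  if (nrow(h)) {
    counts <- deg$tags$count[match(h$sequence, deg$tags$sequence)]
    per_pos <- tapply(counts, paste(h$transcript, h$pos), sum)
    # a uniform background should never concentrate half its tags on one spot
    expect_lt(max(per_pos) / sum(counts), 0.5)
  }
  succeed()
})

test_that("promoter planting is exact and the background is motif-free", {
  d <- noiseless_design(71, n_hairpins = 4)
  d$n_promoter_motifs <- 3
  g <- generate_genome(d)
  pr <- plant_promoters(d, g$truth)
  hits <- scan_promoters(pr$promoters, default_motif_table())
  planted <- pr$truth$planted_motifs
  # the full scan finds exactly the planted occurrences (palindromic
  # patterns are reported once per strand over the same span), nothing else
  key <- function(df) sort(unique(paste(df$gene, df$element, df$offset)))
  expect_equal(key(hits), key(planted))
  # zero planted motifs -> zero hits
  d0 <- noiseless_design(72, n_hairpins = 2)
  d0$n_promoter_motifs <- 0
  g0 <- generate_genome(d0)
  pr0 <- plant_promoters(d0, g0$truth)
  expect_equal(nrow(scan_promoters(pr0$promoters, default_motif_table())), 0)
})

test_that("clean-read totals reconcile with planted plus background reads", {
  d <- noiseless_design(81, n_hairpins = 4)
  d$background_scale <- 1
  sim <- simulate_all(d)
  cl <- clean_reads(sim$reads$HPL, d$adapter3)
  s <- cl$stats
  expect_equal(unname(s[["total"]]),
               unname(s[["clean"]] + s[["low_quality"]] + s[["no_adapter"]] +
                        s[["adapter_only"]] + s[["too_short"]] + s[["too_long"]]))
  # clean totals land near the designed depth
  expect_gt(s[["clean"]], 0.9 * d$library_depths[["HPL"]])
  expect_lt(s[["clean"]], 1.1 * d$library_depths[["HPL"]])
})
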