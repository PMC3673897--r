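# a hand-built precursor: 21-nt mature fully paired, 15-nt loop
toy_hairpin <- function() {
  mature <- "TGACAGAAGAGAGTGAGCACA"
  ext <- "GGATCCGGATCC"
  stemA <- paste0(ext, mature)
  list(mature = mature,
       precursor = paste0(stemA, strrep("A", 15), revcomp(stemA)),
       structure = paste0(strrep("(", 33), strrep(".", 15), strrep(")", 33)),
       mstart = 13L, mend = 33L)
}

test_that("duplex_stats infers the star with a 2-nt 3' overhang", {
  hp <- toy_hairpin()
  ds <- duplex_stats(hp$precursor, hp$structure, hp$mstart, hp$mend)
  expect_true(is.na(ds$reject))
  expect_equal(ds$matched_pairs, 21)
  expect_equal(ds$size_diff, 0)
  expect_equal(ds$arm, "5p")
  expect_equal(nchar(ds$star_seq), 21)
  # the star (minus its 2-nt overhang) is the reverse complement of the
  # mature's pairing region (mature positions 1..19)
  core <- substr(ds$star_seq, 1, 19)
  expect_equal(core, revcomp(substr(hp$mature, 1, 19)))
})

test_that("unpaired mature positions lower matched_pairs below the rule", {
  hp <- toy_hairpin()
  v <- strsplit(hp$structure, "")[[1]]
  # unpair 6 mature positions (and their partners)
  for (i in hp$mstart + c(2, 5, 8, 11, 14, 17)) {
    p <- pairing_table(paste(v, collapse = ""))
    v[p[i]] <- "."
    v[i] <- "."
  }
  ds <- duplex_stats(hp$precursor, paste(v, collapse = ""), hp$mstart, hp$mend)
  expect_equal(ds$matched_pairs, 15)
  cfg <- discovery_config()
  expect_false(ds$matched_pairs > cfg$min_matched_pairs)
})

test_that("a mature spanning the loop is rejected", {
  hp <- toy_hairpin()
  ds <- duplex_stats(hp$precursor, hp$structure, 30L, 52L)
  expect_equal(ds$reject, "loop_spanning")
  flat <- duplex_stats(hp$precursor, strrep(".", nchar(hp$precursor)),
                       hp$mstart, hp$mend)
  expect_equal(flat$reject, "no_duplex")
})

test_that("criteria use the stated threshold semantics", {
  cand <- list(mfe = -40, mfei = 1.2, mature_len = 21, single_stem = TRUE,
               star_detected = TRUE, arm_balance = 0.95)
  cfg <- discovery_config()
  # TPM of exactly 100 passes ("at least 100")
  f <- apply_criteria(cand, c(100, 0, 0, 0), cfg)
  expect_true(f[["c1"]])
  expect_false(apply_criteria(cand, c(99.9, 0, 0, 0), cfg)[["c1"]])
  # MFE of exactly -37 fails (strictly "lower than")
  cand$mfe <- -37.0
  expect_false(apply_criteria(cand, c(200, 0, 0, 0), cfg)[["c4"]])
  cand$mfe <- -37.01
  expect_true(apply_criteria(cand, c(200, 0, 0, 0), cfg)[["c4"]])
  # MFEI of exactly 0.85 fails (strictly "higher than")
  cand$mfei <- 0.85
  expect_false(apply_criteria(cand, c(200, 0, 0, 0), cfg)[["c5"]])
  # arm ratio modes
  cand$mfei <- 1.2
  cand$arm_balance <- 0.5
  expect_true(apply_criteria(cand, 200, cfg)[["c2"]])
  strict <- discovery_config(arm_ratio_mode = "min_over_max")
  expect_false(apply_criteria(cand, 200, strict)[["c2"]])
  cand$arm_balance <- 0.95
  expect_true(apply_criteria(cand, 200, strict)[["c2"]])
  expect_error(apply_criteria(cand, numeric(0), cfg), "expression")
})

test_that("conservation classing follows family species membership", {
  cat <- reference_catalog()
  # exact same-species match is known
  k <- classify_conservation("TCGGACCAGGCTTCATTCCCC", cat)
  expect_equal(k$class, "known")
  expect_equal(k$family, "MIR166")
  # one substitution away from a legume-only family member
  m1507 <- "TCTCATTCCATACATCGTCTGA"
  substr(m1507, 4, 4) <- "A"
  lc <- classify_conservation(m1507, cat)
  expect_equal(lc$class, "less_conserved")
  expect_equal(lc$family, "MIR1507")
  # one substitution away from a family present in non-legumes
  m156 <- "TTGACAGAAGATAGAGAGCAC"
  substr(m156, 5, 5) <- "T"
  expect_equal(classify_conservation(m156, cat)$class, "conserved")
  # no family match
  expect_equal(classify_conservation(strrep("AC", 10), cat)$class, "novel")
  expect_warning(out <- classify_conservation("ACGT", cat[0, ]), "empty")
  expect_equal(out$class, "novel")
})

test_that("extract_windows clips at chromosome ends and honours strand", {
  g <- c(chr1 = paste(rep(c("A", "C", "G", "T"), 250), collapse = ""))
  loc <- list(chrom = "chr1", start = 5, end = 25, strand = "+")
  w <- extract_windows(loc, g, flank = 200)
  expect_equal(w$start[w$window == "upstream"], 1)  # clipped, no error
  expect_equal(w$end[w$window == "downstream"], 225)
  minus <- extract_windows(list(chrom = "chr1", start = 401, end = 421,
                                strand = "-"), g, flank = 50)
  plus <- extract_windows(list(chrom = "chr1", start = 401, end = 421,
                               strand = "+"), g, flank = 50)
  expect_equal(minus$seq[minus$window == "centered"],
               revcomp(plus$seq[plus$window == "centered"]))
  expect_error(extract_windows(list(chrom = "chr1", start = 999, end = 1020,
                                    strand = "+"), g), "bounds")
})

test_that("windows around a planted locus contain the full precursor", {
  d <- noiseless_design(5, n_hairpins = 4)
  g <- generate_genome(d)
  tr <- g$truth$planted_mirnas
  for (i in seq_len(nrow(tr))) {
    w <- extract_windows(list(chrom = tr$chrom[i], start = tr$mat_start[i],
                              end = tr$mat_end[i], strand = tr$strand[i]),
                         g$genome, flank = 200)
    expect_true(any(vapply(w$seq, grepl, logical(1),
                           pattern = tr$precursor_seq[i], fixed = TRUE)))
  }
})

test_that("noiseless discovery recovers planted hairpins exactly", {
  sim <- simulate_all(noiseless_design(101))
  res <- run_discovery(sim)
  cand <- res$candidates
  truth <- sim$truth$planted_mirnas
  pass <- cand[cand$pass, ]
  # recall on planted matures
  expect_gte(mean(truth$mature_seq %in% pass$sequence), 0.95)
  # precision against decoys: every passing candidate overlaps a planted
  # precursor locus
  on_planted <- vapply(seq_len(nrow(pass)), function(i) {
    any(truth$chrom == pass$chrom[i] & truth$pre_start <= pass$end[i] &
          truth$pre_end >= pass$start[i])
  }, logical(1))
  expect_true(all(on_planted))
  # inferred stars agree with the designed stars
  idx <- match(truth$mature_seq, cand$sequence)
  agree <- cand$star_seq[idx] == truth$star_seq
  expect_gte(mean(agree, na.rm = TRUE), 0.95)
})

test_that("every emitted record's precursor refolds as a single-stem hairpin", {
  sim <- simulate_all(noiseless_design(77, n_hairpins = 5))
  cand <- run_discovery(sim)$candidates
  pass <- cand[cand$pass, ]
  refold <- fold(pass$precursor_seq)
  expect_true(all(is_single_stem(refold$structure)))
  # stored MFEI is recomputable from stored fields
  expect_equal(pass$mfei,
               (abs(pass$mfe) / nchar(pass$precursor_seq) * 100) / pass$gc_pct,
               tolerance = 1e-9)
})

test_that("tightening thresholds never increases the passing set", {
  sim <- simulate_all(noiseless_design(55, n_hairpins = 6))
  res <- run_discovery(sim)
  cand <- res$candidates
  base_cfg <- discovery_config()
  tpm_cols <- grep("^tpm_", names(cand), value = TRUE)
  passes <- function(cfg) {
    vapply(seq_len(nrow(cand)), function(i) {
      apply_criteria(cand[i, ], as.numeric(cand[i, tpm_cols]), cfg)[["pass"]]
    }, logical(1))
  }
  base <- passes(base_cfg)
  for (cfg in list(discovery_config(min_tpm = 500),
                   discovery_config(max_mfe = -45),
                   discovery_config(min_mfei = 1.1),
                   discovery_config(mature_len = c(21, 22)))) {
    tightened <- passes(cfg)
    expect_true(all(!tightened | base))  # tightened set is a subset
    expect_lte(sum(tightened), sum(base))
  }
})

test_that("discovery returns an empty catalog when nothing qualifies", {
  d <- simulation_design(seed = 3, n_hairpins = 0, n_decoy_loci = 5,
                         genome_length = 20000,
                         library_depths = c(HPL = 2e4, LPL = 2e4, HPR = 2e4,
                                            LPR = 2e4),
                         expression = default_expression_design(0),
                         n_targets = 0)
  g <- generate_genome(d)
  reads <- simulate_small_rna_libraries(d, g$truth, g$genome, g$annotation)
  cleaned <- lapply(reads, clean_reads, adapter3 = d$adapter3)
  tags <- collapse_tags(lapply(cleaned, `[[`, "tags"))
  clean_tot <- vapply(cleaned, function(x) x$stats[["clean"]], numeric(1))
  cand <- discover_mirnas(tags, build_index(g$genome), g$annotation,
                          clean_tot, reference_catalog())
  expect_equal(sum(cand$pass), 0)
})
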