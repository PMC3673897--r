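test_that("pair_score is zero for a perfect site and weights positions 2-13", {
  m <- "TGACAGAAGAGAGTGAGCACA"
  expect_equal(pair_score(m, revcomp(m))$score, 0)
  # one mismatch opposite miRNA position 15: penalty 1
  s <- revcomp(m)
  L <- nchar(m)
  flip_at <- function(site, j) {
    # set the site base pairing miRNA position j to a non-pairing base
    i <- L - j + 1
    mb <- substr(m, j, j)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", mb),
                     if (mb == "G") "T", if (mb == "T") "G"))[1]
    substr(site, i, i) <- bad
    site
  }
  expect_equal(pair_score(m, flip_at(s, 15))$score, 1)
  expect_equal(pair_score(m, flip_at(s, 5))$score, 2)
  # G:U wobble costs half a mismatch (position 1 is unweighted: m[1]=T -> G)
  s_wob <- s
  substr(s_wob, L, L) <- "G"
  expect_equal(pair_score(m, s_wob)$score, 0.5)
  expect_error(pair_score(m, substr(s, 1, 10)), "length")
})

test_that("pair_score equals a naive oracle over 1- and 2-edit neighbourhoods", {
  set.seed(17)
  m <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  site0 <- revcomp(m)
  bases <- c("A", "C", "G", "T")
  sites <- character(0)
  for (i in 1:21) for (b in bases) {
    s1 <- site0; substr(s1, i, i) <- b
    sites <- c(sites, s1)
  }
  set.seed(18)
  for (k in 1:150) {  # sampled 2-edit neighbourhood
    ij <- sample(21, 2)
    s2 <- site0
    substr(s2, ij[1], ij[1]) <- sample(bases, 1)
    substr(s2, ij[2], ij[2]) <- sample(bases, 1)
    sites <- c(sites, s2)
  }
  for (s in unique(sites)) {
    expect_equal(pair_score(m, s)$score, naive_pair_score(m, s))
  }
})

test_that("adding an edit never decreases the score", {
  set.seed(19)
  m <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  site0 <- revcomp(m)
  for (k in 1:50) {
    i <- sample(21, 1)
    b <- sample(c("A", "C", "G", "T"), 1)
    s1 <- site0; substr(s1, i, i) <- b
    base <- pair_score(m, s1)$score
    j <- sample(setdiff(1:21, i), 1)
    s2 <- s1; substr(s2, j, j) <- sample(c("A", "C", "G", "T"), 1)
    expect_gte(pair_score(m, s2)$score, base - 1e-9)
  }
})

test_that("degradome prep filters polyN tags and normalises to RP10M", {
  # 20-nt tag with 15 As (75% > 70%) is polyN; an even tag is kept
  polyn <- paste0(strrep("A", 15), "CGTCG")
  keep <- "ACGTACGTACGTACGTACGT"
  tx <- c(tx1 = paste0(strrep("C", 50), keep, strrep("G", 50)))
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  reads <- c(rep(paste0(polyn, adapter), 3), rep(paste0(keep, adapter), 5))
  deg <- degradome_prep(reads, adapter, tx)
  expect_equal(deg$tags$sequence, keep)
  expect_equal(unname(deg$stats[["polyn_removed"]]), 1)
  # rp10m = count / clean x 1e7: 5 / 8 clean reads
  expect_equal(deg$tags$rp10m, 5 / 8 * 1e7)
  expect_equal(deg$hits$pos, 51)
  expect_error(degradome_prep(reads, adapter, character(0)), "transcriptome")
})

test_that("rp10m arithmetic matches the definition", {
  expect_equal(25 / 25e6 * 1e7, 10)
})

test_that("degradome tag mapping agrees with a brute-force remap", {
  set.seed(23)
  tx <- setNames(vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""),
    character(1)), paste0("t", 1:4))
  tags <- c(substr(tx[[1]], 50, 69), substr(tx[[2]], 100, 120),
            substr(tx[[3]], 1, 20))
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  deg <- degradome_prep(paste0(tags, adapter), adapter, tx)
  for (i in seq_len(nrow(deg$hits))) {
    h <- deg$hits[i, ]
    expect_equal(substr(tx[[h$transcript]], h$pos,
                        h$pos + nchar(h$sequence) - 1), h$sequence)
  }
  # every occurrence is found
  for (tg in deg$tags$sequence) {
    n_oracle <- sum(vapply(tx, function(s) {
      length(gregexpr(tg, s, fixed = TRUE)[[1]][gregexpr(tg, s,
                                                         fixed = TRUE)[[1]] > 0])
    }, numeric(1)))
    expect_equal(sum(deg$hits$sequence == tg), n_oracle)
  }
})

make_target_fixture <- function(mismatch_at = NULL) {
  m <- "TGACAGAAGAGAGTGAGCACA"          # 21 nt
  site <- revcomp(m)
  if (!is.null(mismatch_at)) {
    i <- nchar(m) - mismatch_at + 1
    mb <- substr(m, mismatch_at, mismatch_at)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", mb),
                     if (mb == "G") "T", if (mb == "T") "G"))[1]
    substr(site, i, i) <- bad
  }
  tx <- paste0(strrep("C", 99), site, strrep("G", 150))
  list(mirna = m, site = site, tx = c(tx1 = tx),
       site_start = 100L, cleavage = 100L + 21L - 10L)
}

test_that("call_targets requires score, 10/11 pairing and degradome support", {
  fx <- make_target_fixture()
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  tag <- substr(fx$tx[[1]], fx$cleavage, fx$cleavage + 20)
  deg <- degradome_prep(rep(paste0(tag, adapter), 10), adapter, fx$tx)
  cds <- data.frame(transcript = "tx1", cds_start = 50, cds_end = 250)
  hits <- call_targets(c(mirX = fx$mirna), fx$tx, deg, cds)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$cleavage_pos, fx$cleavage)
  expect_equal(hits$site_start, fx$site_start)
  expect_equal(hits$region, "CDS")
  expect_gt(hits$rp10m, 0)
  # mismatch at miRNA position 10 kills the hit regardless of signal
  fx10 <- make_target_fixture(mismatch_at = 10)
  deg10 <- degradome_prep(rep(paste0(substr(fx10$tx[[1]], fx10$cleavage,
                                            fx10$cleavage + 20), adapter), 10),
                          adapter, fx10$tx)
  expect_equal(nrow(call_targets(c(mirX = fx10$mirna), fx10$tx, deg10, cds)), 0)
  # without a degradome tag at the cleavage position there is no hit
  offdeg <- degradome_prep(rep(paste0(substr(fx$tx[[1]], 10, 30), adapter), 10),
                           adapter, fx$tx)
  expect_equal(nrow(call_targets(c(mirX = fx$mirna), fx$tx, offdeg, cds)), 0)
})

test_that("the score cap is inclusive at 7 and exclusive above", {
  fx <- make_target_fixture()
  m <- fx$mirna
  site <- revcomp(m)
  # build a site scoring exactly 7: mismatches opposite positions 3 (2),
  # 7 (2), 9 (2) and 16 (1)
  flip <- function(site, j, wobble = FALSE) {
    i <- nchar(m) - j + 1
    mb <- substr(m, j, j)
    repl <- if (wobble) {
      if (mb == "G") "T" else if (mb == "T") "G" else NA
    } else setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", mb),
                     if (mb == "G") "T", if (mb == "T") "G"))[1]
    substr(site, i, i) <- repl
    site
  }
  s7 <- flip(flip(flip(flip(site, 3), 7), 9), 16)
  expect_equal(pair_score(m, s7)$score, 7)
  tx7 <- c(tx7 = paste0(strrep("C", 99), s7, strrep("G", 99)))
  expect_equal(nrow(predict_targets(c(mir = m), tx7)), 1)
  # one extra mismatch at position 17 pushes the score to 8
  s8 <- flip(s7, 17)
  expect_equal(pair_score(m, s8)$score, 8)
  tx8 <- c(tx8 = paste0(strrep("C", 99), s8, strrep("G", 99)))
  expect_equal(nrow(predict_targets(c(mir = m), tx8)), 0)
})

test_that("degradome-mode hits are a subset of predicted-mode hits", {
  sim <- simulate_all(noiseless_design(303))
  truth <- sim$truth$planted_mirnas
  mirs <- setNames(truth$mature_seq, truth$id)
  deg <- degradome_prep(sim$degradome_reads, sim$design$adapter3,
                        sim$transcriptome)
  d_hits <- call_targets(mirs, sim$transcriptome, deg, sim$cds)
  p_hits <- predict_targets(mirs, sim$transcriptome, sim$cds)
  dk <- paste(d_hits$mirna, d_hits$transcript, d_hits$site_start)
  pk <- paste(p_hits$mirna, p_hits$transcript, p_hits$site_start)
  expect_true(all(dk %in% pk))
  # every planted target site is recovered with the right cleavage position
  tt <- sim$truth$planted_targets
  for (i in seq_len(nrow(tt))) {
    sel <- d_hits$mirna == tt$mirna[i] & d_hits$transcript == tt$transcript[i]
    expect_true(any(sel))
    expect_true(tt$cleavage_pos[i] %in% d_hits$cleavage_pos[sel])
  }
  # degradome support invariant: a tag 5' end sits at every called position
  for (i in seq_len(nrow(d_hits))) {
    expect_true(any(deg$hits$transcript == d_hits$transcript[i] &
                      deg$hits$pos == d_hits$cleavage_pos[i]))
  }
})

test_that("locate_site honours CDS boundaries inclusively", {
  expect_equal(locate_site(150, 150, 1050), "CDS")   # start is inclusive
  expect_equal(locate_site(1050, 150, 1050), "CDS")  # end is inclusive
  expect_equal(locate_site(149, 150, 1050), "5UTR")
  expect_equal(locate_site(1051, 150, 1050), "3UTR")
  expect_equal(locate_site(100, NA, NA), "unknown")
  # a PHO2-like 5'UTR site
  expect_equal(locate_site(1050, 1500, 3000), "5UTR")
})

test_that("region proportions reproduce a fixed-count summary", {
  regions <- c(rep("CDS", 182), rep("5UTR", 6), rep("3UTR", 4))
  rp <- region_proportions(regions)
  expect_equal(rp$pct[rp$region == "CDS"], 94.8)
  expect_equal(sum(rp$n), 192)
})

test_that("target mimics are detected and never called as targets", {
  m <- "TGACAGAAGAGAGTGAGCACA"
  L <- nchar(m)
  rc <- revcomp(m)
  mimic_site <- paste0(substr(rc, 1, L - 10), "CTA", substr(rc, L - 9, L))
  seq <- paste0(strrep("G", 80), mimic_site, strrep("C", 80))
  hits <- detect_mimic(seq, m)
  expect_gte(nrow(hits), 1)
  best <- hits[which.min(hits$score), ]
  expect_equal(best$site_start, 81)
  expect_equal(best$bulge_len, 3)
  expect_equal(best$bulge_after, 10)
  expect_equal(best$score, 0)
  # a perfect complement with no bulge is a cleavable site, not a mimic
  clean <- paste0(strrep("G", 80), rc, strrep("C", 80))
  expect_equal(nrow(detect_mimic(clean, m)), 0)
  # and the mimic is never returned by the target caller
  tx <- c(mimic = seq)
  expect_equal(nrow(predict_targets(c(mir = m), tx)), 0)
})

test_that("mimic detection equals a brute-force bulged-alignment enumeration", {
  set.seed(29)
  m <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  L <- nchar(m)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  rc <- revcomp(m)
  ins_at <- sample(100:300, 1)
  substr(seq, ins_at, ins_at + L + 1) <- paste0(substr(rc, 1, L - 9), "GG",
                                                substr(rc, L - 8, L))
  got <- detect_mimic(seq, m)
  # oracle: enumerate every start, bulge length and split point
  oracle <- 0
  sv <- strsplit(seq, "")[[1]]
  mv <- strsplit(m, "")[[1]]
  for (b in 2:4) for (k in 9:11) {
    span <- L + b
    for (p in seq_len(nchar(seq) - span + 1)) {
      sc <- 0
      for (j in seq_len(L)) {
        tb <- sv[p + L - j + if (j <= k) b else 0]
        pen <- if (tb == chartr("ACGT", "TGCA", mv[j])) 0
        else if ((mv[j] == "G" && tb == "T") ||
                   (mv[j] == "T" && tb == "G")) 0.5 else 1
        sc <- sc + pen * if (j >= 2 && j <= 13) 2 else 1
      }
      if (sc <= 7) oracle <- oracle + 1
    }
  }
  expect_equal(nrow(got), oracle)
  expect_gte(nrow(got), 1)   # the planted bulged site is found
})
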