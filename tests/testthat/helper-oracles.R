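# Independent oracles used across the suite. These are deliberately naive
# re-implementations kept free of the package's code paths.

# brute-force exact-match scan of a tag over every position of every
# chromosome, both strands
naive_scan <- function(genome, tag) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
  out <- list()
  for (ch in names(genome)) {
    s <- genome[[ch]]
    L <- nchar(tag)
    for (i in seq_len(max(0, nchar(s) - L + 1))) {
      sub <- substr(s, i, i + L - 1)
      if (sub == tag) {
        out[[length(out) + 1]] <- data.frame(tag = tag, chrom = ch, start = i,
                                             end = i + L - 1, strand = "+",
                                             stringsAsFactors = FALSE)
      }
      if (sub == rc) {
        out[[length(out) + 1]] <- data.frame(tag = tag, chrom = ch, start = i,
                                             end = i + L - 1, strand = "-",
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(tag = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), stringsAsFactors = FALSE)
}

# independent penalty-sum scorer: explicit position loop, complement via
# chartr, no shared lookup tables
naive_pair_score <- function(mirna, site) {
  m <- strsplit(toupper(chartr("U", "T", mirna)), "")[[1]]
  s <- strsplit(toupper(chartr("U", "T", site)), "")[[1]]
  stopifnot(length(m) == length(s))
  L <- length(m)
  total <- 0
  for (j in seq_len(L)) {
    tb <- s[L - j + 1]
    p <- if (tb == chartr("ACGT", "TGCA", m[j])) 0
    else if ((m[j] == "G" && tb == "T") || (m[j] == "T" && tb == "G")) 0.5
    else 1
    if (j >= 2 && j <= 13) p <- 2 * p
    total <- total + p
  }
  total
}

# energy of a given structure on a given sequence, via RNAeval
rnaeval_energy <- function(seq, structure) {
  rna <- gsub("T", "U", toupper(seq), fixed = TRUE)
  inp <- tempfile()
  on.exit(unlink(inp))
  writeLines(c(rna, structure), inp)
  out <- system2(Sys.which("RNAeval"), stdin = inp, stdout = TRUE,
                 stderr = FALSE)
  line <- out[grepl("^[.()]+\\s+\\(", out)][1]
  as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
}

# a small, fast noiseless design shared by recovery tests
noiseless_design <- function(seed, n_hairpins = 8) {
  simulation_design(seed = seed, n_hairpins = n_hairpins, n_decoy_loci = 6,
                    genome_length = 40000,
                    library_depths = c(HPL = 1e5, LPL = 1e5, HPR = 1e5,
                                       LPR = 1e5),
                    dispersion = 0, degradome_background = 0,
                    n_targets = 6)
}

run_discovery <- function(sim) {
  cleaned <- lapply(sim$reads, clean_reads, adapter3 = sim$design$adapter3)
  tags <- collapse_tags(lapply(cleaned, `[[`, "tags"))
  clean_tot <- vapply(cleaned, function(x) x$stats[["clean"]], numeric(1))
  idx <- build_index(sim$genome)
  list(tags = tags, clean_tot = clean_tot, index = idx,
       candidates = discover_mirnas(tags, idx, sim$annotation, clean_tot,
                                    reference_catalog()))
}
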