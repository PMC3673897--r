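#' Round half away from zero
#'
#' Percentages in library reports are rounded half-up (commercial rounding),
#' not banker's rounding, so that recomputed report fields match the printed
#' two-decimal convention.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * trunc(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage of a numerator over a denominator
#'
#' @param num numerator count
#' @param den denominator count
#' @param digits decimal places (default 2)
#' @return percentage rounded half-up, or `NA_real_` when the denominator is
#'   zero (undefined, never reported as 0)
#' @export
pct <- function(num, den, digits = 2) {
  out <- round_half_up(100 * num / den, digits)
  out[rep_len(den == 0, length(out))] <- NA_real_
  out
}

# Normalise a nucleotide string: uppercase, RNA -> DNA alphabet.
dna_norm <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

# Validate sequences over the strict DNA alphabet after normalisation.
assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", dna_norm(x))
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGTU characters: %s",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences (T/U accepted)
#' @return character vector of reverse complements (DNA alphabet)
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna_norm(x))))
}

# Random DNA of given lengths under the current RNG stream (one draw for
# the whole batch, so it stays fast for hundreds of thousands of reads).
random_dna <- function(n, gc = 0.5) {
  if (length(n) == 0 || sum(n) == 0) return(rep("", length(n)))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(names(p), sum(n), replace = TRUE, prob = p)
  big <- paste(chars, collapse = "")
  ends <- cumsum(n)
  substring(big, ends - n + 1, ends)
}

#' GC content of sequences, in percent
#'
#' @param x character vector of sequences
#' @return numeric vector, percent GC (0-100)
#' @export
gc_percent <- function(x) {
  x <- dna_norm(x)
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  ifelse(n == 0, NA_real_, 100 * gc / n)
}

# Derive a reproducible sub-seed from a base seed, kept under 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483587L
}
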