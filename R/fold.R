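#' Fold RNA sequences with RNAfold
#'
#' Thin wrapper around the ViennaRNA `RNAfold` command-line tool. Sequences
#' are folded as RNA (T is transcribed to U on the way in); the returned
#' minimum free energy is in kcal/mol and is non-positive whenever at least
#' one canonical pair can form.
#'
#' @param seqs character vector of sequences (DNA or RNA alphabet)
#' @return data.frame with columns `seq`, `structure` (dot-bracket) and
#'   `mfe` (kcal/mol)
#' @export
fold <- function(seqs) {
  if (length(seqs) == 0) {
    return(data.frame(seq = character(), structure = character(),
                      mfe = numeric(), stringsAsFactors = FALSE))
  }
  seqs <- dna_norm(seqs)
  assert_dna(seqs, "fold() input")
  rna <- gsub("T", "U", seqs, fixed = TRUE)
  out <- run_rnafold(rna)
  # RNAfold echoes: name line (if any), sequence, "structure (energy)"
  hit <- grepl("^[.()]+\\s+\\(", out)
  res <- out[hit]
  if (length(res) != length(seqs)) {
    stop("RNAfold returned ", length(res), " structures for ",
         length(seqs), " sequences", call. = FALSE)
  }
  structure <- sub("^([.()]+).*$", "\\1", res)
  mfe <- as.numeric(sub("^[.()]+\\s+\\(\\s*(-?[0-9.]+)\\)$", "\\1", res))
  check_balanced(structure)
  data.frame(seq = seqs, structure = structure, mfe = mfe,
             stringsAsFactors = FALSE)
}

run_rnafold <- function(rna_seqs) {
  exe <- Sys.which("RNAfold")
  if (exe == "") stop("RNAfold not found on PATH", call. = FALSE)
  inp <- tempfile(fileext = ".fa")
  on.exit(unlink(inp), add = TRUE)
  writeLines(rna_seqs, inp)
  out <- system2(exe, c("--noPS"), stdin = inp, stdout = TRUE, stderr = FALSE)
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
    stop("RNAfold failed with status ", attr(out, "status"), call. = FALSE)
  }
  out
}

check_balanced <- function(structure) {
  for (s in structure) {
    v <- strsplit(s, "")[[1]]
    depth <- cumsum((v == "(") - (v == ")"))
    if (any(depth < 0) || depth[length(depth)] != 0) {
      stop("unbalanced dot-bracket structure from folding engine", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Test whether a dot-bracket structure is a single-stem hairpin
#'
#' A precursor qualifies when its structure contains exactly one hairpin
#' loop, i.e. no multiloop branching: after removing unpaired positions the
#' bracket string never closes and reopens (")(" never occurs).
#'
#' @param structure dot-bracket string(s)
#' @return logical vector
#' @export
is_single_stem <- function(structure) {
  brackets <- gsub(".", "", structure, fixed = TRUE)
  nchar(brackets) > 0 & !grepl(")(", brackets, fixed = TRUE)
}

#' Pairing table from a dot-bracket structure
#'
#' @param structure a single dot-bracket string
#' @return integer vector p where p[i] is the position paired with i, or 0
#'   when i is unpaired
#' @export
pairing_table <- function(structure) {
  v <- strsplit(structure, "")[[1]]
  p <- integer(length(v))
  stack <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] == "(") {
      stack <- c(stack, i)
    } else if (v[i] == ")") {
      if (length(stack) == 0) stop("unbalanced structure", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced structure", call. = FALSE)
  p
}

#' Minimal free energy index (MFEI) of a hairpin
#'
#' MFEI = (|MFE| / length x 100) / GC%, the hairpin-quality statistic that
#' separates miRNA precursors from other small-RNA-producing loci. The
#' numerator |MFE|/length x 100 is the adjusted MFE (AMFE).
#'
#' @param mfe minimum free energy (kcal/mol, <= 0)
#' @param seq precursor sequence
#' @return MFEI (dimensionless); `NA_real_` when GC% is zero (the candidate
#'   then fails the MFEI criterion)
#' @export
compute_mfei <- function(mfe, seq) {
  stopifnot(length(mfe) == length(seq))
  len <- nchar(seq)
  if (any(len == 0)) stop("empty sequence", call. = FALSE)
  gc <- gc_percent(seq)
  amfe <- abs(mfe) / len * 100
  ifelse(gc == 0, NA_real_, amfe / gc)
}
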