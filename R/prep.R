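#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ file (plain or gzip)
#' @return data.frame with columns `seq` and `qual` (character)
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to a FASTQ file
#'
#' @param seqs character vector of read sequences
#' @param path output file
#' @param qual quality characters; a single character is recycled per base
#' @param ids read identifiers (default `read1..readN`)
#' @export
write_fastq <- function(seqs, path, qual = "I", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(seqs))
  quals <- if (length(qual) == 1 && nchar(qual) == 1) {
    vapply(nchar(seqs), function(n) strrep(qual, n), character(1))
  } else qual
  out <- character(4 * length(seqs))
  if (length(seqs)) {
    out[seq(1, length(out), 4)] <- paste0("@", ids)
    out[seq(2, length(out), 4)] <- seqs
    out[seq(3, length(out), 4)] <- "+"
    out[seq(4, length(out), 4)] <- quals
  }
  writeLines(out, path)
  invisible(path)
}

mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (nchar(q) == 0) return(0)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Trim adapters and length-filter raw small RNA reads
#'
#' Reproduces the clean-read accounting of a small RNA library: reads are
#' first screened for quality (no N, mean Phred at or above `min_qual`), the
#' 3' adapter is located by exact match of its first `adapter_k` bases, and
#' the insert upstream of the adapter is kept when its length falls in
#' `[min_len, max_len]`. Reads without an adapter match, adapter-only reads
#' and out-of-window inserts are discarded and counted by reason.
#'
#' @param reads a data.frame from [read_fastq()] (columns `seq`, `qual`), a
#'   character vector of read sequences (assumed high quality), or a FASTQ
#'   path
#' @param adapter3 the 3' adapter sequence
#' @param min_len,max_len clean insert length window (defaults 18 and 31 nt)
#' @param adapter_k number of leading adapter bases matched exactly
#'   (default 8)
#' @param min_qual minimum mean Phred score for a high-quality read
#' @return list with `tags` (character vector of clean inserts, one entry
#'   per read) and `stats` (named counts: total, high_quality, low_quality,
#'   no_adapter, adapter_only, too_short, too_long, clean)
#' @export
clean_reads <- function(reads, adapter3, min_len = 18, max_len = 31,
                        adapter_k = 8, min_qual = 20) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.character(reads)) {
    reads <- data.frame(seq = reads, qual = NA_character_,
                        stringsAsFactors = FALSE)
  }
  stopifnot(nchar(adapter3) >= 1, min_len <= max_len)
  seqs <- dna_norm(reads$seq)
  total <- length(seqs)

  has_qual <- !all(is.na(reads$qual))
  hq <- if (has_qual) {
    !grepl("N", seqs, fixed = TRUE) & mean_phred(reads$qual) >= min_qual
  } else rep(TRUE, total)

  key <- substr(dna_norm(adapter3), 1, adapter_k)
  pos <- rep(-1L, total)
  pos[hq] <- as.integer(regexpr(key, seqs[hq], fixed = TRUE))

  insert_len <- ifelse(pos > 0, pos - 1L, NA_integer_)
  reason <- rep("clean", total)
  reason[!hq] <- "low_quality"
  reason[hq & pos < 0] <- "no_adapter"
  reason[hq & pos == 1] <- "adapter_only"
  short <- hq & pos > 1 & insert_len < min_len
  reason[short] <- "too_short"
  long <- hq & pos > 1 & insert_len > max_len
  reason[long] <- "too_long"

  keep <- reason == "clean"
  tags <- substr(seqs[keep], 1, insert_len[keep])
  stats <- c(total = total,
             high_quality = sum(hq),
             low_quality = sum(reason == "low_quality"),
             no_adapter = sum(reason == "no_adapter"),
             adapter_only = sum(reason == "adapter_only"),
             too_short = sum(reason == "too_short"),
             too_long = sum(reason == "too_long"),
             clean = sum(keep))
  list(tags = tags, stats = stats)
}

# FNV-1a 32-bit hash, used for stable tag identifiers. Arithmetic is done
# in doubles with a 16-bit split so the 32-bit product never loses precision
# (R has no unsigned 32-bit integers); vectorised over sequences, looping
# only over character positions.
fnv1a <- function(x) {
  n <- length(x)
  if (n == 0) return(character(0))
  prime <- 16777619
  L <- nchar(x)
  M <- matrix(0L, n, max(L))
  for (i in seq_len(n)) M[i, seq_len(L[i])] <- utf8ToInt(x[i])
  h <- rep(2166136261, n)
  for (j in seq_len(ncol(M))) {
    act <- j <= L
    if (!any(act)) break
    low <- h[act] %% 256
    h[act] <- h[act] - low + bitwXor(as.integer(low), M[act, j])
    h1 <- h[act] %/% 65536
    h0 <- h[act] %% 65536
    h[act] <- (((h1 * prime) %% 65536) * 65536 + h0 * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Collapse clean tags into unique sequences with per-library counts
#'
#' @param tag_lists named list (one element per library) of character
#'   vectors of clean tag sequences
#' @return data.frame with columns `id`, `sequence`, `length` and one count
#'   column per library; the column sum per library equals that library's
#'   clean-read count
#' @export
collapse_tags <- function(tag_lists) {
  stopifnot(is.list(tag_lists), !is.null(names(tag_lists)))
  all_seqs <- sort(unique(unlist(tag_lists, use.names = FALSE)))
  if (length(all_seqs) == 0) {
    df <- data.frame(id = character(), sequence = character(),
                     length = integer(), stringsAsFactors = FALSE)
    for (l in names(tag_lists)) df[[l]] <- integer()
    return(df)
  }
  counts <- vapply(tag_lists, function(tags) {
    tab <- table(factor(tags, levels = all_seqs))
    as.integer(tab)
  }, integer(length(all_seqs)))
  if (length(all_seqs) == 1) counts <- matrix(counts, nrow = 1,
                                              dimnames = list(NULL, names(tag_lists)))
  if (length(all_seqs) == 0) counts <- matrix(integer(0), nrow = 0, ncol = length(tag_lists),
                                              dimnames = list(NULL, names(tag_lists)))
  df <- data.frame(id = paste0("tag_", fnv1a(all_seqs)),
                   sequence = all_seqs,
                   length = nchar(all_seqs),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(counts))
}

count_columns <- function(tags) {
  setdiff(colnames(tags), c("id", "sequence", "length"))
}

#' Length distribution of collapsed tags
#'
#' @param tags collapsed tag data.frame from [collapse_tags()]
#' @param mode `"total"` weights each length bin by read counts (summed over
#'   libraries unless `library` is given); `"unique"` counts distinct
#'   sequences
#' @param library optional library name to restrict `"total"` mode to
#' @return data.frame with columns `length` and `frequency` (sums to 1)
#' @export
size_distribution <- function(tags, mode = c("total", "unique"), library = NULL) {
  mode <- match.arg(mode)
  if (nrow(tags) == 0) {
    return(data.frame(length = integer(), frequency = numeric()))
  }
  w <- if (mode == "unique") {
    rep(1, nrow(tags))
  } else if (is.null(library)) {
    rowSums(tags[, count_columns(tags), drop = FALSE])
  } else {
    tags[[library]]
  }
  agg <- tapply(w, tags$length, sum)
  data.frame(length = as.integer(names(agg)),
             frequency = as.numeric(agg) / sum(w),
             row.names = NULL)
}

#' First-nucleotide bias by tag length
#'
#' Computes, for each tag length, the percentage of tags starting with each
#' nucleotide. By default each distinct sequence counts once; with
#' `weighted = TRUE` tags are weighted by total read counts.
#'
#' @param tags collapsed tag data.frame
#' @param weighted weight by read counts instead of unique sequences
#' @return data.frame with columns `length`, `A`, `C`, `G`, `T` (percent;
#'   rows sum to 100)
#' @export
first_nt_bias <- function(tags, weighted = FALSE) {
  if (nrow(tags) == 0) {
    return(data.frame(length = integer(), A = numeric(), C = numeric(),
                      G = numeric(), T = numeric()))
  }
  first <- substr(tags$sequence, 1, 1)
  w <- if (weighted) rowSums(tags[, count_columns(tags), drop = FALSE]) else rep(1, nrow(tags))
  lens <- sort(unique(tags$length))
  rows <- lapply(lens, function(len) {
    sel <- tags$length == len
    tot <- sum(w[sel])
    p <- vapply(c("A", "C", "G", "T"),
                function(b) 100 * sum(w[sel & first == b]) / tot, numeric(1))
    data.frame(length = len, A = p["A"], C = p["C"], G = p["G"], T = p["T"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Per-library statistics table
#'
#' Assembles the standard library accounting: total, high-quality and clean
#' read counts with the clean percentage, genome-mapping rates for clean
#' reads and for unique tags. Percentages are recomputed from their
#' numerator/denominator pairs and rounded half-up to two decimals; a zero
#' denominator yields `NA` (undefined), never 0.
#'
#' @param counts data.frame with one row per library and columns `library`,
#'   `total_reads`, `high_quality_reads`, `too_short_reads`, `clean_reads`,
#'   `mapped_clean_reads`, `unique_tags`, `mapped_unique_tags`
#' @return the input with `clean_pct`, `mapped_clean_pct` and
#'   `mapped_unique_pct` columns added
#' @export
library_report <- function(counts) {
  need <- c("library", "total_reads", "high_quality_reads", "clean_reads",
            "mapped_clean_reads", "unique_tags", "mapped_unique_tags")
  missing <- setdiff(need, colnames(counts))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  counts$clean_pct <- pct(counts$clean_reads, counts$high_quality_reads)
  counts$mapped_clean_pct <- pct(counts$mapped_clean_reads, counts$clean_reads)
  counts$mapped_unique_pct <- pct(counts$mapped_unique_tags, counts$unique_tags)
  counts
}
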