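#' Default cis-element motif table
#'
#' Implementer-chosen IUPAC stand-ins for the element classes scanned in
#' phosphate-starvation promoter analysis (the element classes are standard;
#' these consensi are configurable defaults, not ground truth): P1BS/PHR1
#' binding site, W-box, TATA-box, an Inr-like TSS proxy, PHO and PHO-like
#' boxes, NIT2 and TC elements.
#'
#' @return data.frame with columns `name`, `pattern` (IUPAC), `strands`
#' @export
default_motif_table <- function() {
  data.frame(
    name = c("P1BS", "W-box", "TATA-box", "TSS", "PHO", "PHO-like",
             "NIT2", "TC"),
    pattern = c("GNATATNC", "TTGACY", "TATAWAW", "TTCANTYY", "CACGTG",
                "CACGTC", "TATCTA", "TTCTTCTC"),
    strands = c("both", "both", "both", "sense", "both", "both", "both",
                "both"),
    stringsAsFactors = FALSE)
}

iupac_ok <- function(pattern) {
  grepl("^[ACGTUMRWSYKVHDBN]+$", toupper(pattern))
}

#' Extract the upstream (promoter) region of a precursor locus
#'
#' Strand-aware: the region 5' of the precursor on its own strand, reported
#' 5' to 3' on that strand with its 3' end adjacent to the precursor.
#' Regions clipped at a chromosome end are flagged truncated.
#'
#' @param locus list/one-row data.frame with `chrom`, `start`, `end`,
#'   `strand`
#' @param genome named character vector or `DNAStringSet`
#' @param length promoter length in bases (default 2000)
#' @return list with `seq`, `length` (actual), `truncated`
#' @export
extract_upstream <- function(locus, genome, length = 2000) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(dna_norm(genome))
  chrom <- as.character(locus$chrom)
  if (!chrom %in% names(genome)) stop("unknown locus chromosome: ", chrom,
                                      call. = FALSE)
  chrom_len <- Biostrings::width(genome[chrom])
  if (locus$strand == "+") {
    s <- max(1L, locus$start - length)
    e <- locus$start - 1L
  } else {
    s <- locus$end + 1L
    e <- min(chrom_len, locus$end + length)
  }
  if (e < s) return(list(seq = "", length = 0L, truncated = TRUE))
  seq <- as.character(Biostrings::extractAt(genome[[chrom]],
                                            IRanges::IRanges(s, e)))
  if (locus$strand == "-") seq <- revcomp(seq)
  list(seq = seq, length = nchar(seq), truncated = nchar(seq) < length)
}

#' Scan a promoter for cis-element motifs
#'
#' Reports every position whose substring matches the IUPAC pattern, on both
#' strands unless the motif is sense-only; overlapping hits are all
#' reported. The offset is the distance from the hit's 3'-most promoter base
#' to the precursor 5' end (offset 1 = adjacent), the promoter being given
#' 5' to 3' with its last base adjacent to the precursor.
#'
#' @param promoter promoter sequence (5' to 3', 3' end adjacent to the
#'   precursor)
#' @param motif_table data.frame with `name`, `pattern`, `strands`
#' @return data.frame of MotifHits: `element`, `offset`, `strand`, `match`
#' @export
scan_motifs <- function(promoter, motif_table) {
  promoter <- dna_norm(promoter)
  L <- nchar(promoter)
  if (nrow(motif_table) == 0 || L == 0) {
    return(data.frame(element = character(), offset = integer(),
                      strand = character(), match = character(),
                      stringsAsFactors = FALSE))
  }
  bad <- !iupac_ok(motif_table$pattern)
  if (any(bad)) stop("invalid IUPAC pattern for motif: ",
                     paste(motif_table$name[bad], collapse = ", "),
                     call. = FALSE)
  subj <- Biostrings::DNAString(promoter)
  out <- list()
  for (i in seq_len(nrow(motif_table))) {
    pat <- Biostrings::DNAString(dna_norm(motif_table$pattern[i]))
    strands <- if (identical(motif_table$strands[i], "sense")) "+" else c("+", "-")
    for (str in strands) {
      p <- if (str == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(p, subj, fixed = FALSE)
      if (length(m) == 0) next
      ends <- IRanges::end(m)
      out[[length(out) + 1]] <- data.frame(
        element = motif_table$name[i],
        offset = L - ends + 1L,
        strand = str,
        match = as.character(m),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(element = character(), offset = integer(), strand = character(),
               match = character(), stringsAsFactors = FALSE)
  res <- res[order(res$offset, res$element), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan many promoters
#'
#' @param promoters named character vector of promoter sequences
#' @param motif_table motif definitions
#' @return data.frame of hits with a leading `gene` column
#' @export
scan_promoters <- function(promoters, motif_table) {
  rows <- lapply(names(promoters), function(g) {
    h <- scan_motifs(promoters[[g]], motif_table)
    if (nrow(h)) cbind(gene = g, h, stringsAsFactors = FALSE) else NULL
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(gene = character(), element = character(),
                                      offset = integer(), strand = character(),
                                      match = character(), stringsAsFactors = FALSE)
  res
}

#' Positional distribution of motif hits
#'
#' Bins hit offsets into proximal [0, 1000) and distal [1000, 2000] windows
#' upstream of the precursor (half-open lower bin: an offset of exactly 1000
#' falls in the distal bin).
#'
#' @param hits MotifHit data.frame with `element` and `offset`
#' @param edge bin boundary (default 1000)
#' @return data.frame `element` x `bin` counts
#' @export
positional_distribution <- function(hits, edge = 1000) {
  bin <- ifelse(hits$offset < edge,
                sprintf("[0,%d)", edge), sprintf("[%d,2000]", edge))
  tab <- table(hits$element, factor(bin, levels = c(sprintf("[0,%d)", edge),
                                                    sprintf("[%d,2000]", edge))))
  as.data.frame.matrix(tab)
}

#' Mean cis-element counts per gene for induced vs repressed sets
#'
#' @param hits MotifHit data.frame with `gene` and `element` columns
#' @param induced,repressed character vectors of gene ids
#' @return list with `by_element` (element x set mean counts per gene) and
#'   `overall` (mean elements per gene per set); empty sets yield NA with a
#'   warning
#' @export
element_frequency_summary <- function(hits, induced, repressed) {
  mean_counts <- function(set) {
    if (length(set) == 0) {
      warning("empty gene set: means undefined")
      return(list(by_element = stats::setNames(rep(NA_real_,
                                                   length(unique(hits$element))),
                                               sort(unique(hits$element))),
                  overall = NA_real_))
    }
    h <- hits[hits$gene %in% set, , drop = FALSE]
    els <- sort(unique(hits$element))
    by_el <- vapply(els, function(e) sum(h$element == e) / length(set),
                    numeric(1))
    list(by_element = by_el, overall = nrow(h) / length(set))
  }
  ind <- mean_counts(induced)
  rep_ <- mean_counts(repressed)
  list(by_element = data.frame(element = names(ind$by_element),
                               induced = as.numeric(ind$by_element),
                               repressed = as.numeric(rep_$by_element),
                               row.names = NULL),
       overall = c(induced = ind$overall, repressed = rep_$overall))
}
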