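#' Build an exact-match genome index
#'
#' @param genome a named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences
#' @param k seed length retained for validation of query widths (default 12)
#' @return an object of class `genome_index`
#' @export
build_index <- function(genome, k = 12) {
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(dna_norm(genome))
  }
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0) {
    stop("empty genome", call. = FALSE)
  }
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  structure(list(genome = genome, k = k), class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$genome), "sequence(s),",
      sum(Biostrings::width(x$genome)), "bases total\n")
  invisible(x)
}

#' Map tags to the genome by perfect match
#'
#' Reports every exact-match locus of every tag on both strands, as 1-based
#' inclusive coordinates on the forward strand. Minus-strand loci are found
#' by matching the reverse complement of the tag.
#'
#' @param tags character vector of tag sequences (or a collapsed tag
#'   data.frame, in which case its `sequence` column is used)
#' @param index a `genome_index`
#' @param max_hits cap on reported loci per tag (default unlimited)
#' @return data.frame with columns `tag`, `chrom`, `start`, `end`, `strand`;
#'   tags with zero perfect-match loci are absent (see [unmapped_tags()])
#' @export
map_tags <- function(tags, index, max_hits = Inf) {
  stopifnot(inherits(index, "genome_index"))
  if (is.data.frame(tags)) tags <- tags$sequence
  tags <- dna_norm(tags)
  tags <- unique(tags)
  if (length(tags) == 0) {
    return(data.frame(tag = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  assert_dna(tags, "tags")
  if (any(nchar(tags) < index$k)) {
    stop("query shorter than index seed length k = ", index$k, call. = FALSE)
  }

  hits <- list()
  for (str in c("+", "-")) {
    query <- if (str == "+") tags else revcomp(tags)
    by_width <- split(seq_along(query), nchar(query))
    for (idx in by_width) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(query[idx]))
      for (ch in names(index$genome)) {
        m <- Biostrings::matchPDict(pd, index$genome[[ch]])
        n_per <- S4Vectors::elementNROWS(m)
        if (sum(n_per) == 0) next
        u <- unlist(m)
        starts <- IRanges::start(u)
        ends <- IRanges::end(u)
        hits[[length(hits) + 1]] <- data.frame(
          tag = rep(tags[idx], n_per),
          chrom = ch, start = starts, end = ends, strand = str,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(tag = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), stringsAsFactors = FALSE)
  out <- out[order(match(out$tag, tags), out$chrom, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (is.finite(max_hits)) {
    out <- do.call(rbind, lapply(split(out, out$tag), utils::head, max_hits))
    rownames(out) <- NULL
  }
  out
}

#' Tags with no perfect-match locus
#'
#' @param tags character vector (or collapsed tag data.frame)
#' @param loci mapping result from [map_tags()]
#' @return character vector of unmapped tag sequences
#' @export
unmapped_tags <- function(tags, loci) {
  if (is.data.frame(tags)) tags <- tags$sequence
  setdiff(dna_norm(tags), loci$tag)
}

category_levels <- function() {
  c("known_miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "exon", "intron",
    "unannotated")
}

annotation_category <- function(type) {
  map <- c(miRNA_primary_transcript = "known_miRNA", miRNA = "known_miRNA",
           rRNA = "rRNA", tRNA = "tRNA", snRNA = "snRNA", snoRNA = "snoRNA",
           exon = "exon", intron = "intron")
  unname(map[as.character(type)])
}

#' Assign each mapped tag an origin category
#'
#' Each tag is assigned the highest-precedence category among all annotation
#' features any of its loci overlaps, mirroring the sequential
#' remove-structural-then-exonic filtering used before miRNA discovery.
#' Precedence: known_miRNA > rRNA > tRNA > snRNA > snoRNA > exon > intron >
#' unannotated.
#'
#' @param loci mapping data.frame from [map_tags()]
#' @param annotation a `GenomicRanges::GRanges` with a `type` metadata
#'   column using GFF3 feature types (`miRNA_primary_transcript`, `rRNA`,
#'   `tRNA`, `snRNA`, `snoRNA`, `exon`, `intron`)
#' @return data.frame with columns `tag` and `category` (factor over the
#'   precedence levels)
#' @export
categorize_tags <- function(loci, annotation) {
  if (any(GenomicRanges::end(annotation) < GenomicRanges::start(annotation))) {
    stop("annotation feature with end < start", call. = FALSE)
  }
  levs <- category_levels()
  tags <- unique(loci$tag)
  if (length(tags) == 0) {
    return(data.frame(tag = character(),
                      category = factor(character(), levels = levs)))
  }
  gr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start, loci$end),
                               strand = loci$strand)
  ann_cat <- annotation_category(annotation$type)
  keep <- !is.na(ann_cat)
  ov <- GenomicRanges::findOverlaps(gr, annotation[keep],
                                    ignore.strand = TRUE)
  rank <- rep(match("unannotated", levs), length(tags))
  names(rank) <- tags
  if (length(ov)) {
    hit_rank <- match(ann_cat[keep][S4Vectors::subjectHits(ov)], levs)
    hit_tag <- loci$tag[S4Vectors::queryHits(ov)]
    best <- tapply(hit_rank, hit_tag, min)
    rank[names(best)] <- pmin(rank[names(best)], best)
  }
  data.frame(tag = tags,
             category = factor(levs[rank], levels = levs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Category shares of mapped reads
#'
#' @param tags collapsed tag data.frame with count columns
#' @param categories output of [categorize_tags()]
#' @return data.frame of per-category read counts and percentage of mapped
#'   reads (sums to 100 over mapped tags)
#' @export
category_summary <- function(tags, categories) {
  cc <- count_columns(tags)
  reads <- rowSums(tags[, cc, drop = FALSE])
  names(reads) <- tags$sequence
  mapped <- categories$tag
  cat_reads <- tapply(reads[mapped], categories$category, sum, default = 0)
  total <- sum(reads[mapped])
  data.frame(category = names(cat_reads),
             reads = as.numeric(cat_reads),
             pct = pct(as.numeric(cat_reads), total),
             row.names = NULL)
}
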