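#' Read a miRNA catalog TSV
#'
#' Catalog tables carry one row per mature miRNA with its sequence, locus
#' and the four-library TPM profile (printed scale: 0.01 marks an undetected
#' miRNA). Hand-entered tables are accepted as long as the TPM columns are
#' present.
#'
#' @param path TSV file with (at least) columns `mirna`, `tpm_hpl`,
#'   `tpm_lpl`, `tpm_hpr`, `tpm_lpr`
#' @return data.frame
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("tpm_hpl", "tpm_lpl", "tpm_hpr", "tpm_lpr")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) stop("catalog lacks columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  df
}

extdata <- function(name) {
  p <- system.file("extdata", name, package = "phosmiR", mustWork = TRUE)
  p
}

#' Bundled soybean miRNA expression catalog
#'
#' The 126-row catalog of conserved, less-conserved and novel soybean
#' miRNAs with four-library TPM profiles (HPL/LPL/HPR/LPR), as published for
#' the phosphate-starvation study this pipeline reanalyses.
#'
#' @return data.frame with sequence, locus, arm, conservation class and TPM
#'   columns
#' @export
soybean_catalog <- function() {
  read_catalog(extdata("soybean_mirna_catalog.tsv"))
}

#' Bundled published library accounting counts
#'
#' Per-library read-level counts (total, high-quality, shorter-than-18-nt,
#' clean, genome-mapped clean reads and unique tags) as printed for the four
#' soybean small RNA libraries; input for [library_report()].
#'
#' @return data.frame, one row per library
#' @export
soybean_library_counts <- function() {
  utils::read.delim(extdata("soybean_library_counts.tsv"),
                    stringsAsFactors = FALSE)
}

#' Bundled published degradome accounting counts
#'
#' @return named numeric vector (high_quality_reads, clean_reads,
#'   mapped_clean_reads, unique_reads, mapped_unique_reads)
#' @export
soybean_degradome_counts <- function() {
  df <- utils::read.delim(extdata("soybean_degradome_counts.tsv"),
                          stringsAsFactors = FALSE)
  stats::setNames(df$count, df$field)
}

#' Bundled published cleavage-site region counts
#'
#' Counts of degradome/predicted cleavage sites falling in CDS versus all
#' localised sites, split by miRNA conservation class.
#'
#' @return data.frame with columns `class`, `cds_sites`, `total_sites`
#' @export
soybean_target_site_counts <- function() {
  utils::read.delim(extdata("soybean_target_site_counts.tsv"),
                    stringsAsFactors = FALSE)
}

#' Bundled reference miRNA catalog (miRBase-style extract)
#'
#' A compact reference catalog emulating a miRBase extract: mature
#' sequences with species codes and family membership across key plant
#' species, used for conservation classing. Non-soybean entries are
#' synthetic stand-ins consistent with the published family/species
#' homology table.
#'
#' @return data.frame with columns `mature_seq`, `species`, `family`, `name`
#' @export
reference_catalog <- function() {
  utils::read.delim(extdata("reference_mirna_catalog_synthetic.tsv"),
                    stringsAsFactors = FALSE)
}

#' Read a motif definition TSV
#'
#' @param path TSV with columns `name`, `pattern` (IUPAC), `strands`
#' @return data.frame
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "pattern", "strands")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) stop("motif table lacks columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  bad <- !iupac_ok(df$pattern)
  if (any(bad)) stop("invalid IUPAC pattern for motif: ",
                     paste(df$name[bad], collapse = ", "), call. = FALSE)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
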