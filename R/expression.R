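#' TPM normalisation
#'
#' @param count read count(s) of a tag in one library
#' @param library_clean_reads clean-read total of that library
#' @return TPM = count / clean reads x 10^6
#' @export
tpm_normalize <- function(count, library_clean_reads) {
  if (any(count < 0)) stop("negative count", call. = FALSE)
  if (any(library_clean_reads <= 0)) stop("clean read total must be positive",
                                          call. = FALSE)
  count / library_clean_reads * 1e6
}

#' Reported TPM with the zero pseudocount
#'
#' Tables report undetected miRNAs as 0.01 TPM (actually 0, used only so the
#' log fold change is defined). The pseudocount is applied on the TPM scale,
#' never to raw counts.
#'
#' @param tpm numeric TPM values
#' @return TPM with exact zeros replaced by 0.01
#' @export
reported_tpm <- function(tpm) {
  ifelse(tpm == 0, 0.01, tpm)
}

#' Log2 fold change of -Pi over +Pi expression
#'
#' @param tpm_lowPi reported TPM under phosphate depletion
#' @param tpm_highPi reported TPM under phosphate sufficiency
#' @return log2(tpm_lowPi / tpm_highPi)
#' @export
log2_fold_change <- function(tpm_lowPi, tpm_highPi) {
  if (any(tpm_lowPi < 0.01) || any(tpm_highPi < 0.01)) {
    stop("inputs must carry the 0.01 pseudocount; use reported_tpm()",
         call. = FALSE)
  }
  log2(tpm_lowPi / tpm_highPi)
}

#' Classify a log2 fold change as induced, repressed or unchanged
#'
#' Strict inequalities on both sides: a fold change of exactly 1 is
#' unchanged (the induction rule is "greater than 1").
#'
#' @param log2fc log2(-Pi/+Pi) value(s)
#' @param up_thresh induction threshold (default 1)
#' @param down_thresh repression threshold (default -1)
#' @return character vector over {induced, repressed, unchanged}
#' @export
classify_response <- function(log2fc, up_thresh = 1, down_thresh = -1) {
  stopifnot(up_thresh > down_thresh)
  ifelse(log2fc > up_thresh, "induced",
         ifelse(log2fc < down_thresh, "repressed", "unchanged"))
}

catalog_tpm <- function(catalog, reported = TRUE) {
  cols <- c("tpm_hpl", "tpm_lpl", "tpm_hpr", "tpm_lpr")
  missing <- setdiff(cols, colnames(catalog))
  if (length(missing)) stop("catalog lacks TPM columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(catalog[, cols])
  if (reported) reported_tpm(m) else ifelse(m == 0.01, 0, m)
}

#' Phosphate-response calls per tissue
#'
#' Computes leaf (LPL vs HPL) and root (LPR vs HPR) log2 fold changes from a
#' catalog's reported TPM columns and classifies each miRNA per tissue.
#'
#' @param catalog data.frame with columns `mirna` (or `name`) and `tpm_hpl`,
#'   `tpm_lpl`, `tpm_hpr`, `tpm_lpr` (printed scale; 0.01 = undetected)
#' @param up_thresh,down_thresh classification thresholds
#' @return data.frame with one row per miRNA x tissue: `mirna`, `tissue`,
#'   `log2fc`, `class`
#' @export
response_calls <- function(catalog, up_thresh = 1, down_thresh = -1) {
  ids <- if ("mirna" %in% colnames(catalog)) catalog$mirna else catalog$name
  tpm <- catalog_tpm(catalog, reported = TRUE)
  leaf <- log2_fold_change(tpm[, "tpm_lpl"], tpm[, "tpm_hpl"])
  root <- log2_fold_change(tpm[, "tpm_lpr"], tpm[, "tpm_hpr"])
  data.frame(mirna = rep(ids, 2),
             tissue = rep(c("leaf", "root"), each = length(ids)),
             log2fc = c(leaf, root),
             class = classify_response(c(leaf, root), up_thresh, down_thresh),
             stringsAsFactors = FALSE)
}

#' Leaf- and root-specific miRNAs
#'
#' A miRNA undetectable (raw TPM of zero; a printed 0.01 means undetected)
#' in one tissue but detected in the other is specific to the latter.
#'
#' @param catalog catalog data.frame with TPM columns
#' @param condition `"+Pi"`, `"-Pi"`, or `"both"` (the pattern must hold
#'   under both conditions)
#' @return list with character vectors `leaf_specific` and `root_specific`
#' @export
tissue_specificity <- function(catalog, condition = c("+Pi", "-Pi", "both")) {
  condition <- match.arg(condition)
  ids <- if ("mirna" %in% colnames(catalog)) catalog$mirna else catalog$name
  tpm <- catalog_tpm(catalog, reported = FALSE)
  spec <- function(leaf_col, root_col) {
    list(leaf = tpm[, leaf_col] > 0 & tpm[, root_col] == 0,
         root = tpm[, root_col] > 0 & tpm[, leaf_col] == 0)
  }
  hi <- spec("tpm_hpl", "tpm_hpr")
  lo <- spec("tpm_lpl", "tpm_lpr")
  sel <- switch(condition,
                "+Pi" = hi,
                "-Pi" = lo,
                both = list(leaf = hi$leaf & lo$leaf, root = hi$root & lo$root))
  list(leaf_specific = ids[sel$leaf], root_specific = ids[sel$root])
}

#' Venn counts for leaf/root responsive sets
#'
#' @param leaf_set,root_set character vectors of miRNA ids
#' @return named numeric vector: `leaf_only`, `root_only`, `shared`, `total`
#'   (a partition: leaf_only + root_only + shared = total)
#' @export
overlap_summary <- function(leaf_set, root_set) {
  shared <- intersect(leaf_set, root_set)
  c(leaf_only = length(setdiff(leaf_set, root_set)),
    root_only = length(setdiff(root_set, leaf_set)),
    shared = length(shared),
    total = length(union(leaf_set, root_set)))
}

#' Reanalyze a miRNA catalog: response, specificity and Venn summaries
#'
#' The bridge that makes a hand-entered TPM table an executable input: give
#' it any catalog with the four TPM columns and it recomputes per-tissue
#' log2 fold changes, induction/repression calls, tissue specificity under
#' both conditions, and the Venn overlap counts.
#'
#' @param catalog catalog data.frame (see [response_calls()])
#' @param up_thresh,down_thresh classification thresholds
#' @return list with `calls`, `maxima` (max leaf/root log2fc, 2 d.p.),
#'   `venn` (responsive/induced/repressed overlap counts),
#'   `specificity_highPi`, `specificity_lowPi`
#' @export
reanalyze_catalog <- function(catalog, up_thresh = 1, down_thresh = -1) {
  calls <- response_calls(catalog, up_thresh, down_thresh)
  leaf <- calls[calls$tissue == "leaf", ]
  root <- calls[calls$tissue == "root", ]
  sets <- function(cls) {
    list(leaf = leaf$mirna[leaf$class %in% cls],
         root = root$mirna[root$class %in% cls])
  }
  ind <- sets("induced")
  rep_ <- sets("repressed")
  resp <- sets(c("induced", "repressed"))
  list(calls = calls,
       maxima = c(max_leaf_log2fc = round_half_up(max(leaf$log2fc), 2),
                  max_root_log2fc = round_half_up(max(root$log2fc), 2)),
       venn = rbind(responsive = overlap_summary(resp$leaf, resp$root),
                    induced = overlap_summary(ind$leaf, ind$root),
                    repressed = overlap_summary(rep_$leaf, rep_$root)),
       specificity_highPi = tissue_specificity(catalog, "+Pi"),
       specificity_lowPi = tissue_specificity(catalog, "-Pi"))
}
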