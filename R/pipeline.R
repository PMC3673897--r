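#' Build a run configuration
#'
#' Collects every input path and tunable threshold of the pipeline in one
#' serialisable list. Thresholds default to the published study settings
#' (recorded beside each value in the YAML round-trip): 100 TPM abundance
#' floor, 20-24 nt mature window, MFE strictly below -37, MFEI strictly
#' above 0.85, target score cap 7.
#'
#' @param out_dir output directory
#' @param seed RNG seed
#' @param simulate logical; generate synthetic inputs instead of reading
#'   paths
#' @param genome,annotation,libraries,degradome,catalog,motifs input paths
#'   (`libraries` is a named vector HPL/LPL/HPR/LPR); ignored when
#'   `simulate = TRUE`
#' @param adapter3 3' adapter
#' @param discovery list of [discovery_config()] overrides
#' @param max_target_score degradome/prediction score cap
#' @param design_args list of [simulation_design()] overrides used when
#'   simulating
#' @return list of class `phosmir_config`
#' @export
run_config <- function(out_dir, seed = 1, simulate = TRUE, genome = NULL,
                       annotation = NULL, libraries = NULL, degradome = NULL,
                       catalog = NULL, motifs = NULL,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       discovery = list(), max_target_score = 7,
                       design_args = list()) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
              genome = genome, annotation = annotation, libraries = libraries,
              degradome = degradome, catalog = catalog, motifs = motifs,
              adapter3 = adapter3, discovery = discovery,
              max_target_score = max_target_score, design_args = design_args)
  class(cfg) <- "phosmir_config"
  cfg
}

#' @export
print.phosmir_config <- function(x, ...) {
  cat("phosmiR run config: out_dir =", x$out_dir,
      "| seed =", x$seed, "| simulate =", x$simulate, "\n")
  invisible(x)
}

#' Write/read a run configuration as YAML
#'
#' The round-trip is lossless for all configuration fields.
#'
#' @param config a [run_config()] list
#' @param path YAML file
#' @return `write_config` the path; `read_config` the config list
#' @export
write_config <- function(config, path) {
  # YAML sequences drop element names, so named vectors go out as maps
  prep <- function(x) {
    if (is.list(x)) lapply(x, prep)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(prep(unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::yaml.load_file(path)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$libraries)) cfg$libraries <- unlist(cfg$libraries)
  # YAML maps come back as lists; restore the named-vector fields
  for (f in c("library_depths", "mature_length_range")) {
    if (!is.null(cfg$design_args[[f]])) {
      cfg$design_args[[f]] <- unlist(cfg$design_args[[f]])
    }
  }
  if (!is.null(cfg$discovery)) {
    cfg$discovery <- lapply(cfg$discovery,
                            function(x) if (is.list(x)) unlist(x) else x)
  }
  class(cfg) <- "phosmir_config"
  cfg
}

validate_config <- function(config) {
  if (!isTRUE(config$simulate)) {
    for (f in c("genome", "annotation", "degradome")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        stop("missing input: ", f, call. = FALSE)
      }
    }
    if (is.null(config$libraries) || !all(file.exists(config$libraries))) {
      stop("missing input: libraries", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order: simulate (or load) inputs,
#' clean and collapse reads, map and categorise tags, discover miRNAs,
#' classify phosphate responses and tissue specificity, call degradome
#' targets, scan promoters, and write report tables plus a manifest. Re-runs
#' with the same config reproduce identical outputs.
#'
#' @param config a [run_config()]
#' @return invisible list of all stage results
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                            "\n", file = log_path, append = TRUE)

  # --- inputs -------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    design <- do.call(simulation_design,
                      c(list(seed = config$seed,
                             adapter3 = config$adapter3), config$design_args))
    sim <- simulate_all(design, file.path(config$out_dir, "sim"))
    genome <- sim$genome
    annotation <- sim$annotation
    lib_reads <- sim$reads
    deg_reads <- sim$degradome_reads
    transcriptome <- sim$transcriptome
    cds <- sim$cds
    promoters <- sim$promoters
    logf("simulate: ", length(genome), " chromosome(s), ",
         nrow(sim$truth$planted_mirnas), " planted hairpins")
  } else {
    sim <- NULL
    genome_set <- Biostrings::readDNAStringSet(config$genome)
    genome <- stats::setNames(as.character(genome_set),
                              sub("\\s.*$", "", names(genome_set)))
    annotation <- rtracklayer::import(config$annotation, format = "gff3")
    lib_reads <- lapply(config$libraries, read_fastq)
    deg_reads <- read_fastq(config$degradome)
    transcriptome <- NULL; cds <- NULL; promoters <- NULL
  }

  # --- prep ---------------------------------------------------------------
  cleaned <- lapply(lib_reads, clean_reads, adapter3 = config$adapter3)
  tags <- collapse_tags(lapply(cleaned, `[[`, "tags"))
  clean_totals <- vapply(cleaned, function(x) x$stats[["clean"]], numeric(1))
  logf("prep: ", nrow(tags), " unique tags; clean totals ",
       paste(clean_totals, collapse = "/"))

  # --- map ----------------------------------------------------------------
  index <- build_index(genome)
  loci <- map_tags(tags, index)
  cats <- categorize_tags(loci, annotation)
  libs <- names(lib_reads)
  mapped_seqs <- unique(loci$tag)
  stats_df <- data.frame(
    library = libs,
    total_reads = vapply(cleaned, function(x) x$stats[["total"]], numeric(1)),
    high_quality_reads = vapply(cleaned, function(x) x$stats[["high_quality"]],
                                numeric(1)),
    too_short_reads = vapply(cleaned, function(x) x$stats[["too_short"]],
                             numeric(1)),
    clean_reads = clean_totals,
    mapped_clean_reads = vapply(libs, function(l) {
      sum(tags[[l]][tags$sequence %in% mapped_seqs])
    }, numeric(1)),
    unique_tags = vapply(libs, function(l) sum(tags[[l]] > 0), numeric(1)),
    mapped_unique_tags = vapply(libs, function(l) {
      sum(tags[[l]] > 0 & tags$sequence %in% mapped_seqs)
    }, numeric(1)),
    row.names = NULL)
  lib_stats <- library_report(stats_df)
  logf("map: ", nrow(loci), " loci for ", length(mapped_seqs), " tags")

  # --- discovery ----------------------------------------------------------
  disc_cfg <- do.call(discovery_config, config$discovery)
  candidates <- discover_mirnas(tags, index, annotation, clean_totals,
                                reference_catalog = tryCatch(reference_catalog(),
                                                             error = function(e) NULL),
                                config = disc_cfg)
  catalog <- candidates[candidates$pass, , drop = FALSE]
  catalog$mirna <- catalog$name
  logf("discover: ", nrow(candidates), " candidates, ", nrow(catalog),
       " passing")

  # --- expression ---------------------------------------------------------
  expression <- if (nrow(catalog)) reanalyze_catalog(catalog) else NULL

  # --- targets ------------------------------------------------------------
  targets <- NULL
  if (!is.null(transcriptome) && nrow(catalog)) {
    deg <- degradome_prep(deg_reads, config$adapter3, transcriptome)
    mir_df <- data.frame(name = catalog$mirna, sequence = catalog$sequence,
                         stringsAsFactors = FALSE)
    targets <- list(
      degradome = call_targets(mir_df, transcriptome, deg, cds,
                               config$max_target_score),
      predicted = predict_targets(mir_df, transcriptome, cds,
                                  config$max_target_score),
      degradome_stats = deg$stats)
    logf("targets: ", nrow(targets$degradome), " degradome-supported hits")
  }

  # --- promoters ----------------------------------------------------------
  promoter_hits <- NULL
  motif_table <- if (!is.null(config$motifs)) read_motif_table(config$motifs)
  else default_motif_table()
  if (is.null(promoters) && nrow(catalog)) {
    promoters <- stats::setNames(vapply(seq_len(nrow(catalog)), function(i) {
      extract_upstream(catalog[i, ], genome)$seq
    }, character(1)), catalog$mirna)
  }
  if (!is.null(promoters) && length(promoters)) {
    promoter_hits <- scan_promoters(promoters, motif_table)
    logf("promoters: ", nrow(promoter_hits), " motif hits over ",
         length(promoters), " promoters")
  }

  results <- list(config = config, sim = sim, tags = tags,
                  library_stats = lib_stats, loci = loci, categories = cats,
                  candidates = candidates, catalog = catalog,
                  expression = expression, targets = targets,
                  promoter_hits = promoter_hits)
  make_reports(results, config$out_dir)
  invisible(results)
}

# hash of the scientific configuration (output location excluded, so two
# runs of the same analysis hash identically wherever they are written)
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null", force = TRUE))
}

#' Write report tables from pipeline results
#'
#' Emits the library-statistics table, the miRNA catalog split by
#' conservation class, response-call and Venn tables, target tables, the
#' promoter motif summary, and a JSON manifest with the config hash and
#' per-stage row counts.
#'
#' @param results list returned by [run_pipeline()]
#' @param out_dir output directory
#' @return invisible vector of written paths
#' @export
make_reports <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  paths <- character(0)

  write_tsv(results$library_stats, fp("library_stats.tsv"))
  paths <- c(paths, fp("library_stats.tsv"))

  cat_cols <- intersect(c("mirna", "sequence", "mature_len", "chrom", "start",
                          "end", "strand", "arm", "mfe", "mfei",
                          "conservation", "family", "tpm_hpl", "tpm_lpl",
                          "tpm_hpr", "tpm_lpr"), colnames(results$catalog))
  cat_out <- results$catalog[, cat_cols, drop = FALSE]
  write_tsv(cat_out, fp("mirna_catalog.tsv"))
  if (nrow(cat_out) && "conservation" %in% colnames(cat_out)) {
    for (cls in unique(cat_out$conservation)) {
      if (is.na(cls)) next
      write_tsv(cat_out[cat_out$conservation %in% cls, , drop = FALSE],
                fp(paste0("mirna_catalog_", cls, ".tsv")))
    }
  }

  if (!is.null(results$expression)) {
    write_tsv(results$expression$calls, fp("response_calls.tsv"))
    venn <- as.data.frame(results$expression$venn)
    venn <- cbind(set = rownames(venn), venn)
    write_tsv(venn, fp("venn_counts.tsv"))
    jsonlite::write_json(list(maxima = as.list(results$expression$maxima),
                              venn = venn),
                         fp("expression_summary.json"), auto_unbox = TRUE)
  }
  if (!is.null(results$targets)) {
    write_tsv(results$targets$degradome, fp("targets_degradome.tsv"))
    write_tsv(results$targets$predicted, fp("targets_predicted.tsv"))
  }
  if (!is.null(results$promoter_hits)) {
    write_tsv(results$promoter_hits, fp("promoter_hits.tsv"))
  }

  manifest <- list(
    config_hash = config_hash(results$config),
    seed = results$config$seed,
    rows = list(tags = nrow(results$tags),
                loci = nrow(results$loci),
                candidates = nrow(results$candidates),
                catalog = nrow(results$catalog),
                targets_degradome = if (!is.null(results$targets))
                  nrow(results$targets$degradome) else 0,
                promoter_hits = if (!is.null(results$promoter_hits))
                  nrow(results$promoter_hits) else 0))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, fp("manifest.json")))
}
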