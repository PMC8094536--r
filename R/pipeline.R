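# End-to-end driver: validates a configuration, runs annotate -> enrich ->
# signature -> motif (-> EM quantification), and assembles a machine-readable
# run report.

.required_config_keys <- c("genes", "peaks", "counts", "metadata",
                           "orthologs", "stages")

#' Validate a pipeline configuration
#'
#' The configuration is a named list (or a YAML file holding one) with
#' entries: `genes` (GFF3 paths for `focal`, `ref_uni`, `ref_multi`),
#' `genome` (FASTA path(s), at least `focal`, used for motif scanning),
#' `peaks` (`focal_uni`: narrowPeak replicate paths; `focal_multi`: a list of
#' replicate-path vectors, one per multicellular stage; `ref_uni`,
#' `ref_multi`), `counts` and `metadata` (TSV paths), `orthologs` (TSV path),
#' `stages` (`unicellular` label, `multicellular` labels), and optional
#' `params` overriding `upstream` (1500), `downstream` (3000), `min_cpm` (1),
#' `min_samples` (2), `alpha` (0.05), `motif` (`CCATATATGG`), `region`
#' (`promoter`), `threshold_frac` (0.15). All referenced paths must exist.
#'
#' @param config a named list or the path of a YAML file.
#' @return the validated configuration list (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_cellsig("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  missing <- setdiff(.required_config_keys, names(config))
  if (length(missing))
    stop_cellsig("config is missing key(s): %s", paste(missing, collapse = ", "))
  paths <- c(unlist(config$genes), unlist(config$genome),
             unlist(config$peaks), config$counts, config$metadata,
             config$orthologs)
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop_cellsig("input path(s) not found: %s", paste(absent, collapse = ", "))
  defaults <- list(upstream = 1500L, downstream = 3000L, min_cpm = 1,
                   min_samples = 2, alpha = 0.05, motif = "CCATATATGG",
                   region = "promoter", threshold_frac = 0.15)
  config$params <- utils::modifyList(defaults, config$params %||% list())
  bad <- setdiff(names(config$params), names(defaults))
  if (length(bad))
    stop_cellsig("unknown parameter key(s): %s", paste(bad, collapse = ", "))
  config
}

.read_condition_calls <- function(paths, genes, condition, region, upstream) {
  sets <- lapply(paths, read_bed, condition = condition)
  call_accessibility(merge_peak_sets(sets, condition = condition), genes,
                     region = region, condition = condition,
                     upstream = upstream)
}

#' Run the full comparative-epigenomics pipeline
#'
#' Executes, in order: per-condition accessibility calls for the focal
#' organism and the two references; focal stage-enrichment classification;
#' the conserved-gene table and signature calls; the accessibility-expression
#' chi-square association; and motif enrichment of promoters of
#' multicellular-accessible genes against all promoters. Fails before any
#' computation when the configuration or an input path is invalid.
#'
#' @param config a configuration list or YAML path; see [validate_config()].
#' @return a list of class `cellsig_run`: `config`, `config_hash`,
#'   `signatures` (a `signature_result`), `association`
#'   (a `contingency_result`), `motif` (a `motif_enrichment`), `enrichment`
#'   (the per-gene `enrichment_result`), `calls` (per-condition call tables),
#'   and `version`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  pars <- config$params

  genes_focal <- read_gff3(config$genes$focal)
  genes_ru <- read_gff3(config$genes$ref_uni)
  genes_rm <- read_gff3(config$genes$ref_multi)

  multi_stages <- as.character(unlist(config$stages$multicellular))
  calls_fu <- .read_condition_calls(config$peaks$focal_uni, genes_focal,
                                    config$stages$unicellular, pars$region,
                                    pars$upstream)
  calls_fm <- lapply(seq_along(multi_stages), function(i)
    .read_condition_calls(config$peaks$focal_multi[[i]], genes_focal,
                          multi_stages[i], pars$region, pars$upstream))
  calls_ru <- .read_condition_calls(config$peaks$ref_uni, genes_ru,
                                    "ref_uni", pars$region, pars$upstream)
  calls_rm <- .read_condition_calls(config$peaks$ref_multi, genes_rm,
                                    "ref_multi", pars$region, pars$upstream)

  counts <- read_counts(config$counts, config$metadata)
  enr <- classify_stage_enrichment(counts, config$stages$unicellular,
                                   multi_stages, alpha = pars$alpha,
                                   min_cpm = pars$min_cpm,
                                   min_samples = pars$min_samples)

  orth <- read_ortholog_tsv(config$orthologs)
  tab <- build_conserved_table(orth, calls_fu, calls_fm, calls_ru, calls_rm, enr)
  sig <- call_signatures(tab)
  assoc <- accessibility_expression_association(enr, calls_fu, calls_fm)

  mot <- NULL
  if (!is.null(config$genome$focal)) {
    genome <- read_fasta(config$genome$focal)
    proms <- promoter_sequences(genome, genes_focal, pars$upstream)
    acc_multi <- Reduce(`|`, lapply(calls_fm, function(cc)
      stats::setNames(cc$accessible, cc$gene_id)[genes_focal$gene_id]))
    fg <- proms[intersect(names(proms), genes_focal$gene_id[acc_multi])]
    if (length(fg) > 0L)
      mot <- motif_enrichment(fg, proms, motif = pars$motif)
  }

  report <- list(config = config, config_hash = .config_hash(config),
                 signatures = sig, association = assoc, motif = mot,
                 enrichment = enr, conserved_table = tab,
                 calls = list(focal_uni = calls_fu, focal_multi = calls_fm,
                              ref_uni = calls_ru, ref_multi = calls_rm),
                 version = as.character(utils::packageVersion("cellsig")))
  class(report) <- "cellsig_run"
  report
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.cellsig_run <- function(x, ...) {
  cat("cellsig pipeline run (config", substr(x$config_hash, 1, 8), ")\n\n")
  print(x$signatures)
  cat("\nAccessibility-expression association:\n")
  print(x$association)
  if (!is.null(x$motif)) { cat("\n"); print(x$motif) }
  invisible(x)
}

#' Write a run report as JSON
#'
#' Serializes the counts, percentages, gene lists, association and motif
#' results of a pipeline run (not the full per-gene tables).
#'
#' @param run a `cellsig_run`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  sig <- run$signatures
  out <- list(
    version = run$version, config_hash = run$config_hash,
    signatures = sig[c("n_conserved", "n_acc_focal_uni", "n_acc_focal_multi",
                       "n_uni_shared", "n_uni_exclusive", "n_multi_shared",
                       "n_multi_exclusive", "pct_uni_shared",
                       "pct_uni_exclusive", "pct_multi_shared",
                       "pct_multi_exclusive", "unicellular_signature",
                       "multicellular_signature")],
    association = list(table = run$association$table,
                       chi2 = run$association$chi2, df = run$association$df,
                       pvalue = run$association$pvalue),
    motif = if (!is.null(run$motif))
      run$motif[c("motif", "n_fg", "n_fg_hit", "n_bg", "n_bg_hit", "fold",
                  "pvalue")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
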