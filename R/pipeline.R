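# End-to-end orchestration: simulate -> thresholds -> IHS -> constraint
# -> structure -> report.

#' ReportBundle: the outputs of a full analysis run
#'
#' @slot thresholds a [DepletionScan-class].
#' @slot thresholdsUsed the [StabilityThresholds-class] applied
#'   downstream (the scan's choice, or the configured fallback when the
#'   scan ended in the not-found sentinel).
#' @slot ihs per-gene IHS table.
#' @slot constraint per-gene, per-class constraint records.
#' @slot confusion 10 x 10 decile-membership matrix (pLoF vs DoS).
#' @slot ranking genes ordered by |LOEUF_plof - LOEUF_dos|.
#' @slot strata per-stratum ddG distribution summaries.
#' @slot structureGroups grouped ordered-fraction summaries.
#' @slot fdr DoS false-discovery rate on the benign set.
#' @slot dosFraction [countDosFraction()] result on the pathogenic set.
#' @slot provenance list: seed, config hash, package version.
#' @export
setClass("ReportBundle",
  representation(thresholds = "DepletionScan",
                 thresholdsUsed = "StabilityThresholds",
                 ihs = "data.frame", constraint = "data.frame",
                 confusion = "matrix", ranking = "data.frame",
                 strata = "data.frame", structureGroups = "data.frame",
                 fdr = "numeric", dosFraction = "list",
                 provenance = "list"))

setMethod("show", "ReportBundle", function(object) {
  cat("ReportBundle\n")
  cat(sprintf("  genes: %d   thresholds used: %g / %g kcal/mol\n",
              nrow(object@ihs), object@thresholdsUsed@lower,
              object@thresholdsUsed@upper))
  cat(sprintf("  benign FDR: %.4f   pathogenic DoS fraction: %.4f\n",
              object@fdr, object@dosFraction$fraction))
  cat(sprintf("  seed %s, config %s\n", object@provenance$seed,
              object@provenance$config_hash))
})

# Flat key-value config file (YAML scalar map) -> simulationConfig plus
# pipeline options. Unknown keys are rejected so typos surface.
.pipeline_keys <- c("ci", "cap", "grid_step", "depletion_cutoff",
                    "min_tail_n", "n_benign", "n_pathogenic",
                    "fallback_threshold")

#' Read a pipeline configuration file
#'
#' A flat key-value YAML file. Keys in snake_case map onto
#' [simulationConfig()] arguments (e.g. `n_genes`, `cohort_size`,
#' `sigma_ordered_base`); pipeline-level keys are `ci`, `cap`,
#' `grid_step`, `depletion_cutoff`, `min_tail_n`, `n_benign`,
#' `n_pathogenic` and `fallback_threshold`.
#'
#' @param path YAML file.
#' @return list with `config` (a [SimulationConfig-class]) and `options`
#'   (pipeline parameters with defaults filled in).
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) .stopf("config must be a flat key-value map")
  camel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  sim_args <- list(); opts <- list()
  for (key in names(raw)) {
    if (key %in% .pipeline_keys) opts[[key]] <- raw[[key]]
    else {
      arg <- camel(key)
      if (!arg %in% names(formals(simulationConfig)))
        .stopf("unknown config key '%s'", key)
      sim_args[[arg]] <- raw[[key]]
    }
  }
  defaults <- list(ci = 0.90, cap = 2.0, grid_step = 0.05,
                   depletion_cutoff = 0.1, min_tail_n = 50,
                   n_benign = 2000L, n_pathogenic = 2000L,
                   fallback_threshold = 0.5)
  for (key in names(defaults))
    if (is.null(opts[[key]])) opts[[key]] <- defaults[[key]]
  list(config = do.call(simulationConfig, sim_args), options = opts)
}

# Deterministic hash of the configuration (content-addressed provenance).
.config_hash <- function(config, opts) {
  slots <- methods::slotNames(class(config))
  vals <- lapply(slots, function(s) {
    v <- slot(config, s)
    if (is(v, "MutationRateTable")) v <- v@rates
    v
  })
  txt <- paste(utils::capture.output(utils::str(c(setNames(vals, slots),
                                                  opts),
                                                digits.d = 15L)),
               collapse = "\n")
  tmp <- tempfile()
  writeLines(txt, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Simulate a cohort, derive tolerated-stability thresholds from the
#' most- versus least-constrained strata, score every protein's IHS,
#' compute pLoF and DoS constraint records with decile bins, and write a
#' machine-readable report. All stages are deterministic under the
#' configured seed (a rerun writes byte-identical outputs).
#'
#' @param config a [SimulationConfig-class], or the path to a YAML file
#'   for [readPipelineConfig()].
#' @param outDir output directory (created); `NULL` skips writing.
#' @param seed optional seed overriding the config's.
#' @param options pipeline options (see [readPipelineConfig()]); merged
#'   over the defaults.
#' @return a [ReportBundle-class], invisibly when `outDir` is set.
#' @export
runFullAnalysis <- function(config, outDir = NULL, seed = NULL,
                            options = list()) {
  if (is.character(config)) {
    parsed <- readPipelineConfig(config)
    opts <- utils::modifyList(parsed$options, options)
    config <- parsed$config
  } else {
    opts <- utils::modifyList(list(ci = 0.90, cap = 2.0, grid_step = 0.05,
                                   depletion_cutoff = 0.1, min_tail_n = 50,
                                   n_benign = 2000L, n_pathogenic = 2000L,
                                   fallback_threshold = 0.5), options)
  }
  stopifnot(is(config, "SimulationConfig"))
  if (!is.null(seed)) config@seed <- as.integer(seed)

  gen <- generateGenes(config)
  mats <- generateDdgMatrices(gen$genes, gen$truth, config)
  variants <- simulatePopulationVariants(gen$genes, mats$matrices,
                                         gen$truth, config)
  clinical <- generateClinicalLabels(mats$matrices, config,
                                     nBenign = opts$n_benign,
                                     nPathogenic = opts$n_pathogenic)

  # Threshold derivation: population missense ddG in the top versus
  # bottom selection-strength deciles (the constrained and unconstrained
  # strata an analyst would take from published constraint bins).
  s_bins <- assignDeciles(setNames(-gen$truth$s, gen$truth$gene_id))
  constrained_ids <- names(s_bins)[s_bins == 0L]
  unconstrained_ids <- names(s_bins)[s_bins == 9L]
  mis <- variants$consequence == "missense" & !is.na(variants$ddg)
  scan <- deriveThresholds(
    variants$ddg[mis & variants$gene_id %in% constrained_ids],
    variants$ddg[mis & variants$gene_id %in% unconstrained_ids],
    gridStep = opts$grid_step, depletionCutoff = opts$depletion_cutoff,
    minTailN = opts$min_tail_n)
  thr <- chosenThresholds(scan) %||%
    stabilityThresholds(-opts$fallback_threshold, opts$fallback_threshold)

  fdr <- computeFdr(clinical$benign$ddg, thr)
  dos_fraction <- countDosFraction(clinical$pathogenic, thr)
  ihs <- ihsTable(mats$matrices, threshold = thr@upper)

  constraint <- constraintTable(gen$genes, mats$matrices, variants,
                                config@rateTable, thresholds = thr,
                                ci = opts$ci, cap = opts$cap)
  rec_plof <- constraint[constraint$variant_class == "plof", ]
  rec_dos <- constraint[constraint$variant_class == "dos", ]
  confusion <- decileConfusion(setNames(rec_plof$decile, rec_plof$gene_id),
                               setNames(rec_dos$decile, rec_dos$gene_id))
  ranking <- rankLoeufDifferences(rec_plof, rec_dos)

  strata <- do.call(rbind, lapply(0:9, function(b) {
    ids <- names(s_bins)[s_bins == b]
    x <- variants$ddg[mis & variants$gene_id %in% ids]
    if (!length(x))
      return(cbind(data.frame(s_decile = b), n = 0L, q_lower = NA_real_,
                   median = NA_real_, q_upper = NA_real_,
                   whisker_lower = NA_real_, whisker_upper = NA_real_))
    cbind(data.frame(s_decile = b), distributionSummary(x))
  }))

  ordered_frac <- data.frame(
    gene_id = names(mats$confidence),
    value = vapply(mats$confidence, orderedFraction, numeric(1L)),
    row.names = NULL)
  structure_groups <- groupedMetricTable(
    ordered_frac, data.frame(gene_id = rec_dos$gene_id),
    grouping = "loeuf_decile_grouped",
    deciles = setNames(rec_dos$decile, rec_dos$gene_id))

  provenance <- list(seed = config@seed,
                     config_hash = .config_hash(config, opts),
                     package_version =
                       as.character(utils::packageVersion("dosconstraint")))
  bundle <- new("ReportBundle", thresholds = scan, thresholdsUsed = thr,
                ihs = ihs, constraint = constraint, confusion = confusion,
                ranking = ranking, strata = strata,
                structureGroups = structure_groups, fdr = fdr,
                dosFraction = dos_fraction, provenance = provenance)
  if (!is.null(outDir)) {
    writeReportBundle(bundle, outDir)
    return(invisible(bundle))
  }
  bundle
}

#' Write a report bundle to a directory
#'
#' TSV tables per section plus a JSON report of the scalar results and
#' provenance.
#'
#' @param bundle a [ReportBundle-class].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeReportBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    write.table(df, file.path(outDir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  writeDepletionScan(bundle@thresholds, file.path(outDir,
                                                  "threshold_scan.tsv"))
  wt(bundle@ihs, "ihs.tsv")
  wt(bundle@constraint, "constraint.tsv")
  wt(as.data.frame(bundle@confusion), "decile_confusion.tsv")
  wt(bundle@ranking, "loeuf_ranking.tsv")
  wt(bundle@strata, "stratum_summaries.tsv")
  wt(bundle@structureGroups, "structure_groups.tsv")
  report <- list(
    thresholds = list(lower = bundle@thresholdsUsed@lower,
                      upper = bundle@thresholdsUsed@upper,
                      scan_found = !is.null(chosenThresholds(bundle@thresholds))),
    fdr_benign = bundle@fdr,
    dos_fraction_pathogenic = bundle@dosFraction,
    provenance = bundle@provenance)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Join per-gene scores with external annotations
#'
#' Left join of an IHS (or any per-gene) table onto external annotation
#' columns (published LOEUF, pLi, S-het category, Bayes factors). The
#' join is how stability fragility is compared against orthogonal
#' constraint evidence; unmatched genes are tallied, never dropped.
#'
#' @param ihsTable data.frame with a `gene_id` column.
#' @param annotations data.frame with `gene_id` plus annotation columns.
#' @return merged data.frame (all rows of `ihsTable`), with attribute
#'   `n_unmatched` counting genes without an annotation row.
#' @export
joinExternalScores <- function(ihsTable, annotations) {
  if (!length(intersect(ihsTable$gene_id, annotations$gene_id)))
    .stopf("no overlap between gene ids of the two tables")
  merged <- merge(ihsTable, annotations, by = "gene_id", all.x = TRUE,
                  sort = TRUE)
  extra <- setdiff(names(annotations), "gene_id")
  unmatched <- !ihsTable$gene_id %in% annotations$gene_id
  attr(merged, "n_unmatched") <- sum(unmatched)
  merged
}
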