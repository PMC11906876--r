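# Tolerated-stability threshold derivation from constraint-stratified
# population variation, and the FDR of DoS calls against benign variants.

#' Derive tolerated-stability thresholds from tail depletion
#'
#' Formalises the choice of DoS cut-offs as a grid scan: for each
#' candidate threshold t > 0, the empirical survival probability of the
#' constrained missense ddG sample beyond t is compared with that of the
#' unconstrained sample, and the upper threshold is the smallest t whose
#' ratio drops to `depletionCutoff` or below; the lower threshold is the
#' symmetric scan on the left tail. Strict-inequality tails match the DoS
#' boundary convention. Grid points where the unconstrained tail holds
#' fewer than `minTailN` variants are too noisy to judge depletion and
#' are skipped.
#'
#' When no grid point qualifies on a side, the scan carries an `NA`
#' sentinel there and [chosenThresholds()] returns `NULL`; in particular,
#' identically distributed samples (tail ratio near 1 everywhere) find no
#' threshold.
#'
#' @param ddgConstrained,ddgUnconstrained numeric vectors of ddG values
#'   (kcal/mol) for observed missense variants in constrained and
#'   unconstrained gene strata.
#' @param gridStep grid spacing, default 0.05 kcal/mol.
#' @param depletionCutoff survival-ratio cut-off in (0,1). The default
#'   0.1 demands a ten-fold depletion; on a sample whose constrained
#'   stratum is hard-truncated at the true tolerated bound the first
#'   ten-fold-depleted grid point is the truncation bound itself (see the
#'   methods vignette for the closed-form argument).
#' @param minTailN minimum unconstrained tail count, default 50.
#' @return a [DepletionScan-class].
#' @export
deriveThresholds <- function(ddgConstrained, ddgUnconstrained,
                             gridStep = 0.05, depletionCutoff = 0.1,
                             minTailN = 50) {
  ddgConstrained <- ddgConstrained[!is.na(ddgConstrained)]
  ddgUnconstrained <- ddgUnconstrained[!is.na(ddgUnconstrained)]
  if (!length(ddgConstrained) || !length(ddgUnconstrained))
    .stopf("both ddG samples must be nonempty")
  if (!(depletionCutoff > 0 && depletionCutoff < 1))
    .stopf("depletionCutoff must lie in (0, 1)")
  n_c <- length(ddgConstrained)
  n_u <- length(ddgUnconstrained)
  top <- max(abs(c(ddgConstrained, ddgUnconstrained)))
  grid <- seq(gridStep, top + gridStep, by = gridStep)

  tail_ratio <- function(sign) {
    vapply(grid, function(t) {
      cnt_u <- sum(sign * ddgUnconstrained > t)
      if (cnt_u < minTailN) return(NA_real_)
      (sum(sign * ddgConstrained > t) / n_c) / (cnt_u / n_u)
    }, numeric(1L))
  }
  up_ratio <- tail_ratio(+1)
  lo_ratio <- tail_ratio(-1)
  if (all(is.na(up_ratio)) && all(is.na(lo_ratio)))
    .warnf("all grid points fail the min_tail_n=%g requirement; no threshold can be evaluated",
           minTailN)

  pick <- function(r) {
    hit <- which(!is.na(r) & r <= depletionCutoff)
    if (length(hit)) grid[hit[1L]] else NA_real_
  }
  new("DepletionScan", grid = grid, upperTailRatio = up_ratio,
      lowerTailRatio = lo_ratio, chosenUpper = pick(up_ratio),
      chosenLower = -pick(lo_ratio), depletionCutoff = depletionCutoff,
      minTailN = minTailN)
}

#' Write the grid scan of a threshold derivation as TSV
#'
#' @param scan a [DepletionScan-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDepletionScan <- function(scan, path) {
  tab <- data.frame(threshold = scan@grid,
                    upper_tail_ratio = scan@upperTailRatio,
                    lower_tail_ratio = scan@lowerTailRatio)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# depletion_cutoff=%g min_tail_n=%g chosen_lower=%s chosen_upper=%s",
                     scan@depletionCutoff, scan@minTailN,
                     format(scan@chosenLower), format(scan@chosenUpper)),
             con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' False-discovery rate of DoS calls on benign variants
#'
#' Fraction of benign-labelled missense ddG values classified as DoS
#' under the given thresholds. Non-increasing as the thresholds widen.
#'
#' @param benignDdgs numeric vector of ddG values for benign variants
#'   (missing values dropped).
#' @param thresholds a [StabilityThresholds-class].
#' @return fraction in [0, 1].
#' @export
computeFdr <- function(benignDdgs, thresholds = stabilityThresholds()) {
  benignDdgs <- benignDdgs[!is.na(benignDdgs)]
  if (!length(benignDdgs)) .stopf("benign ddG set is empty")
  mean(classifySubstitution(benignDdgs, thresholds) != "tolerated")
}

#' Deterministic distribution summary (boxplot statistics)
#'
#' Median, quartiles and whisker bounds at 1.5 IQR (clipped to the data
#' range), under the linear-interpolation quantile definition
#' (`stats::quantile` type 7) so summaries are bit-reproducible.
#'
#' @param ddgs numeric vector (missing values dropped).
#' @param probs lower/middle/upper quantile probabilities, default the
#'   quartiles.
#' @return one-row data.frame: `n`, `q_lower`, `median`, `q_upper`,
#'   `whisker_lower`, `whisker_upper`.
#' @export
distributionSummary <- function(ddgs, probs = c(0.25, 0.5, 0.75)) {
  ddgs <- ddgs[!is.na(ddgs)]
  if (!length(ddgs)) .stopf("cannot summarise an empty sample")
  stopifnot(length(probs) == 3L, !is.unsorted(probs))
  q <- unname(quantile(ddgs, probs, type = 7L))
  iqr <- q[3L] - q[1L]
  data.frame(n = length(ddgs), q_lower = q[1L], median = q[2L],
             q_upper = q[3L],
             whisker_lower = min(ddgs[ddgs >= q[1L] - 1.5 * iqr]),
             whisker_upper = max(ddgs[ddgs <= q[3L] + 1.5 * iqr]))
}
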