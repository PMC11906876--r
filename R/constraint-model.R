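# Expected-variant model from trinucleotide mutation rates, observed
# counting, and LOEUF-style 90% upper bounds of O/E for pLoF and DoS
# variant classes.

# Attach per-SNV rates to an enumeration, imputing edge codons whose
# trinucleotide context is incomplete with the mean rate of the same
# (ref, alt) change. Policy "error" refuses incomplete contexts.
.snv_rates <- function(snvs, rates, edgePolicy = c("impute", "error")) {
  edgePolicy <- match.arg(edgePolicy)
  r <- rateLookup(rates, snvs$context, snvs$alt)
  miss <- is.na(r)
  if (any(miss)) {
    if (edgePolicy == "error")
      .stopf("%d SNVs lack a trinucleotide context (missing flanking bases)",
             sum(miss))
    means <- .mean_rates_by_change(rates)
    r[miss] <- unname(means[paste0(snvs$ref[miss], ">", snvs$alt[miss])])
    message(sprintf("%d edge SNVs without full context: mean-rate imputation applied",
                    sum(miss)))
  }
  r
}

# Attach ddG values to enumerated SNVs (missense only) from a DdgMatrix.
.snv_ddg <- function(snvs, ddgMatrix) {
  out <- rep(NA_real_, nrow(snvs))
  mis <- snvs$consequence == "missense"
  if (any(mis) && !is.null(ddgMatrix)) {
    vals <- ddgValues(ddgMatrix)
    i <- snvs$aa_position[mis]
    j <- match(snvs$alt_aa[mis], AA_ALPHABET)
    ok <- i <= nrow(vals)
    out[which(mis)[ok]] <- vals[cbind(i[ok], j[ok])]
  }
  out
}

# Resolve a class predicate (character shorthand or function) into a
# logical over enumerated SNVs. "dos" needs a ddg column.
.class_mask <- function(snvs, classPredicate, threshold,
                        splicePositions = NULL) {
  if (is.function(classPredicate)) return(classPredicate(snvs))
  switch(classPredicate,
    synonymous = snvs$consequence == "synonymous",
    missense   = snvs$consequence == "missense",
    nonsense   = snvs$consequence == "nonsense",
    stop_loss  = snvs$consequence == "stop_loss",
    all        = rep(TRUE, nrow(snvs)),
    plof       = snvs$consequence == "nonsense" |
                 (!is.null(splicePositions) &
                  snvs$position %in% splicePositions),
    dos        = snvs$consequence == "missense" & !is.na(snvs$ddg) &
                 abs(snvs$ddg) > threshold,
    .stopf("unknown class predicate '%s'", classPredicate))
}

#' Expected variant count for a class of SNVs
#'
#' Enumerates all possible SNVs of the gene, selects the class of
#' interest, and returns `E = k * sum(rate(context, alt))` over the
#' qualifying sites -- the trinucleotide-context expected-variant model
#' behind observed/expected constraint scores. For the `"dos"` class a
#' ddG matrix must be supplied; missense SNVs whose ddG is missing are
#' excluded from the class and tallied in the `n_missing_ddg` attribute.
#'
#' @param gene a [GeneModel-class].
#' @param rates a [MutationRateTable-class].
#' @param k calibration scale: a [CalibrationFactor-class] or a positive
#'   number (default 1).
#' @param classPredicate `"synonymous"`, `"missense"`, `"nonsense"`,
#'   `"stop_loss"`, `"plof"` (nonsense, plus any supplied splice-site
#'   positions), `"dos"` (missense with |ddG| strictly above
#'   `threshold`), `"all"`, or a function mapping the enumeration
#'   data.frame to a logical vector.
#' @param ddgMatrix [DdgMatrix-class] for the `"dos"` class.
#' @param threshold |ddG| cut-off for `"dos"`, default 0.5.
#' @param splicePositions optional CDS positions counted as pLoF in
#'   addition to nonsense SNVs.
#' @param edgePolicy handling of edge codons lacking flank context:
#'   `"impute"` (mean rate of the same base change, logged) or
#'   `"error"`.
#' @return expected count (nonnegative), with attribute `n_missing_ddg`.
#' @export
expectedClassCount <- function(gene, rates, k = 1, classPredicate,
                               ddgMatrix = NULL, threshold = 0.5,
                               splicePositions = NULL,
                               edgePolicy = c("impute", "error")) {
  snvs <- enumerateSnvs(gene)
  snvs$ddg <- .snv_ddg(snvs, ddgMatrix)
  r <- .snv_rates(snvs, rates, edgePolicy)
  if (identical(classPredicate, "dos") && is.null(ddgMatrix))
    .stopf("class 'dos' requires a ddG matrix")
  mask <- .class_mask(snvs, classPredicate, threshold, splicePositions)
  kval <- if (is(k, "CalibrationFactor")) calibrationK(k) else k
  out <- kval * sum(r[mask])
  attr(out, "n_missing_ddg") <-
    if (identical(classPredicate, "dos"))
      sum(snvs$consequence == "missense" & is.na(snvs$ddg))
    else 0L
  out
}

#' Calibrate the mutation-rate scale on synonymous variation
#'
#' Fits the dimensionless factor k mapping per-gene summed context rates
#' to observed synonymous variant counts: the least-squares-through-
#' origin estimate `k = sum(observed) / sum(rate sums)`. Synonymous
#' variation is taken as effectively neutral, so it carries the cohort's
#' mutation supply without selection.
#'
#' @param genes named list of [GeneModel-class] objects.
#' @param rates a [MutationRateTable-class].
#' @param observedSynonymous named numeric vector of per-gene observed
#'   synonymous counts (names matching gene ids; genes absent from the
#'   vector count 0).
#' @param edgePolicy see [expectedClassCount()].
#' @return a [CalibrationFactor-class] with a `diagnostics` attribute
#'   holding per-gene observed, rate sum, fitted count and residual.
#' @export
calibrateRateScale <- function(genes, rates, observedSynonymous,
                               edgePolicy = c("impute", "error")) {
  rate_sums <- vapply(genes, function(g)
    as.numeric(expectedClassCount(g, rates, k = 1,
                                  classPredicate = "synonymous",
                                  edgePolicy = edgePolicy)),
    numeric(1L))
  ids <- vapply(genes, geneId, character(1L))
  obs <- unname(observedSynonymous[ids])
  obs[is.na(obs)] <- 0
  if (sum(rate_sums) <= 0)
    .stopf("total synonymous rate sum is zero; cannot calibrate")
  k <- sum(obs) / sum(rate_sums)
  if (k <= 0)
    .stopf("degenerate calibration: no observed synonymous variants")
  out <- new("CalibrationFactor", k = k,
             fittedOn = sprintf("synonymous variants of %d genes",
                                length(genes)))
  attr(out, "diagnostics") <- data.frame(gene_id = ids, observed = obs,
                                         rate_sum = rate_sums,
                                         fitted = k * rate_sums,
                                         residual = obs - k * rate_sums,
                                         row.names = NULL)
  out
}

#' LOEUF-style upper bound of the observed/expected ratio
#'
#' The one-sided upper bound of the level-`ci` confidence interval for a
#' Poisson rate ratio: with O observed events against E expected, the
#' bound r_U solves the accumulation of `(1+ci)/2` mass of the
#' normalised Poisson likelihood over the ratio r, which in closed form
#' is the gamma quantile with shape O+1 and rate E. For O = 0 this
#' reduces to `-log((1-ci)/2)/E`. The result is capped at `cap`
#' (published constraint tables use 2.0).
#'
#' The `"grid"` method evaluates the normalised likelihood numerically on
#' an r grid of step 0.001 and serves as an independent cross-check of
#' the closed form; the two agree within 0.002.
#'
#' @param observed nonnegative observed count(s).
#' @param expected positive expected count(s).
#' @param ci confidence level in (0,1), default 0.90.
#' @param cap upper cap, default 2.0.
#' @param method `"gamma"` (closed form, vectorised) or `"grid"`.
#' @return the capped upper bound(s).
#' @examples
#' loeufUpperBound(0, 10)    # -log(0.05)/10 = 0.2996
#' loeufUpperBound(10, 10)   # ~1.70
#' @export
loeufUpperBound <- function(observed, expected, ci = 0.90, cap = 2.0,
                            method = c("gamma", "grid")) {
  method <- match.arg(method)
  if (any(expected <= 0)) .stopf("expected must be positive")
  if (any(observed < 0)) .stopf("observed must be nonnegative")
  if (!(ci > 0 && ci < 1)) .stopf("ci must lie in (0,1)")
  level <- (1 + ci) / 2
  if (method == "gamma")
    return(pmin(qgamma(level, shape = observed + 1, rate = expected), cap))
  mapply(function(o, e) {
    step <- 0.001
    rmax <- (o + 1) / e + 20 * sqrt(o + 1) / e
    r <- seq(0, rmax, by = step)
    loglik <- o * log(pmax(r, .Machine$double.xmin)) - e * r
    if (o == 0) loglik <- -e * r
    f <- exp(loglik - max(loglik))
    cum <- cumsum(f) / sum(f)
    min(r[which(cum >= level)[1L]], cap)
  }, observed, expected)
}

#' Count observed variants of a class per gene
#'
#' Distinct qualifying variants (gene, position, ref, alt) with allele
#' count at least `minAlleleCount`. The `"dos"` class is missense
#' variation outside the tolerated stability interval; `"plof"` is SNV
#' nonsense.
#'
#' @param variants a [variantTable()] data.frame.
#' @param class `"plof"`, `"dos"`, `"synonymous"` or `"missense"`.
#' @param thresholds a [StabilityThresholds-class] (used for `"dos"`).
#' @param minAlleleCount minimum allele count, default 1.
#' @return named integer vector of per-gene counts.
#' @export
observedClassCount <- function(variants, class = c("plof", "dos",
                                                   "synonymous",
                                                   "missense"),
                               thresholds = stabilityThresholds(),
                               minAlleleCount = 1L) {
  class <- match.arg(class)
  v <- variants[!is.na(variants$allele_count) &
                variants$allele_count >= minAlleleCount, , drop = FALSE]
  key <- paste(v$gene_id, v$nt_position, v$ref_base, v$alt_base, sep = ":")
  v <- v[!duplicated(key), , drop = FALSE]
  keep <- switch(class,
    plof = v$consequence == "nonsense",
    synonymous = v$consequence == "synonymous",
    missense = v$consequence == "missense" & !is.na(v$ddg),
    dos = v$consequence == "missense" & !is.na(v$ddg) &
      classifySubstitution(ifelse(is.na(v$ddg), 0, v$ddg),
                           thresholds) != "tolerated")
  cnt <- table(v$gene_id[keep])
  setNames(as.integer(cnt), names(cnt))
}

#' Per-gene constraint records for pLoF and DoS variation
#'
#' Assembles, for each gene and both variant classes, the observed
#' count, the calibrated expected count, the O/E ratio, the LOEUF-style
#' upper bound and the decile bin (per class, 0 = most constrained).
#'
#' @param genes named list of [GeneModel-class] objects.
#' @param matrices named list of [DdgMatrix-class] objects (by gene id).
#' @param variants population [variantTable()] data.frame.
#' @param rates a [MutationRateTable-class].
#' @param k a [CalibrationFactor-class] or positive scale; by default
#'   calibrated on the synonymous variants of `variants` via
#'   [calibrateRateScale()].
#' @param thresholds a [StabilityThresholds-class].
#' @param ci,cap see [loeufUpperBound()].
#' @param edgePolicy see [expectedClassCount()].
#' @return data.frame with columns `gene_id`, `variant_class`,
#'   `observed`, `expected`, `oe`, `loeuf`, `decile`.
#' @export
constraintTable <- function(genes, matrices, variants, rates, k = NULL,
                            thresholds = stabilityThresholds(), ci = 0.90,
                            cap = 2.0, edgePolicy = "impute") {
  ids <- vapply(genes, geneId, character(1L))
  if (is.null(k)) {
    obs_syn <- observedClassCount(variants, "synonymous", thresholds)
    k <- calibrateRateScale(genes, rates, obs_syn, edgePolicy = edgePolicy)
  }
  threshold <- thresholds@upper  # symmetric |ddG| rule for expected DoS
  exp_plof <- vapply(genes, function(g)
    as.numeric(expectedClassCount(g, rates, k, "plof",
                                  edgePolicy = edgePolicy)), numeric(1L))
  exp_dos <- vapply(ids, function(gid)
    as.numeric(expectedClassCount(genes[[gid]], rates, k, "dos",
                                  ddgMatrix = matrices[[gid]],
                                  threshold = threshold,
                                  edgePolicy = edgePolicy)), numeric(1L))
  obs_plof <- observedClassCount(variants, "plof", thresholds)
  obs_dos <- observedClassCount(variants, "dos", thresholds)
  get0s <- function(cnt) {
    out <- unname(cnt[ids]); out[is.na(out)] <- 0L; out
  }
  build <- function(cls, obs, expd) {
    expd <- pmax(expd, .Machine$double.eps)
    loeuf <- loeufUpperBound(obs, expd, ci = ci, cap = cap)
    data.frame(gene_id = ids, variant_class = cls, observed = obs,
               expected = expd, oe = obs / expd, loeuf = loeuf,
               decile = unname(assignDeciles(setNames(loeuf, ids))),
               row.names = NULL)
  }
  rbind(build("plof", get0s(obs_plof), exp_plof),
        build("dos", get0s(obs_dos), exp_dos))
}

#' Assign constraint decile bins
#'
#' Ascending-rank deciles of per-gene scores: bin 0 holds the lowest
#' (most constrained) values. Bin sizes are equal up to the remainder
#' (the first `n %% 10` bins take one extra gene); ties are broken by
#' lexicographic gene id so the partition is deterministic.
#'
#' @param scores named numeric vector (names are gene ids), length >= 10.
#' @return named integer vector of bins 0-9.
#' @export
assignDeciles <- function(scores) {
  n <- length(scores)
  if (n < 10L) .stopf("decile binning needs at least 10 genes, got %d", n)
  ids <- names(scores)
  if (is.null(ids)) .stopf("scores must be named by gene id")
  ord <- order(scores, ids)
  sizes <- rep(n %/% 10L, 10L)
  if (n %% 10L) sizes[seq_len(n %% 10L)] <- sizes[seq_len(n %% 10L)] + 1L
  bins <- integer(n)
  bins[ord] <- rep(0:9, times = sizes)
  setNames(bins, ids)
}

#' Decile-membership confusion matrix
#'
#' Cross-tabulates two decile assignments over the same gene universe:
#' cell (i, j) counts genes in bin i under the first binning and bin j
#' under the second (the comparison behind heatmaps of gene membership
#' across constraint scores).
#'
#' @param binsA,binsB named integer vectors of bins 0-9 over identical
#'   gene sets.
#' @return 10 x 10 integer matrix with dimnames `0:9`.
#' @export
decileConfusion <- function(binsA, binsB) {
  onlyA <- setdiff(names(binsA), names(binsB))
  onlyB <- setdiff(names(binsB), names(binsA))
  if (length(onlyA) || length(onlyB))
    .stopf("gene universes differ (only in A: %s; only in B: %s)",
           paste(head(onlyA, 5L), collapse = ","),
           paste(head(onlyB, 5L), collapse = ","))
  binsB <- binsB[names(binsA)]
  m <- table(factor(binsA, levels = 0:9), factor(binsB, levels = 0:9))
  matrix(as.integer(m), nrow = 10L, dimnames = list(A = 0:9, B = 0:9))
}

#' Rank genes by pLoF-vs-DoS LOEUF difference
#'
#' Joins the two constraint record sets on gene id and orders genes by
#' descending absolute difference of their LOEUF values. Short genes
#' with few or no observed pLoF variants but ample DoS variation surface
#' at the top of this ranking.
#'
#' @param recordsPlof,recordsDos constraint data.frames with columns
#'   `gene_id`, `observed`, `expected`, `oe`, `loeuf`.
#' @return merged data.frame with `_plof` / `_dos` suffixed columns,
#'   `loeuf_diff` (plof - dos) and `abs_diff`, ordered by descending
#'   `abs_diff` then gene id.
#' @export
rankLoeufDifferences <- function(recordsPlof, recordsDos) {
  cols <- c("gene_id", "observed", "expected", "oe", "loeuf")
  merged <- merge(recordsPlof[, cols], recordsDos[, cols], by = "gene_id",
                  suffixes = c("_plof", "_dos"))
  if (nrow(merged) == 0L) .stopf("no genes shared between the two record sets")
  merged$loeuf_diff <- merged$loeuf_plof - merged$loeuf_dos
  merged$abs_diff <- abs(merged$loeuf_diff)
  merged[order(-merged$abs_diff, merged$gene_id), , drop = FALSE]
}
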