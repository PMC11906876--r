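# Order/disorder and mobility summaries from structure-confidence values.

#' Fraction of ordered residues in a predicted model
#'
#' Fraction of residues with pLDDT strictly above the cutoff (default 70
#' on the 0-100 scale; values supplied on a 0-1 scale are rescaled when
#' the maximum is <= 1, since the same confidence is written both ways
#' in the wild). Invariant under residue reordering.
#'
#' @param conf a [StructureConfidence-class]; expected to be a predicted
#'   model (a warning is raised for experimental sources).
#' @param cutoff pLDDT cutoff, default 70.
#' @return fraction in [0, 1].
#' @export
orderedFraction <- function(conf, cutoff = 70) {
  stopifnot(is(conf, "StructureConfidence"))
  v <- conf@values
  if (!length(v)) .stopf("structure %s has no residues", conf@proteinId)
  if (sourceKind(conf) != "predicted_model")
    .warnf("orderedFraction expects a predicted model; %s is %s",
           conf@proteinId, sourceKind(conf))
  if (max(v) <= 1) v <- v * 100
  mean(v > cutoff)
}

#' Median B-factor of an experimental structure
#'
#' Median of the per-residue B-factors (even counts average the two
#' central order statistics). Higher values indicate greater positional
#' uncertainty / mobility of atoms in the crystal.
#'
#' @param conf a [StructureConfidence-class]; expected experimental.
#' @return median B-factor (A^2).
#' @export
medianBfactor <- function(conf) {
  stopifnot(is(conf, "StructureConfidence"))
  if (!length(conf@values))
    .stopf("structure %s has no residues", conf@proteinId)
  if (sourceKind(conf) != "experimental")
    .warnf("medianBfactor expects an experimental structure; %s is %s",
           conf@proteinId, sourceKind(conf))
  median(conf@values)
}

# Decile bins 0-2 / 3-6 / 7-9 grouped as in constraint-category summaries.
.decile_group <- function(decile) {
  cut(decile, breaks = c(-1, 2, 6, 9),
      labels = c("Most", "Intermediate", "Least"))
}

#' Per-group summaries of a gene-level metric
#'
#' Groups per-gene values by a constraint annotation and emits a
#' deterministic summary (n, median, quartiles) per group.
#' Groupings: `"loeuf_decile_grouped"` collapses LOEUF deciles to Most
#' (bins 0-2), Intermediate (3-6) and Least (7-9); `"shet_category"`
#' uses the extreme/strong/weak/neutral vocabulary; `"pli_binary"`
#' splits at pLi 0.5 (low < 0.5 <= high). Genes that cannot be resolved
#' to a group are dropped and tallied in the `n_dropped` attribute;
#' empty groups are emitted with n = 0 and missing summaries.
#'
#' @param values data.frame with columns `gene_id` and `value`.
#' @param annotations data.frame with `gene_id` and the columns the
#'   grouping needs (`loeuf`, `shet_category` or `pli`).
#' @param grouping grouping rule.
#' @param deciles optional named decile vector overriding the
#'   LOEUF-derived binning.
#' @return data.frame with `group`, `n`, `median`, `q_lower`, `q_upper`;
#'   attribute `n_dropped`.
#' @export
groupedMetricTable <- function(values, annotations,
                               grouping = c("loeuf_decile_grouped",
                                            "shet_category", "pli_binary"),
                               deciles = NULL) {
  grouping <- match.arg(grouping)
  j <- match(values$gene_id, annotations$gene_id)
  group <- switch(grouping,
    loeuf_decile_grouped = {
      d <- if (!is.null(deciles)) unname(deciles[values$gene_id])
           else {
             lo <- annotations$loeuf[j]
             names(lo) <- values$gene_id
             unname(assignDeciles(lo[!is.na(lo)])[values$gene_id])
           }
      as.character(.decile_group(d))
    },
    shet_category = annotations$shet_category[j],
    pli_binary = ifelse(is.na(annotations$pli[j]), NA,
                        ifelse(annotations$pli[j] < 0.5, "low_pli",
                               "high_pli")))
  levels <- switch(grouping,
                   loeuf_decile_grouped = c("Most", "Intermediate", "Least"),
                   shet_category = SHET_CATEGORIES,
                   pli_binary = c("low_pli", "high_pli"))
  dropped <- is.na(group)
  out <- do.call(rbind, lapply(levels, function(g) {
    v <- values$value[!dropped & group == g]
    if (!length(v))
      return(data.frame(group = g, n = 0L, median = NA_real_,
                        q_lower = NA_real_, q_upper = NA_real_))
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7L))
    data.frame(group = g, n = length(v), median = q[2L], q_lower = q[1L],
               q_upper = q[3L])
  }))
  attr(out, "n_dropped") <- sum(dropped)
  out
}
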