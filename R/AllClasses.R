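# S4 classes for the core data containers.

#' DdgMatrix: per-protein grid of predicted stability changes
#'
#' Holds the predicted change in folding free energy (ddG, kcal/mol) for
#' every possible single amino-acid substitution in one protein: an L x 20
#' matrix indexed by (position, alternate amino acid). Cells for the
#' wild-type residue at each position are masked out of all aggregations;
#' substitutions without a prediction are `NA`.
#'
#' @slot proteinId single protein/gene identifier.
#' @slot aaSequence wild-type amino-acid sequence of length L. Positions
#'   whose residue is unknown (e.g. a sparse input table) are `"X"`.
#' @slot ddg numeric L x 20 matrix, columns in alphabetical one-letter
#'   amino-acid order.
#'
#' @seealso [readDdgTable()], [computeIHS()], [ihsProfile()]
#' @export
setClass("DdgMatrix",
  representation(proteinId = "character",
                 aaSequence = "character",
                 ddg = "matrix"))

setValidity("DdgMatrix", function(object) {
  msg <- character()
  if (!.is_scalar_string(object@proteinId))
    msg <- c(msg, "proteinId must be a single string")
  if (!.is_scalar_string(object@aaSequence))
    msg <- c(msg, "aaSequence must be a single string")
  if (!is.numeric(object@ddg))
    msg <- c(msg, "ddg must be a numeric matrix")
  if (!identical(colnames(object@ddg), AA_ALPHABET))
    msg <- c(msg, "ddg columns must be the 20 amino acids in alphabetical order")
  if (nrow(object@ddg) != nchar(object@aaSequence))
    msg <- c(msg, "ddg row count must equal sequence length")
  aa <- .chars(object@aaSequence)
  if (!all(aa %in% c(AA_ALPHABET, "X")))
    msg <- c(msg, "sequence letters must be standard amino acids or 'X'")
  bad <- is.infinite(object@ddg)
  if (any(bad)) msg <- c(msg, "ddg cells must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a DdgMatrix
#'
#' @param proteinId protein identifier.
#' @param sequence wild-type amino-acid sequence (length L).
#' @param ddg numeric L x 20 matrix of ddG values (kcal/mol), columns named
#'   by the 20 amino acids in alphabetical order. Missing predictions are
#'   `NA`; values in wild-type cells are ignored downstream.
#' @return a [DdgMatrix-class] object.
#' @examples
#' m <- matrix(0, nrow = 2, ncol = 20, dimnames = list(NULL, dosconstraint:::AA_ALPHABET))
#' DdgMatrix("P1", "MW", m)
#' @export
DdgMatrix <- function(proteinId, sequence, ddg) {
  if (is.null(colnames(ddg))) colnames(ddg) <- AA_ALPHABET
  new("DdgMatrix", proteinId = proteinId, aaSequence = sequence,
      ddg = as.matrix(ddg))
}

setMethod("show", "DdgMatrix", function(object) {
  L <- nrow(object@ddg)
  n_na <- sum(is.na(object@ddg) & !wildtypeMask(object))
  cat("DdgMatrix", object@proteinId, "\n",
      " length:", L, "residues;", L * 19L, "substitutions,",
      n_na, "missing\n")
})

#' StabilityThresholds: the tolerated ddG interval
#'
#' Lower (negative, overly-stabilising) and upper (positive, destabilising)
#' ddG cut-offs in kcal/mol. A substitution strictly inside the open
#' interval is tolerated; outside it is a Disruption-of-Stability (DoS)
#' variant.
#'
#' @slot lower negative bound (kcal/mol).
#' @slot upper positive bound (kcal/mol).
#' @export
setClass("StabilityThresholds",
  representation(lower = "numeric", upper = "numeric"))

setValidity("StabilityThresholds", function(object) {
  if (!.is_scalar_number(object@lower) || !.is_scalar_number(object@upper))
    return("lower and upper must be single finite numbers")
  if (!(object@lower < 0 && 0 < object@upper))
    return("thresholds must satisfy lower < 0 < upper")
  TRUE
})

#' Construct stability thresholds
#'
#' @param lower negative cut-off, default -0.5 kcal/mol.
#' @param upper positive cut-off, default 0.5 kcal/mol.
#' @return a [StabilityThresholds-class] object.
#' @export
stabilityThresholds <- function(lower = -0.5, upper = 0.5) {
  new("StabilityThresholds", lower = lower, upper = upper)
}

setMethod("show", "StabilityThresholds", function(object) {
  cat(sprintf("StabilityThresholds: tolerated %g < ddG < %g kcal/mol\n",
              object@lower, object@upper))
})

#' GeneModel: one canonical coding sequence
#'
#' A coding sequence (CDS) on its coding strand, with optional single
#' flanking bases so edge codpositions have a full trinucleotide context.
#'
#' @slot geneId gene identifier.
#' @slot transcriptId transcript identifier.
#' @slot cds nucleotide string over ACGT, length divisible by 3.
#' @slot upstreamBase single base 5' of the CDS, or `NA`.
#' @slot downstreamBase single base 3' of the CDS, or `NA`.
#' @export
setClass("GeneModel",
  representation(geneId = "character", transcriptId = "character",
                 cds = "character", upstreamBase = "character",
                 downstreamBase = "character"))

setValidity("GeneModel", function(object) {
  msg <- character()
  if (!.is_scalar_string(object@geneId))
    msg <- c(msg, "geneId must be a single string")
  if (!.is_scalar_string(object@cds))
    msg <- c(msg, "cds must be a single string")
  else {
    if (nchar(object@cds) %% 3L != 0L)
      msg <- c(msg, "CDS length must be divisible by 3")
    if (!all(.chars(object@cds) %in% DNA_BASES))
      msg <- c(msg, "CDS alphabet must be {A,C,G,T}")
  }
  for (fl in c("upstreamBase", "downstreamBase")) {
    b <- slot(object, fl)
    if (!(length(b) == 1L && (is.na(b) || b %in% DNA_BASES)))
      msg <- c(msg, paste(fl, "must be a single base or NA"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneId,transcriptId identifiers.
#' @param cds coding sequence over ACGT, length divisible by 3, coding
#'   strand, including the terminal stop codon if present.
#' @param upstreamBase,downstreamBase optional single flanking bases used
#'   to complete trinucleotide contexts at the CDS edges.
#' @return a [GeneModel-class] object.
#' @export
GeneModel <- function(geneId, cds, transcriptId = geneId,
                      upstreamBase = NA_character_,
                      downstreamBase = NA_character_) {
  new("GeneModel", geneId = geneId, transcriptId = transcriptId,
      cds = toupper(cds), upstreamBase = as.character(upstreamBase),
      downstreamBase = as.character(downstreamBase))
}

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId, sprintf("(%s):", object@transcriptId),
      nchar(object@cds), "nt,", nchar(object@cds) / 3L, "codons\n")
})

#' MutationRateTable: trinucleotide-context substitution rates
#'
#' Relative per-site mutation rates keyed by (trinucleotide context,
#' alternate central base). Either a full 64 x 3 table on the coding
#' strand, or a strand-collapsed 32 x 3 table with central base in {A, C},
#' in which case lookups for G/T-centred contexts resolve through the
#' reverse complement.
#'
#' @slot rates named numeric vector; names are `"NNN>B"` with `NNN` the
#'   context and `B` the alternate central base.
#' @slot strandCollapsed logical flag.
#' @export
setClass("MutationRateTable",
  representation(rates = "numeric", strandCollapsed = "logical"))

.rate_keys <- function(collapsed) {
  centrals <- if (collapsed) c("A", "C") else DNA_BASES
  keys <- character()
  for (up in DNA_BASES) for (ce in centrals) for (dn in DNA_BASES)
    for (alt in setdiff(DNA_BASES, ce))
      keys <- c(keys, paste0(up, ce, dn, ">", alt))
  keys
}

setValidity("MutationRateTable", function(object) {
  msg <- character()
  if (any(!is.finite(object@rates)) || any(object@rates < 0))
    msg <- c(msg, "all rates must be finite and >= 0")
  expected <- sort(.rate_keys(object@strandCollapsed))
  if (!identical(sort(names(object@rates)), expected))
    msg <- c(msg, sprintf("rate table must contain exactly the %d (context, alt) keys",
                          length(expected)))
  if (length(msg)) msg else TRUE
})

#' Construct a MutationRateTable
#'
#' @param rates named numeric vector keyed `"NNN>B"`.
#' @param strandCollapsed whether contexts are restricted to central A/C
#'   with reverse-complement lookup for the rest.
#' @return a [MutationRateTable-class] object.
#' @seealso [defaultMutationRateTable()], [rateLookup()]
#' @export
MutationRateTable <- function(rates, strandCollapsed = FALSE) {
  new("MutationRateTable", rates = rates, strandCollapsed = strandCollapsed)
}

setMethod("show", "MutationRateTable", function(object) {
  cat("MutationRateTable:", length(object@rates), "entries",
      if (object@strandCollapsed) "(strand-collapsed)" else "(full)",
      sprintf("mean rate %.3g\n", mean(object@rates)))
})

#' StructureConfidence: per-residue B-factor / pLDDT track
#'
#' Ordered per-residue confidence values for one protein structure:
#' crystallographic B-factors (A^2) for experimental structures, or pLDDT
#' (0-100) stored in the B-factor column of predicted models.
#'
#' @slot proteinId protein identifier.
#' @slot residueIndex strictly increasing 1-based residue indices.
#' @slot values finite, nonnegative per-residue values.
#' @slot sourceKind `"experimental"` or `"predicted_model"`.
#' @export
setClass("StructureConfidence",
  representation(proteinId = "character", residueIndex = "integer",
                 values = "numeric", sourceKind = "character"))

setValidity("StructureConfidence", function(object) {
  msg <- character()
  if (length(object@residueIndex) != length(object@values))
    msg <- c(msg, "residueIndex and values must have equal length")
  if (length(object@residueIndex) &&
      any(diff(object@residueIndex) <= 0L))
    msg <- c(msg, "residue indices must be strictly increasing")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and nonnegative")
  if (!(length(object@sourceKind) == 1L &&
        object@sourceKind %in% c("experimental", "predicted_model")))
    msg <- c(msg, "sourceKind must be 'experimental' or 'predicted_model'")
  if (length(msg)) msg else TRUE
})

#' Construct a StructureConfidence track
#'
#' @param proteinId identifier.
#' @param values per-residue values.
#' @param residueIndex 1-based residue indices (default sequential).
#' @param sourceKind `"experimental"` or `"predicted_model"`.
#' @return a [StructureConfidence-class] object.
#' @export
StructureConfidence <- function(proteinId, values,
                                residueIndex = seq_along(values),
                                sourceKind = "experimental") {
  new("StructureConfidence", proteinId = proteinId,
      residueIndex = as.integer(residueIndex), values = as.numeric(values),
      sourceKind = sourceKind)
}

setMethod("show", "StructureConfidence", function(object) {
  cat("StructureConfidence", object@proteinId,
      sprintf("(%s): %d residues, values %.1f-%.1f\n", object@sourceKind,
              length(object@values),
              if (length(object@values)) min(object@values) else NA,
              if (length(object@values)) max(object@values) else NA))
})

#' InstabilityHeatScore: per-protein mutational fragility
#'
#' Mean of |ddG| over the set S of possible substitutions whose absolute
#' predicted stability change exceeds the threshold. A protein with no
#' qualifying substitution has value 0 with `nQualifying` 0; any non-empty
#' S yields a value strictly greater than the threshold, so the sentinel
#' is unambiguous.
#'
#' @slot proteinId protein identifier.
#' @slot value IHS in kcal/mol.
#' @slot nQualifying size of S.
#' @slot thresholdUsed |ddG| cut-off (kcal/mol).
#' @export
setClass("InstabilityHeatScore",
  representation(proteinId = "character", value = "numeric",
                 nQualifying = "integer", thresholdUsed = "numeric"))

setValidity("InstabilityHeatScore", function(object) {
  if (object@nQualifying == 0L && object@value != 0)
    return("value must be 0 when no substitution qualifies")
  if (object@nQualifying > 0L && object@value <= object@thresholdUsed)
    return("a non-empty qualifying set implies value > threshold")
  TRUE
})

setMethod("show", "InstabilityHeatScore", function(object) {
  cat(sprintf("IHS %s: %.3f kcal/mol (%d substitutions > %g)\n",
              object@proteinId, object@value, object@nQualifying,
              object@thresholdUsed))
})

#' CalibrationFactor: mutation-rate to cohort-count scale
#'
#' Dimensionless factor k mapping summed context rates to expected variant
#' counts in the analysed cohort, fitted on synonymous variation.
#'
#' @slot k positive scale.
#' @slot fittedOn free-text description of the fitting set.
#' @export
setClass("CalibrationFactor",
  representation(k = "numeric", fittedOn = "character"))

setValidity("CalibrationFactor", function(object) {
  if (!.is_scalar_number(object@k) || object@k <= 0)
    return("k must be a single positive number")
  TRUE
})

setMethod("show", "CalibrationFactor", function(object) {
  cat(sprintf("CalibrationFactor k = %.4g (fitted on %s)\n", object@k,
              object@fittedOn))
})

#' DepletionScan: threshold derivation from constrained-vs-unconstrained tails
#'
#' Grid scan of survival-probability ratios between a constrained and an
#' unconstrained ddG sample, and the chosen tolerated-stability thresholds
#' (NA when no grid point met the depletion cut-off).
#'
#' @slot grid strictly increasing candidate thresholds (kcal/mol).
#' @slot upperTailRatio,lowerTailRatio per-grid-point constrained /
#'   unconstrained survival ratios (NA where the unconstrained tail was
#'   below `minTailN`).
#' @slot chosenLower,chosenUpper selected thresholds or NA sentinels.
#' @slot depletionCutoff ratio in (0,1) a tail must drop to.
#' @slot minTailN minimum unconstrained tail count for a grid point to be
#'   evaluated.
#' @export
setClass("DepletionScan",
  representation(grid = "numeric", upperTailRatio = "numeric",
                 lowerTailRatio = "numeric", chosenLower = "numeric",
                 chosenUpper = "numeric", depletionCutoff = "numeric",
                 minTailN = "numeric"))

setValidity("DepletionScan", function(object) {
  msg <- character()
  if (length(object@grid) && any(diff(object@grid) <= 0))
    msg <- c(msg, "grid must be strictly increasing")
  if (length(object@upperTailRatio) != length(object@grid) ||
      length(object@lowerTailRatio) != length(object@grid))
    msg <- c(msg, "tail ratio vectors must align with the grid")
  ok <- function(r) all(is.na(r) | r >= 0)
  if (!ok(object@upperTailRatio) || !ok(object@lowerTailRatio))
    msg <- c(msg, "tail ratios must be nonnegative or NA")
  for (ch in c(object@chosenLower, object@chosenUpper))
    if (!is.na(ch) && !any(abs(object@grid - abs(ch)) < 1e-9))
      msg <- c(msg, "chosen thresholds must be members of the grid")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DepletionScan", function(object) {
  cat("DepletionScan over", length(object@grid), "grid points,",
      sprintf("depletion cutoff %g\n", object@depletionCutoff))
  if (is.na(object@chosenUpper) && is.na(object@chosenLower)) {
    cat("  no thresholds found (no tail depleted below the cutoff)\n")
  } else {
    cat(sprintf("  chosen thresholds: lower %s, upper %s kcal/mol\n",
                format(object@chosenLower), format(object@chosenUpper)))
  }
})

#' Extract the chosen thresholds of a depletion scan
#'
#' @param scan a [DepletionScan-class] object.
#' @return a [StabilityThresholds-class] object, or `NULL` when the scan
#'   ended in the not-found sentinel on either side.
#' @export
chosenThresholds <- function(scan) {
  stopifnot(is(scan, "DepletionScan"))
  if (is.na(scan@chosenLower) || is.na(scan@chosenUpper)) return(NULL)
  stabilityThresholds(lower = scan@chosenLower, upper = scan@chosenUpper)
}
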