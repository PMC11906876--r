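# DoS classification and the Instability Heat Score.

#' Classify substitutions by their stability effect
#'
#' A substitution is tolerated iff its ddG lies strictly inside the open
#' interval (lower, upper); `ddg > upper` is a destabilising DoS variant
#' and `ddg < lower` an overly-stabilising one. Boundary values are
#' tolerated: a DoS call requires a strict exceedance, consistent with the
#' IHS qualifying rule (|ddG| strictly above the threshold). The
#' convention is measure-zero for real-valued predictions and
#' configurable through `thresholds`.
#'
#' @param ddg numeric vector of stability changes (kcal/mol); must be
#'   finite.
#' @param thresholds a [StabilityThresholds-class]; default -0.5 / 0.5.
#' @return character vector over `"stabilizing_dos"`, `"tolerated"`,
#'   `"destabilizing_dos"` -- a partition of the finite reals.
#' @examples
#' classifySubstitution(c(0.6, -0.7, 0.5), stabilityThresholds())
#' @export
classifySubstitution <- function(ddg, thresholds = stabilityThresholds()) {
  stopifnot(is(thresholds, "StabilityThresholds"))
  if (any(!is.finite(ddg)))
    .stopf("ddg values must be finite (%d offending)", sum(!is.finite(ddg)))
  out <- rep("tolerated", length(ddg))
  out[ddg > thresholds@upper] <- "destabilizing_dos"
  out[ddg < thresholds@lower] <- "stabilizing_dos"
  out
}

#' Compute the Instability Heat Score of a protein
#'
#' IHS is the mean of |ddG| over the set S of all possible substitutions
#' whose absolute predicted stability change is strictly greater than the
#' threshold. Wild-type cells and missing predictions are excluded from S
#' and from its size. When S is empty the score is 0 with
#' `nQualifying = 0` -- unambiguous, since a non-empty S always yields a
#' value above the threshold.
#'
#' @param matrix a [DdgMatrix-class] with at least one non-missing,
#'   non-wild-type cell.
#' @param threshold symmetric |ddG| cut-off, default 0.5 kcal/mol.
#' @return an [InstabilityHeatScore-class].
#' @examples
#' m <- matrix(NA_real_, 1, 20, dimnames = list(NULL, dosconstraint:::AA_ALPHABET))
#' m[1, c("A", "C", "D", "E")] <- c(0.6, -0.8, 0.1, -0.2)
#' ihsValue(computeIHS(DdgMatrix("p", "M", m)))  # 0.7
#' @export
computeIHS <- function(matrix, threshold = 0.5) {
  stopifnot(is(matrix, "DdgMatrix"))
  cells <- ddgValues(matrix)[!wildtypeMask(matrix)]
  cells <- cells[!is.na(cells)]
  if (!length(cells))
    .stopf("protein %s: ddG matrix is entirely missing", proteinId(matrix))
  qual <- abs(cells) > threshold
  value <- if (any(qual)) mean(abs(cells[qual])) else 0
  new("InstabilityHeatScore", proteinId = proteinId(matrix), value = value,
      nQualifying = sum(qual), thresholdUsed = threshold)
}

#' Per-position instability heat profile
#'
#' For each residue position, the mean |ddG| over qualifying cells
#' (|ddG| strictly above the threshold) and their count; positions with
#' no qualifying substitution report (0, 0). The count-weighted mean of
#' the profile recombines exactly to [computeIHS()].
#'
#' @inheritParams computeIHS
#' @return data.frame with columns `position`, `residue`, `mean_abs_ddg`,
#'   `n_qualifying`.
#' @export
ihsProfile <- function(matrix, threshold = 0.5) {
  stopifnot(is(matrix, "DdgMatrix"))
  vals <- abs(ddgValues(matrix))
  vals[wildtypeMask(matrix)] <- NA_real_
  if (all(is.na(vals)))
    .stopf("protein %s: ddG matrix is entirely missing", proteinId(matrix))
  qual <- !is.na(vals) & vals > threshold
  n_q <- rowSums(qual)
  sums <- rowSums(vals * qual, na.rm = TRUE)
  data.frame(position = seq_len(nrow(vals)),
             residue = .chars(aaSequence(matrix)),
             mean_abs_ddg = ifelse(n_q > 0L, sums / pmax(n_q, 1L), 0),
             n_qualifying = as.integer(n_q))
}

#' Fraction of missense variants classified DoS
#'
#' Counts, among missense variants with a non-missing ddG, those falling
#' outside the tolerated stability interval.
#'
#' @param variants a [variantTable()] data.frame.
#' @param thresholds a [StabilityThresholds-class].
#' @return list with `n_dos`, `n_missense` (missense with non-missing
#'   ddG) and `fraction`.
#' @export
countDosFraction <- function(variants, thresholds = stabilityThresholds()) {
  eligible <- variants$consequence == "missense" & !is.na(variants$ddg)
  if (!any(eligible))
    .stopf("no missense variants with a ddG value")
  cls <- classifySubstitution(variants$ddg[eligible], thresholds)
  n_dos <- sum(cls != "tolerated")
  n_mis <- sum(eligible)
  list(n_dos = n_dos, n_missense = n_mis, fraction = n_dos / n_mis)
}

#' Export a ddG matrix for heatmap plotting
#'
#' Writes a TSV grid with one row per position and one column per amino
#' acid; wild-type cells carry the token `WT`, missing predictions an
#' empty field. The export is lossless: [readHeatmapMatrix()] restores
#' the matrix.
#'
#' @param matrix a [DdgMatrix-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
exportHeatmapMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "DdgMatrix"))
  vals <- ddgValues(matrix)
  mask <- wildtypeMask(matrix)
  grid <- matrix(ifelse(is.na(vals), "",
                        format(vals, digits = 15L, trim = TRUE,
                               scientific = FALSE)),
                 nrow = nrow(vals), dimnames = dimnames(vals))
  grid[mask] <- "WT"
  out <- data.frame(position = seq_len(nrow(vals)), grid,
                    check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# protein_id=", proteinId(matrix)), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a heatmap-matrix export
#'
#' @param path TSV written by [exportHeatmapMatrix()].
#' @return a [DdgMatrix-class].
#' @export
readHeatmapMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  pid <- sub("^# protein_id=", "", first)
  tab <- read.delim(path, skip = 1L, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  grid <- as.matrix(tab[, AA_ALPHABET])
  wt <- grid == "WT"
  vals <- suppressWarnings(matrix(as.numeric(ifelse(grid %in% c("", "WT"),
                                                    NA, grid)),
                                  nrow = nrow(grid),
                                  dimnames = list(NULL, AA_ALPHABET)))
  seq_aa <- rep("X", nrow(grid))
  has_wt <- rowSums(wt) > 0L
  seq_aa[has_wt] <- AA_ALPHABET[apply(wt[has_wt, , drop = FALSE], 1L,
                                      which.max)]
  DdgMatrix(pid, paste(seq_aa, collapse = ""), vals)
}

#' Per-protein IHS table
#'
#' @param matrices list of [DdgMatrix-class] objects.
#' @param threshold |ddG| cut-off, default a constant 0.5. A named
#'   numeric vector (names = protein ids) applies a per-protein cut-off,
#'   e.g. a user-supplied length-dependent threshold rule.
#' @return data.frame with `gene_id`, `ihs`, `n_qualifying`, `threshold`.
#' @export
ihsTable <- function(matrices, threshold = 0.5) {
  scores <- lapply(matrices, function(m) {
    thr <- if (length(threshold) > 1L || !is.null(names(threshold))) {
      t1 <- unname(threshold[proteinId(m)])
      if (length(t1) != 1L || is.na(t1))
        .stopf("no threshold supplied for protein %s", proteinId(m))
      t1
    } else threshold
    computeIHS(m, threshold = thr)
  })
  data.frame(gene_id = vapply(scores, function(s) s@proteinId, character(1L)),
             ihs = vapply(scores, ihsValue, numeric(1L)),
             n_qualifying = vapply(scores, nQualifying, integer(1L)),
             threshold = vapply(scores, function(s) s@thresholdUsed,
                                numeric(1L)),
             row.names = NULL)
}
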