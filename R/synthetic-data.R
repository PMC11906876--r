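# Synthetic cohort generator: genes, ddG matrices, structure-confidence
# tracks and population variants with the statistical structure the
# analysis assumes (constraint narrows tolerated stability variation,
# constrained proteins are more disordered and 'colder', pathogenic
# labels skew destabilising).

#' SimulationConfig: parameters of the synthetic cohort
#'
#' See [simulationConfig()] for slot semantics and defaults.
#'
#' @export
setClass("SimulationConfig",
  representation(nGenes = "integer", lengthMeanLog = "numeric",
                 lengthSdLog = "numeric", minLength = "integer",
                 maxLength = "integer", selectionAlpha = "numeric",
                 selectionBeta = "numeric", selectionS = "numeric",
                 disorderBase = "numeric", disorderSlope = "numeric",
                 sigmaDisordered = "numeric", sigmaOrderedBase = "numeric",
                 sigmaOrderedSlope = "numeric",
                 truncationThreshold = "numeric",
                 pathogenicDosRate = "numeric", pathogenicSkew = "numeric",
                 benignContamination = "numeric",
                 rateTable = "MutationRateTable", cohortSize = "integer",
                 mutationSupply = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pos <- c(sigmaDisordered = object@sigmaDisordered,
           sigmaOrderedBase = object@sigmaOrderedBase,
           truncationThreshold = object@truncationThreshold,
           mutationSupply = object@mutationSupply)
  if (any(pos <= 0))
    msg <- c(msg, "spreads, threshold and mutation supply must be positive")
  prob <- c(object@disorderBase, object@disorderSlope,
            object@pathogenicDosRate, object@pathogenicSkew,
            object@benignContamination, object@selectionS)
  if (any(prob < 0 | prob > 1))
    msg <- c(msg, "probabilities must lie in [0,1]")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (length(object@selectionS) &&
      length(object@selectionS) != object@nGenes)
    msg <- c(msg, "selectionS must be empty or length nGenes")
  if (length(msg)) msg else TRUE
})

#' Configure the synthetic cohort generator
#'
#' The defaults encode the study conditions the generator emulates: a
#' disease-free cohort of 3115 diploid individuals; gene lengths
#' log-normal with median 250 amino acids; per-gene purifying-selection
#' strength s ~ Beta(0.5, 0.5) (mass near both the unconstrained and the
#' strongly constrained ends); intrinsic disorder rising with constraint
#' (expected disordered fraction 0.1 + 0.4 s); near-neutral stability
#' effects in disordered regions (sigma 0.2 kcal/mol) and a wider spread
#' in ordered regions that narrows with constraint
#' (1.0 x (1 - 0.4 s) kcal/mol); a true tolerated bound of +/-0.5
#' kcal/mol beyond which variants face selection; benign labels
#' contaminated with DoS cells at rate 0.06 and pathogenic labels drawn
#' from DoS cells at rate 0.184 with a 0.9 destabilising skew (the
#' ClinVar-like composition the generator is asked to mimic).
#'
#' @param nGenes number of genes, default 200.
#' @param seed RNG seed; every generator output is byte-identical under a
#'   fixed seed.
#' @param lengthMeanLog,lengthSdLog log-normal parameters of protein
#'   length (amino acids, excluding the stop).
#' @param minLength,maxLength clamp on protein length.
#' @param selectionAlpha,selectionBeta Beta parameters for s.
#' @param selectionS optional explicit per-gene s vector (overrides the
#'   Beta draw).
#' @param disorderBase,disorderSlope expected disordered fraction is
#'   `disorderBase + disorderSlope * s`.
#' @param sigmaDisordered ddG spread in disordered regions (kcal/mol).
#' @param sigmaOrderedBase,sigmaOrderedSlope ordered-region spread is
#'   `sigmaOrderedBase * (1 - sigmaOrderedSlope * s)`.
#' @param truncationThreshold true tolerated |ddG| bound (kcal/mol).
#' @param pathogenicDosRate probability a pathogenic label is drawn from
#'   DoS cells.
#' @param pathogenicSkew probability a pathogenic DoS draw is
#'   destabilising rather than overly-stabilising.
#' @param benignContamination probability a benign label is drawn from
#'   DoS cells.
#' @param rateTable a [MutationRateTable-class].
#' @param cohortSize diploid individuals in the simulated cohort.
#' @param mutationSupply per-site scale: a relative-rate-1 site receives
#'   `Poisson(2 * cohortSize * mutationSupply)` mutation events.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nGenes = 200L, seed = 1L,
                             lengthMeanLog = log(250), lengthSdLog = 0.5,
                             minLength = 30L, maxLength = 2000L,
                             selectionAlpha = 0.5, selectionBeta = 0.5,
                             selectionS = numeric(),
                             disorderBase = 0.1, disorderSlope = 0.4,
                             sigmaDisordered = 0.2,
                             sigmaOrderedBase = 1.0,
                             sigmaOrderedSlope = 0.4,
                             truncationThreshold = 0.5,
                             pathogenicDosRate = 0.184,
                             pathogenicSkew = 0.9,
                             benignContamination = 0.06,
                             rateTable = defaultMutationRateTable(),
                             cohortSize = 3115L,
                             mutationSupply = 1.6e-5) {
  new("SimulationConfig", nGenes = as.integer(nGenes),
      lengthMeanLog = lengthMeanLog, lengthSdLog = lengthSdLog,
      minLength = as.integer(minLength), maxLength = as.integer(maxLength),
      selectionAlpha = selectionAlpha, selectionBeta = selectionBeta,
      selectionS = selectionS, disorderBase = disorderBase,
      disorderSlope = disorderSlope, sigmaDisordered = sigmaDisordered,
      sigmaOrderedBase = sigmaOrderedBase,
      sigmaOrderedSlope = sigmaOrderedSlope,
      truncationThreshold = truncationThreshold,
      pathogenicDosRate = pathogenicDosRate,
      pathogenicSkew = pathogenicSkew,
      benignContamination = benignContamination, rateTable = rateTable,
      cohortSize = as.integer(cohortSize),
      mutationSupply = mutationSupply, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d genes, cohort %d, seed %d\n",
              object@nGenes, object@cohortSize, object@seed))
})

#' Default trinucleotide mutation-rate table
#'
#' A full 64 x 3 relative-rate table on the coding strand with the two
#' dominant empirical features of human germline mutation: transitions
#' four-fold faster than transversions and CpG transitions boosted a
#' further ten-fold (C>T in a CG context and its complement G>A after
#' C). Rates are normalised to mean 1 so the calibration factor carries
#' the cohort scale. The table is deterministic.
#'
#' @return a [MutationRateTable-class].
#' @export
defaultMutationRateTable <- function() {
  keys <- .rate_keys(collapsed = FALSE)
  ref <- substr(keys, 2L, 2L)
  alt <- substr(keys, 5L, 5L)
  up <- substr(keys, 1L, 1L)
  dn <- substr(keys, 3L, 3L)
  transition <- paste0(ref, alt) %in% c("AG", "GA", "CT", "TC")
  r <- ifelse(transition, 4, 1)
  cpg <- (ref == "C" & dn == "G" & alt == "T") |
         (ref == "G" & up == "C" & alt == "A")
  r[cpg] <- r[cpg] * 10
  MutationRateTable(setNames(r / mean(r), keys), strandCollapsed = FALSE)
}

# Sense codons (61) for random CDS construction.
.sense_codons <- function() {
  gc <- .codon_table()
  names(gc)[gc != "*"]
}

# Derived sub-seeds keep the stages independently reproducible while
# staying within 32-bit integer range.
.stage_seed <- function(config, offset) {
  as.integer((as.numeric(config@seed) * 7L + offset) %% .Machine$integer.max)
}

#' Generate synthetic gene models and their truth table
#'
#' Random coding sequences with a valid start codon, no internal stops
#' and a terminal stop, lengths drawn from the configured log-normal.
#' The truth table records the per-gene selection strength s and the
#' target disordered fraction used downstream.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `genes` (named list of [GeneModel-class]) and
#'   `truth` (data.frame `gene_id`, `s`, `disorder_fraction`,
#'   `length_aa`).
#' @export
generateGenes <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(.stage_seed(config, 1L))
  n <- config@nGenes
  len <- round(rlnorm(n, config@lengthMeanLog, config@lengthSdLog))
  len <- as.integer(.clamp(len, config@minLength, config@maxLength))
  s <- if (length(config@selectionS)) config@selectionS
       else rbeta(n, config@selectionAlpha, config@selectionBeta)
  target <- .clamp(config@disorderBase + config@disorderSlope * s, 0, 1)
  sense <- setdiff(.sense_codons(), "ATG")
  stops <- c("TAA", "TAG", "TGA")
  ids <- sprintf("G%04d", seq_len(n))
  genes <- lapply(seq_len(n), function(i) {
    body <- sample(sense, len[i] - 1L, replace = TRUE)
    cds <- paste0("ATG", paste(body, collapse = ""),
                  sample(stops, 1L))
    GeneModel(ids[i], cds, transcriptId = sprintf("T%04d", i),
              upstreamBase = sample(DNA_BASES, 1L),
              downstreamBase = sample(DNA_BASES, 1L))
  })
  list(genes = setNames(genes, ids),
       truth = data.frame(gene_id = ids, s = s,
                          disorder_fraction = target, length_aa = len))
}

# Two-state (ordered/disordered) segment chain with target stationary
# disorder fraction f and mean disordered segment length m residues.
.disorder_mask <- function(L, f, m = 25) {
  if (f <= 0) return(rep(FALSE, L))
  if (f >= 1) return(rep(TRUE, L))
  q_leave_dis <- min(1 / m, 0.5)
  q_leave_ord <- min(f / (m * (1 - f)), 0.5)
  state <- logical(L)
  state[1L] <- runif(1L) < f
  flips <- runif(L)
  for (i in seq_len(L - 1L)) {
    p <- if (state[i]) q_leave_dis else q_leave_ord
    state[i + 1L] <- if (flips[i] < p) !state[i] else state[i]
  }
  state
}

#' Generate ddG matrices, disorder masks and pLDDT tracks
#'
#' Disorder is laid out as contiguous blocks (two-state segment model,
#' mean segment ~25 residues) covering on average the truth-table
#' fraction. Substitution ddG values are independent draws:
#' disordered-region cells from Normal(0, sigmaDisordered) -- stability
#' effects are near-neutral where there is no structure to disrupt --
#' and ordered-region cells from Normal(0, sigmaOrdered(s)), narrowing
#' with constraint. Wild-type cells are exactly 0. pLDDT tracks are high
#' in ordered blocks (about 90) and low in disordered blocks (about 45).
#'
#' @param genes,truth output of [generateGenes()].
#' @param config the same [SimulationConfig-class].
#' @return list with `matrices` (named list of [DdgMatrix-class]),
#'   `disorder` (named list of per-residue logical masks) and
#'   `confidence` (named list of [StructureConfidence-class] tracks,
#'   predicted_model kind).
#' @export
generateDdgMatrices <- function(genes, truth, config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(.stage_seed(config, 2L))
  ids <- truth$gene_id
  matrices <- list(); disorder <- list(); confidence <- list()
  for (i in seq_along(ids)) {
    g <- genes[[ids[i]]]
    aa <- translateCds(cdsSequence(g))
    if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
    L <- length(aa)
    mask <- .disorder_mask(L, truth$disorder_fraction[i])
    sigma_ord <- config@sigmaOrderedBase *
      (1 - config@sigmaOrderedSlope * truth$s[i])
    sigma <- ifelse(mask, config@sigmaDisordered, sigma_ord)
    m <- matrix(rnorm(L * 20L, sd = rep(sigma, 20L)), nrow = L,
                dimnames = list(NULL, AA_ALPHABET))
    dm <- DdgMatrix(ids[i], paste(aa, collapse = ""), m)
    wt <- wildtypeMask(dm)
    m[wt] <- 0
    dm@ddg <- m
    plddt <- .clamp(ifelse(mask, rnorm(L, 45, 10), rnorm(L, 90, 5)),
                    0, 100)
    matrices[[ids[i]]] <- dm
    disorder[[ids[i]]] <- mask
    confidence[[ids[i]]] <- StructureConfidence(ids[i], plddt,
                                                sourceKind = "predicted_model")
  }
  list(matrices = matrices, disorder = disorder, confidence = confidence)
}

#' Simulate observed population variants under purifying selection
#'
#' Candidate SNVs arise along each gene in proportion to the
#' trinucleotide mutation rate: each possible SNV receives
#' `Poisson(2 * cohortSize * mutationSupply * rate)` mutation events in
#' the cohort, and a site with at least one event is a distinct
#' candidate variant. Selection then thins the candidates: a missense
#' candidate whose |ddG| exceeds the tolerated bound, or a nonsense
#' candidate, is retained with probability (1 - s); tolerated missense
#' and synonymous candidates are always retained. The output is
#' deduplicated by construction (one row per distinct variant, allele
#' count = event count).
#'
#' @param genes,matrices,truth generator outputs.
#' @param config the [SimulationConfig-class].
#' @return a [variantTable()] data.frame (cohort label `"population"`).
#' @export
simulatePopulationVariants <- function(genes, matrices, truth, config) {
  stopifnot(is(config, "SimulationConfig"))
  if (all(config@rateTable@rates == 0))
    .stopf("mutation-rate table is identically zero")
  set.seed(.stage_seed(config, 3L))
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    gid <- truth$gene_id[i]
    s <- truth$s[i]
    snvs <- enumerateSnvs(genes[[gid]])
    r <- suppressMessages(.snv_rates(snvs, config@rateTable))
    lambda <- 2 * config@cohortSize * config@mutationSupply * r
    events <- rpois(length(lambda), lambda)
    cand <- events > 0L
    snvs <- snvs[cand, , drop = FALSE]
    if (!nrow(snvs)) next
    snvs$ddg <- .snv_ddg(snvs, matrices[[gid]])
    big <- snvs$consequence == "missense" & !is.na(snvs$ddg) &
      abs(snvs$ddg) > config@truncationThreshold
    selected <- big | snvs$consequence == "nonsense"
    keep <- !selected | runif(nrow(snvs)) < (1 - s)
    snvs <- snvs[keep, , drop = FALSE]
    if (!nrow(snvs)) next
    ddg <- snvs$ddg
    ddg[snvs$consequence != "missense"] <- NA_real_
    rows[[i]] <- data.frame(gene_id = gid, nt_position = snvs$position,
                            ref_base = snvs$ref, alt_base = snvs$alt,
                            aa_position = snvs$aa_position,
                            ref_aa = snvs$ref_aa, alt_aa = snvs$alt_aa,
                            consequence = snvs$consequence, ddg = ddg,
                            cohort_label = "population",
                            clinical_label = "unlabeled",
                            allele_count = events[cand][keep],
                            stringsAsFactors = FALSE)
  }
  variantTable(do.call(rbind, c(rows[!vapply(rows, is.null, logical(1L))],
                                list(make.row.names = FALSE))))
}

#' Generate benign and pathogenic labelled variant sets
#'
#' Benign labels are drawn from tolerated cells of the ddG matrices,
#' with a configurable contamination rate drawn from DoS cells (the
#' rate at which a DoS call would contradict a benign label).
#' Pathogenic labels are drawn from DoS cells at `pathogenicDosRate`
#' (destabilising cells with probability `pathogenicSkew`, matching the
#' destabilising skew of clinically pathogenic missense variation) and
#' from tolerated cells otherwise.
#'
#' @param matrices named list of [DdgMatrix-class] objects.
#' @param config the [SimulationConfig-class].
#' @param nBenign,nPathogenic set sizes.
#' @return list of two [variantTable()] data.frames, `benign` and
#'   `pathogenic`.
#' @export
generateClinicalLabels <- function(matrices, config, nBenign = 2000L,
                                   nPathogenic = 2000L) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(.stage_seed(config, 4L))
  pool <- do.call(rbind, lapply(matrices, function(m) {
    mask <- wildtypeMask(m)
    idx <- which(!mask & !is.na(ddgValues(m)), arr.ind = TRUE)
    data.frame(gene_id = proteinId(m), aa_position = idx[, 1L],
               ref_aa = .chars(aaSequence(m))[idx[, 1L]],
               alt_aa = AA_ALPHABET[idx[, 2L]],
               ddg = ddgValues(m)[idx], stringsAsFactors = FALSE)
  }))
  thr <- config@truncationThreshold
  tolerated <- which(abs(pool$ddg) <= thr)
  destab <- which(pool$ddg > thr)
  stab <- which(pool$ddg < -thr)
  if (!length(tolerated))
    .stopf("no tolerated cells available for benign labels")

  draw <- function(n, idx) {
    if (n > 0L && !length(idx))
      .stopf("no qualifying cells for the requested label mixture")
    pool[sample(idx, n, replace = TRUE), , drop = FALSE]
  }
  n_contam <- sum(runif(nBenign) < config@benignContamination)
  dos_pool <- c(destab, stab)
  benign <- rbind(draw(nBenign - n_contam, tolerated),
                  draw(n_contam, dos_pool))
  n_dos <- sum(runif(nPathogenic) < config@pathogenicDosRate)
  n_destab <- sum(runif(n_dos) < config@pathogenicSkew)
  pathogenic <- rbind(draw(nPathogenic - n_dos, tolerated),
                      draw(n_destab, destab),
                      draw(n_dos - n_destab, stab))
  finish <- function(df, label) {
    df$consequence <- "missense"
    df$clinical_label <- label
    df$cohort_label <- "clinical"
    df$allele_count <- 1L
    variantTable(df[sample.int(nrow(df)), , drop = FALSE])
  }
  list(benign = finish(benign, "benign"),
       pathogenic = finish(pathogenic, "pathogenic"))
}
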