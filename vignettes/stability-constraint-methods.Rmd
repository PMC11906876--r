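---
title: "Stability-disruption variation and gene constraint: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-disruption variation and gene constraint: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosconstraint)
```

## The model in one page

A missense substitution changes the folding free energy of its protein by
ΔΔG (kcal/mol): positive values destabilise, negative values
over-stabilise. Two complementary quantities are built on a tolerated
interval (lower, upper) of stability change:

1. **Disruption-of-Stability (DoS) classification.** A substitution whose
   ΔΔG lies strictly inside the open interval is *tolerated*; strictly
   above the upper cut-off it is a *destabilising DoS* variant, strictly
   below the lower cut-off an *overly-stabilising DoS* variant. The three
   labels partition the finite reals.

2. **Instability Heat Score (IHS).** For a protein with an exhaustive
   L x 20 grid of predicted ΔΔG values, IHS is the mean of |ΔΔG| over the
   set S of possible substitutions with |ΔΔG| strictly above the
   threshold. IHS quantifies how *fragile* the protein is to mutational
   stability change; proteins with low IHS are "cold" and accommodate
   substitutions with little energetic consequence.

The population-genetic use of DoS variation rests on one assumption:
variants with stability effects beyond the tolerated bounds impair
function, and in a functionally constrained gene such variants are removed
by purifying selection. Depletion of large-|ΔΔG| variation in constrained
genes is therefore both the signal used to *locate* the bounds and the
signal that DoS-based constraint scores quantify per gene.

## Deriving the tolerated interval

The cut-offs are located by a depletion scan (`deriveThresholds()`).
Given missense ΔΔG values observed in a strongly constrained stratum and
an unconstrained stratum, define for each candidate threshold t > 0 the
ratio of empirical survival probabilities

  R(t) = P̂_constrained(ΔΔG > t) / P̂_unconstrained(ΔΔG > t),

with strict-inequality tails matching the DoS boundary convention. The
upper threshold is the smallest grid value (step 0.05 kcal/mol) at which
R(t) drops to the depletion cut-off or below; the lower threshold scans
the left tail symmetrically. Grid points where the unconstrained tail
holds fewer than `minTailN = 50` variants are skipped as too noisy, and a
scan in which no point qualifies returns an explicit "not found" sentinel
rather than a value — identically distributed strata (R ≈ 1 everywhere)
therefore find nothing, by design. Inputs are expected to be
*distinct variants* (deduplicated upstream); recurrent alleles would
otherwise weight the tails by frequency rather than by site.

**Choice of the depletion cut-off (0.1).** The scan is a formalisation of
what is, in practice, a judgement call made by eye on stratified
distributions, so the default cut-off deserves a derivation. Take the
idealised calibration case: unconstrained ΔΔG ~ Normal(0, 0.6) and a
constrained stratum that is the same distribution hard-truncated at the
true tolerated bound ±0.5. Closed form, for 0 < t < 0.5:

  R(t) = [(Φ(5/6) − Φ(t/0.6)) / (2Φ(5/6) − 1)] / (1 − Φ(t/0.6)),

which falls from 1 at t = 0 to R(0.45) ≈ 0.18, and to exactly 0 at
t ≥ 0.5 (the truncated stratum has no mass beyond the bound). A mild
cut-off (0.5, "two-fold depletion") is reached already at t ≈ 0.35 —
ordinary tail thinning, well inside the true bound. Any cut-off below
0.18 first triggers at the truncation point itself. The default 0.1
("ten-fold depletion") therefore recovers the generating bound exactly in
the calibration case while retaining a noise margin, and is the value
under which the recovery tests in this package are run. It remains a
tunable parameter: on real strata, which differ in shape as well as in
truncation, the appropriate severity of "depleted" is a scientific
choice, not a statistical constant.

On the package's full synthetic cohorts the scan typically lands one grid
step *inside* the generating bound (±0.45 for a truth of ±0.5). This is
not an error: constrained genes in the generator — like constrained genes
in nature — are also intrinsically narrower in ΔΔG (more intrinsic
disorder, colder ordered regions), which steepens the apparent depletion
beyond what selection alone would produce. The two causes are
confounded in any observational comparison of strata.

**FDR against benign labels.** `computeFdr()` reports the fraction of
benign-labelled missense ΔΔG values that the interval would call DoS; it
is non-increasing as the interval widens, which is also a property test.

## The constraint model

Expected variant counts come from a trinucleotide-context mutation model.
`enumerateSnvs()` lists all 3L single-nucleotide variants of a CDS with
their context (the reference base plus its immediate neighbours; optional
flanking bases complete the edge codons) and their coding consequence
under the standard genetic code. For a variant class C,

  E_C = k · Σ_{SNV ∈ C} rate(context, alt),

with k a dimensionless calibration factor fitted on synonymous variation
by least squares through the origin (k = Σ observed / Σ rate-sums),
synonymous variation being taken as effectively neutral. Edge codons
lacking a flank are mean-rate imputed per (ref, alt) change by default
(with a logged count); an `error` policy is available. Expected counts
are exactly additive over consequence classes.

The DoS class is "missense with |ΔΔG| strictly above the threshold under
the supplied ΔΔG matrix"; missense SNVs without a prediction are excluded
and tallied. The pLoF class is SNV nonsense only: frameshifts need an
indel model and canonical splice sites need intron context, both outside
a CDS-level SNV model, so published pLoF-based scores count more variant
types than this package's pLoF expectation does. A user-supplied list of
splice-site CDS positions can be added to the pLoF class where that
information exists.

**LOEUF-style upper bound.** With O observed and E expected events, the
bound is the upper end of the level-ci (default 0.90) confidence interval
of the Poisson rate ratio, i.e. the point where the normalised likelihood
r^O e^{−Er} accumulates (1+ci)/2 of its mass:

  r_U = qgamma((1 + ci)/2, shape = O + 1, rate = E),

which for O = 0 reduces to −log(0.05)/E at ci = 0.90. Results are capped
at 2.0, the convention of published constraint tables (the cap, not the
bound, is what breaks the `loeuf ≥ O/E` inequality when O/E itself
exceeds the cap). A second, numerical route — evaluating the normalised
likelihood on an r grid of step 0.001 and reading off the quantile —
cross-checks the closed form to within 0.002 in the tests. The grid is
laid over [0, (O+1)/E + 20·sqrt(O+1)/E]: the quantile must be located on
the *full* likelihood before capping, because renormalising over a
cap-truncated domain would shift the quantile of any gene whose
uncapped bound exceeds the cap.

Deciles are ascending-rank tenths (bin 0 = most constrained), equal-sized
up to the remainder, with ties broken by lexicographic gene id so the
partition is reproducible. Observed counting uses distinct variants
(gene, position, ref, alt) with allele count ≥ 1; no allele-frequency
ceiling is applied by default, since cohort-frequency handling is a
property of the upstream call set rather than of this model.

## Structure metrics

Per-residue confidence values are read from the B-factor column of the
C-alpha atom (mean of the residue's atoms when no C-alpha exists, with a
message). Predicted models store pLDDT there; a residue is *ordered* when
pLDDT is strictly above 70 on the 0–100 scale, and tracks supplied on a
0–1 scale are rescaled when their maximum is ≤ 1 — the same cutoff is
written both ways in the wild, and the detector reconciles them.
Experimental structures are summarised by their median B-factor. When a
gene has several (often partial) structures, the package's convention is
the median over all residues of all supplied structures. Grouped
summaries collapse LOEUF deciles to Most (bins 0–2), Intermediate (3–6)
and Least (7–9), split pLi at 0.5, or use the four S-het categories.

## What the synthetic generator does and does not emulate

The generator exists so that every pipeline stage can be exercised — and
its statistical behaviour tested — without external downloads. Its
defaults are fixed study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| cohort size | 3115 diploid individuals | a realistic disease-free cohort scale |
| mutation supply | Poisson mean 0.1 events per relative-rate-1 site | gives tens of distinct variants per gene at this cohort size |
| gene length | log-normal, median 250 aa (clamped 30–2000) | right-skewed, protein-like lengths at desk scale |
| selection s | Beta(0.5, 0.5) per gene | mass near both the neutral and the strongly constrained ends |
| disorder fraction | 0.1 + 0.4·s | constraint increases intrinsic disorder |
| ΔΔG spread | 0.2 kcal/mol (disordered), 1.0·(1 − 0.4·s) (ordered) | disordered regions are energetically near-neutral; constrained ordered regions are colder |
| tolerated bound | ±0.5 kcal/mol | the true threshold selection acts on |
| benign contamination | 0.06 | rate at which benign labels carry DoS cells |
| pathogenic DoS rate / skew | 0.184 / 0.9 | pathogenic labels drawn from DoS cells at this rate, predominantly destabilising |

Mechanics: random CDS with valid start/stop and no internal stops;
disorder as contiguous blocks from a two-state chain (mean segment ~25
residues) so pLDDT tracks look model-like; ΔΔG cells independent normals
(no epistasis, no residue-contact correlation); mutation events per SNV
Poisson-proportional to the trinucleotide rate; selection as hard
thinning — an out-of-bound missense or nonsense candidate survives with
probability 1 − s. The default rate table is deterministic, with
transitions 4x transversions and CpG transitions boosted 10x, normalised
to mean 1.

This reproduces the structures the analysis needs — narrower tolerated
ΔΔG and lower IHS with constraint, DoS variants far outnumbering
nonsense variants, destabilising skew of pathogenic labels, and a
recoverable truncation bound — while omitting much of what real cohorts
contain: linkage and demography, coverage and call-quality artefacts,
shared calibration constants with published scores, epistasis, and any
relationship between a protein's sequence and its ΔΔG values. Passing
tests on this generator therefore validate the *estimators* (that the
pipeline recovers what generated the data), not the biological claims on
real data.

## Numerical conventions and degenerate inputs

* Boundary rule: DoS requires strict exceedance (|ΔΔG| > threshold;
  classification tolerates exact boundary values). Measure-zero for
  real-valued predictors, but stated so ties are reproducible.
* Empty qualifying set: IHS = 0 with n = 0 — distinguishable from any
  real score, which necessarily exceeds the threshold.
* Quantiles: linear interpolation between order statistics
  (`stats::quantile` type 7) everywhere, so summaries are
  bit-reproducible; whiskers at 1.5·IQR are clipped to the data range.
* Entirely missing ΔΔG matrices, empty strata, empty benign sets,
  zero-rate tables, calibration with no observed synonymous variants, and
  decile binning below 10 genes are errors, not silent zeros.
* Consequence vocabulary: codon annotation emits synonymous / missense /
  nonsense / stop_loss as a pure function of the amino-acid pair;
  `other` is accepted from external tables but never produced.
* Determinism: every generator stage reseeds from the configured seed
  plus a fixed offset, and a rerun of the full pipeline writes
  byte-identical files; the report records the seed and a content hash of
  the configuration.

## Problem sizes

The test suite and the acceptance script run cohorts of 200–300 genes
(median ~250 aa), 10,000 variants per stratum for threshold recovery,
200,000 draws for the FDR closed-form check, and 1,000 random matrices
for the IHS invariants — sizes at which every recovery criterion is
comfortably identified on a single CPU in minutes, chosen as the
package's desk-scale study conditions.

## Known limitations

* pLoF here is SNV nonsense (plus optional user-supplied splice
  positions); comparisons with published pLoF constraint absorb that
  scope difference.
* The calibration factor is fitted on the analysed cohort's synonymous
  variants; it does not reuse any published mutational-model constants.
* ΔΔG tables are consumed, never computed; nothing in the package
  evaluates the accuracy of the upstream predictor.
* Length-dependent instability thresholds have no canonical functional
  form; `ihsTable()` accepts a per-protein named threshold vector so a
  user-supplied length → threshold rule can be applied, and otherwise a
  constant 0.5 is used.
* The depletion scan assumes the two strata differ mainly by selection;
  intrinsic distributional differences between strata (disorder, length)
  are confounded with depletion, as discussed above.
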