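# dosconstraint

Missense mutations that perturb protein folding stability are one of the
most common pathogenic mechanisms in human genetic disease, yet most
gene-level constraint scores are built only from unambiguous
loss-of-function (pLoF) variation, which is rare and leaves short genes
underpowered. `dosconstraint` implements, in R, an analysis that treats
**Disruption-of-Stability (DoS)** missense variation — substitutions whose
predicted folding free-energy change (ΔΔG, kcal/mol) falls outside a
tolerated interval — as a first-class variant category for constraint
estimation. It is aimed at statistical/population geneticists and
structural bioinformaticians who have per-protein ΔΔG substitution tables
(from predictors such as MAESTRO, DynaMut2 or DDGun; this package consumes
such tables, it never computes ΔΔG itself) and want to connect them to
population variation.

The package provides:

* **DoS classification** — a substitution with ddG strictly inside the open
  interval (lower, upper), by default (−0.5, 0.5) kcal/mol, is *tolerated*;
  above the upper cut-off it is *destabilising DoS*, below the lower one
  *overly-stabilising DoS*.

* **Instability Heat Score (IHS)** — per-protein mutational fragility:

  IHS = (1/|S|) · Σ_{i ∈ S} |ΔΔG_i|,

  where S is the set of all possible single amino-acid substitutions with
  |ΔΔG_i| strictly above the threshold (default 0.5 kcal/mol). A protein
  with empty S scores 0; any non-empty S gives a value above the
  threshold, so the sentinel is unambiguous. `ihsProfile()` returns the
  per-position decomposition used for mutational-scanning heatmaps
  (`exportHeatmapMatrix()`).

* **Threshold derivation** — `deriveThresholds()` formalises the choice of
  the tolerated interval as a grid scan of tail-survival ratios between
  missense ΔΔG observed in strongly constrained versus unconstrained gene
  strata, picking the smallest cut-off at which the constrained tail is
  depleted below a configurable ratio; `computeFdr()` reports how often
  benign-labelled variants would be called DoS.

* **Constraint model** — `enumerateSnvs()` lists all 3L single-nucleotide
  variants of a coding sequence with trinucleotide contexts;
  `expectedClassCount()` turns a context-resolved mutation-rate table into
  expected counts per variant class (E = k · Σ rates), with the scale k
  calibrated on synonymous variation (`calibrateRateScale()`);
  `loeufUpperBound()` computes the LOEUF-style upper bound of the 90%
  confidence interval of observed/expected as the gamma quantile
  qgamma((1+ci)/2, shape = O + 1, rate = E), capped at 2. Deciles,
  decile-membership confusion matrices and pLoF-vs-DoS LOEUF difference
  rankings complete the module.

* **Structure metrics** — per-residue B-factor/pLDDT extraction from
  PDB/mmCIF (`readStructureConfidence()`), ordered fraction at pLDDT > 70
  and median B-factor summaries grouped by constraint category.

* **Synthetic cohorts** — `simulationConfig()` and the `generate*()` /
  `simulatePopulationVariants()` functions build genes, ΔΔG matrices,
  pLDDT tracks and a population cohort in which purifying selection thins
  out-of-bound variants, so the whole pipeline is exercisable and testable
  without any external download.

## Worked example

```r
library(dosconstraint)

cfg  <- simulationConfig(nGenes = 60L, seed = 42L)
gen  <- generateGenes(cfg)
mats <- generateDdgMatrices(gen$genes, gen$truth, cfg)
v    <- simulatePopulationVariants(gen$genes, mats$matrices, gen$truth, cfg)

## thresholds from the most- vs least-constrained strata
s_bins <- assignDeciles(setNames(-gen$truth$s, gen$truth$gene_id))
mis    <- v$consequence == "missense" & !is.na(v$ddg)
scan   <- deriveThresholds(
  v$ddg[mis & v$gene_id %in% names(s_bins)[s_bins == 0]],
  v$ddg[mis & v$gene_id %in% names(s_bins)[s_bins == 9]])
scan
#> DepletionScan over 62 grid points, depletion cutoff 0.1
#>   chosen thresholds: lower -0.45, upper 0.45 kcal/mol

computeIHS(mats$matrices[[1]])
#> IHS G0001: 1.028 kcal/mol (3137 substitutions > 0.5)

ct  <- constraintTable(gen$genes, mats$matrices, v, cfg@rateTable,
                       thresholds = chosenThresholds(scan))
head(subset(ct, variant_class == "dos"), 3)
#>    gene_id variant_class observed expected        oe     loeuf decile
#> 61   G0001           dos       71 93.41283 0.7600669 0.9260187      6
#> 62   G0002           dos       54 81.60126 0.6617545 0.8301354      5
#> 63   G0003           dos       43 53.87931 0.7980801 1.0291335      7
```

The scan recovers the tolerated interval one grid step inside the
generating bound of ±0.5 kcal/mol: constrained genes in the simulation are
*also* intrinsically narrower in ΔΔG (more disorder, colder ordered
regions), which steepens the apparent depletion — the same confound the
real data carry. Each constraint record shows the observed count of DoS
variants, the expected count from the trinucleotide model, their ratio and
its 90% upper bound (LOEUF); lower LOEUF means more constrained. On this
cohort the Spearman correlation between the generating selection strength
and DoS-LOEUF is −0.87.

`runFullAnalysis()` chains all stages (threshold scan, IHS table,
pLoF/DoS constraint records, decile confusion, LOEUF difference ranking,
stratum summaries, structure groups) and writes a TSV/JSON report bundle;
`inst/scripts/dosconstraint-cli.R` exposes the same stages as shell
subcommands (`run`, `simulate`, `ihs`, `thresholds`, `constraint`,
`structure`).

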