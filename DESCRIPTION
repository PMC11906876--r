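Package: dosconstraint
Title: Disruption-of-Stability Variant Classification and Gene Constraint
    Scoring from Protein Stability Predictions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies single amino-acid substitutions as
    Disruption-of-Stability (DoS) variants from predicted folding free-energy
    changes, computes per-protein Instability Heat Scores, derives
    tolerated-stability thresholds from the depletion of large-effect variants
    in functionally constrained genes, and computes observed/expected
    constraint scores (LOEUF-style 90 percent confidence upper bounds) from
    DoS variation using a trinucleotide-context expected-variant model. A
    synthetic-data module generates coding sequences, stability matrices,
    structure-confidence tracks and population cohorts with the statistical
    structure the analysis assumes, so the full pipeline is exercisable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    bio3d,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: VariantAnnotation, StructuralPrediction, GeneticVariability,
    PopulationGenetics, Software
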