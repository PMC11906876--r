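# The synthetic cohort generator: determinism, constructive invariants,
# and the constraint structure it must imprint.

small_cfg <- function(...) simulationConfig(nGenes = 40L, seed = 7L, ...)

test_that("generated genes are valid CDS with reproducible draws", {
  cfg <- small_cfg()
  g1 <- generateGenes(cfg)
  g2 <- generateGenes(cfg)
  expect_identical(vapply(g1$genes, cdsSequence, character(1L)),
                   vapply(g2$genes, cdsSequence, character(1L)))
  expect_identical(g1$truth, g2$truth)
  for (g in g1$genes) {
    aa <- translateCds(cdsSequence(g))
    expect_equal(aa[1], "M")
    expect_equal(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))  # no internal stop
  }
  expect_true(all(g1$truth$length_aa >= 30L))
})

test_that("gene lengths follow the configured log-normal at scale", {
  cfg <- simulationConfig(nGenes = 5000L, seed = 3L, lengthMeanLog = log(250),
                          lengthSdLog = 0.5)
  len <- generateGenes(cfg)$truth$length_aa
  q <- quantile(len, c(0.25, 0.5, 0.75))
  want <- qlnorm(c(0.25, 0.5, 0.75), log(250), 0.5)
  expect_equal(unname(q) / want, rep(1, 3), tolerance = 0.05)
})

test_that("ddG matrices have zero wild-type cells and constraint narrows them", {
  cfg <- simulationConfig(nGenes = 20L, seed = 5L,
                          selectionS = rep(c(0, 1), each = 10L))
  gen <- generateGenes(cfg)
  mats <- generateDdgMatrices(gen$genes, gen$truth, cfg)
  for (m in mats$matrices)
    expect_true(all(ddgValues(m)[wildtypeMask(m)] == 0))
  ihs <- ihsTable(mats$matrices)
  s <- gen$truth$s[match(ihs$gene_id, gen$truth$gene_id)]
  # constrained (s = 1) proteins are 'colder'
  expect_lt(mean(ihs$ihs[s == 1]), mean(ihs$ihs[s == 0]))
  # pLDDT tracks are high in ordered blocks, low in disordered ones
  id <- gen$truth$gene_id[1]
  mask <- mats$disorder[[id]]
  conf <- unname(confidenceValues(mats$confidence[[id]]))
  if (any(mask) && any(!mask))
    expect_lt(mean(conf[mask]), mean(conf[!mask]))
})

test_that("fully disordered proteins are nearly all tolerated", {
  cfg <- simulationConfig(nGenes = 10L, seed = 9L,
                          selectionS = rep(0.5, 10L), disorderBase = 1,
                          disorderSlope = 0)
  gen <- generateGenes(cfg)
  mats <- generateDdgMatrices(gen$genes, gen$truth, cfg)
  cells <- unlist(lapply(mats$matrices, function(m)
    ddgValues(m)[!wildtypeMask(m)]))
  # sigma 0.2 leaves ~1.2% of mass beyond +/-0.5
  expect_lt(mean(abs(cells) > 0.5), 0.03)
  expect_true(all(ihsTable(mats$matrices)$n_qualifying <
                  0.05 * lengths(lapply(mats$matrices, ddgValues))))
})

test_that("selection removes DoS and nonsense candidates from fully constrained genes", {
  cfg <- simulationConfig(nGenes = 30L, seed = 13L,
                          selectionS = rep(c(0, 1), 15L))
  gen <- generateGenes(cfg)
  mats <- generateDdgMatrices(gen$genes, gen$truth, cfg)
  v <- simulatePopulationVariants(gen$genes, mats$matrices, gen$truth, cfg)
  s_of <- setNames(gen$truth$s, gen$truth$gene_id)
  hard <- v[s_of[v$gene_id] == 1, ]
  expect_equal(sum(hard$consequence == "nonsense"), 0L)
  expect_equal(sum(hard$consequence == "missense" & !is.na(hard$ddg) &
                   abs(hard$ddg) > 0.5), 0L)
  # but tolerated missense and synonymous variation is still there
  expect_gt(sum(hard$consequence == "synonymous"), 0L)
  expect_gt(sum(hard$consequence == "missense"), 0L)
})

test_that("unconstrained genes retain candidate class proportions", {
  cfg <- simulationConfig(nGenes = 12L, seed = 17L,
                          selectionS = rep(0, 12L))
  gen <- generateGenes(cfg)
  mats <- generateDdgMatrices(gen$genes, gen$truth, cfg)
  v <- simulatePopulationVariants(gen$genes, mats$matrices, gen$truth, cfg)
  # with s = 0 nothing is thinned: retained proportions match the
  # rate-weighted enumeration within binomial noise
  rates <- cfg@rateTable
  expected_ratio <- sum(vapply(gen$genes, function(g)
    as.numeric(expectedClassCount(g, rates, 1, "nonsense")), numeric(1L))) /
    sum(vapply(gen$genes, function(g)
      as.numeric(expectedClassCount(g, rates, 1, "synonymous")),
      numeric(1L)))
  got_ratio <- sum(v$consequence == "nonsense") /
    sum(v$consequence == "synonymous")
  expect_equal(got_ratio, expected_ratio, tolerance = 0.35)
  # genetic-code asymmetry: far more DoS than nonsense per gene
  dos <- observedClassCount(v, "dos")
  plof <- observedClassCount(v, "plof")
  ids <- gen$truth$gene_id
  dos <- ifelse(is.na(dos[ids]), 0L, dos[ids])
  plof <- ifelse(is.na(plof[ids]), 0L, plof[ids])
  expect_true(all(dos > plof))
})

test_that("clinical label sets have the requested sizes and skews", {
  cfg <- small_cfg()
  gen <- generateGenes(cfg)
  mats <- generateDdgMatrices(gen$genes, gen$truth, cfg)
  lab <- generateClinicalLabels(mats$matrices, cfg, nBenign = 500L,
                                nPathogenic = 400L)
  expect_equal(nrow(lab$benign), 500L)
  expect_equal(nrow(lab$pathogenic), 400L)
  expect_gt(median(lab$pathogenic$ddg), median(lab$benign$ddg))
  # zero contamination makes the benign FDR exactly zero
  cfg0 <- small_cfg(benignContamination = 0)
  lab0 <- generateClinicalLabels(mats$matrices, cfg0, nBenign = 300L)
  expect_equal(computeFdr(lab0$benign$ddg), 0)
})

test_that("increasing selection stochastically narrows retained ddG (KS ordering)", {
  cfg <- simulationConfig(nGenes = 30L, seed = 23L,
                          selectionS = rep(c(0, 0.5, 1), each = 10L))
  gen <- generateGenes(cfg)
  mats <- generateDdgMatrices(gen$genes, gen$truth, cfg)
  v <- simulatePopulationVariants(gen$genes, mats$matrices, gen$truth, cfg)
  s_of <- setNames(gen$truth$s, gen$truth$gene_id)
  absddg <- function(s) {
    x <- v$ddg[s_of[v$gene_id] == s & v$consequence == "missense"]
    abs(x[!is.na(x)])
  }
  # |ddG| of retained missense is stochastically smaller at higher s
  expect_gt(suppressWarnings(ks.test(absddg(1), absddg(0),
                                     alternative = "greater"))$statistic,
            0.1)
  expect_gt(mean(absddg(0)), mean(absddg(0.5)))
  expect_gt(mean(absddg(0.5)), mean(absddg(1)))
})

test_that("generator outputs are byte-identical across reruns through the writers", {
  cfg <- small_cfg()
  run <- function() {
    gen <- generateGenes(cfg)
    mats <- generateDdgMatrices(gen$genes, gen$truth, cfg)
    v <- simulatePopulationVariants(gen$genes, mats$matrices, gen$truth, cfg)
    d <- withr::local_tempdir()
    writeCdsFasta(gen$genes, file.path(d, "genes.fa"))
    writeDdgTable(mats$matrices[1:3], file.path(d, "ddg.tsv"))
    writeVariants(v, file.path(d, "variants.tsv"))
    unname(tools::md5sum(file.path(d, c("genes.fa", "ddg.tsv",
                                        "variants.tsv"))))
  }
  expect_identical(run(), run())
})
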