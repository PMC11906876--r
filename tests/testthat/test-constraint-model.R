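# Expected-variant model, calibration, LOEUF bounds, deciles.

test_that("enumerateSnvs produces 3 alternates per site with codon-table consequences", {
  g <- GeneModel("g1", "ATGTGGTAA", upstreamBase = "A", downstreamBase = "C")
  snvs <- enumerateSnvs(g)
  expect_equal(nrow(snvs), 27L)
  expect_equal(sum(snvs$consequence == "nonsense"), 2L)  # TGG>TAG, TGG>TGA
  expect_setequal(snvs$alt[snvs$consequence == "nonsense"], "A")
  # GGG third-position changes are all synonymous
  g2 <- GeneModel("g2", "ATGGGGTAA")
  snvs2 <- enumerateSnvs(g2)
  expect_equal(sum(snvs2$position == 6L &
                   snvs2$consequence == "synonymous"), 3L)
  # internal stops are refused unless permitted
  g3 <- GeneModel("g3", "ATGTAATAA")
  expect_error(enumerateSnvs(g3), "internal stop")
  expect_silent(enumerateSnvs(g3, allowInternalStops = TRUE))
})

test_that("trinucleotide contexts use flanks and collapse strands correctly", {
  g <- GeneModel("g1", "ATGTGGTAA", upstreamBase = "A", downstreamBase = "C")
  snvs <- enumerateSnvs(g)
  expect_equal(snvs$context[snvs$position == 1L][1], "AAT")
  expect_equal(snvs$context[snvs$position == 9L][1], "AAC")
  gn <- GeneModel("g2", "ATGTGGTAA")
  expect_true(all(is.na(enumerateSnvs(gn)$context[c(1, 27)])))

  full <- defaultMutationRateTable()
  # build the collapsed version by keeping A/C-centred keys
  keys <- names(full@rates)
  keep <- substr(keys, 2L, 2L) %in% c("A", "C")
  coll <- MutationRateTable(full@rates[keep], strandCollapsed = TRUE)
  # G-centred lookup resolves through the reverse complement
  expect_equal(rateLookup(coll, "TGG", "A"),
               unname(full@rates["CCA>T"]))
  expect_error(rateLookup(full, "ZZZ", "A"), "no rate")
})

test_that("expected counts follow k * sum(rates) and the enumeration oracle", {
  uniform <- MutationRateTable(
    setNames(rep(1, 192), dosconstraint:::.rate_keys(FALSE)))
  g <- GeneModel("g1", "ATGTGGTAA", upstreamBase = "A", downstreamBase = "C")
  expect_equal(as.numeric(expectedClassCount(g, uniform, 1, "nonsense")), 2)
  zero <- MutationRateTable(
    setNames(rep(0, 192), dosconstraint:::.rate_keys(FALSE)))
  expect_equal(as.numeric(expectedClassCount(g, zero, 1, "missense")), 0)

  # additivity over consequence classes
  rates <- defaultMutationRateTable()
  parts <- vapply(c("synonymous", "missense", "nonsense", "stop_loss"),
                  function(cl)
                    as.numeric(expectedClassCount(g, rates, 2.5, cl)),
                  numeric(1L))
  expect_equal(sum(parts),
               as.numeric(expectedClassCount(g, rates, 2.5, "all")),
               tolerance = 1e-12)
})

test_that("streaming expected counts equal the brute-force oracle on random genes", {
  set.seed(90)
  rates <- defaultMutationRateTable()
  for (rep in 1:20) {
    gene <- random_gene(n_codons = sample(4:8, 1L),
                        flanks = runif(1) < 0.7)
    k <- runif(1, 0.5, 3)
    for (cl in c("synonymous", "nonsense", "missense")) {
      got <- suppressMessages(expectedClassCount(gene, rates, k, cl))
      want <- oracle_expected_count(gene, rates, k, cl)
      expect_equal(as.numeric(got), want, tolerance = 1e-12)
    }
  }
})

test_that("the DoS class respects the ddG matrix and tallies missing predictions", {
  set.seed(91)
  gene <- random_gene(n_codons = 8L)
  aa <- translateCds(cdsSequence(gene))
  aa <- paste(aa[-length(aa)], collapse = "")
  L <- nchar(aa)
  m <- matrix(rnorm(L * 20L), L, 20L, dimnames = list(NULL, AA20))
  m[2, ] <- NA  # an unpredicted position
  ddg <- DdgMatrix(geneId(gene), aa, m)
  rates <- defaultMutationRateTable()
  got <- expectedClassCount(gene, rates, 1, "dos", ddgMatrix = ddg)
  want <- oracle_expected_count(gene, rates, 1, "dos", ddg = ddg)
  expect_equal(as.numeric(got), want, tolerance = 1e-12)
  expect_gt(attr(got, "n_missing_ddg"), 0L)
  expect_error(expectedClassCount(gene, rates, 1, "dos"), "requires")
})

test_that("rate calibration recovers the true scale", {
  set.seed(92)
  rates <- defaultMutationRateTable()
  genes <- setNames(lapply(1:12, function(i)
    random_gene(n_codons = 10L, id = sprintf("g%02d", i))),
    sprintf("g%02d", 1:12))
  sums <- vapply(genes, function(g)
    as.numeric(expectedClassCount(g, rates, 1, "synonymous")), numeric(1L))
  # identity: observed exactly k0 * rate sums
  k0 <- 1.7
  cal <- calibrateRateScale(genes, rates, setNames(k0 * sums, names(sums)))
  expect_equal(calibrationK(cal), k0, tolerance = 1e-12)
  diag <- attr(cal, "diagnostics")
  expect_equal(nrow(diag), 12L)
  expect_equal(diag$residual, rep(0, 12L), tolerance = 1e-9)
  # degenerate: nothing observed
  expect_error(calibrateRateScale(genes["g01"], rates,
                                  c(g01 = 0)), "degenerate")
})

test_that("Poisson-noisy calibration lands within 5% at 500 genes", {
  set.seed(93)
  rates <- defaultMutationRateTable()
  genes <- setNames(lapply(1:500, function(i)
    random_gene(n_codons = sample(5:15, 1L), id = sprintf("g%03d", i))),
    sprintf("g%03d", 1:500))
  sums <- vapply(genes, function(g)
    as.numeric(expectedClassCount(g, rates, 1, "synonymous")), numeric(1L))
  k0 <- 2.4
  obs <- setNames(rpois(500, k0 * sums), names(sums))
  cal <- calibrateRateScale(genes, rates, obs)
  expect_lt(abs(calibrationK(cal) - k0) / k0, 0.05)
})

test_that("loeufUpperBound matches the zero-observation closed form and known values", {
  for (E in c(1, 10, 100))
    expect_equal(loeufUpperBound(0, E, cap = Inf), -log(0.05) / E,
                 tolerance = 1e-9)
  expect_equal(loeufUpperBound(10, 10), 1.70, tolerance = 0.01)
  expect_error(loeufUpperBound(1, 0), "positive")
  expect_error(loeufUpperBound(-1, 1), "nonnegative")
})

test_that("loeuf bound is monotone and approaches O/E as E grows", {
  E <- c(1, 2, 5, 10, 50, 1000, 1e5)
  b <- loeufUpperBound(20, E, cap = Inf)
  expect_true(all(diff(b) < 0))            # decreasing in expected
  expect_equal(b[length(b)], 20 / 1e5, tolerance = 0.05)
  o <- 0:15
  b2 <- loeufUpperBound(o, 10, cap = Inf)
  expect_true(all(diff(b2) > 0))           # increasing in observed
  # bound always at or above the point estimate (uncapped)
  oe <- o / 10
  expect_true(all(b2 >= oe))
})

test_that("gamma and grid methods agree within 0.002 on a spot grid", {
  for (o in c(0, 3, 17)) for (e in c(2, 9, 31)) {
    expect_lt(abs(loeufUpperBound(o, e, method = "grid") -
                  unname(loeufUpperBound(o, e))), 0.002)
  }
})

test_that("decile assignment is an equal partition with deterministic ties", {
  set.seed(94)
  scores <- setNames(runif(20), sprintf("g%02d", sample(20)))
  bins <- assignDeciles(scores)
  expect_equal(unname(table(bins)), rep(2L, 10L), ignore_attr = TRUE)
  low2 <- names(sort(scores))[1:2]
  expect_true(all(bins[low2] == 0L))
  # all-tied scores fall back to lexicographic gene order
  tied <- setNames(rep(1, 20), sprintf("g%02d", 20:1))
  bt <- assignDeciles(tied)
  expect_equal(unname(bt[sort(names(tied))]), rep(0:9, each = 2L))
  expect_error(assignDeciles(setNames(1:5, letters[1:5])), "at least 10")
  # partition: every gene in exactly one bin
  expect_equal(sort(names(bins)), sort(names(scores)))
})

test_that("decile confusion matches marginals and the per-gene tally", {
  set.seed(95)
  ids <- sprintf("g%03d", 1:137)
  a <- assignDeciles(setNames(runif(137), ids))
  b <- assignDeciles(setNames(runif(137), ids))
  m <- decileConfusion(a, b)
  expect_equal(sum(m), 137L)
  expect_equal(unname(rowSums(m)), unname(as.integer(table(factor(a, 0:9)))))
  expect_equal(unname(colSums(m)), unname(as.integer(table(factor(b, 0:9)))))
  # brute-force per-gene tally
  want <- matrix(0L, 10, 10)
  for (g in ids) want[a[[g]] + 1L, b[[g]] + 1L] <-
      want[a[[g]] + 1L, b[[g]] + 1L] + 1L
  expect_equal(unname(m), want)
  # identical binnings are diagonal
  expect_equal(sum(diag(decileConfusion(a, a))), 137L)
  expect_error(decileConfusion(a, b[-1]), "universes differ")
})

test_that("LOEUF difference ranking orders by absolute gap and carries both records", {
  rp <- data.frame(gene_id = c("a", "b", "c"), observed = c(0, 5, 3),
                   expected = c(2, 5, 3), oe = c(0, 1, 1),
                   loeuf = c(1.5, 1.0, 0.4))
  rd <- data.frame(gene_id = c("a", "b", "c"), observed = c(30, 5, 10),
                   expected = c(30, 5, 10), oe = c(1, 1, 1),
                   loeuf = c(0.3, 0.9, 0.4))
  rk <- rankLoeufDifferences(rp, rd)
  expect_equal(rk$gene_id, c("a", "b", "c"))
  expect_equal(rk$abs_diff, c(1.2, 0.1, 0))
  expect_true(all(c("observed_plof", "observed_dos") %in% names(rk)))
  # all-equal LOEUF: ties resolved by gene id
  rk2 <- rankLoeufDifferences(rp, rp)
  expect_equal(rk2$gene_id, c("a", "b", "c"))
  expect_error(rankLoeufDifferences(rp, data.frame(gene_id = "z",
                                                   observed = 1,
                                                   expected = 1, oe = 1,
                                                   loeuf = 1)),
               "no genes shared")
})

test_that("observed counting deduplicates variants and honours the DoS boundary", {
  tab <- variantTable(data.frame(
    gene_id = c("g1", "g1", "g1", "g1", "g2"),
    nt_position = c(4L, 4L, 7L, 8L, 5L),
    ref_base = "A", alt_base = "G",
    consequence = c("missense", "missense", "missense", "nonsense",
                    "missense"),
    ddg = c(0.8, 0.8, 0.5, NA, -0.9),
    allele_count = c(3L, 1L, 1L, 2L, 1L)))
  dos <- observedClassCount(tab, "dos")
  expect_equal(dos, c(g1 = 1L, g2 = 1L))  # duplicate collapsed; 0.5 tolerated
  plof <- observedClassCount(tab, "plof")
  expect_equal(plof, c(g1 = 1L))
})

test_that("a gene with no observed pLoF but ample DoS variation tops the ranking", {
  set.seed(96)
  rates <- defaultMutationRateTable()
  genes <- setNames(lapply(1:12, function(i)
    random_gene(n_codons = 60L, id = sprintf("g%02d", i))),
    sprintf("g%02d", 1:12))
  mats <- setNames(lapply(names(genes), function(id) {
    aa <- translateCds(cdsSequence(genes[[id]]))
    aa <- paste(aa[-length(aa)], collapse = "")
    m <- matrix(rnorm(nchar(aa) * 20L, sd = 1.2), nchar(aa), 20L,
                dimnames = list(NULL, AA20))
    DdgMatrix(id, aa, m)
  }), names(genes))
  k <- 5
  rec <- function(cls) {
    E <- vapply(names(genes), function(id)
      as.numeric(expectedClassCount(genes[[id]], rates, k,
                                    if (cls == "plof") "plof" else "dos",
                                    ddgMatrix = mats[[id]])), numeric(1L))
    O <- round(E)  # every gene neutral: observed matches expectation ...
    if (cls == "plof") O["g01"] <- 0  # ... except no pLoF seen in g01
    data.frame(gene_id = names(genes), observed = O, expected = E,
               oe = O / E, loeuf = loeufUpperBound(O, E), row.names = NULL)
  }
  rk <- rankLoeufDifferences(rec("plof"), rec("dos"))
  # the zero-pLoF gene shows the starkest constraint disagreement
  expect_equal(rk$gene_id[1], "g01")
  expect_equal(rk$observed_plof[1], 0)
  expect_gt(rk$observed_dos[1], 10)
})
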