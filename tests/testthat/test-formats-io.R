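# Readers/writers and the round-trip / consequence-annotation contracts.

test_that("readDdgTable builds matrices from long TSV, tolerating sparse positions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tref_aa\talt_aa\tddg",
               "p1\t1\tM\tA\t0.2", "p1\t1\tM\tC\t-0.4", "p1\t1\tM\tD\t1.5"),
             path)
  mats <- readDdgTable(path)
  expect_named(mats, "p1")
  m <- ddgValues(mats$p1)
  expect_equal(unname(m[1, c("A", "C", "D")]), c(0.2, -0.4, 1.5))
  expect_equal(sum(!is.na(m)), 3L)
  expect_equal(aaSequence(mats$p1), "M")
})

test_that("empty ddG tables warn and yield an empty collection", {
  path <- withr::local_tempfile(fileext = ".tsv")
  file.create(path)
  expect_warning(out <- readDdgTable(path), "empty")
  expect_length(out, 0L)
})

test_that("conflicting duplicate ddG rows are rejected by key", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tref_aa\talt_aa\tddg",
               "p1\t2\tM\tA\t0.2", "p1\t2\tM\tA\t0.9"), path)
  expect_error(readDdgTable(path), "p1:2:A")
})

test_that("malformed rows and inconsistent reference residues are named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tref_aa\talt_aa\tddg",
               "p1\t1\tM\tA\t0.2", "p1\tx\tM\tC\t0.1"), path)
  expect_error(readDdgTable(path), "line 3")
  writeLines(c("protein_id\tposition\tref_aa\talt_aa\tddg",
               "p1\t1\tM\tA\t0.2", "p1\t1\tW\tC\t0.1"), path)
  expect_error(readDdgTable(path), "inconsistent ref_aa")
})

test_that("ddG write/read round trip is lossless, including missing cells", {
  set.seed(101)
  mats <- list(a = random_ddg(8L, "a"), b = random_ddg(5L, "b"))
  v <- ddgValues(mats$b)
  wt2 <- strsplit(aaSequence(mats$b), "")[[1]][2]
  v[2, setdiff(AA20, wt2)[1:4]] <- NA
  mats$b <- DdgMatrix("b", aaSequence(mats$b), v)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDdgTable(mats, path)
  back <- readDdgTable(path)
  for (id in names(mats)) {
    expect_equal(aaSequence(back[[id]]), aaSequence(mats[[id]]))
    ref <- ddgValues(mats[[id]])
    ref[wildtypeMask(mats[[id]])] <- NA  # wild-type cells are not exchanged
    expect_equal(ddgValues(back[[id]]), ref, tolerance = 1e-12)
  }
})

test_that("VCF reading splits multiallelics, skips non-SNVs and annotates consequences", {
  genes <- list(g1 = GeneModel("g1", "ATGTGGTAA"))
  path <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"), list(
    c("g1", "6", ".", "G", "A", ".", ".", "."),    # TGG>TGA nonsense
    c("g1", "9", ".", "A", "G", ".", ".", "."),    # TAA>TAG synonymous stop
    c("g1", "4", ".", "T", "AT", ".", ".", "."),   # indel -> skipped
    c("g1", "50", ".", "A", "G", ".", ".", "."),   # outside CDS -> skipped
    c("g1", "2", ".", "T", "C,A", ".", ".", ".")))  # multiallelic split
  v <- readVariants(path, genes)
  expect_equal(attr(v, "n_skipped_non_snv"), 1L)
  expect_equal(attr(v, "n_outside_cds"), 1L)
  expect_equal(nrow(v), 4L)
  expect_equal(v$consequence[v$nt_position == 6], "nonsense")
  expect_equal(v$consequence[v$nt_position == 9], "synonymous")
  expect_setequal(v$alt_base[v$nt_position == 2], c("C", "A"))
})

test_that("unknown genes and REF mismatches are errors", {
  genes <- list(g1 = GeneModel("g1", "ATGTGGTAA"))
  path <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                        list(c("gX", "3", ".", "G", "A", ".", ".", ".")))
  expect_error(readVariants(path, genes), "unknown gene_id")
  path2 <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                         list(c("g1", "6", ".", "C", "A", ".", ".", ".")))
  expect_error(readVariants(path2, genes), "REF allele")
})

test_that("third-position GGG changes annotate as synonymous", {
  genes <- list(g1 = GeneModel("g1", "ATGGGGTAA"))
  path <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"), list(
    c("g1", "6", ".", "G", "A", ".", ".", "."),
    c("g1", "6", ".", "G", "C", ".", ".", "."),
    c("g1", "6", ".", "G", "T", ".", ".", ".")))
  v <- readVariants(path, genes)
  expect_equal(v$consequence, rep("synonymous", 3L))
})

test_that("consequence annotation agrees with the brute-force translation oracle", {
  set.seed(202)
  for (rep in 1:5) {
    gene <- random_gene(n_codons = sample(4:9, 1L), id = "g")
    snvs <- enumerateSnvs(gene)
    expect_equal(nrow(snvs), 3L * nchar(cdsSequence(gene)))
    oracle <- mapply(oracle_consequence,
                     MoreArgs = list(cds = cdsSequence(gene)),
                     pos = snvs$position, alt = snvs$alt)
    expect_equal(snvs$consequence, unname(oracle))
  }
})

test_that("structure confidence comes from C-alpha B-factors with mean fallback", {
  path <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"),
                        c(10, 20, 30))
  sc <- readStructureConfidence(path)
  expect_equal(unname(confidenceValues(sc)), c(10, 20, 30))
  expect_equal(sourceKind(sc), "experimental")

  # residue 2 has no C-alpha; falls back to the mean of its atoms
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, " CA ", 1, 5),
               pdb_atom_line(2, " N  ", 2, 10),
               pdb_atom_line(3, " O  ", 2, 14), "END"), p2)
  expect_message(sc2 <- readStructureConfidence(p2), "lacks a C-alpha")
  expect_equal(unname(confidenceValues(sc2)), c(5, 12))
})

test_that("AlphaFold-style files are tagged as predicted models", {
  path <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"), c(90, 95),
                        header = "TITLE     ALPHAFOLD MONOMER V2.0 PREDICTION")
  sc <- readStructureConfidence(path)
  expect_equal(sourceKind(sc), "predicted_model")
  expect_equal(unname(confidenceValues(sc)), c(90, 95))
})

test_that("variant tables enforce the consequence and ddg invariants", {
  expect_error(variantTable(data.frame(gene_id = "g", consequence = "weird")),
               "unknown consequence")
  expect_error(variantTable(data.frame(gene_id = "g",
                                       consequence = "synonymous",
                                       ddg = 0.4)),
               "only for missense")
  tab <- variantTable(data.frame(gene_id = "g", consequence = "missense",
                                 ref_aa = "M", alt_aa = "V", ddg = 0.3))
  expect_equal(tab$allele_count, 1L)
  expect_error(variantTable(data.frame(gene_id = "g",
                                       consequence = "nonsense",
                                       ref_aa = "M", alt_aa = "V")),
               "inconsistent")
})

test_that("FASTA gene models round-trip with flanking bases from the transcript table", {
  genes <- list(g1 = GeneModel("g1", "ATGTGGTAA", transcriptId = "t1"),
                g2 = GeneModel("g2", "ATGAAATGA", transcriptId = "t2"))
  path <- withr::local_tempfile(fileext = ".fa")
  writeCdsFasta(genes, path)
  tx <- data.frame(gene_id = c("g1", "g2"), transcript_id = c("t1", "t2"),
                   upstream_base = c("A", "C"), downstream_base = c("G", "T"))
  back <- readCdsFasta(path, transcripts = tx)
  expect_equal(cdsSequence(back$g1), "ATGTGGTAA")
  expect_equal(back$g2@upstreamBase, "C")
  expect_equal(back$g1@transcriptId, "t1")
})
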