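# Readers and writers for the external formats the pipeline touches.
# Downstream modules only ever see the domain types produced here.

#' Read a long-format ddG substitution table
#'
#' The canonical exchange format is a TSV with columns `protein_id`,
#' `position` (1-based), `ref_aa`, `alt_aa`, `ddg` (kcal/mol; an empty
#' field is a missing prediction). One [DdgMatrix-class] is built per
#' protein; positions without all 19 alternate entries are recorded as
#' missing, never as an error.
#'
#' @param path TSV file path.
#' @return named list of [DdgMatrix-class] objects (one per protein). An
#'   empty file yields an empty list with a warning.
#' @seealso [writeDdgTable()]
#' @export
readDdgTable <- function(path) {
  if (!file.exists(path)) .stopf("ddG table not found: %s", path)
  if (file.size(path) == 0L) {
    .warnf("ddG table %s is empty", path)
    return(setNames(list(), character()))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(ddg = "character"))
  need <- c("protein_id", "position", "ref_aa", "alt_aa", "ddg")
  if (!all(need %in% names(tab)))
    .stopf("ddG table must have columns %s", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) {
    .warnf("ddG table %s is empty", path)
    return(setNames(list(), character()))
  }

  line_no <- seq_len(nrow(tab)) + 1L  # account for the header line
  pos <- suppressWarnings(as.integer(tab$position))
  ddg <- suppressWarnings(as.numeric(ifelse(tab$ddg == "", NA, tab$ddg)))
  bad <- which(is.na(pos) | pos < 1L |
               !(tab$ref_aa %in% AA_ALPHABET) |
               !(tab$alt_aa %in% AA_ALPHABET) |
               (tab$ddg != "" & is.na(ddg)))
  if (length(bad))
    .stopf("malformed ddG table row at line %d of %s", line_no[bad[1L]], path)
  self <- which(tab$ref_aa == tab$alt_aa)
  if (length(self))
    .stopf("wild-type self-substitution row at line %d of %s",
           line_no[self[1L]], path)

  key <- paste(tab$protein_id, pos, tab$alt_aa, sep = ":")
  if (anyDuplicated(key)) {
    dup <- split(ddg, key)
    dup <- dup[lengths(dup) > 1L]
    diff_dup <- names(dup)[vapply(dup, function(v) {
      length(unique(v[!is.na(v)])) > 1L || anyNA(v) && any(!is.na(v))
    }, logical(1L))]
    if (length(diff_dup))
      .stopf("duplicate (protein, position, alt) rows with differing ddg: %s",
             diff_dup[1L])
    keep <- !duplicated(key)
    tab <- tab[keep, ]; pos <- pos[keep]; ddg <- ddg[keep]
  }

  out <- list()
  for (pid in unique(tab$protein_id)) {
    i <- tab$protein_id == pid
    L <- max(pos[i])
    seq_aa <- rep("X", L)
    ref_by_pos <- tapply(tab$ref_aa[i], pos[i], unique)
    if (any(lengths(ref_by_pos) > 1L))
      .stopf("protein %s: inconsistent ref_aa at position %s", pid,
             names(ref_by_pos)[lengths(ref_by_pos) > 1L][1L])
    seq_aa[as.integer(names(ref_by_pos))] <- unlist(ref_by_pos)
    m <- matrix(NA_real_, nrow = L, ncol = 20L,
                dimnames = list(NULL, AA_ALPHABET))
    m[cbind(pos[i], match(tab$alt_aa[i], AA_ALPHABET))] <- ddg[i]
    out[[pid]] <- DdgMatrix(pid, paste(seq_aa, collapse = ""), m)
  }
  out
}

#' Write ddG matrices as a long TSV
#'
#' Emits every non-wild-type cell (missing predictions with an empty
#' `ddg` field, so a write/read round trip is lossless).
#'
#' @param matrices a [DdgMatrix-class] or list of them.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeDdgTable <- function(matrices, path) {
  if (is(matrices, "DdgMatrix")) matrices <- list(matrices)
  rows <- lapply(matrices, function(m) {
    mask <- wildtypeMask(m)
    idx <- which(!mask, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    v <- ddgValues(m)[idx]
    data.frame(protein_id = proteinId(m), position = idx[, 1L],
               ref_aa = .chars(aaSequence(m))[idx[, 1L]],
               alt_aa = AA_ALPHABET[idx[, 2L]],
               ddg = ifelse(is.na(v), "", format(v, digits = 15L,
                                                 trim = TRUE,
                                                 scientific = FALSE)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  # rows whose residue is unknown carry ref_aa "X" and cannot round-trip;
  # such rows only arise from sparse inputs
  tab <- tab[tab$ref_aa != "X" | tab$ddg != "", ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read coding sequences from FASTA
#'
#' FASTA headers are either `gene_id` alone or `gene_id|transcript_id`.
#' An optional transcript table supplies transcript identifiers and
#' flanking bases per gene.
#'
#' @param path FASTA file of CDS nucleotide sequences.
#' @param transcripts optional data.frame with columns `gene_id` and any
#'   of `transcript_id`, `upstream_base`, `downstream_base`.
#' @return named list of [GeneModel-class] objects.
#' @export
readCdsFasta <- function(path, transcripts = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  gene_ids <- sub("\\|.*$", "", ids)
  tx_ids <- ifelse(grepl("|", ids, fixed = TRUE), sub("^[^|]*\\|", "", ids),
                   gene_ids)
  up <- rep(NA_character_, length(ids))
  dn <- rep(NA_character_, length(ids))
  if (!is.null(transcripts)) {
    j <- match(gene_ids, transcripts$gene_id)
    if ("transcript_id" %in% names(transcripts))
      tx_ids <- ifelse(is.na(j), tx_ids, transcripts$transcript_id[j])
    if ("upstream_base" %in% names(transcripts))
      up <- transcripts$upstream_base[j]
    if ("downstream_base" %in% names(transcripts))
      dn <- transcripts$downstream_base[j]
  }
  out <- lapply(seq_along(ids), function(i) {
    GeneModel(gene_ids[i], as.character(seqs[[i]]), transcriptId = tx_ids[i],
              upstreamBase = up[i], downstreamBase = dn[i])
  })
  setNames(out, gene_ids)
}

#' Write gene models as FASTA
#'
#' @param genes list of [GeneModel-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCdsFasta <- function(genes, path) {
  seqs <- Biostrings::DNAStringSet(vapply(genes, cdsSequence, character(1L)))
  names(seqs) <- vapply(genes, function(g)
    paste0(g@geneId, "|", g@transcriptId), character(1L))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# Column template for variant observation tables.
.variant_columns <- c("gene_id", "nt_position", "ref_base", "alt_base",
                      "aa_position", "ref_aa", "alt_aa", "consequence",
                      "ddg", "cohort_label", "clinical_label",
                      "allele_count")

#' Construct / validate a variant observation table
#'
#' One row per observed (or simulated) coding variant. Enforces the
#' invariants: consequence drawn from the fixed vocabulary and consistent
#' with the amino-acid pair under the standard genetic code, and `ddg`
#' present only for missense variants.
#'
#' @param df data.frame carrying at least `gene_id` and `consequence`;
#'   missing columns are filled with `NA` (`allele_count` with 1,
#'   `clinical_label` with `"unlabeled"`).
#' @return a validated data.frame with the canonical column set.
#' @export
variantTable <- function(df) {
  for (col in .variant_columns)
    if (is.null(df[[col]]))
      df[[col]] <- switch(col, allele_count = 1L,
                          clinical_label = "unlabeled",
                          cohort_label = NA_character_, NA)
  df <- df[, .variant_columns]
  if (!all(df$consequence %in% CONSEQUENCE_LEVELS))
    .stopf("unknown consequence value(s): %s",
           paste(setdiff(unique(df$consequence), CONSEQUENCE_LEVELS),
                 collapse = ", "))
  if (!all(df$clinical_label %in% c("benign", "pathogenic", "unlabeled")))
    .stopf("clinical_label must be benign, pathogenic or unlabeled")
  if (any(!is.na(df$allele_count) & df$allele_count < 0))
    .stopf("allele_count must be nonnegative")
  bad_ddg <- !is.na(df$ddg) & df$consequence != "missense"
  if (any(bad_ddg))
    .stopf("ddg must be present only for missense variants (%d offending rows)",
           sum(bad_ddg))
  both <- !is.na(df$ref_aa) & !is.na(df$alt_aa)
  if (any(both)) {
    expect <- .consequence_from_aa(df$ref_aa[both], df$alt_aa[both])
    mism <- df$consequence[both] != expect & df$consequence[both] != "other"
    if (any(mism))
      .stopf("consequence inconsistent with amino-acid pair in %d rows",
             sum(mism))
  }
  df
}

# Annotate SNVs (gene_id, nt_position, ref_base, alt_base) against gene
# models. Returns the annotated subset plus skip tallies.
.annotate_snvs <- function(df, genes) {
  unknown <- setdiff(unique(df$gene_id), names(genes))
  if (length(unknown))
    .stopf("unknown gene_id(s): %s", paste(unknown, collapse = ", "))
  n <- nrow(df)
  keep <- rep(TRUE, n)
  aa_position <- ref_aa <- alt_aa <- rep(NA_character_, n)
  cds_len <- vapply(genes, function(g) nchar(g@cds), integer(1L))
  outside <- df$nt_position < 1L | df$nt_position > cds_len[df$gene_id]
  keep[outside] <- FALSE
  for (gid in unique(df$gene_id[keep])) {
    i <- which(keep & df$gene_id == gid)
    cds <- genes[[gid]]@cds
    pos <- df$nt_position[i]
    ref_obs <- substring(cds, pos, pos)
    mism <- ref_obs != df$ref_base[i]
    if (any(mism))
      .stopf("gene %s: REF allele %s does not match the CDS base %s at position %d",
             gid, df$ref_base[i][mism][1L], ref_obs[mism][1L],
             pos[mism][1L])
    codon_i <- (pos - 1L) %/% 3L + 1L
    start <- (codon_i - 1L) * 3L + 1L
    ref_codon <- substring(cds, start, start + 2L)
    alt_codon <- ref_codon
    substr(alt_codon, pos - start + 1L, pos - start + 1L) <- df$alt_base[i]
    ref_aa[i] <- .aa_from_codons(ref_codon)
    alt_aa[i] <- .aa_from_codons(alt_codon)
    aa_position[i] <- codon_i
  }
  df$aa_position <- as.integer(aa_position)
  df$ref_aa <- ref_aa
  df$alt_aa <- alt_aa
  df$consequence <- NA_character_
  df$consequence[keep] <- .consequence_from_aa(ref_aa[keep], alt_aa[keep])
  list(variants = df[keep, , drop = FALSE],
       n_outside_cds = sum(outside))
}

#' Read observed variants from VCF or TSV
#'
#' VCF mode expects CDS-relative coordinates on the coding strand:
#' `CHROM` holds the gene identifier and `POS` the 1-based CDS position.
#' Multiallelic records are split; only single-nucleotide records are
#' kept (skipped non-SNV records are tallied, as are records outside the
#' CDS). Every kept record is annotated with its coding consequence by
#' codon translation. TSV mode reads a table already carrying the
#' [variantTable()] columns (consequence recomputed when gene models are
#' supplied and `nt_position` is present).
#'
#' @param path input file.
#' @param genes named list of [GeneModel-class] objects.
#' @param format `"vcf"` or `"tsv"` (default guessed from the extension).
#' @return a variant table (see [variantTable()]) with attributes
#'   `n_skipped_non_snv` and `n_outside_cds`.
#' @export
readVariants <- function(path, genes, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"

  if (format == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    n_skip <- 0L; n_out <- 0L
    if (!is.null(tab$nt_position) && !missing(genes)) {
      ann <- .annotate_snvs(tab, genes)
      tab <- ann$variants
      n_out <- ann$n_outside_cds
    }
    out <- variantTable(tab)
    attr(out, "n_skipped_non_snv") <- n_skip
    attr(out, "n_outside_cds") <- n_out
    return(out)
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- variantTable(data.frame(gene_id = character(),
                                   consequence = character()))
    attr(out, "n_skipped_non_snv") <- 0L
    attr(out, "n_outside_cds") <- 0L
    return(out)
  }
  alts <- strsplit(fix$ALT %||% "", ",", fixed = TRUE)
  rep_i <- rep(seq_len(nrow(fix)), lengths(alts))
  df <- data.frame(gene_id = fix$CHROM[rep_i],
                   nt_position = as.integer(fix$POS[rep_i]),
                   ref_base = fix$REF[rep_i],
                   alt_base = unlist(alts),
                   stringsAsFactors = FALSE)
  snv <- nchar(df$ref_base) == 1L & nchar(df$alt_base) == 1L &
    df$ref_base %in% DNA_BASES & df$alt_base %in% DNA_BASES
  n_skip <- sum(!snv)
  df <- df[snv, , drop = FALSE]
  ann <- .annotate_snvs(df, genes)
  out <- ann$variants
  out$allele_count <- 1L
  out <- variantTable(out)
  attr(out, "n_skipped_non_snv") <- n_skip
  attr(out, "n_outside_cds") <- ann$n_outside_cds
  out
}

#' Write a variant table as TSV
#'
#' @param variants a [variantTable()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue structure-confidence track from PDB/mmCIF
#'
#' Takes one value per residue from the C-alpha atom's B-factor field
#' (crystallographic B-factor for experimental structures; predicted
#' models such as AlphaFold store pLDDT there). A residue lacking a
#' C-alpha falls back to the mean B-factor of its atoms, with a message.
#'
#' @param path PDB or mmCIF file.
#' @param format `"pdb"` or `"cif"`; guessed from the extension by default.
#' @param chain chain identifier; default the first protein chain with
#'   C-alpha atoms.
#' @param sourceKind `"experimental"` or `"predicted_model"`; by default
#'   files whose header mentions AlphaFold are tagged `predicted_model`,
#'   all others `experimental`.
#' @param proteinId identifier for the track; defaults to the file stem.
#' @return a [StructureConfidence-class] object.
#' @export
readStructureConfidence <- function(path, format = c("auto", "pdb", "cif"),
                                    chain = NULL, sourceKind = NULL,
                                    proteinId = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  pdb <- if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) .stopf("no ATOM records in %s", path)
  if (is.null(chain)) {
    with_ca <- unique(at$chain[at$elety == "CA"])
    chain <- if (length(with_ca)) with_ca[1L] else unique(at$chain)[1L]
  }
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) .stopf("chain %s not found in %s", chain, path)
  resnos <- sort(unique(at$resno))
  vals <- vapply(resnos, function(rn) {
    res <- at[at$resno == rn, , drop = FALSE]
    ca <- res$b[res$elety == "CA"]
    if (length(ca)) ca[1L] else {
      message(sprintf("residue %d lacks a C-alpha; using mean of %d atom B-factors",
                      rn, nrow(res)))
      mean(res$b)
    }
  }, numeric(1L))
  if (is.null(sourceKind)) {
    hdr <- readLines(path, n = 50L, warn = FALSE)
    sourceKind <- if (any(grepl("alphafold", hdr, ignore.case = TRUE)))
      "predicted_model" else "experimental"
  }
  if (is.null(proteinId))
    proteinId <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                     ignore.case = TRUE)
  StructureConfidence(proteinId, vals, residueIndex = resnos,
                      sourceKind = sourceKind)
}

#' Read a per-gene annotation table
#'
#' TSV with `gene_id` and any of `loeuf` (published LOEUF), `pli`,
#' `shet_category`, plus `bf_`-prefixed Bayes-factor columns which are
#' carried through untouched (consumed only, never computed here).
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readGeneAnnotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(tab$gene_id)) .stopf("annotation table must have gene_id")
  if (!is.null(tab$pli)) {
    bad <- !is.na(tab$pli) & (tab$pli < 0 | tab$pli > 1)
    if (any(bad)) .stopf("pli values must lie in [0,1]")
  }
  if (!is.null(tab$shet_category)) {
    bad <- !is.na(tab$shet_category) &
      !(tab$shet_category %in% SHET_CATEGORIES)
    if (any(bad))
      .stopf("shet_category must be one of %s",
             paste(SHET_CATEGORIES, collapse = ", "))
  }
  tab
}

#' Read / write a trinucleotide mutation-rate table
#'
#' TSV with columns `context`, `alt`, `rate`.
#'
#' @param path TSV path.
#' @param strandCollapsed whether the table keys only central-A/C contexts.
#' @return a [MutationRateTable-class].
#' @export
readMutationRateTable <- function(path, strandCollapsed = FALSE) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("context", "alt", "rate")
  if (!all(need %in% names(tab)))
    .stopf("rate table must have columns %s", paste(need, collapse = ", "))
  MutationRateTable(setNames(tab$rate, paste0(tab$context, ">", tab$alt)),
                    strandCollapsed = strandCollapsed)
}

#' @rdname readMutationRateTable
#' @param table a [MutationRateTable-class].
#' @export
writeMutationRateTable <- function(table, path) {
  keys <- names(table@rates)
  tab <- data.frame(context = substr(keys, 1L, 3L),
                    alt = substr(keys, 5L, 5L),
                    rate = unname(table@rates))
  tab <- tab[order(tab$context, tab$alt), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
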