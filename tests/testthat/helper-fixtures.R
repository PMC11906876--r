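# Fixtures and independent oracles used across the suite. Everything is
# generated in code at test time.

AA20 <- dosconstraint:::AA_ALPHABET

# A DdgMatrix with given per-cell values (named list position -> named
# vector of alt -> ddg); unspecified cells are missing.
make_ddg <- function(sequence, cells = list(), id = "prot1") {
  L <- nchar(sequence)
  m <- matrix(NA_real_, L, 20L, dimnames = list(NULL, AA20))
  for (pos in names(cells))
    m[as.integer(pos), names(cells[[pos]])] <- cells[[pos]]
  DdgMatrix(id, sequence, m)
}

# Fully observed random matrix (wild-type cells zero, like predictor
# output), from the current RNG stream.
random_ddg <- function(L = 10L, id = "prot1", sd = 1) {
  seq <- paste(sample(AA20, L, replace = TRUE), collapse = "")
  m <- matrix(rnorm(L * 20L, sd = sd), L, 20L,
              dimnames = list(NULL, AA20))
  d <- DdgMatrix(id, seq, m)
  m[wildtypeMask(d)] <- 0
  DdgMatrix(id, seq, m)
}

SENSE_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# Random valid gene: ATG + sense codons + stop, with flanks.
random_gene <- function(n_codons = 6L, id = "g1", flanks = TRUE) {
  cds <- paste0("ATG",
                paste(sample(setdiff(SENSE_CODONS, "ATG"), n_codons - 1L,
                             replace = TRUE), collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  GeneModel(id, cds,
            upstreamBase = if (flanks) sample(c("A","C","G","T"), 1L)
                           else NA_character_,
            downstreamBase = if (flanks) sample(c("A","C","G","T"), 1L)
                             else NA_character_)
}

# Independent consequence oracle: mutate the CDS string, translate both
# alleles in full with Biostrings::translate, and compare the proteins.
oracle_consequence <- function(cds, pos, alt) {
  mut <- cds
  substr(mut, pos, pos) <- alt
  tr <- function(s) strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(s),
                          no.init.codon = TRUE)), "")[[1]]
  a <- tr(cds); b <- tr(mut)
  i <- (pos - 1L) %/% 3L + 1L
  if (a[i] == b[i]) "synonymous"
  else if (a[i] != "*" && b[i] == "*") "nonsense"
  else if (a[i] == "*" && b[i] != "*") "stop_loss"
  else "missense"
}

# Independent expected-count oracle: explicit double loop over every
# position and alternate base, rate looked up in a plain data.frame.
oracle_expected_count <- function(gene, rates, k, class, ddg = NULL,
                                  threshold = 0.5) {
  cds <- cdsSequence(gene)
  keys <- names(rates@rates)
  rate_df <- data.frame(context = substr(keys, 1, 3),
                        alt = substr(keys, 5, 5),
                        rate = unname(rates@rates))
  mean_rate <- function(ref, alt) {
    mean(rate_df$rate[substr(rate_df$context, 2, 2) == ref &
                      rate_df$alt == alt])
  }
  total <- 0
  for (pos in seq_len(nchar(cds))) {
    ref <- substr(cds, pos, pos)
    up <- if (pos == 1L) gene@upstreamBase else substr(cds, pos - 1L, pos - 1L)
    dn <- if (pos == nchar(cds)) gene@downstreamBase
          else substr(cds, pos + 1L, pos + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      csq <- oracle_consequence(cds, pos, alt)
      keep <- switch(class,
        synonymous = csq == "synonymous",
        nonsense = csq == "nonsense",
        missense = csq == "missense",
        dos = {
          if (csq != "missense") FALSE else {
            i <- (pos - 1L) %/% 3L + 1L
            start <- (i - 1L) * 3L + 1L
            mutc <- substr(`substr<-`(cds, pos, pos, alt), start, start + 2L)
            alt_aa <- unname(Biostrings::GENETIC_CODE[mutc])
            v <- ddgValues(ddg)[i, alt_aa]
            !is.na(v) && abs(v) > threshold
          }
        })
      if (!keep) next
      r <- if (is.na(up) || is.na(dn)) mean_rate(ref, alt)
           else rate_df$rate[rate_df$context == paste0(up, ref, dn) &
                             rate_df$alt == alt]
      total <- total + r
    }
  }
  k * total
}

# Minimal PDB fixture writer (fixed-column ATOM records).
pdb_atom_line <- function(serial, name, resno, b, resname = "ALA",
                          chain = "A") {
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain, resno, 1.0, 2.0, 3.0, 1.00, b,
          substr(trimws(name), 1L, 1L))
}

write_toy_pdb <- function(path, bfactors, header = NULL) {
  lines <- c(header,
             vapply(seq_along(bfactors), function(i)
               pdb_atom_line(i, " CA ", i, bfactors[i]), character(1L)),
             "END")
  writeLines(lines, path)
  path
}

write_toy_vcf <- function(path, rows) {
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               vapply(rows, paste, character(1L), collapse = "\t")),
             path)
  path
}

# Small missense-only variant table with given ddg values.
missense_table <- function(ddg, gene_id = "g1") {
  variantTable(data.frame(gene_id = gene_id, consequence = "missense",
                          ddg = ddg, stringsAsFactors = FALSE))
}
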