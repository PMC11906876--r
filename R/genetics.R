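# Codon-level machinery: translation, consequence calls, exhaustive SNV
# enumeration with trinucleotide contexts.

.codon_table <- function() Biostrings::GENETIC_CODE

# Vectorised codon -> amino acid ('*' for stop).
.aa_from_codons <- function(codons) {
  unname(.codon_table()[codons])
}

#' Translate a coding sequence
#'
#' @param cds nucleotide string over ACGT, length divisible by 3.
#' @return character vector of amino acids, one per codon, `"*"` for stop.
#' @export
translateCds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) .stopf("CDS length %d is not divisible by 3", n)
  starts <- seq(1L, n, by = 3L)
  .aa_from_codons(substring(cds, starts, starts + 2L))
}

# Consequence of an amino-acid pair under the standard genetic code.
.consequence_from_aa <- function(refAa, altAa) {
  out <- rep("missense", length(refAa))
  out[refAa == altAa] <- "synonymous"
  out[refAa != "*" & altAa == "*"] <- "nonsense"
  out[refAa == "*" & altAa != "*"] <- "stop_loss"
  out
}

#' Enumerate all possible single-nucleotide variants of a gene
#'
#' Produces the 3L alternate alleles of an L-nucleotide CDS, each with its
#' trinucleotide context, codon change and coding consequence under the
#' standard genetic code. This enumeration underlies the expected-variant
#' model: many more point mutations create missense changes than nonsense
#' changes, which is why stability-disrupting missense variation is so
#' much more abundant than loss-of-function variation.
#'
#' @param gene a [GeneModel-class].
#' @param allowInternalStops keep going when the CDS translates with an
#'   internal stop codon (default errors).
#' @return data.frame with columns `position` (1-based CDS), `ref`, `alt`,
#'   `context` (trinucleotide, `NA` at a CDS edge lacking a flanking
#'   base), `aa_position`, `ref_aa`, `alt_aa`, `consequence`.
#' @examples
#' g <- GeneModel("g1", "ATGTGGTAA")
#' snv <- enumerateSnvs(g)
#' nrow(snv)                                  # 27
#' sum(snv$consequence == "nonsense")         # 2 (TGG>TAG, TGG>TGA)
#' @export
enumerateSnvs <- function(gene, allowInternalStops = FALSE) {
  stopifnot(is(gene, "GeneModel"))
  cds <- gene@cds
  L <- nchar(cds)
  bases <- .chars(cds)
  aa <- translateCds(cds)
  n_codons <- length(aa)
  internal <- if (n_codons > 1L) aa[-n_codons] else character()
  if (!allowInternalStops && any(internal == "*"))
    .stopf("gene %s: CDS contains an internal stop codon at codon %d",
           gene@geneId, which(internal == "*")[1L])

  pos <- rep(seq_len(L), each = 3L)
  ref <- bases[pos]
  alt_by_base <- lapply(setNames(DNA_BASES, DNA_BASES),
                        function(b) setdiff(DNA_BASES, b))
  alt <- unlist(alt_by_base[bases], use.names = FALSE)

  up <- c(gene@upstreamBase, bases)[pos]
  dn <- c(bases, gene@downstreamBase)[pos + 1L]
  context <- ifelse(is.na(up) | is.na(dn), NA_character_,
                    paste0(up, ref, dn))

  codon_i <- (pos - 1L) %/% 3L + 1L
  within <- (pos - 1L) %% 3L + 1L
  codon_start <- (codon_i - 1L) * 3L + 1L
  ref_codon <- substring(cds, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt
  ref_aa <- aa[codon_i]
  alt_aa <- .aa_from_codons(alt_codon)

  data.frame(position = pos, ref = ref, alt = alt, context = context,
             aa_position = codon_i, ref_aa = ref_aa, alt_aa = alt_aa,
             consequence = .consequence_from_aa(ref_aa, alt_aa),
             stringsAsFactors = FALSE)
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(.chars(s)), collapse = "")
  }, character(1L), USE.NAMES = FALSE))
}

#' Look up trinucleotide mutation rates
#'
#' Vectorised lookup of the relative rate of `context -> alt` central-base
#' substitutions. For a strand-collapsed table, G/T-centred queries are
#' resolved through the reverse complement. `NA` contexts (CDS edges
#' without a flanking base) return `NA`.
#'
#' @param table a [MutationRateTable-class].
#' @param context character vector of trinucleotides.
#' @param alt character vector of alternate central bases.
#' @return numeric vector of rates.
#' @export
rateLookup <- function(table, context, alt) {
  stopifnot(is(table, "MutationRateTable"))
  context <- as.character(context)
  alt <- as.character(alt)
  if (table@strandCollapsed) {
    central <- substr(context, 2L, 2L)
    flip <- !is.na(context) & central %in% c("G", "T")
    if (any(flip)) {
      context[flip] <- .revcomp(context[flip])
      alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    }
  }
  key <- paste0(context, ">", alt)
  out <- unname(table@rates[key])
  out[is.na(context)] <- NA_real_
  bad <- !is.na(context) & is.na(out)
  if (any(bad))
    .stopf("no rate for context %s", paste(unique(key[bad]), collapse = ", "))
  out
}

# Mean rate per (central ref base, alt) pair; used to impute edge codons
# whose trinucleotide context is incomplete.
.mean_rates_by_change <- function(table) {
  keys <- names(table@rates)
  central <- substr(keys, 2L, 2L)
  alt <- substr(keys, 5L, 5L)
  means <- tapply(table@rates, paste0(central, ">", alt), mean)
  if (table@strandCollapsed) {
    # mirror onto G/T-centred changes through the complement
    comp <- setNames(as.numeric(means), chartr("ACGT", "TGCA",
                                               names(means)))
    means <- c(means, comp)
  }
  means
}
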