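# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical one-letter codes. Column order
# of every ddG matrix in the package.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_BASES <- c("A", "C", "G", "T")

CONSEQUENCE_LEVELS <- c("synonymous", "missense", "nonsense", "stop_loss",
                        "other")

SHET_CATEGORIES <- c("extreme", "strong", "weak", "neutral")

`%||%` <- function(x, y) if (is.null(x)) y else x

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

.is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

# Splits a sequence string into single characters.
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
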