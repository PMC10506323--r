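## Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T")

## Reverse complement of plain character strings (vectorised).
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

## Phred+33 encode/decode.
phred_encode <- function(q) {
  vapply(q, function(v) intToUtf8(as.integer(v) + 33L), character(1))
}

phred_decode <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)

## Ranks of a taxonomic lineage, shallowest to deepest.
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")
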