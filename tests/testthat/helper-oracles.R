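## Independent oracles and small fixture builders used across the suite.

## Build an in-memory read table at constant quality.
make_reads <- function(seqs, quality = 40, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%04d", seq_along(seqs))
  data.frame(id = ids, seq = seqs,
             qual = vapply(nchar(seqs), function(l)
               intToUtf8(base::rep(quality + 33L, l)), character(1)),
             stringsAsFactors = FALSE)
}

## Brute-force tag discovery: enumerate every distinct >=65 bp prefix and
## count the samples containing it.
brute_force_tags <- function(samples, prevalence = 0.25, tag_len = 65) {
  prefixes <- lapply(samples, function(s) {
    sq <- s$seq[nchar(s$seq) >= tag_len]
    unique(substr(sq, 1, tag_len))
  })
  all_tags <- unique(unlist(prefixes))
  n_with <- vapply(all_tags, function(tg)
    sum(vapply(prefixes, function(p) tg %in% p, logical(1))), numeric(1))
  sort(all_tags[n_with / length(samples) >= prevalence])
}

## Smith-Waterman oracle via Biostrings (affine: gap of length g costs
## 5 + 2 g, matching the package's search scoring).
sw_oracle <- function(query, subject, match = 1, mismatch = -2,
                      gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::pairwiseAlignment(
    query, subject, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE))
}

## Closed-form one-way random-effects ANOVA estimators for a balanced
## design with r records per animal: between/within mean squares.
anova_oneway_vc <- function(y, animal) {
  animal <- as.factor(animal)
  r <- unique(table(animal))
  stopifnot(length(r) == 1)
  q <- nlevels(animal)
  means <- tapply(y, animal, mean)
  msb <- r * sum((means - mean(y))^2) / (q - 1)
  msw <- sum((y - means[animal])^2) / (q * (r - 1))
  c(between = (msb - msw) / r, within = msw)
}

## A tiny three-genus reference with dense planted sites, for fast
## end-to-end fixtures.
toy_reference <- function(n_genera = 3, genomes_per_genus = 1,
                          genome_length = 20000, seed = 11) {
  simulate_reference(n_genera = n_genera,
                     genomes_per_genus = genomes_per_genus,
                     genome_length = genome_length,
                     site_density = 1 / 400, window_frac = 0.5, seed = seed)
}

## Wrap a plain matrix as a profile with given provenance (tests only).
new_profile_for_test <- function(m, provenance = "log10") {
  structure(m, provenance = provenance,
            class = c("profile_matrix", "matrix", "array"))
}

## Random DNA string (test-local; independent of the package generator).
random_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
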