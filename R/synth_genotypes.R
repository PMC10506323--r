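## Synthetic SNP genotypes with half-sib family structure.

#' Simulate biallelic genotypes with half-sib families
#'
#' Animals are partitioned into paternal half-sib families: each family
#' shares a sire whose gametes segregate to the offspring, while dam gametes
#' are drawn from population allele frequencies.  This plants the
#' off-diagonal structure (expected genomic relationship of 0.25 between half
#' sibs) needed to test GRM construction and REML recovery.  Monomorphic
#' markers are removed.
#'
#' @param n_animals number of animals (>= 2).
#' @param n_markers number of simulated markers before monomorphic filtering
#'   (>= 10; frequency estimation is meaningless below that).
#' @param n_families number of half-sib families.
#' @param maf_range range from which population allele frequencies are drawn.
#' @param seed integer seed.
#' @return integer matrix animals x markers with values in \{0, 1, 2\},
#'   rownames `A0001`..., with attributes `freq` (post-filter allele
#'   frequencies) and `family` (family index per animal).
#' @export
simulate_genotypes <- function(n_animals, n_markers = 1000, n_families = 20,
                               maf_range = c(0.1, 0.9), seed = 1) {
  if (!is_count(n_animals) || n_animals < 2) stopf("n_animals must be >= 2")
  if (n_markers < 10) stopf("n_markers must be >= 10")
  if (!is_count(n_families) || n_families < 1) stopf("n_families must be >= 1")
  set.seed(seed)

  p <- runif(n_markers, maf_range[1], maf_range[2])
  fam <- sort(rep_len(seq_len(n_families), n_animals))
  ## sire haplotypes: two gametes per sire per locus
  sire_h1 <- matrix(rbinom(n_families * n_markers, 1, rep(p, each = n_families)),
                    n_families, n_markers)
  sire_h2 <- matrix(rbinom(n_families * n_markers, 1, rep(p, each = n_families)),
                    n_families, n_markers)
  ## each offspring inherits, per locus, one of its sire's two alleles
  pick <- matrix(rbinom(n_animals * n_markers, 1, 0.5), n_animals, n_markers)
  paternal <- sire_h1[fam, , drop = FALSE] * pick +
    sire_h2[fam, , drop = FALSE] * (1 - pick)
  maternal <- matrix(rbinom(n_animals * n_markers, 1, rep(p, each = n_animals)),
                     n_animals, n_markers)
  geno <- paternal + maternal

  obs <- colMeans(geno) / 2
  keep <- obs > 0 & obs < 1
  geno <- geno[, keep, drop = FALSE]
  rownames(geno) <- sprintf("A%04d", seq_len(n_animals))
  colnames(geno) <- sprintf("M%05d", which(keep))
  structure(geno, freq = colMeans(geno) / 2, family = fam)
}

#' Write / read genotype matrices as TSV
#'
#' @param geno animals x markers matrix in \{0,1,2\}.
#' @param path output TSV path (animals in rows).
#' @return invisibly, `path`.
#' @export
write_genotypes <- function(geno, path) {
  write.table(geno, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                       check.names = FALSE))
}
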