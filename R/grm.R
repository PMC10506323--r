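## VanRaden (method 1) genomic relationship matrix.

#' Genomic relationship matrix, VanRaden method 1
#'
#' `G = (M - 2p)(M - 2p)' / (2 sum_k p_k (1 - p_k))`, where `M` is the
#' animals x markers genotype matrix in \{0, 1, 2\} and `p_k` the allele
#' frequencies used for column-wise centring.
#'
#' @param genotypes animals x markers matrix with values in \{0, 1, 2\};
#'   monomorphic markers must already be removed.
#' @param freq allele frequencies; by default observed column means / 2.
#' @return symmetric matrix of class `grm` with attributes `n_markers` and
#'   `freq`.
#' @export
grm_vanraden <- function(genotypes, freq = NULL) {
  M <- as.matrix(genotypes)
  if (!all(M %in% c(0, 1, 2))) stopf("genotypes must be coded 0/1/2")
  p <- if (is.null(freq)) colMeans(M) / 2 else freq
  if (any(p <= 0 | p >= 1))
    stopf("allele frequencies in {0,1} after filtering; remove monomorphic markers")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  structure(G, n_markers = ncol(M), freq = p,
            class = c("grm", class(G)))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d animals, %d markers; mean diagonal %.3f\n",
              nrow(x), attr(x, "n_markers"), mean(diag(x))))
  invisible(x)
}

#' Write / read a GRM as TSV
#' @param grm the matrix.
#' @param path TSV path.
#' @return invisibly, `path`.
#' @export
write_grm <- function(grm, path) {
  write.table(unclass(grm), path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE))
  structure(m, class = c("grm", class(m)))
}
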