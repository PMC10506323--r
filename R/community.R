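## Sample networks, community detection and PERMANOVA.

#' Mutual k-nearest-neighbour sample graph
#'
#' Connects samples i and j when each is among the other's `k` most
#' correlated neighbours (mutual kNN), the construction used for
#' NetView-style sample networks.  Edge weights are the correlations.
#'
#' @param relmatrix a sample correlation matrix ([relationship_matrix()]).
#' @param k neighbourhood size, `1 <= k < n`; defaults to `min(10, n - 1)`
#'   (150 is the value used at full study scale).
#' @return an undirected weighted igraph object with graph attribute `k`.
#' @export
mknn_graph <- function(relmatrix, k = NULL) {
  r <- as.matrix(relmatrix)
  n <- nrow(r)
  if (is.null(k)) k <- min(10L, n - 1L)
  if (k <= 0) stopf("k must be positive")
  if (k >= n) stopf("k must be smaller than the number of samples")
  diag(r) <- -Inf
  nn <- apply(r, 1, function(row) order(row, decreasing = TRUE)[seq_len(k)])
  nn <- matrix(nn, ncol = n)  # k x n
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adj[i, nn[, i]] <- TRUE
  adj <- adj & t(adj)
  diag(r) <- 1
  w <- r * adj
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(rownames(r)))
    igraph::V(g)$name <- rownames(r)
  g <- igraph::set_graph_attr(g, "k", k)
  g
}

#' Random-walk (Walktrap) community detection
#'
#' Pons-Latapy random-walk agglomeration via igraph, cutting the merge
#' sequence at maximum modularity.  Negative edge weights (possible for
#' correlation graphs) are floored at a small positive value, since random
#' walks require non-negative transition weights.
#'
#' @param graph an igraph object (e.g. from [mknn_graph()]).
#' @param steps random-walk length (default 4, the algorithm's common
#'   default).
#' @param seed integer seed (the agglomeration is deterministic; the seed
#'   is fixed for strict reproducibility of any tie-breaking).
#' @return integer membership vector named by node.
#' @export
detect_communities <- function(graph, steps = 4, seed = 1) {
  if (igraph::vcount(graph) == 0) stopf("empty graph")
  set.seed(seed)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- base::rep(1, igraph::ecount(graph))
  w <- pmax(w, 1e-6)
  cl <- igraph::cluster_walktrap(graph, weights = w, steps = steps)
  m <- igraph::membership(cl)
  setNames(as.integer(m), names(m))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum |x_f - y_f| / sum (x_f + y_f)` over features, computed on
#' non-negative (typically relative-abundance) rows.
#'
#' @param relabund samples x features matrix with non-negative entries
#'   (e.g. from [relative_abundance()]).
#' @return a `dist` object.
#' @export
bray_curtis <- function(relabund) {
  m <- unclass(as_counts(relabund))
  if (any(m < 0)) stopf("Bray-Curtis requires non-negative input")
  if (any(rowSums(m) == 0))
    stopf("all-zero sample row(s) make Bray-Curtis undefined: %s",
          paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' PERMANOVA with sequential sums of squares
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' the Gower-centred inner-product matrix is partitioned by sequential
#' (Type I) projections onto the model terms in the order given; pseudo-F
#' per term is `(SS_term / df_term) / (SS_res / df_res)` and the p-value is
#' `(1 + #permuted F >= observed) / (n_perm + 1)` under free permutation of
#' sample identities.  Permutations are drawn with R's Mersenne-Twister
#' generator under `seed`, so results are bit-reproducible.
#'
#' @param dist a `dist` or symmetric distance matrix.
#' @param design data.frame of sample-aligned factors/covariates.
#' @param terms character vector: model terms in fitting order.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return object of class `permanova`: ANOVA-style table (`term`, `df`,
#'   `ss`, `pseudo_f`, `p_value` plus Residual and Total rows) with
#'   attributes `n_perm` and `seed`.
#' @export
permanova <- function(dist, design, terms, n_perm = 999, seed = 1) {
  d <- as.matrix(dist)
  n <- nrow(d)
  stopifnot(nrow(design) == n, length(terms) >= 1)
  for (tm in terms) {
    v <- design[[tm]]
    if (is.null(v)) stopf("term '%s' not found in design", tm)
    if (!is.numeric(v) && length(unique(v)) < 2)
      stopf("term '%s' has a single level", tm)
  }
  ## Gower-centred inner products
  A <- -0.5 * d^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C

  ## sequential projectors
  Hs <- vector("list", length(terms))
  prev <- matrix(1 / n, n, n)  # intercept projector
  prev_rank <- 1L
  df <- integer(length(terms))
  for (j in seq_along(terms)) {
    fml <- stats::as.formula(paste("~", paste(terms[seq_len(j)],
                                              collapse = " + ")))
    X <- model.matrix(fml, data = design)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    H <- tcrossprod(Q)
    Hs[[j]] <- H - prev
    df[j] <- q$rank - prev_rank
    prev <- H
    prev_rank <- q$rank
  }
  df_res <- n - prev_rank
  ss_total <- sum(diag(G))

  fstat <- function(Gp) {
    ss <- vapply(Hs, function(h) sum(h * Gp), numeric(1))
    ss_res <- sum(diag(Gp)) - sum(ss)
    list(ss = ss, ss_res = ss_res,
         f = (ss / df) / (ss_res / df_res))
  }
  obs <- fstat(G)

  set.seed(seed)
  exceed <- base::rep(0L, length(terms))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    fp <- fstat(G[p, p])$f
    exceed <- exceed + (fp >= obs$f - 1e-12)
  }
  pval <- (1 + exceed) / (n_perm + 1)

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, n - 1L),
    ss = c(obs$ss, obs$ss_res, ss_total),
    pseudo_f = c(obs$f, NA, NA),
    p_value = c(pval, NA, NA),
    stringsAsFactors = FALSE)
  structure(tab, class = c("permanova", "data.frame"),
            n_perm = n_perm, seed = seed)
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d free permutations, seed %d)\n",
              attr(x, "n_perm"), attr(x, "seed")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}
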