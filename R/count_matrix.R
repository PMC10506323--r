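## Shared samples x features count container for the RB and RF profilers.

#' Samples x features count matrix
#'
#' Container shared by the reference-based (genus columns) and
#' reference-free (tag columns) profilers: integer counts, per-sample read
#' totals (all QC-passed reads, not just assigned ones) and the per-sample
#' assignment rate `rowSums(counts) / totals`.
#'
#' @param counts integer matrix, samples in rows.
#' @param totals per-sample total QC-passed reads (>= row sums).
#' @return object of class `count_matrix` with elements `counts`, `totals`,
#'   `assignment_rate`.
#' @export
count_matrix <- function(counts, totals) {
  stopifnot(is.matrix(counts), length(totals) == nrow(counts))
  if (any(counts < 0)) stopf("counts must be non-negative")
  assigned <- rowSums(counts)
  if (any(assigned > totals + 1e-9)) stopf("row sums exceed sample totals")
  rate <- ifelse(totals > 0, assigned / totals, 0)
  structure(list(counts = counts, totals = as.numeric(totals),
                 assignment_rate = as.numeric(rate)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d samples x %d features; mean assignment rate %.1f%%\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(x$assignment_rate)))
  invisible(x)
}

#' Write a count matrix and its per-sample statistics as TSV
#'
#' @param x a `count_matrix`.
#' @param counts_path samples x features TSV.
#' @param stats_path per-sample stats TSV (total, assigned, assignment_rate).
#' @return invisibly, the paths.
#' @export
write_count_matrix <- function(x, counts_path, stats_path = NULL) {
  write.table(x$counts, counts_path, sep = "\t", quote = FALSE,
              col.names = NA)
  if (!is.null(stats_path)) {
    write.table(data.frame(sample = rownames(x$counts), total = x$totals,
                           assigned = rowSums(x$counts),
                           assignment_rate = x$assignment_rate),
                stats_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(counts_path, stats_path))
}
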