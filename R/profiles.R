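## Profile transformations: relative abundance, log10 proportions,
## column normalisation and Cohort adjustment.

new_profile <- function(mat, provenance) {
  structure(mat, provenance = provenance, class = c("profile_matrix",
                                                    class(mat)))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix [%s]: %d samples x %d features\n",
              attr(x, "provenance"), nrow(x), ncol(x)))
  invisible(x)
}

#' @export
`[.profile_matrix` <- function(x, ..., drop = FALSE) {
  out <- unclass(x)[..., drop = drop]
  if (is.matrix(out)) new_profile(out, attr(x, "provenance")) else out
}

#' Provenance of a profile matrix
#' @param x a `profile_matrix`.
#' @return one of `"relabund"`, `"log10"`, `"log10norm"`, `"cohortadj"`.
#' @export
provenance <- function(x) attr(x, "provenance")

as_counts <- function(counts) {
  if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
}

#' Relative abundances
#'
#' Divides each count by its row sum, so rows sum to one.
#'
#' @param counts a [count_matrix] or plain matrix.
#' @return a `profile_matrix` with provenance `"relabund"`.
#' @export
relative_abundance <- function(counts) {
  m <- as_counts(counts)
  rs <- rowSums(m)
  if (any(rs == 0))
    stopf("sample(s) with zero counts: %s",
          paste(rownames(m)[rs == 0], collapse = ", "))
  new_profile(m / rs, "relabund")
}

#' Log10 proportions
#'
#' Adds one to every count, divides by the new row sum (reads assigned plus
#' the number of taxa) and takes log base 10; per row, the antilogs sum to
#' one.  All-zero rows are valid (uniform proportions).
#'
#' @param counts a [count_matrix] or plain matrix with >= 1 feature.
#' @return a `profile_matrix` with provenance `"log10"`.
#' @export
log10_proportions <- function(counts) {
  m <- as_counts(counts)
  if (ncol(m) < 1) stopf("at least one feature is required")
  new_profile(log10((m + 1) / (rowSums(m) + ncol(m))), "log10")
}

## z-score the columns of a plain matrix (n-1 denominator); constant
## columns map to zero so downstream correlations stay defined.
zscore_mat <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  z <- sweep(sweep(m, 2, mu), 2, ifelse(s > 0, s, 1), "/")
  z[, s == 0] <- 0
  z
}

#' Column normalisation (z-score)
#'
#' Centers and scales each column to mean zero and (sample) standard
#' deviation one.  Constant columns are set to zero rather than NaN.
#'
#' @param profile a `profile_matrix` (typically log10 proportions).
#' @return a `profile_matrix` with provenance `"log10norm"`.
#' @export
zscore_columns <- function(profile) {
  m <- unclass(profile)
  if (nrow(m) < 2) stopf("at least two samples are required")
  new_profile(zscore_mat(m), "log10norm")
}

#' Cohort adjustment
#'
#' Z-scores every column independently within each cohort, so that within
#' each column every cohort has mean zero and standard deviation one.  This
#' removes environmental structure (diet, age, time off feed) shared by a
#' cohort.  Columns constant within a cohort become zero for that cohort.
#' The input must be a log10-proportion profile; raw counts are refused.
#'
#' @param profile a `profile_matrix` with provenance `"log10"`.
#' @param cohort_labels cohort factor, one per sample (every cohort needs
#'   at least two samples).
#' @return a `profile_matrix` with provenance `"cohortadj"`.
#' @export
cohort_adjust <- function(profile, cohort_labels) {
  if (!inherits(profile, "profile_matrix") ||
      !identical(provenance(profile), "log10"))
    stopf("cohort_adjust expects a log10-proportion profile_matrix; %s",
          "transform counts with log10_proportions() first")
  m <- unclass(profile)
  stopifnot(length(cohort_labels) == nrow(m))
  cohort_labels <- as.character(cohort_labels)
  sizes <- table(cohort_labels)
  if (any(sizes < 2))
    stopf("singleton cohort(s): %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  out <- m
  for (ch in unique(cohort_labels)) {
    i <- cohort_labels == ch
    out[i, ] <- zscore_mat(m[i, , drop = FALSE])
  }
  new_profile(out, "cohortadj")
}

#' Sample relationship (correlation) matrix
#'
#' Pearson correlation between sample rows across features: an n x n
#' matrix over samples with unit diagonal.
#'
#' @param profile a `profile_matrix`.
#' @return symmetric correlation matrix of class `relationship_matrix`
#'   with attribute `provenance` of the source profile.
#' @export
relationship_matrix <- function(profile) {
  m <- unclass(profile)
  v <- apply(m, 1, sd)
  if (any(v == 0))
    stopf("constant sample row(s): %s",
          paste(rownames(m)[v == 0], collapse = ", "))
  r <- cor(t(m))
  structure(r, provenance = attr(profile, "provenance"),
            class = c("relationship_matrix", class(r)))
}

#' Write a profile or relationship matrix as TSV with a provenance sidecar
#'
#' @param x the matrix.
#' @param path TSV output path.
#' @param sidecar optional JSON path recording the provenance.
#' @return invisibly, `path`.
#' @export
write_profile <- function(x, path, sidecar = NULL) {
  write.table(unclass(x), path, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(sidecar))
    jsonlite::write_json(list(provenance = attr(x, "provenance"),
                              dim = dim(x)),
                         sidecar, auto_unbox = TRUE)
  invisible(path)
}
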