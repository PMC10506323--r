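## Per-feature variance-component scans over a profile matrix.

#' Heritability and repeatability for every feature of a profile
#'
#' Fits the animal + permanent-environment REML model to each column of a
#' Cohort-adjusted profile.  The expensive design preparation (GRM
#' eigendecomposition) is shared across features.
#'
#' @param profile a `profile_matrix` with provenance `"cohortadj"`
#'   (rownames = sample ids); other provenances are refused because
#'   uncorrected cohort structure biases the components.
#' @param grm genomic relationship matrix (rownames = animal ids).
#' @param design a `study_design` or a data.frame with `sample_id` and
#'   `animal_id`.
#' @param ... passed to [reml_fit()] (`max_iter`, `tol`, `ridge`).
#' @return object of class `herit_scan`: data.frame with one row per
#'   feature (`sigma2_g`, `sigma2_pe`, `sigma2_e`, SEs, `h2`, `h2_se`,
#'   `repeatability`, `rep_se`, `logLik`, `converged`).
#' @export
fit_feature_table <- function(profile, grm, design, ...) {
  if (!inherits(profile, "profile_matrix") ||
      !identical(provenance(profile), "cohortadj"))
    stopf("fit_feature_table expects a Cohort-adjusted profile %s",
          "(provenance 'cohortadj'); run cohort_adjust() first")
  s <- if (inherits(design, "study_design")) design$samples else design
  m <- unclass(profile)
  i <- match(rownames(m), s$sample_id)
  if (anyNA(i)) stopf("profile rows missing from the design")
  animal <- s$animal_id[i]
  prep <- reml_prepare(grm, animal)
  rows <- lapply(colnames(m), function(f) {
    fit <- reml_fit(m[, f], animal = animal, prep = prep, ...)
    data.frame(feature = f,
               sigma2_g = fit$varcomp[["g"]],
               sigma2_pe = fit$varcomp[["pe"]],
               sigma2_e = fit$varcomp[["e"]],
               se_g = fit$se[["g"]], se_pe = fit$se[["pe"]],
               se_e = fit$se[["e"]],
               h2 = fit$h2, h2_se = fit$h2_se,
               repeatability = fit$repeatability, rep_se = fit$rep_se,
               logLik = fit$logLik, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("herit_scan", "data.frame"))
}

#' @export
print.herit_scan <- function(x, ...) {
  cat(sprintf("herit_scan: %d features; mean h2 %.3f, mean repeatability %.3f (%d converged)\n",
              nrow(x), mean(x$h2), mean(x$repeatability),
              sum(x$converged)))
  print.data.frame(head(as.data.frame(x)[, c("feature", "h2", "h2_se",
                                             "repeatability", "rep_se")]),
                   row.names = FALSE, digits = 3)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Correlation of estimates between two sample subsets
#'
#' Pearson correlations of per-feature heritability and repeatability
#' estimates between two scans of (usually disjoint) sample sets, the
#' consistency measure used to compare diets.
#'
#' @param a,b `herit_scan` objects sharing feature names.
#' @return named vector `h2_cor`, `rep_cor`, `n_features`.
#' @export
compare_scans <- function(a, b) {
  common <- intersect(a$feature, b$feature)
  if (length(common) < 3) stopf("fewer than 3 shared features")
  ia <- match(common, a$feature); ib <- match(common, b$feature)
  c(h2_cor = cor(a$h2[ia], b$h2[ib]),
    rep_cor = cor(a$repeatability[ia], b$repeatability[ib]),
    n_features = length(common))
}
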