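## Partitioning variance across systematic and biological fixed factors.

#' Percent variance explained by systematic and biological factors
#'
#' Fits `y = mu + Group + Cohort + Library + BatchShelf + Well + BRR + AOD
#' + BDEV + PE + e` (any subset of terms present in the design).  The
#' permanent-environment term is absorbed as a random effect whose variance
#' is estimated by REML first; fixed factors are then tested conditionally
#' on the whitened (generalised least squares) scale.  Each factor's
#' contribution is its marginal (drop-one) sum of squares as a percent of
#' the total sum of squares, with an F-test on residual degrees of freedom.
#' Cohort is nested in Group, so the cohort block is orthogonalised against
#' the group block before drop-one testing; a factor whose columns are
#' entirely aliased by the others is reported as inestimable rather than
#' silently dropped.
#'
#' @param y numeric response (one entry per sample), e.g. number of reads,
#'   assignment rate, or a taxon's log10 relative abundance.
#' @param design a `study_design` or sample data.frame; recognised term
#'   columns: `group`, `cohort`, `library`, `batch_shelf`, `well`, `brr`,
#'   `aod` (factors) and `bdev` (covariate), plus `animal_id` for the PE
#'   term.
#' @param terms character vector of terms to fit (default: all of the
#'   above that exist in the design).
#' @param pe_random include the permanent-environment random effect when
#'   animals have repeated records.
#' @param nest named character vector declaring nesting
#'   (default `c(cohort = "group")`).
#' @return object of class `fixed_partition`: data.frame with `term`,
#'   `df`, `ss`, `percent`, `f`, `p_value`, `status`, plus a Residual row;
#'   attribute `sigma2` holds the estimated PE/residual variances.
#' @export
fixed_partition <- function(y, design,
                            terms = c("group", "cohort", "library",
                                      "batch_shelf", "well", "brr", "aod",
                                      "bdev"),
                            pe_random = TRUE, nest = c(cohort = "group")) {
  s <- if (inherits(design, "study_design")) design$samples else design
  terms <- terms[terms %in% names(s)]
  if (!length(terms)) stopf("no model terms found in the design")
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(s) == n)

  numeric_terms <- c("bdev")
  blocks <- list()
  for (tm in terms) {
    v <- s[[tm]]
    if (tm %in% numeric_terms && is.numeric(v)) {
      blocks[[tm]] <- matrix(scale(v, scale = FALSE), ncol = 1)
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) stopf("term '%s' has a single level: inestimable", tm)
      blocks[[tm]] <- model.matrix(~f)[, -1, drop = FALSE]
    }
  }
  ## orthogonalise nested children against their parents (e.g. cohort
  ## dummies span group differences; remove the group component first)
  for (child in intersect(names(nest), names(blocks))) {
    parent <- nest[[child]]
    if (parent %in% names(blocks)) {
      Xp <- cbind(1, blocks[[parent]])
      blocks[[child]] <- blocks[[child]] -
        Xp %*% qr.coef(qr(Xp), blocks[[child]])
      blocks[[child]][is.na(blocks[[child]])] <- 0
    }
  }

  ## estimate PE and residual variances, then whiten
  sigma2 <- c(pe = 0, e = var(y))
  if (pe_random && "animal_id" %in% names(s) &&
      anyDuplicated(s$animal_id)) {
    Xfull <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
    qx <- qr(Xfull)
    Xfull <- Xfull[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    fit0 <- reml_fit(y, grm = NULL, animal = s$animal_id, X = Xfull)
    sigma2 <- c(pe = fit0$varcomp[["pe"]], e = fit0$varcomp[["e"]])
    Z <- model.matrix(~0 + factor(s$animal_id))
    V <- sigma2[["pe"]] * tcrossprod(Z) + diag(sigma2[["e"]], n)
    eg <- eigen(V, symmetric = TRUE)
    Wh <- eg$vectors %*% (t(eg$vectors) / sqrt(pmax(eg$values, 1e-12)))
    yt <- as.vector(Wh %*% y)
    blocks <- lapply(blocks, function(b) Wh %*% b)
    ones <- Wh %*% base::rep(1, n)
  } else {
    yt <- y
    ones <- matrix(1, n, 1)
  }

  Xall <- cbind(ones, do.call(cbind, blocks))
  qf <- qr(Xall)
  rank_full <- qf$rank
  rss_full <- sum(qr.resid(qf, yt)^2)
  df_res <- n - rank_full
  q0 <- qr(ones)
  ss_tot <- sum(qr.resid(q0, yt)^2)

  rows <- lapply(terms, function(tm) {
    Xm <- cbind(ones, do.call(cbind, blocks[setdiff(terms, tm)]))
    qm <- qr(Xm)
    dfj <- rank_full - qm$rank
    if (dfj == 0)
      return(data.frame(term = tm, df = 0L, ss = NA_real_,
                        percent = NA_real_, f = NA_real_,
                        p_value = NA_real_, status = "inestimable",
                        stringsAsFactors = FALSE))
    ssj <- sum(qr.resid(qm, yt)^2) - rss_full
    fj <- (ssj / dfj) / (rss_full / df_res)
    data.frame(term = tm, df = dfj, ss = ssj,
               percent = 100 * ssj / ss_tot, f = fj,
               p_value = pf(fj, dfj, df_res, lower.tail = FALSE),
               status = "ok", stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(term = "Residual", df = df_res,
                               ss = rss_full,
                               percent = 100 * rss_full / ss_tot,
                               f = NA, p_value = NA, status = "ok"))
  structure(tab, class = c("fixed_partition", "data.frame"),
            sigma2 = sigma2)
}

#' @export
print.fixed_partition <- function(x, ...) {
  cat("Percent variance explained by fixed factors (drop-one SS)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
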