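## Average-information REML for the repeated-records animal model
##   y = X b + Z a + Z pe + e,   a ~ N(0, G sg2),  pe ~ N(0, I spe2),
##   e ~ N(0, I se2),
## where Z maps records to animals.  All linear algebra is done in the
## eigenbasis of G so each iteration costs O(q^2) for q animals: with
## G = U L U' and T = Z U, V = T D T' + se2 I with D diagonal, and the
## Woodbury identity reduces solves with V to a q x q system.

## Moore-Penrose solve for (possibly singular) AI systems.
pinv_step <- function(A, b, rtol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > rtol * max(sv$d)
  if (!any(pos)) return(NULL)
  as.vector(sv$v[, pos, drop = FALSE] %*%
              ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos]))
}

## One-off preparation shared across features fitted on the same design.
reml_prepare <- function(grm, animal, X = NULL, ridge = 1e-6) {
  animal <- as.character(animal)
  n <- length(animal)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(grm)) {
    ids <- unique(animal)
    q <- length(ids)
    U <- diag(q)
    lam <- base::rep(0, q)
  } else {
    ids <- rownames(grm)
    if (is.null(ids)) stopf("grm must have rownames (animal ids)")
    if (!all(animal %in% ids)) stopf("records reference animals absent from the GRM")
    use <- ids %in% animal
    Gm <- unclass(grm)[use, use, drop = FALSE]
    ids <- ids[use]
    q <- length(ids)
    eg <- eigen(Gm + diag(ridge, q), symmetric = TRUE)
    U <- eg$vectors
    lam <- pmax(eg$values, 0)
  }
  ai <- match(animal, ids)
  Tm <- U[ai, , drop = FALSE]                 # Z %*% U
  r <- tabulate(ai, nbins = q)                # records per animal
  Rq <- crossprod(U * sqrt(r))                # U' diag(r) U = T'T
  list(n = n, q = q, X = X, U = U, lam = lam, Tm = Tm, Rq = Rq, ai = ai,
       ids = ids)
}

## Evaluate the REML log-likelihood and all quadratics/traces at vc.
## vc = c(g, pe, e); when include_g is FALSE the g component is absent.
reml_state <- function(vc, y, prep, include_g) {
  n <- prep$n; q <- prep$q
  lam <- if (include_g) prep$lam else base::rep(0, q)
  sg <- if (include_g) vc[["g"]] else 0
  sp <- vc[["pe"]]; se <- vc[["e"]]
  d <- sg * lam + sp
  sq <- sqrt(d)
  Mq <- diag(se, q) + outer(sq, sq) * prep$Rq     # se I + D^1/2 Rq D^1/2
  ch <- chol(Mq)
  Wi <- chol2inv(ch)
  W <- outer(sq, sq) * Wi                         # (se D^-1 + Rq)^-1
  logdetV <- (n - q) * log(se) + 2 * sum(log(diag(ch)))

  vinv <- function(x) (x - prep$Tm %*% (W %*% crossprod(prep$Tm, x))) / se
  Xv <- vinv(prep$X)
  XtVX <- crossprod(prep$X, Xv)
  Cx <- solve(XtVX)
  Pfun <- function(x) vinv(x) - Xv %*% (Cx %*% crossprod(Xv, x))
  Py <- Pfun(y)
  beta <- Cx %*% crossprod(Xv, y)

  w <- as.vector(crossprod(prep$Tm, Py))
  quad <- c(g = sum(lam * w^2), pe = sum(w^2), e = sum(Py^2))

  Mt <- (prep$Rq - prep$Rq %*% W %*% prep$Rq) / se   # T' V^-1 T
  S <- crossprod(prep$Tm, Xv)                        # q x p
  trv <- c(g = sum(diag(Mt) * lam), pe = sum(diag(Mt)),
           e = (n - sum(W * prep$Rq)) / se)
  Ag <- crossprod(S, lam * S)
  Ape <- crossprod(S)
  Ae <- crossprod(Xv)
  trP <- c(g = trv[["g"]] - sum(Cx * t(Ag)),
           pe = trv[["pe"]] - sum(Cx * t(Ape)),
           e = trv[["e"]] - sum(Cx * t(Ae)))

  comp <- if (include_g) c("g", "pe", "e") else c("pe", "e")
  fvec <- list(g = prep$Tm %*% (lam * w), pe = prep$Tm %*% w, e = Py)
  Pf <- lapply(fvec[comp], Pfun)
  k <- length(comp)
  AI <- matrix(0, k, k, dimnames = list(comp, comp))
  for (i in seq_len(k)) for (j in i:k)
    AI[i, j] <- AI[j, i] <- 0.5 * sum(fvec[[comp[i]]] * Pf[[comp[j]]])

  yPy <- sum(y * Py)
  logL <- -0.5 * (logdetV + determinant(XtVX, logarithm = TRUE)$modulus +
                  yPy)
  grad <- -0.5 * (trP[comp] - quad[comp])
  list(logL = as.numeric(logL), grad = grad, AI = AI, quad = quad,
       trP = trP, Py = Py, w = w, beta = beta, Cx = Cx, comp = comp)
}

#' Fit the animal + permanent-environment variance-component model by REML
#'
#' Maximises the restricted likelihood of
#' `y = mu + Animal + PE + e`, with the animal genetic effect distributed
#' `N(0, G sigma2_g)` for a genomic relationship matrix `G`, the permanent
#' environmental effect `N(0, I sigma2_pe)` shared by all records of an
#' animal, and residuals `N(0, I sigma2_e)`.  Updates use average
#' information with step-halving onto an EM fallback (EM steps never
#' decrease the restricted likelihood); variance components are clamped at
#' a small positive bound.  Standard errors come from the inverse
#' average-information matrix, with delta-method propagation to the derived
#' heritability `sigma2_g / sigma2_T` and repeatability
#' `(sigma2_g + sigma2_pe) / sigma2_T`.
#'
#' @param y numeric response, one entry per record (finite, non-constant).
#' @param grm genomic relationship matrix with animal ids as rownames, or
#'   `NULL` to drop the genetic component (PE + residual only).
#' @param animal character/factor of length `length(y)` mapping records to
#'   animals (every animal must appear in the GRM).
#' @param X fixed-effect design matrix (default: intercept only).
#' @param max_iter,tol iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param ridge diagonal stabiliser added to `G` before eigendecomposition.
#' @param prep precomputed [reml_prepare()] structure (used internally when
#'   fitting many features on one design).
#' @return object of class `reml_fit`; see [summary.reml_fit()].  Fields
#'   include `varcomp`, `se`, `h2`, `repeatability` (with SEs), `beta`,
#'   `logLik`, `converged`, `iterations`, `blup` (genetic and PE values per
#'   animal).
#' @export
reml_fit <- function(y, grm = NULL, animal, X = NULL, max_iter = 100,
                     tol = 1e-8, ridge = 1e-6, prep = NULL) {
  if (!is.null(prep)) {
    include_g <- !all(prep$lam == 0)
  } else {
    prep <- reml_prepare(grm, animal, X, ridge)
    include_g <- !is.null(grm)
  }
  y <- as.numeric(y)
  stopifnot(length(y) == prep$n)
  if (!all(is.finite(y))) stopf("y must be finite")
  vy <- var(y)
  if (vy == 0) stopf("y is constant")
  lb <- 1e-8 * vy

  comp <- if (include_g) c("g", "pe", "e") else c("pe", "e")
  nlev <- c(g = prep$q, pe = prep$q, e = prep$n)[comp]
  vc <- setNames(base::rep(vy / length(comp), length(comp)), comp)
  if (!include_g) vc <- c(vc)
  st <- reml_state(vc, y, prep, include_g)
  converged <- FALSE
  it <- 0
  trace <- st$logL
  while (it < max_iter) {
    it <- it + 1
    ## average-information proposal; if AI is singular (confounded
    ## components, e.g. G = I makes g and pe indistinguishable) take the
    ## Moore-Penrose step, i.e. Newton in the estimable subspace
    cand <- NULL
    deltas <- list(tryCatch(solve(st$AI, st$grad), error = function(e) NULL),
                   pinv_step(st$AI, st$grad))
    for (delta in deltas) {
      if (is.null(delta) || !all(is.finite(delta))) next
      prop <- pmax(vc + delta, lb)
      stp <- tryCatch(reml_state(prop, y, prep, include_g),
                      error = function(e) NULL)
      if (!is.null(stp) && stp$logL >= st$logL) {
        cand <- list(vc = prop, st = stp)
        break
      }
    }
    if (is.null(cand)) {
      ## EM fallback: theta + theta^2/m (y'PKPy - tr(PK)); never decreases
      prop <- vc + vc^2 / nlev * (st$quad[comp] - st$trP[comp])
      prop <- pmax(prop, lb)
      stp <- reml_state(prop, y, prep, include_g)
      if (stp$logL < st$logL - 1e-6) break   # numerical floor reached
      cand <- list(vc = prop, st = stp)
    }
    dl <- cand$st$logL - st$logL
    vc <- cand$vc
    st <- cand$st
    trace <- c(trace, st$logL)
    if (abs(dl) / (abs(st$logL) + 1) < tol) {
      converged <- TRUE
      break
    }
  }

  vcfull <- c(g = 0, pe = 0, e = 0)
  vcfull[comp] <- vc
  se <- setNames(base::rep(NA_real_, 3), c("g", "pe", "e"))
  Vc <- tryCatch(solve(st$AI), error = function(e) NULL)
  if (!is.null(Vc)) se[comp] <- sqrt(pmax(diag(Vc), 0))

  tot <- sum(vcfull)
  h2 <- vcfull[["g"]] / tot
  rp <- (vcfull[["g"]] + vcfull[["pe"]]) / tot
  h2_se <- rep_se <- NA_real_
  if (!is.null(Vc) && include_g) {
    gh <- c((tot - vcfull[["g"]]), -vcfull[["g"]], -vcfull[["g"]]) / tot^2
    grp <- c(tot - (vcfull[["g"]] + vcfull[["pe"]]),
             tot - (vcfull[["g"]] + vcfull[["pe"]]),
             -(vcfull[["g"]] + vcfull[["pe"]])) / tot^2
    h2_se <- sqrt(max(0, gh %*% Vc %*% gh))
    rep_se <- sqrt(max(0, grp %*% Vc %*% grp))
  }

  ## BLUPs of genetic and permanent-environment values per animal
  lam <- if (include_g) prep$lam else base::rep(0, prep$q)
  ghat <- as.vector(vcfull[["g"]] * (prep$U %*% (lam * st$w)))
  pehat <- as.vector(vcfull[["pe"]] * (prep$U %*% st$w))
  names(ghat) <- names(pehat) <- prep$ids

  structure(list(
    varcomp = vcfull, se = se, h2 = h2, repeatability = rp,
    h2_se = h2_se, rep_se = rep_se,
    beta = setNames(as.vector(st$beta), colnames(prep$X)),
    beta_vcov = st$Cx, AI = st$AI,
    logLik = st$logL, trace = trace, converged = converged,
    iterations = it, n = prep$n, q = prep$q, include_g = include_g,
    blup = data.frame(animal = prep$ids, g = ghat, pe = pehat,
                      row.names = NULL),
    fitted = as.vector(prep$X %*% st$beta) + ghat[prep$ai] + pehat[prep$ai],
    y = y, call = match.call()),
    class = "reml_fit")
}

#' Heritability and repeatability from a converged fit
#'
#' `h2 = sigma2_g / sigma2_T` and
#' `repeatability = (sigma2_g + sigma2_pe) / sigma2_T` with
#' `sigma2_T = sigma2_g + sigma2_pe + sigma2_e`; standard errors by
#' first-order delta-method propagation from the component covariance.
#'
#' @param fit a [reml_fit()] object.
#' @return named list `h2`, `repeatability`, `h2_se`, `rep_se`.
#' @export
h2_repeatability <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (sum(fit$varcomp) == 0) stopf("total variance is zero")
  list(h2 = fit$h2, repeatability = fit$repeatability,
       h2_se = fit$h2_se, rep_se = fit$rep_se)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML animal model (", if (x$include_g) "G + PE + e" else "PE + e",
      "), ", x$n, " records / ", x$q, " animals\n", sep = "")
  cat(sprintf("  sigma2_g = %.4f  sigma2_pe = %.4f  sigma2_e = %.4f\n",
              x$varcomp[["g"]], x$varcomp[["pe"]], x$varcomp[["e"]]))
  cat(sprintf("  h2 = %.3f (SE %.3f)   repeatability = %.3f (SE %.3f)\n",
              x$h2, x$h2_se, x$repeatability, x$rep_se))
  cat(sprintf("  logLik = %.3f after %d iterations (%s)\n", x$logLik,
              x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Summary of a REML fit
#' @param object a `reml_fit`.
#' @param ... unused.
#' @return a `summary.reml_fit` with a component table and the ratios.
#' @export
summary.reml_fit <- function(object, ...) {
  tab <- data.frame(component = c("genetic", "permanent_env", "residual"),
                    variance = unname(object$varcomp),
                    se = unname(object$se))
  structure(list(table = tab, h2 = object$h2, h2_se = object$h2_se,
                 repeatability = object$repeatability,
                 rep_se = object$rep_se, beta = object$beta,
                 converged = object$converged, n = object$n, q = object$q),
            class = "summary.reml_fit")
}

#' @export
print.summary.reml_fit <- function(x, ...) {
  cat(sprintf("Variance components (%d records, %d animals):\n", x$n, x$q))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("h2 = %.3f (SE %.3f); repeatability = %.3f (SE %.3f)\n",
              x$h2, x$h2_se, x$repeatability, x$rep_se))
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) object$beta

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$beta) +
              sum(object$varcomp > 0), class = "logLik")
}

#' @export
fitted.reml_fit <- function(object, ...) object$fitted

#' @export
residuals.reml_fit <- function(object, ...) object$y - object$fitted

#' Predicted genetic values (BLUPs)
#' @param object a `reml_fit`.
#' @param ... unused.
#' @return data.frame `animal`, `g` (genetic value), `pe`.
#' @export
predict.reml_fit <- function(object, ...) object$blup

#' @export
vcov.reml_fit <- function(object, ...) {
  tryCatch(solve(object$AI), error = function(e)
    matrix(NA_real_, nrow(object$AI), ncol(object$AI),
           dimnames = dimnames(object$AI)))
}
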