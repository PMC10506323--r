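test_that("VanRaden GRM reproduces the hand example and clone symmetry", {
  ## 2 animals, p = (0.5, 0.5), genotypes (0,2) and (2,0)
  M <- rbind(a1 = c(0, 2), a2 = c(2, 0))
  G <- grm_vanraden(M, freq = c(0.5, 0.5))
  expect_equal(unclass(G), rbind(a1 = c(2, -2), a2 = c(-2, 2)),
               ignore_attr = TRUE)

  ## duplicated animal rows: clones have off-diagonal equal to diagonal
  set.seed(8)
  geno <- simulate_genotypes(20, 100, 4, seed = 8)
  M2 <- rbind(geno, clone = geno[1, ])
  G2 <- grm_vanraden(M2)
  expect_equal(G2[1, 1], G2[nrow(G2), nrow(G2)])
  expect_equal(G2[1, nrow(G2)], G2[1, 1])

  expect_error(grm_vanraden(rbind(c(0, 0), c(0, 2))))   # monomorphic
  expect_error(grm_vanraden(rbind(c(0, 3), c(1, 1))))   # bad coding
})

test_that("GRM mean diagonal is ~1 under HWE and invariant to relabelling", {
  set.seed(12)
  n <- 500; m <- 2000
  p <- runif(m, 0.1, 0.9)
  M <- matrix(rbinom(n * m, 2, base::rep(p, each = n)), n, m)
  keep <- colMeans(M) / 2 > 0 & colMeans(M) / 2 < 1
  M <- M[, keep, drop = FALSE]
  G <- grm_vanraden(M)
  expect_lt(abs(mean(diag(G)) - 1), 0.02)

  ## invariance to marker order and allele-label swap (0<->2, p<->1-p)
  perm <- sample(ncol(M))
  expect_equal(unclass(grm_vanraden(M[, perm])), unclass(G),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(grm_vanraden(2 - M)), unclass(G),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("REML on a balanced identity-GRM design matches one-way ANOVA closed forms", {
  set.seed(31)
  q <- 150; r <- 2
  ids <- sprintf("A%03d", seq_len(q))
  animal <- base::rep(ids, each = r)
  y <- 2 + base::rep(rnorm(q, 0, sqrt(0.4)), each = r) +
    rnorm(q * r, 0, sqrt(0.6))
  G <- diag(q); dimnames(G) <- list(ids, ids)
  fit <- reml_fit(y, G, animal, ridge = 0, tol = 1e-10)
  vc <- anova_oneway_vc(y, animal)
  expect_true(fit$converged)
  ## G = I confounds g and pe; their sum is the between-animal component
  expect_equal(fit$varcomp[["g"]] + fit$varcomp[["pe"]],
               unname(vc["between"]), tolerance = 1e-6)
  expect_equal(fit$varcomp[["e"]], unname(vc["within"]), tolerance = 1e-6)
  ## the REML log-likelihood trace never decreases
  expect_true(all(diff(fit$trace) >= -1e-8))
})

test_that("REML recovers planted variance components with a family GRM", {
  geno <- simulate_genotypes(400, 1500, 20, seed = 41)
  G <- grm_vanraden(geno)
  ids <- rownames(geno)
  animal <- base::rep(ids, each = 2)
  ai <- base::rep(seq_along(ids), each = 2)
  L <- t(chol(unclass(G) + diag(1e-6, length(ids))))
  hits <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    g <- as.vector(L %*% rnorm(length(ids))) * sqrt(0.3)
    pe <- rnorm(length(ids), 0, sqrt(0.2))
    y <- g[ai] + pe[ai] + rnorm(length(ai), 0, sqrt(0.5))
    fit <- reml_fit(y, G, animal)
    expect_true(fit$converged)
    expect_lte(fit$h2, fit$repeatability)
    ok <- abs(fit$varcomp[["g"]] - 0.3) <= 2 * fit$se[["g"]] + 1e-9 &&
      abs(fit$varcomp[["e"]] - 0.5) <= 2 * fit$se[["e"]] + 1e-9
    hits <- hits + ok
  }
  expect_gte(hits, 4)  # truth inside +/- 2 SE for most replicates
})

test_that("null traits give near-zero heritability at the boundary", {
  geno <- simulate_genotypes(300, 1000, 15, seed = 51)
  G <- grm_vanraden(geno)
  animal <- base::rep(rownames(geno), each = 2)
  h2s <- vapply(1:5, function(s) {
    set.seed(200 + s)
    reml_fit(rnorm(600), G, animal)$h2
  }, numeric(1))
  expect_lt(mean(h2s), 0.05)
})

test_that("variance ratios and their arithmetic follow the definitions", {
  fake <- structure(list(varcomp = c(g = 0.2, pe = 0.1, e = 0.7),
                         h2 = 0.2, repeatability = 0.3,
                         h2_se = 0.01, rep_se = 0.01), class = "reml_fit")
  r <- h2_repeatability(fake)
  expect_equal(r$h2, 0.2)
  expect_equal(r$repeatability, 0.3)
  ## sigma_pe = 0: h2 equals repeatability
  fake$varcomp <- c(g = 0.3, pe = 0, e = 0.7)
  fake$h2 <- 0.3; fake$repeatability <- 0.3
  r <- h2_repeatability(fake)
  expect_equal(r$h2, r$repeatability)
  ## sigma_g = 0: h2 = 0, repeatability = pe / total
  fake$varcomp <- c(g = 0, pe = 0.25, e = 0.75)
  fake$h2 <- 0; fake$repeatability <- 0.25
  r <- h2_repeatability(fake)
  expect_equal(r$h2, 0)
  expect_equal(r$repeatability, 0.25)
  fake$varcomp <- c(g = 0, pe = 0, e = 0)
  expect_error(h2_repeatability(fake))
})

test_that("reml_fit methods expose the classic modelling surface", {
  set.seed(61)
  geno <- simulate_genotypes(80, 400, 8, seed = 61)
  G <- grm_vanraden(geno)
  animal <- base::rep(rownames(geno), each = 2)
  y <- rnorm(160) + base::rep(rnorm(80, 0, 0.5), each = 2)
  fit <- reml_fit(y, G, animal)
  expect_output(print(fit), "REML animal model")
  expect_output(print(summary(fit)), "Variance components")
  expect_named(coef(fit), "(Intercept)")
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(length(fitted(fit)), 160)
  expect_equal(residuals(fit), y - fitted(fit))
  blup <- predict(fit)
  expect_equal(nrow(blup), 80)
  expect_true(all(c("animal", "g", "pe") %in% names(blup)))
  expect_error(reml_fit(base::rep(1, 160), G, animal))
})

test_that("per-feature scans share the design and correlate across subsets", {
  geno <- simulate_genotypes(240, 1200, 16, seed = 71)
  G <- grm_vanraden(geno)
  des <- simulate_design(animal_ids = rownames(geno),
                         groups = default_groups()[c(1, 5), ],
                         cohorts_per_group = 3, samples_per_cohort = 80,
                         seed = 71)
  tr <- simulate_abundances(des, grm = G, n_taxa = 30,
                            h2 = runif(30, 0.05, 0.45),
                            rep = runif(30, 0.5, 0.7), cohort_var = 1,
                            seed = 72)
  lp <- structure(tr$latent, provenance = "log10",
                  class = c("profile_matrix", "matrix", "array"))
  adj <- cohort_adjust(lp, des$samples$cohort)

  ## single feature reduces to reml_fit
  one <- fit_feature_table(adj[, 1, drop = FALSE], G, des)
  expect_equal(nrow(one), 1)
  direct <- reml_fit(unclass(adj)[, 1], G,
                     des$samples$animal_id)
  expect_equal(one$h2, direct$h2, tolerance = 1e-6)

  ## two disjoint sample subsets share the architecture: estimates correlate
  g1 <- des$samples$group == des$samples$group[1]
  scan_a <- fit_feature_table(adj[g1, , drop = FALSE], G, des)
  scan_b <- fit_feature_table(adj[!g1, , drop = FALSE], G, des)
  cc <- compare_scans(scan_a, scan_b)
  expect_gt(cc[["h2_cor"]], 0.3)
  expect_equal(cc[["n_features"]], 30)

  ## non-cohort-adjusted input refused
  expect_error(fit_feature_table(lp, G, des), "cohortadj")
})

test_that("fixed-factor partition attributes variance where it was planted", {
  des <- simulate_design(n_animals = 50, groups = default_groups()[1:4, ],
                         cohorts_per_group = 2, samples_per_cohort = 10,
                         seed = 81)
  s <- des$samples
  ## pure group means + tiny noise: group share ~100%
  gm <- c(GLS = 0, GAS = 3, GLL = 6, GAL = 9)
  set.seed(82)
  y <- gm[s$group] + rnorm(nrow(s), 0, 0.01)
  fp <- fixed_partition(y, des, terms = c("group", "cohort", "brr", "aod"))
  expect_gt(fp$percent[fp$term == "group"], 90)
  expect_lt(sum(fp$percent[fp$term %in% c("brr", "aod")], na.rm = TRUE), 2)
  expect_lt(fp$p_value[fp$term == "group"], 1e-10)

  ## independent y: p-values not systematically small, shares near df-share
  set.seed(83)
  ps <- replicate(30, {
    y0 <- rnorm(nrow(s))
    fp0 <- fixed_partition(y0, des, terms = c("group", "brr", "aod"),
                           pe_random = FALSE)
    fp0$p_value[fp0$term == "brr"]
  })
  expect_gt(mean(ps < 0.05), 0)   # not degenerate
  expect_lt(mean(ps < 0.05), 0.2) # roughly alpha-level rejection

  ## single-level factor is inestimable
  s2 <- s; s2$brr <- 1
  expect_error(fixed_partition(y, s2, terms = c("group", "brr")),
               "single level")
})
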