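## Synthetic study designs and ground-truth community abundances.

#' Default group table for a two-country grazing study
#'
#' Eight strata defined by diet, age, time off feed and country, mirroring
#' the sampling structure of large multi-flock rumen studies (grass vs pellet
#' diets, lambs vs adults, short vs long time off feed, plus one group
#' sampled in a second country).
#'
#' @return data.frame with columns `group`, `diet`, `age`, `time_off_feed`,
#'   `country`.
#' @export
default_groups <- function() {
  data.frame(
    group = c("GLS", "GAS", "GLL", "GAL", "LLS", "LLL", "MAS", "AUS"),
    diet = c("Grass", "Grass", "Grass", "Grass", "LucernePellet",
             "LucernePellet", "MaintenancePellet", "ChaffedHay"),
    age = c("Lamb", "Adult", "Lamb", "Adult", "Lamb", "Lamb", "Adult",
            "Adult"),
    time_off_feed = c("Short", "Short", "Long", "Long", "Short", "Long",
                      "Short", "Short"),
    country = c("NZ", "NZ", "NZ", "NZ", "NZ", "NZ", "NZ", "AUS"),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-group, multi-cohort sampling design
#'
#' Builds a sample table with the factors used throughout the pipeline:
#' Group (diet/age/time-off-feed/country stratum), Cohort (a flock sampled
#' over one window; every cohort belongs to exactly one group), Library,
#' BatchShelf, Well, plus per-animal birth covariates (BRR, AOD, BDEV) and a
#' methane selection line.  Animals from the home country are sampled
#' repeatedly across groups (repeated records per animal); animals from the
#' second country are sampled once.  Each sample receives a barcode, unique
#' within its sequencing library (fixed-length barcodes, hence prefix-free).
#'
#' @param n_animals number of home-country (NZ) animals available.
#' @param groups group table as from [default_groups()]; subset rows for
#'   smaller designs.
#' @param cohorts_per_group,samples_per_cohort cohort structure per group.
#' @param library_size samples per sequencing library.
#' @param barcode_len barcode length in bp.
#' @param line_prob probabilities of the `low`/`high`/`other` methane
#'   selection lines for home-country animals.
#' @param n_batch_shelf number of freeze-drying batch-shelf levels.
#' @param animal_ids optional explicit home-country animal ids (e.g. the
#'   rownames of a genotype matrix); overrides `n_animals`.
#' @param seed integer seed.
#' @return object of class `study_design`: list with `samples` (one row per
#'   sample), `animals`, and `groups`.
#' @export
simulate_design <- function(n_animals = 80, groups = default_groups(),
                            cohorts_per_group = 2, samples_per_cohort = 10,
                            library_size = 48, barcode_len = 6,
                            line_prob = c(0.25, 0.25, 0.5),
                            n_batch_shelf = 4, animal_ids = NULL, seed = 1) {
  if (!is.null(animal_ids)) n_animals <- length(animal_ids)
  if (!is_count(n_animals) || n_animals < samples_per_cohort)
    stopf("n_animals must be at least samples_per_cohort")
  set.seed(seed)

  nz <- if (is.null(animal_ids)) sprintf("N%04d", seq_len(n_animals))
        else as.character(animal_ids)
  aus_groups <- groups$group[groups$country != "NZ"]
  n_aus <- length(aus_groups) * cohorts_per_group * samples_per_cohort
  aus <- if (n_aus) sprintf("U%04d", seq_len(n_aus)) else character(0)

  animals <- data.frame(
    animal_id = c(nz, aus),
    country = c(rep("NZ", length(nz)), rep("AUS", length(aus))),
    line = c(sample(c("low", "high", "other"), length(nz), TRUE, line_prob),
             rep("other", length(aus))),
    brr = sample(1:3, length(nz) + n_aus, TRUE),
    aod = sample(1:3, length(nz) + n_aus, TRUE),
    bdev = round(rnorm(length(nz) + n_aus, 0, 5), 2),
    stringsAsFactors = FALSE)

  rows <- list()
  aus_next <- 1L
  for (gi in seq_len(nrow(groups))) {
    g <- groups$group[gi]
    for (ci in seq_len(cohorts_per_group)) {
      if (groups$country[gi] == "NZ") {
        ids <- sample(nz, samples_per_cohort)
      } else {
        ids <- aus[aus_next:(aus_next + samples_per_cohort - 1L)]
        aus_next <- aus_next + samples_per_cohort
      }
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = ids, group = g,
        cohort = sprintf("%s_C%d", g, ci), stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)
  samples$sample_id <- sprintf("S%04d", seq_len(nrow(samples)))
  n <- nrow(samples)

  samples$library <- sprintf("L%02d", (seq_len(n) - 1L) %/% library_size + 1L)
  samples$well <- (seq_len(n) - 1L) %% library_size + 1L
  samples$batch_shelf <- sprintf("B%02d", sample(n_batch_shelf, n, TRUE))
  i <- match(samples$animal_id, animals$animal_id)
  samples$brr <- animals$brr[i]
  samples$aod <- animals$aod[i]
  samples$bdev <- animals$bdev[i]
  samples$line <- animals$line[i]

  ## fixed-length barcodes, unique within each library
  for (lib in unique(samples$library)) {
    sel <- samples$library == lib
    bc <- character(0)
    while (length(bc) < sum(sel)) {
      bc <- unique(c(bc, random_dna(barcode_len)))
    }
    samples$barcode[sel] <- bc[seq_len(sum(sel))]
  }
  samples <- samples[, c("sample_id", "animal_id", "group", "cohort",
                         "library", "batch_shelf", "well", "brr", "aod",
                         "bdev", "line", "barcode")]
  structure(list(samples = samples, animals = animals, groups = groups),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d samples, %d animals, %d groups, %d cohorts\n",
              nrow(x$samples), length(unique(x$samples$animal_id)),
              length(unique(x$samples$group)),
              length(unique(x$samples$cohort))))
  invisible(x)
}

#' Simulate latent log-abundances with a known genetic architecture
#'
#' For each taxon the latent (log-scale) value of a sample is
#' `mu + group + cohort + g + pe + e`, where `g` is an additive genetic value
#' shared by all samples of an animal and drawn with covariance proportional
#' to the genomic relationship matrix, `pe` a permanent-environment value
#' also shared within animal, and `e` a per-sample residual.  The non-cohort,
#' non-group variance is scaled to 1 with `Var(g) = h2` and
#' `Var(g + pe) = rep`, so the generative heritability and repeatability of
#' each taxon are known exactly.
#'
#' @param design a [simulate_design()] object.
#' @param grm genomic relationship matrix with dimnames covering the design's
#'   animals, or `NULL` for unrelated animals (identity).
#' @param n_taxa number of taxa.
#' @param h2,rep per-taxon heritability and repeatability (recycled);
#'   requires `0 <= h2 <= rep <= 1`.
#' @param cohort_var variance of cohort effects (shared environment).
#' @param group_var variance of group (diet) effects.
#' @param line_var variance of a two-line (e.g. methane selection line)
#'   contrast: each taxon receives an effect of magnitude `sqrt(line_var)`
#'   with random sign, added for `high`-line animals and subtracted for
#'   `low`-line animals (animals in `other` lines are unaffected).
#' @param mu grand mean.
#' @param seed integer seed.
#' @return object of class `abundance_truth`: list with `latent` (samples x
#'   taxa), `g`, `pe` (animals x taxa), `group_effects`, `cohort_effects`,
#'   and `params`.
#' @export
simulate_abundances <- function(design, grm = NULL, n_taxa = 20,
                                h2 = 0.2, rep = 0.35, cohort_var = 0,
                                group_var = 0, line_var = 0, mu = 0,
                                seed = 1) {
  stopifnot(inherits(design, "study_design"))
  h2 <- rep_len(h2, n_taxa)
  rp <- rep_len(rep, n_taxa)
  if (any(h2 < 0 | rp > 1 | h2 > rp))
    stopf("per-taxon parameters must satisfy 0 <= h2 <= rep <= 1")
  set.seed(seed)

  s <- design$samples
  animals <- unique(s$animal_id)
  q <- length(animals)
  if (is.null(grm)) {
    L <- diag(q)
  } else {
    if (!all(animals %in% rownames(grm)))
      stopf("grm is missing some animals in the design")
    L <- t(chol(grm[animals, animals] + diag(1e-6, q)))
  }
  groups <- unique(s$group)
  cohorts <- unique(s$cohort)
  ai <- match(s$animal_id, animals)

  latent <- matrix(0, nrow(s), n_taxa,
                   dimnames = list(s$sample_id, sprintf("taxon%02d", seq_len(n_taxa))))
  g_mat <- matrix(0, q, n_taxa, dimnames = list(animals, colnames(latent)))
  pe_mat <- g_mat
  ge <- matrix(rnorm(length(groups) * n_taxa), length(groups), n_taxa,
               dimnames = list(groups, colnames(latent)))
  ge <- sweep(ge, 2, sqrt(rep_len(group_var, n_taxa)), "*")
  ce <- matrix(rnorm(length(cohorts) * n_taxa), length(cohorts), n_taxa,
               dimnames = list(cohorts, colnames(latent)))
  ce <- sweep(ce, 2, sqrt(rep_len(cohort_var, n_taxa)), "*")
  le <- sqrt(rep_len(line_var, n_taxa)) * sample(c(-1, 1), n_taxa, TRUE)
  lsign <- ifelse(s$line == "high", 1, ifelse(s$line == "low", -1, 0))

  for (t in seq_len(n_taxa)) {
    g <- as.vector(L %*% rnorm(q)) * sqrt(h2[t])
    pe <- rnorm(q) * sqrt(rp[t] - h2[t])
    e <- rnorm(nrow(s)) * sqrt(1 - rp[t])
    g_mat[, t] <- g
    pe_mat[, t] <- pe
    latent[, t] <- mu + ge[s$group, t] + ce[s$cohort, t] +
      lsign * le[t] + g[ai] + pe[ai] + e
  }
  structure(list(latent = latent, g = g_mat, pe = pe_mat,
                 group_effects = ge, cohort_effects = ce,
                 line_effects = le,
                 params = data.frame(taxon = colnames(latent), h2 = h2,
                                     rep = rp,
                                     cohort_var = rep_len(cohort_var, n_taxa),
                                     group_var = rep_len(group_var, n_taxa))),
            class = "abundance_truth")
}

#' Write a study design (with barcodes) as TSV
#' @param design a `study_design`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_design <- function(design, path) {
  write.table(design$samples, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
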