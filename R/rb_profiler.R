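## Reference-based profiling: seeded local alignment + LCA assignment.

#' Filter a reference database to genomes with known genus
#'
#' Genomes whose taxonomy is not resolved to the genus level are removed so
#' that every retained genome can contribute to genus-level assignment.
#'
#' @param refdb a `reference_db`.
#' @return the filtered `reference_db`, with attribute `n_removed`.
#' @export
filter_reference <- function(refdb) {
  stopifnot(inherits(refdb, "reference_db"))
  keep <- !is.na(refdb$taxonomy$genus)
  if (!any(keep)) stopf("no genomes with genus-level taxonomy remain")
  out <- structure(list(taxonomy = refdb$taxonomy[keep, , drop = FALSE],
                        sequences = refdb$sequences[keep]),
                   class = "reference_db")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Build an exact word-seed index over a reference
#'
#' Enumerates every `word_size`-mer of every genome into a hash (words
#' containing ambiguous bases never seed).  The index is the seeding stage
#' of the read search: a read can only hit a genome with which it shares an
#' exact word.
#'
#' @param refdb a `reference_db` (normally after [filter_reference()]).
#' @param word_size seed word length (default 16).
#' @return object of class `search_index`.
#' @export
build_search_index <- function(refdb, word_size = 16) {
  stopifnot(inherits(refdb, "reference_db"))
  ids <- refdb$taxonomy$genome_id
  gidx <- integer(0); pos <- integer(0); words <- character(0)
  for (i in seq_along(ids)) {
    s <- refdb$sequences[[ids[i]]]
    L <- nchar(s)
    if (L < word_size) next
    st <- seq_len(L - word_size + 1L)
    w <- substring(s, st, st + word_size - 1L)
    ok <- !grepl("[^ACGT]", w)
    words <- c(words, w[ok]); gidx <- c(gidx, base::rep(i, sum(ok)))
    pos <- c(pos, st[ok])
  }
  ## each entry encodes (genome index, position) in one double
  env <- list2env(split(gidx * 1e9 + pos, words), hash = TRUE,
                  parent = emptyenv())
  structure(list(map = env, word_size = word_size,
                 genome_ids = ids, sequences = refdb$sequences[ids],
                 db_length = sum(nchar(refdb$sequences[ids]))),
            class = "search_index")
}

#' Karlin-Altschul lambda for an ungapped scoring scheme
#'
#' Solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` for uniform base
#' composition under a match/mismatch scheme.
#'
#' @param match,mismatch match score and mismatch penalty.
#' @return the positive root `lambda`.
#' @export
karlin_lambda <- function(match = 1, mismatch = -2) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  uniroot(f, c(1e-8, 10))$root
}

#' Default read-search parameters
#'
#' BLASTN-style defaults: word size 16, e-value cutoff 0.01, match +1,
#' mismatch -2, gap open -5, gap extend -2, with lambda computed for the
#' scheme and `K` a configurable constant.
#'
#' @param ... overrides of any parameter.
#' @return named list of search parameters.
#' @export
search_params <- function(...) {
  p <- list(word_size = 16, evalue_max = 0.01, match = 1, mismatch = -2,
            gap_open = -5, gap_extend = -2, K = 0.333, lambda = NULL)
  dots <- list(...)
  p[names(dots)] <- dots
  if (is.null(p$lambda)) p$lambda <- karlin_lambda(p$match, p$mismatch)
  p
}

#' Search one read against the index
#'
#' Seed-and-extend local alignment: exact word seeds locate candidate
#' regions; each region is scored by Smith-Waterman with affine gaps.  One
#' hit (the best region) is reported per genome; ties across genomes are
#' preserved.  Bitscore is `(lambda * raw - ln K) / ln 2`; e-value is
#' `m * n * 2^-bitscore` with `m` the read length and `n` the database
#' length.  Hits with e-value above the cutoff are dropped; the rest are
#' returned sorted by decreasing bitscore.
#'
#' @param read a single read sequence (character).
#' @param index a `search_index`.
#' @param params parameters from [search_params()].
#' @return data.frame with columns `genome_id`, `score`, `bitscore`,
#'   `evalue` (possibly zero rows).
#' @export
search_read <- function(read, index, params = search_params()) {
  w <- index$word_size
  empty <- data.frame(genome_id = character(0), score = numeric(0),
                      bitscore = numeric(0), evalue = numeric(0))
  L <- nchar(read)
  if (L < w) return(empty)
  st <- seq_len(L - w + 1L)
  kmers <- substring(read, st, st + w - 1L)
  hits <- mget(unique(kmers), envir = index$map, ifnotfound = list(NULL))
  qpos <- st[match(names(hits), kmers)]
  seed <- do.call(rbind, Map(function(h, qp) {
    if (is.null(h)) return(NULL)
    g <- floor(h / 1e9)
    cbind(g, h - g * 1e9 - qp)   # genome index, diagonal
  }, hits, as.list(qpos)))
  if (is.null(seed)) return(empty)

  margin <- 2L * w
  scores <- vapply(unique(seed[, 1]), function(g) {
    dg <- sort(unique(seed[seed[, 1] == g, 2]))
    subj <- index$sequences[[g]]
    ## cluster diagonals separated by more than a read length
    grp <- cumsum(c(1, diff(dg) > L))
    max(vapply(split(dg, grp), function(d) {
      a <- max(1L, min(d) + 1L - margin)
      b <- min(nchar(subj), max(d) + L + margin)
      sw_best_score(read, substr(subj, a, b), params$match, params$mismatch,
                    -params$gap_open, -params$gap_extend)
    }, numeric(1)))
  }, numeric(1))

  bits <- (params$lambda * scores - log(params$K)) / log(2)
  ev <- L * index$db_length * 2^(-bits)
  out <- data.frame(genome_id = index$genome_ids[unique(seed[, 1])],
                    score = scores, bitscore = bits, evalue = ev)
  out <- out[out$evalue <= params$evalue_max, , drop = FALSE]
  out[order(-out$bitscore), , drop = FALSE]
}

#' Lowest-common-ancestor taxonomic assignment of a hit list
#'
#' Retains hits with bitscore within `top_percent` percent of the best (or
#' exactly equal to the best in `exact_top` mode), maps them to lineages and
#' returns their lowest common ancestor.  If the LCA lies above
#' `target_rank` the read is unassigned at that rank.
#'
#' @param hits data.frame from [search_read()] (sorted by bitscore).
#' @param taxonomy lineage table (`genome_id`, domain ... species).
#' @param mode `"top_percent"` (MEGAN-style) or `"exact_top"`.
#' @param top_percent retention window below the best bitscore, in percent.
#' @param target_rank rank at which the assignment is reported.
#' @return list with `taxon` (name at `target_rank`, or `NA`), `lca_rank`
#'   and `lca_taxon` (deepest resolved node), `assigned` (logical).
#' @export
lca_assign <- function(hits, taxonomy, mode = c("top_percent", "exact_top"),
                       top_percent = 10, target_rank = "genus") {
  mode <- match.arg(mode)
  unassigned <- list(taxon = NA_character_, lca_rank = NA_character_,
                     lca_taxon = NA_character_, assigned = FALSE)
  if (is.null(hits) || !nrow(hits)) return(unassigned)
  best <- max(hits$bitscore)
  keep <- if (mode == "exact_top") hits$bitscore == best
          else hits$bitscore >= (1 - top_percent / 100) * best
  lin <- taxonomy[match(hits$genome_id[keep], taxonomy$genome_id),
                  TAX_RANKS, drop = FALSE]
  depth <- 0L
  for (r in seq_along(TAX_RANKS)) {
    v <- lin[[r]]
    if (anyNA(v) || length(unique(v)) != 1L) break
    depth <- r
  }
  if (depth == 0L) return(unassigned)
  ti <- match(target_rank, TAX_RANKS)
  list(taxon = if (depth >= ti) lin[[ti]][1] else NA_character_,
       lca_rank = TAX_RANKS[depth], lca_taxon = lin[[depth]][1],
       assigned = depth >= ti)
}

#' Reference-based genus profiles for a set of samples
#'
#' Searches every read of every QC-passed sample against the index, assigns
#' genera by the LCA rule, and tallies a samples x genera count matrix.
#' Identical read sequences are searched once and counted with their
#' multiplicity.
#'
#' @param samples named list of per-sample read data.frames (post-QC).
#' @param index a `search_index` built from the filtered reference.
#' @param taxonomy lineage table of the (filtered) reference.
#' @param params search parameters ([search_params()]).
#' @param mode,top_percent LCA options, see [lca_assign()].
#' @return a [count_matrix] with one column per genus in the reference,
#'   per-sample totals (all QC-passed reads) and assignment rates.
#' @export
profile_samples <- function(samples, index, taxonomy,
                            params = search_params(),
                            mode = "top_percent", top_percent = 10) {
  genera <- sort(unique(na.omit(taxonomy$genus)))
  counts <- matrix(0L, length(samples), length(genera),
                   dimnames = list(names(samples), genera))
  totals <- vapply(samples, nrow, integer(1))
  cache <- new.env(hash = TRUE, parent = emptyenv())
  for (si in seq_along(samples)) {
    reads <- samples[[si]]$seq
    if (!length(reads)) next
    tab <- table(reads)
    for (u in names(tab)) {
      genus <- get0(u, envir = cache, inherits = FALSE)
      if (is.null(genus)) {
        hits <- search_read(u, index, params)
        g <- lca_assign(hits, taxonomy, mode = mode,
                        top_percent = top_percent)$taxon
        genus <- if (is.na(g)) "" else g
        assign(u, genus, envir = cache)
      }
      if (nzchar(genus))
        counts[si, genus] <- counts[si, genus] + as.integer(tab[[u]])
    }
  }
  count_matrix(counts, totals)
}
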