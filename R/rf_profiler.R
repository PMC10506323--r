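## Reference-free profiling: 65 bp cut-site tags.

TAG_LENGTH <- 65L

#' Extract the 65 bp cut-site tag of a read
#'
#' Post-QC reads begin at the cut-site remnant; the tag is their first 65
#' bases.  Reads shorter than 65 bp are ignored (`NA`).
#'
#' @param reads character vector of post-QC read sequences.
#' @param tag_len tag length (default 65).
#' @return character vector of tags, `NA` for short reads.
#' @export
extract_tag <- function(reads, tag_len = TAG_LENGTH) {
  ifelse(nchar(reads) >= tag_len, substr(reads, 1L, tag_len), NA_character_)
}

#' Discover tags at a prevalence threshold
#'
#' A tag (non-redundant 65 bp sequence) enters the set when the fraction of
#' samples containing it at least once is `>= prevalence` (inclusive, "at
#' least 25% of samples").
#'
#' @param samples named list of per-sample read data.frames (post-QC).
#' @param prevalence inclusive prevalence threshold in `[0, 1]`.
#' @param label label of the source sample set (e.g. `"All"` or a group).
#' @param tag_len tag length.
#' @return object of class `tag_set`: list with `tags`, `prevalence`
#'   (fraction of source samples per tag), `label`, `n_samples`.
#' @export
discover_tags <- function(samples, prevalence = 0.25, label = "All",
                          tag_len = TAG_LENGTH) {
  if (!length(samples)) stopf("at least one sample is required")
  per_sample <- lapply(samples, function(s)
    unique(na.omit(extract_tag(s$seq, tag_len))))
  tab <- table(unlist(per_sample, use.names = FALSE))
  frac <- as.numeric(tab) / length(samples)
  keep <- frac >= prevalence
  ord <- order(names(tab)[keep])
  structure(list(tags = names(tab)[keep][ord], prevalence = frac[keep][ord],
                 label = label, n_samples = length(samples)),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set '%s': %d tags from %d samples\n", x$label,
              length(x$tags), x$n_samples))
  invisible(x)
}

#' Count tag occurrences per sample
#'
#' Each cell is the number of reads in a sample whose 65 bp prefix equals
#' the tag; the assignment rate is tag-matching reads over all reads.
#'
#' @param samples named list of per-sample read data.frames.
#' @param tagset a `tag_set`.
#' @param tag_len tag length.
#' @return a [count_matrix] with one column per tag.
#' @export
count_tags <- function(samples, tagset, tag_len = TAG_LENGTH) {
  stopifnot(inherits(tagset, "tag_set"))
  counts <- matrix(0L, length(samples), length(tagset$tags),
                   dimnames = list(names(samples), tagset$tags))
  for (i in seq_along(samples)) {
    tg <- na.omit(extract_tag(samples[[i]]$seq, tag_len))
    m <- match(tg, tagset$tags)
    t2 <- tabulate(m[!is.na(m)], nbins = length(tagset$tags))
    counts[i, ] <- t2
  }
  count_matrix(counts, vapply(samples, nrow, integer(1)))
}

#' Proportion of tags that differ between two tag sets
#'
#' Jaccard distance: the size of the symmetric difference over the size of
#' the union, in `[0, 1]`.
#'
#' @param a,b `tag_set` objects or character vectors of tags.
#' @return the distance.
#' @export
tagset_distance <- function(a, b) {
  ta <- if (inherits(a, "tag_set")) a$tags else a
  tb <- if (inherits(b, "tag_set")) b$tags else b
  if (!length(ta) && !length(tb)) stopf("both tag sets are empty")
  u <- union(ta, tb)
  length(setdiff(u, intersect(ta, tb))) / length(u)
}

#' Pairwise tag-set distance matrix
#'
#' @param tagsets named list of `tag_set`s (or tag vectors).
#' @return symmetric matrix of Jaccard distances.
#' @export
tagset_distance_matrix <- function(tagsets) {
  n <- length(tagsets)
  labs <- names(tagsets)
  if (is.null(labs))
    labs <- vapply(tagsets, function(t)
      if (inherits(t, "tag_set")) t$label else "", character(1))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    d[i, j] <- d[j, i] <- tagset_distance(tagsets[[i]], tagsets[[j]])
  d
}

#' Average-linkage (UPGMA) dendrogram of a distance matrix
#'
#' Wraps `hclust(method = "average")`; merge heights are non-decreasing and
#' the tree is exported as Newick via ape.
#'
#' @param dist_matrix symmetric zero-diagonal distance matrix.
#' @param labels optional leaf labels (default: dimnames).
#' @return list with `hclust` (the fit), `newick` (string), `heights`.
#' @export
upgma <- function(dist_matrix, labels = NULL) {
  dist_matrix <- as.matrix(dist_matrix)
  if (nrow(dist_matrix) < 2) stopf("at least two leaves are required")
  if (max(abs(dist_matrix - t(dist_matrix))) > 1e-12 ||
      any(abs(diag(dist_matrix)) > 1e-12))
    stopf("distance matrix must be symmetric with zero diagonal")
  if (!is.null(labels)) dimnames(dist_matrix) <- list(labels, labels)
  hc <- hclust(as.dist(dist_matrix), method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy), heights = hc$height)
}

#' Venn region counts for 2-4 tag sets
#'
#' @param tagsets named list of 2 to 4 `tag_set`s (or tag vectors).
#' @return data.frame with one row per membership region (columns of 0/1
#'   per set plus `count`); counts sum to the size of the union.
#' @export
venn_counts <- function(tagsets) {
  n <- length(tagsets)
  if (n < 2 || n > 4) stopf("venn_counts supports 2 to 4 sets")
  sets <- lapply(tagsets, function(t)
    if (inherits(t, "tag_set")) t$tags else t)
  labs <- names(sets)
  if (is.null(labs)) labs <- paste0("set", seq_len(n))
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1L) member <- matrix(member, nrow = 1)
  pat <- do.call(expand.grid, base::rep(list(c(0L, 1L)), n))
  pat <- pat[rowSums(pat) > 0, , drop = FALSE]
  names(pat) <- labs
  key <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  pkey <- apply(pat, 1, paste, collapse = "")
  pat$count <- as.integer(table(factor(key, levels = pkey)))
  rownames(pat) <- NULL
  pat
}

#' Intersect group tag sets
#'
#' The set of tags present in every group's tag set.
#'
#' @param group_tagsets named list of >= 2 `tag_set`s.
#' @return a `tag_set` labelled `"AllGroups"` (prevalence 1 by convention:
#'   present in all source sets).
#' @export
intersect_groups <- function(group_tagsets) {
  if (length(group_tagsets) < 2) stopf("at least two group tag sets required")
  tags <- sort(Reduce(intersect, lapply(group_tagsets, function(t)
    if (inherits(t, "tag_set")) t$tags else t)))
  structure(list(tags = tags, prevalence = base::rep(1, length(tags)),
                 label = "AllGroups", n_samples = NA_integer_),
            class = "tag_set")
}

#' Assign taxonomy to tags (host screen, then LCA over top-bitscore hits)
#'
#' Stage 1: tags that map uniquely (a single exact occurrence, forward or
#' reverse-complement) to the host genome are labelled `host`.  Stage 2:
#' remaining tags are searched against the reference index; only hits whose
#' bitscore equals the top bitscore are considered and the LCA lineage is
#' recorded at every rank.
#'
#' @param tagset a `tag_set`.
#' @param host character vector of host genome sequence(s), or `NULL` to
#'   skip the host screen.
#' @param index a `search_index` over the reference.
#' @param taxonomy lineage table of the reference.
#' @param params search parameters.
#' @return data.frame: `tag`, `status` (`host`/`assigned`/`unassigned`),
#'   and lineage columns domain ... species (`NA` below the LCA).
#' @export
assign_tag_taxonomy <- function(tagset, host, index, taxonomy,
                                params = search_params()) {
  stopifnot(inherits(tagset, "tag_set"))
  tags <- tagset$tags
  out <- data.frame(tag = tags, status = "unassigned",
                    stringsAsFactors = FALSE)
  for (r in TAX_RANKS) out[[r]] <- NA_character_
  if (!length(tags)) return(out)

  is_host <- rep(FALSE, length(tags))
  if (!is.null(host) && length(host)) {
    subj <- Biostrings::DNAStringSet(host)
    for (i in seq_along(tags)) {
      nf <- sum(Biostrings::vcountPattern(tags[i], subj))
      nr <- sum(Biostrings::vcountPattern(revcomp(tags[i]), subj))
      is_host[i] <- (nf + nr) == 1L
    }
  }
  out$status[is_host] <- "host"

  for (i in which(!is_host)) {
    hits <- search_read(tags[i], index, params)
    a <- lca_assign(hits, taxonomy, mode = "exact_top")
    if (!is.na(a$lca_rank)) {
      depth <- match(a$lca_rank, TAX_RANKS)
      lin <- taxonomy[match(hits$genome_id[which.max(hits$bitscore)],
                            taxonomy$genome_id), TAX_RANKS]
      out[i, TAX_RANKS[seq_len(depth)]] <-
        as.character(lin[seq_len(depth)])
      out$status[i] <- "assigned"
    }
  }
  out
}

#' Cluster tag counts into genus-level profiles
#'
#' Sums read counts of tags assigned to the same genus; host tags, tags not
#' assigned at genus level, and tags outside the retained domains are
#' ignored.  The assignment rate is recomputed against the total reads.
#'
#' @param tag_counts a [count_matrix] of tags.
#' @param tag_taxonomy data.frame from [assign_tag_taxonomy()].
#' @param domains_keep domains to retain (default Bacteria + Archaea), or
#'   `NULL` for all.
#' @return a [count_matrix] at genus level.
#' @export
cluster_by_genus <- function(tag_counts, tag_taxonomy,
                             domains_keep = c("Bacteria", "Archaea")) {
  stopifnot(inherits(tag_counts, "count_matrix"))
  tt <- tag_taxonomy[match(colnames(tag_counts$counts), tag_taxonomy$tag), ]
  use <- tt$status == "assigned" & !is.na(tt$genus)
  if (!is.null(domains_keep)) use <- use & tt$domain %in% domains_keep
  genera <- sort(unique(tt$genus[use]))
  agg <- matrix(0L, nrow(tag_counts$counts), length(genera),
                dimnames = list(rownames(tag_counts$counts), genera))
  for (g in genera) {
    cols <- which(use & tt$genus == g)
    agg[, g] <- as.integer(rowSums(tag_counts$counts[, cols, drop = FALSE]))
  }
  count_matrix(agg, tag_counts$totals)
}

#' Write a tag set as a two-column TSV (tag, prevalence)
#' @param tagset a `tag_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tagset <- function(tagset, path) {
  write.table(data.frame(tag = tagset$tags, prevalence = tagset$prevalence),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
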