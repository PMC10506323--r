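test_that("tag extraction takes exactly the first 65 bases", {
  reads <- c(strrep("A", 64), strrep("C", 65), paste0(strrep("G", 65),
                                                      strrep("T", 26)))
  tags <- extract_tag(reads)
  expect_true(is.na(tags[1]))
  expect_equal(tags[2], strrep("C", 65))
  expect_equal(tags[3], strrep("G", 65))
  expect_equal(nchar(na.omit(tags)), c(65, 65))
})

test_that("tag discovery applies the inclusive prevalence threshold", {
  tag <- function(ch) paste0("TGCAG", strrep(ch, 60))
  mk <- function(...) make_reads(c(...))
  ## 4 samples, tag in exactly 1: 0.25 >= 0.25, included
  samples <- list(s1 = mk(tag("A"), tag("C")), s2 = mk(tag("C")),
                  s3 = mk(tag("C")), s4 = mk(tag("C")))
  ts <- discover_tags(samples)
  expect_true(tag("A") %in% ts$tags)
  ## 5 samples, tag in 1 (0.20): excluded
  samples5 <- c(samples, list(s5 = mk(tag("C"))))
  ts5 <- discover_tags(samples5)
  expect_false(tag("A") %in% ts5$tags)
  ## tag in all samples: included at any threshold <= 1
  expect_true(tag("C") %in% discover_tags(samples5, prevalence = 1)$tags)
  expect_error(discover_tags(list()))
})

test_that("tag discovery equals brute-force prefix enumeration", {
  set.seed(77)
  for (rep_i in 1:10) {
    n_s <- sample(3:8, 1)
    pool <- vapply(1:6, function(i) random_dna(sample(60:80, 1)),
                   character(1))
    samples <- setNames(lapply(seq_len(n_s), function(i)
      make_reads(sample(pool, sample(5:20, 1), replace = TRUE))),
      paste0("s", seq_len(n_s)))
    prev <- sample(c(0.2, 0.25, 0.5), 1)
    expect_identical(discover_tags(samples, prev)$tags,
                     brute_force_tags(samples, prev))
  }
})

test_that("tag counting tallies 65 bp prefixes with assignment rates", {
  t1 <- paste0("TGCAG", strrep("A", 60))
  t2 <- paste0("TGCAG", strrep("C", 60))
  s <- list(
    x = make_reads(c(base::rep(paste0(t1, "GGG"), 3), base::rep(t2, 4),
                     base::rep(strrep("T", 70), 2), strrep("G", 40))),
    y = make_reads(strrep("T", 30)))
  ts <- structure(list(tags = c(t1, t2), prevalence = c(1, 1),
                       label = "All", n_samples = 2), class = "tag_set")
  cm <- count_tags(s, ts)
  expect_equal(unname(cm$counts["x", c(t1, t2)]), c(3, 4))
  expect_equal(cm$assignment_rate[1], 7 / 10)
  ## sample with no reads >= 65 bp: zero row
  expect_equal(sum(cm$counts["y", ]), 0)
  ## all reads planted tags: rate 1
  s2 <- list(z = make_reads(c(t1, t1, t2)))
  expect_equal(count_tags(s2, ts)$assignment_rate, 1)
})

test_that("tag-set distance is the Jaccard distance and a metric", {
  A <- c("a", "b", "c"); B <- c("b", "c", "d")
  expect_equal(tagset_distance(A, A), 0)
  expect_equal(tagset_distance(A, c("x", "y")), 1)
  expect_equal(tagset_distance(A, B), 0.5)
  expect_error(tagset_distance(character(0), character(0)))

  ## metric axioms over all pairs/triples of small sets
  sets <- list(c("a"), c("a", "b"), c("b", "c"), c("a", "b", "c"),
               c("c", "d"), c("d"))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    dij <- tagset_distance(sets[[i]], sets[[j]])
    expect_equal(dij, tagset_distance(sets[[j]], sets[[i]]))
    if (identical(sort(sets[[i]]), sort(sets[[j]]))) expect_equal(dij, 0)
    for (k in seq_along(sets))
      expect_lte(dij, tagset_distance(sets[[i]], sets[[k]]) +
                   tagset_distance(sets[[k]], sets[[j]]) + 1e-12)
  }
})

test_that("UPGMA merges at average linkage with non-decreasing heights", {
  ## 2 leaves join at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  u2 <- upgma(d2)
  expect_equal(u2$heights, 0.4)

  ## 3-leaf hand computation: (A,B) at 0.2, then C at 0.6
  d3 <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  u3 <- upgma(d3)
  expect_equal(u3$heights, c(0.2, 0.6))
  expect_equal(cutree(u3$hclust, 2)[["A"]], cutree(u3$hclust, 2)[["B"]])
  expect_true(grepl("C", u3$newick, fixed = TRUE))

  ## identical rows: all merges at the same height
  d4 <- matrix(0.3, 4, 4); diag(d4) <- 0
  dimnames(d4) <- list(letters[1:4], letters[1:4])
  expect_true(all(abs(upgma(d4)$heights - 0.3) < 1e-12))
  expect_error(upgma(matrix(0, 1, 1)))
})

test_that("Venn regions partition the union for 2-4 sets", {
  v <- venn_counts(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(sum(v$count), 3)
  expect_equal(v$count[v$A == 1 & v$B == 0], 1)
  expect_equal(v$count[v$A == 1 & v$B == 1], 1)
  expect_equal(v$count[v$A == 0 & v$B == 1], 1)

  ## equal sets: only the full intersection is non-empty
  v2 <- venn_counts(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(v2$count[v2$A == 1 & v2$B == 1], 2)
  expect_equal(sum(v2$count), 2)

  ## three disjoint sets: only exclusive regions
  v3 <- venn_counts(list(A = "a", B = "b", C = "c"))
  expect_equal(sum(v3$count[rowSums(v3[, 1:3]) > 1]), 0)
  expect_equal(sum(v3$count), 3)
  expect_error(venn_counts(list(1, 2, 3, 4, 5)))
})

test_that("group tag-set intersection obeys the subset law", {
  gsets <- list(g1 = c("a", "b", "c"), g2 = c("b", "c"), g3 = c("c"))
  inter <- intersect_groups(gsets)
  expect_equal(inter$tags, "c")
  expect_equal(inter$label, "AllGroups")
  for (g in gsets) expect_true(all(inter$tags %in% g))
  same <- intersect_groups(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(sort(same$tags), c("x", "y"))
})

test_that("tag taxonomy: host screen then exact-top LCA", {
  ref <- toy_reference(2, 1, 20000)
  host <- random_dna(30000)
  tag_host <- substr(host, 101, 165)
  tag_host_rc <- rerrs:::revcomp(substr(host, 501, 565))
  tag_microbe <- substr(ref$sequences[[1]], 1001, 1065)
  tag_none <- random_dna(65)
  ts <- structure(list(tags = c(tag_host, tag_host_rc, tag_microbe,
                                tag_none),
                       prevalence = base::rep(1, 4), label = "All",
                       n_samples = 4), class = "tag_set")
  idx <- build_search_index(ref)
  tt <- assign_tag_taxonomy(ts, host, idx, ref$taxonomy)
  expect_equal(tt$status[tt$tag == tag_host], "host")
  expect_equal(tt$status[tt$tag == tag_host_rc], "host")
  expect_equal(tt$status[tt$tag == tag_microbe], "assigned")
  expect_equal(tt$genus[tt$tag == tag_microbe], ref$taxonomy$genus[1])
  expect_equal(tt$status[tt$tag == tag_none], "unassigned")

  ## equal bitscore in two species of one genus: assigned at genus
  ref2 <- simulate_reference(1, 2, 10000, seed = 5)
  frag <- substr(ref2$sequences[[1]], 2001, 2065)
  ref2$sequences[2] <- paste0(ref2$sequences[[2]], frag)
  idx2 <- build_search_index(ref2)
  ts2 <- structure(list(tags = frag, prevalence = 1, label = "x",
                        n_samples = 1), class = "tag_set")
  tt2 <- assign_tag_taxonomy(ts2, NULL, idx2, ref2$taxonomy)
  expect_equal(tt2$status, "assigned")
  expect_equal(tt2$genus, ref2$taxonomy$genus[1])
  expect_true(is.na(tt2$species))
})

test_that("genus clustering sums member tags and recomputes rates", {
  tags <- c(t1 = paste0("TGCAG", strrep("A", 60)),
            t2 = paste0("TGCAG", strrep("C", 60)),
            t3 = paste0("TGCAG", strrep("G", 60)))
  counts <- matrix(c(3, 4, 5,
                     1, 0, 2), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), unname(tags)))
  cm <- count_matrix(counts, c(20, 10))
  tt <- data.frame(tag = unname(tags),
                   status = c("assigned", "assigned", "assigned"),
                   domain = c("Bacteria", "Bacteria", "Eukaryota"),
                   phylum = "P", class = "C", order = "O", family = "F",
                   genus = c("GenX", "GenX", "GenY"),
                   species = NA, stringsAsFactors = FALSE)
  byg <- cluster_by_genus(cm, tt)
  expect_equal(unname(byg$counts[, "GenX"]), c(7, 1))
  expect_false("GenY" %in% colnames(byg$counts))   # non-bacterial dropped
  expect_equal(byg$assignment_rate, c(7 / 20, 1 / 10))

  ## domains_keep = NULL keeps the eukaryote column too
  all_d <- cluster_by_genus(cm, tt, domains_keep = NULL)
  expect_equal(sort(colnames(all_d$counts)), c("GenX", "GenY"))

  ## everything unassigned: empty matrix, rate zero
  tt$status <- "unassigned"
  none <- cluster_by_genus(cm, tt)
  expect_equal(ncol(none$counts), 0)
  expect_equal(none$assignment_rate, c(0, 0))
})

test_that("RF assignment rate exceeds RB when the reference is incomplete", {
  ref <- toy_reference(3, 1, 20000)
  des <- simulate_design(n_animals = 4, groups = default_groups()[1, ],
                         cohorts_per_group = 1, samples_per_cohort = 4,
                         seed = 13)
  tr <- simulate_abundances(des, n_taxa = 3, h2 = 0, rep = 0, seed = 13)
  fq <- render_fastq(ref, tr, des, reads_per_sample = 1500, seed = 14)
  qc <- run_qc(do.call(rbind, fq),
               des$samples[, c("sample_id", "barcode")], min_reads = 100)

  ## RB reference deliberately misses one genus of the community
  partial <- ref
  keep <- partial$taxonomy$genus != partial$taxonomy$genus[1]
  partial$taxonomy <- partial$taxonomy[keep, , drop = FALSE]
  partial$sequences <- partial$sequences[partial$taxonomy$genome_id]
  rb <- profile_samples(qc$samples, build_search_index(partial),
                        partial$taxonomy)
  tags <- discover_tags(qc$samples, prevalence = 0.25)
  rf <- count_tags(qc$samples, tags)
  expect_true(all(rf$assignment_rate >= rb$assignment_rate))
  expect_gt(mean(rf$assignment_rate) - mean(rb$assignment_rate), 0.1)
})
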