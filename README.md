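# rerrs

Restriction-enzyme reduced-representation sequencing (RE-RRS) is a
low-cost way to profile microbial communities at scale: genomic DNA is
digested with PstI, fragments of 193–318 bp are amplified and sequenced
as barcoded 101 bp single-end reads, and the reads are turned into
per-sample community profiles.  `rerrs` implements the full analysis
chain for such data — aimed at quantitative geneticists and
microbiologists working with livestock (e.g. rumen) microbiomes — plus a
synthetic-data generator with known ground truth so every stage can be
tested end to end without real sequencing data.

The package provides:

* **Simulation** — reference genomes with planted `CTGCAG` sites, in
  silico digestion (`CTGCA^G`) and size selection, multi-group /
  multi-cohort study designs, latent taxon abundances with a known
  genetic architecture, and barcoded FASTQ reads.
* **Read QC** — exact barcode + cut-site demultiplexing, 3'
  quality trimming by the partial-sum rule (q = 20, min length 40),
  sample pass/fail at a read-count threshold.
* **Reference-based (RB) profiling** — 16-mer seeded Smith–Waterman
  search against a genus-labelled reference and lowest-common-ancestor
  (LCA) assignment at genus level, yielding a samples × genera count
  matrix with assignment rates.
* **Reference-free (RF) profiling** — 65 bp cut-site tags at an
  inclusive 25% prevalence threshold, tag counting, Jaccard tag-set
  distances with UPGMA dendrograms, Venn/intersection comparisons, host
  screening and tag taxonomy, and genus-level clustering of tags.
* **Normalisation** — relative abundances; log10 proportions
  `log10((c+1)/(rowsum+m))`; column z-scoring; **cohort adjustment**
  (within-cohort z-scoring that removes shared-environment structure);
  sample correlation matrices.
* **Community structure** — mutual k-nearest-neighbour networks,
  Walktrap communities, Bray–Curtis distances, and a seeded PERMANOVA
  with sequential sums of squares (cross-checked against
  `vegan::adonis2`).
* **Genetics** — VanRaden (method 1) genomic relationship matrix
  `G = (M−2p)(M−2p)'/(2Σp(1−p))` and an average-information REML animal
  model `y = µ + Animal + PE + e` with `Animal ~ N(0, G σ²g)` and
  permanent-environment effects shared by an animal's repeated records.
  Heritability is `h² = σ²g/σ²T` and repeatability
  `(σ²g+σ²pe)/σ²T` with `σ²T = σ²g+σ²pe+σ²e`, both with delta-method
  standard errors; per-feature scans and a fixed-factor
  variance-partition (Group, Cohort, Library, BatchShelf, Well, BRR,
  AOD, BDEV) complete the module.

## Worked example

Simulate a small two-diet study, sequence it, and profile it both ways:

```r
library(rerrs)

ref <- simulate_reference(n_genera = 3, genomes_per_genus = 2,
                          genome_length = 30000, seed = 1)
#> reference_db: 6 genomes, 3 genera (0 without genus), 180,000 bp total

des <- simulate_design(n_animals = 40, groups = default_groups()[c(1, 5), ],
                       cohorts_per_group = 2, samples_per_cohort = 8, seed = 2)
#> study_design: 32 samples, 23 animals, 2 groups, 4 cohorts

tr <- simulate_abundances(des, n_taxa = 3, h2 = 0.25, rep = 0.4,
                          cohort_var = 1, seed = 3)
fq <- render_fastq(ref, tr, des, reads_per_sample = 4000, seed = 4)
qc <- run_qc(do.call(rbind, fq), des$samples[, c("sample_id", "barcode")],
             min_reads = 1000)
head(qc$report, 3)
#>   sample n_raw n_kept mean_length status
#> 1  S0001  4000   4000          95   pass
#> 2  S0002  4000   4000          95   pass
#> 3  S0003  4000   4000          95   pass

idx <- build_search_index(filter_reference(ref))
rb <- profile_samples(qc$samples, idx, ref$taxonomy)
round(colSums(rb$counts) / sum(rb$counts), 3)
#> Genus01 Genus02 Genus03
#>   0.423   0.295   0.282

discover_tags(qc$samples, prevalence = 0.25)
#> tag_set 'All': 99 tags from 32 samples
```

Every read passes QC (error-free Q40 reads) and the genus shares reflect
each genus's abundance weight times its number of selectable fragments.
Estimating heritability of a taxon abundance on a larger simulated
cohort:

```r
geno <- simulate_genotypes(300, 1500, 20, seed = 5)
G <- grm_vanraden(geno)
#> grm: 300 animals, 1500 markers; mean diagonal 0.993

des <- simulate_design(animal_ids = rownames(geno),
                       groups = default_groups()[c(1, 2), ],
                       cohorts_per_group = 1, samples_per_cohort = 300,
                       seed = 6)
tr <- simulate_abundances(des, grm = G, n_taxa = 1, h2 = 0.25, rep = 0.4,
                          cohort_var = 0.5, seed = 7)
adj <- cohort_adjust(
  structure(tr$latent, provenance = "log10",
            class = c("profile_matrix", "matrix", "array")),
  des$samples$cohort)
reml_fit(unclass(adj)[, 1], G, des$samples$animal_id)
#> REML animal model (G + PE + e), 600 records / 300 animals
#>   sigma2_g = 0.1728  sigma2_pe = 0.1673  sigma2_e = 0.6531
#>   h2 = 0.174 (SE 0.078)   repeatability = 0.342 (SE 0.052)
#>   logLik = -277.978 after 6 iterations (converged)
```

The planted heritability (0.25) and repeatability (0.40) lie within two
standard errors of the estimates from this single 300-animal replicate.
The fit object supports `summary()`, `coef()`, `logLik()`, `fitted()`,
`residuals()`, `predict()` (animal BLUPs) and `vcov()`.

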