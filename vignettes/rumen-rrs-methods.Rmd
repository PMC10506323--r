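---
title: "Reduced-representation metagenome profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-representation metagenome profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`rerrs` implements the analysis chain used to profile microbial
communities — typically rumen contents — by restriction-enzyme
reduced-representation sequencing (RE-RRS): genomic DNA is digested with
PstI, fragments in a fixed size window are amplified and sequenced as
barcoded 101 bp single-end reads, and the resulting reads are turned into
per-sample community profiles either by alignment to a genus-labelled
reference (reference-based, RB) or by counting 65 bp cut-site tags
(reference-free, RF).  Downstream, the package normalises profiles,
removes shared-environment structure by within-cohort adjustment, examines
sample relationships (correlation networks, PERMANOVA), and estimates the
genomic heritability and repeatability of taxon abundances with an animal
model.  A synthetic-data generator produces every input with known ground
truth, so each stage is testable without any real sequencing data.

# The synthetic-data generator

The generator is first-class, tested code.  It emulates:

* **Reference genomes** (`simulate_reference()`): random DNA with planted
  `CTGCAG` motifs.  Inter-site spacings are a mixture of a uniform draw
  inside 200–310 bp (so every genome yields selectable fragments) and an
  exponential tail controlled by `site_density`; `site_density = 0` plants
  nothing.  Lineages (domain → species) are generated consistently: two
  genera per family, two families per phylum, so the taxonomy is a valid
  tree for LCA assignment.
* **Digestion and size selection** (`digest_genome()`, `size_select()`):
  PstI cuts `CTGCA^G` (the enzyme's biochemistry; remnant on reads is
  `TGCAG`).  Only fragments with a cut site at *both* ends are
  sequenceable, because ligation of barcode and adapter requires
  compatible overhangs; terminal fragments are discarded before the
  193–318 bp window is applied.  Whether the window includes adapter
  length is configurable (`adapter_len`, default 0: the window applies to
  the raw fragment), since library-preparation conventions differ.
* **Study designs** (`simulate_design()`): eight groups (diet × age ×
  time-off-feed × country), cohorts nested in groups, libraries of fixed
  size with per-library unique fixed-length barcodes (fixed length implies
  prefix-free, which exact demultiplexing requires), freeze-drying
  batch-shelf levels, well positions, per-animal birth covariates and a
  two-level methane selection line.  Home-country animals are sampled
  repeatedly across groups, giving the repeated records that make
  permanent-environment variance estimable.
* **Abundance truth** (`simulate_abundances()`): each taxon's latent
  log-abundance is `mu + group + cohort + line + g + pe + e` with `g`
  drawn with covariance proportional to a genomic relationship matrix and
  shared (with `pe`) by all samples of an animal.  Variances are scaled so
  the non-group, non-cohort variance is 1 with `Var(g) = h2` and
  `Var(g + pe) = rep`; the generative heritability and repeatability are
  therefore exact.  Latents are Gaussian on the log scale and
  exponentiated into sampling weights, matching the log-scale analysis
  downstream.
* **Reads** (`render_fastq()`): a read is
  `barcode + TGCAG + fragment-after-the-cut`, truncated to the read
  length; fragments are drawn multinomially with weight
  `exp(latent of the fragment's taxon)`, so a genome's weight is
  proportional to abundance × fragments-per-genome.  Qualities are a
  constant baseline with optional linear 3' decay (to exercise trimming
  deterministically) and substitution errors are applied at a configurable
  rate.  Reads are emitted from one strand orientation; no indels,
  chimeras or PCR duplicates are modelled.

What the generator does *not* emulate — GC bias, coverage waviness, real
quality profiles, strain-level variation, incomplete digestion — bounds
what passing tests show: they demonstrate that the algorithms implement
their contracts and recover planted truth, not that any particular real
dataset satisfies the model.

# Read QC

Demultiplexing assigns a read if and only if it begins with an exact
barcode immediately followed by the exact `TGCAG` remnant; the barcode is
stripped and the remnant retained, so every retained read begins at the
cut site (tags "commence at the initial cut site"; whether the original
toolchain stripped the remnant is not documented, so retention is the
package's convention).  Trimming uses the standard 3' partial-sum rule
(the documented Cutadapt/BWA algorithm): subtract the threshold `q = 20`
from each quality, accumulate from the 3' end, cut at the maximum of the
partial sum if positive.  Reads shorter than 40 bp are discarded; samples
with fewer than `min_reads` surviving reads fail (inclusive boundary:
exactly `min_reads` passes; the full-scale default is 100,000,
configurable for toy scale).  Only the 3' end is trimmed — the 5' end was
validated exactly — and no read-through adapter trimming is performed.

# Reference-based profiling

The search is seed-and-extend local alignment: an exact 16-mer word table
over the (genus-filtered) reference seeds candidate diagonals, and each
candidate region is scored by affine-gap Smith–Waterman (in C++), so a
seeded alignment attains the true optimal local score.  Scoring defaults
are match +1, mismatch −2, gap open −5, gap extend −2 (a gap of length
*g* costs 5 + 2*g*); ambiguous bases never seed and always score as
mismatches.  Bitscore is `(lambda * S − ln K) / ln 2` with `lambda`
solved from the ungapped Karlin–Altschul equation for the configured
scheme and `K` a configurable constant (default 0.333); the e-value is
`m n 2^-bitscore` over the database length, with hits kept at e-value
≤ 0.01.  Ties are preserved, never broken arbitrarily.

Taxonomic assignment is a lowest-common-ancestor rule: hits within 10% of
the best bitscore (or exactly equal to it, in `exact_top` mode — the rule
used for tag taxonomy) are mapped to lineages, and the deepest rank on
which all retained lineages agree is the assignment; reads whose LCA lies
above the genus are unassigned.  Minimum support is 1 and no minimum
bitscore is imposed at toy scale; all of these are exposed as
configuration because the original pipeline's exact settings are not
documented.

# Reference-free profiling

A tag is a non-redundant 65 bp sequence starting at the cut-site remnant;
reads shorter than 65 bp are ignored.  A tag enters a tag set when the
fraction of samples containing it at least once is ≥ the prevalence
threshold (inclusive, default 25%); presence means count ≥ 1 with no
minimum-count filter.  Tag-set similarity between groups is summarised by
the Jaccard distance (symmetric difference over union) — the natural
reading of "proportion of tags that differ", whose denominator the source
methods leave unstated — and clustered by average-linkage (UPGMA) through
`hclust(method = "average")` with Newick export.  Venn region counts and
exact multi-group intersections ("AllGroups") support the same
comparisons.  Tag taxonomy proceeds in two stages: tags with a single
exact occurrence in the host genome (forward or reverse complement) are
flagged host — the unique-mapping contract rather than any specific
aligner's flags — and the remainder are searched against the reference
with only top-bitscore hits retained before LCA.  Genus-level profiles
sum the counts of same-genus tags, dropping host, unassigned and
out-of-domain tags, and recompute assignment rates against total reads.

# Profile normalisation and cohort adjustment

Four transforms, exactly as the pipeline defines them:

1. *Relative abundance*: divide each count by its row sum.
2. *Log10 proportions*: `log10((c + 1) / (rowsum + m))` with `m` features;
   per row the antilogs sum to one, and all-zero rows are valid.
3. *Column normalisation*: z-score each column to mean 0, sd 1 (sample
   sd, n − 1).
4. *Cohort adjustment*: the same z-scoring applied independently within
   each cohort, which removes diet/age/time-off-feed structure shared by
   a cohort.  It operates on the log10-proportion matrix; raw counts are
   refused.

Constant columns (or constant-within-cohort cells) are mapped to zero
rather than NaN so that downstream correlation matrices stay defined; the
source methods do not say how such columns were handled, so zero-fill is
the package's documented choice.  A consequence worth stating plainly:
because cohort means are removed *exactly in-sample*, a between-cohort
ANOVA on adjusted values has F near 0 (not near 1); the tests assert
exactly that.  Sample relationship matrices are Pearson correlations
between sample rows of a normalised profile.

# Community structure

Sample networks connect mutual k-nearest neighbours by correlation
(`k = min(10, n - 1)` at package scale; 150 is the full-scale value) and
communities come from igraph's Walktrap with walk length 4.  Negative
edge weights are floored at a small positive value because random walks
need non-negative transition weights.

PERMANOVA is implemented in-package: Gower-centred inner products,
sequential (Type I) sums of squares in the order the terms are given
(matching `adonis2`'s `by = "terms"` default; marginal SS is not used),
pseudo-F per term, and `p = (1 + #{permuted F ≥ observed}) / (n_perm + 1)`
under free (unrestricted) permutation of sample identities — no strata
are declared.  Permutations come from R's Mersenne–Twister under the
caller's seed, so results are bit-reproducible.  The test suite
cross-checks sums of squares and pseudo-F against `vegan::adonis2` to
1e-9 and verifies the classical identity that univariate Euclidean input
reproduces the one-way ANOVA F.  Bray–Curtis distances are computed via
`vegan::vegdist`, with an explicit error for all-zero rows.

# Heritability and repeatability

The genomic relationship matrix is VanRaden's first method,
`G = (M − 2p)(M − 2p)' / (2 Σ p(1 − p))`; frequencies default to the
observed column means.  The per-taxon model is

&nbsp;&nbsp;&nbsp;&nbsp;`y = mu + Animal + PE + e`,

with `Animal ~ N(0, G sigma2_g)`, `PE ~ N(0, I sigma2_pe)` linking
repeated records of one animal, and `e ~ N(0, I sigma2_e)`.  REML
maximisation uses average-information updates with two fallbacks, each
accepted only if the restricted likelihood does not decrease: a
Moore–Penrose AI step (Newton in the estimable subspace, which handles
exactly confounded components such as `g` and `pe` under an identity
GRM), then an EM step, which cannot decrease the likelihood.  Variance
components are clamped at `1e-8 * var(y)` rather than allowed negative,
and a `1e-6` ridge stabilises near-singular `G` (clones, duplicates).
All linear algebra runs in the eigenbasis of `G`, so one
eigendecomposition is shared across all taxa of a profile and each
iteration costs O(q²) for q animals.  Standard errors come from the
inverse average-information matrix; heritability
`h2 = sigma2_g / sigma2_T` and repeatability
`(sigma2_g + sigma2_pe) / sigma2_T` get delta-method standard errors.
Convergence is declared when the relative log-likelihood change falls
below `tol`; non-convergence is flagged, never silent.
`fit_feature_table()` refuses profiles that are not cohort-adjusted,
because uncorrected cohort structure biases the components.

The fixed-factor partition fits
`y = mu + Group + Cohort + Library + BatchShelf + Well + BRR + AOD +
BDEV + PE + e`.  The PE variance is estimated first by the same REML
machinery; the data are then whitened and each factor's contribution is
its marginal (drop-one) sum of squares as a percent of the total sum of
squares, with conditional F-tests on residual degrees of freedom.  This
percent-of-SS convention is the package's own (the original mixed-model
software's computation is unspecified).  Cohort is nested in Group, so
the cohort block is orthogonalised against the group block before
drop-one testing; factors wholly aliased by others are reported as
inestimable rather than dropped silently.

# Numerical and scale choices

Test and acceptance problem sizes are chosen so the whole suite runs on a
single CPU in minutes: references of 3–5 genera × 20–30 kb, libraries of
thousands to tens of thousands of reads, REML recovery at 500 animals ×
2 records with 20 replicates per cell of an (h², repeatability) grid, and
PERMANOVA calibration over 200 null data sets of 30 samples with 999
permutations.  The line-signal simulation uses eight groups × two cohorts
× 32 samples with 80 taxa and variance components (group 4, cohort 0.05,
line 0.003, residual 0.03 on the squared log10 scale): group and cohort
effects 1,300× and 17× the line variance respectively, which reproduces
the masking-then-unmasking pattern — a near-zero line contrast in
correlations before cohort adjustment, a clear one after, and a line term
that PERMANOVA detects once Group is fitted first.

# Known limitations

* The error model is substitution-only; no indels, chimeras or
  duplicates, so demultiplexing and tag extraction never face frameshifts.
* Karlin–Altschul `K` is a configured constant, not fitted; bitscores are
  therefore comparable within a configuration, and the acceptance
  fixtures use exact-substring reads so no conclusion rests on `K`.
* The host screen uses exact unique substring matching; a real screen
  with a mapper would tolerate mismatches.
* `fixed_partition`'s percents depend on the whitened scale and the
  orthogonalisation convention for nested factors; they are comparable
  within the package, not across software.
* Heritability estimation assumes the cohort adjustment fully removed
  shared-environment means; taxa absent from entire cohorts carry no
  information after adjustment (their cells are zero).
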