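## Synthetic reference genomes with planted PstI sites.

PSTI_SITE <- "CTGCAG"
PSTI_CUT_OFFSET <- 5L
PSTI_REMNANT <- "TGCAG"

#' Simulate a genus-labelled reference genome database
#'
#' Generates random genomes with planted PstI recognition sites (`CTGCAG`)
#' whose spacing is chosen so that a controllable fraction of internal
#' restriction fragments falls inside the sequencable size window used by
#' RE-RRS library preparation.  Each genome carries a full taxonomic lineage
#' (domain to species); genera are grouped into consistent higher ranks so
#' the lineages form a valid tree.
#'
#' @param n_genera number of genera to simulate (>= 1).
#' @param genomes_per_genus number of genome assemblies per genus.
#' @param genome_length length of each genome in bp (>= 1000).
#' @param site_density expected planted sites per bp for the non-window
#'   spacing component; `0` plants no sites at all (random background
#'   occurrences of the motif may still exist).
#' @param window_frac fraction of inter-site spacings drawn uniformly inside
#'   the selectable window (so every genome yields size-selectable
#'   fragments).
#' @param p_no_genus proportion of genomes whose taxonomy is only known above
#'   the genus level (genus recorded as `NA`), emulating partially annotated
#'   collections.
#' @param archaea_genera number of genera labelled as domain Archaea (the
#'   remainder are Bacteria).
#' @param seed integer seed; the same seed reproduces the database exactly.
#' @return An object of class `reference_db`: a list with `taxonomy` (one row
#'   per genome: `genome_id`, `domain` ... `species`, `genus` possibly `NA`)
#'   and `sequences` (named character vector of genome sequences).
#' @export
simulate_reference <- function(n_genera = 3, genomes_per_genus = 2,
                               genome_length = 50000,
                               site_density = 1 / 800, window_frac = 0.35,
                               p_no_genus = 0, archaea_genera = 0,
                               seed = 1) {
  if (!is_count(n_genera) || n_genera < 1) stopf("n_genera must be >= 1")
  if (!is_count(genomes_per_genus) || genomes_per_genus < 1)
    stopf("genomes_per_genus must be >= 1")
  if (genome_length < 1000) stopf("genome_length must be >= 1000")
  if (site_density < 0) stopf("site_density must be non-negative")
  set.seed(seed)

  fam_of <- ceiling(seq_len(n_genera) / 2)       # two genera per family
  phy_of <- ceiling(fam_of / 2)                  # two families per phylum
  domains <- c(rep("Archaea", archaea_genera),
               rep("Bacteria", n_genera - archaea_genera))

  tax <- list()
  seqs <- character(0)
  for (g in seq_len(n_genera)) {
    for (m in seq_len(genomes_per_genus)) {
      id <- sprintf("G%02d_%02d", g, m)
      genus <- sprintf("Genus%02d", g)
      known <- runif(1) >= p_no_genus
      tax[[id]] <- data.frame(
        genome_id = id,
        domain  = domains[g],
        phylum  = sprintf("%s_Phylum%02d", domains[g], phy_of[g]),
        class   = sprintf("Class%02d", phy_of[g]),
        order   = sprintf("Order%02d", fam_of[g]),
        family  = sprintf("Family%02d", fam_of[g]),
        genus   = if (known) genus else NA_character_,
        species = if (known) sprintf("%s sp%d", genus, m) else NA_character_,
        stringsAsFactors = FALSE)
      seqs[id] <- plant_sites(random_dna(genome_length), site_density,
                              window_frac)
    }
  }
  structure(list(taxonomy = do.call(rbind, c(tax, make.row.names = FALSE)),
                 sequences = seqs),
            class = "reference_db")
}

## Overwrite CTGCAG motifs along a background sequence.  Spacings are a
## mixture of a uniform draw inside the selectable window and an exponential
## tail, so digests yield both selectable and discarded fragments.
plant_sites <- function(seq, site_density, window_frac) {
  if (site_density == 0) return(seq)
  n <- nchar(seq)
  pos <- integer(0)
  at <- 1 + ceiling(rexp(1, site_density))
  while (at + 5 <= n) {
    pos <- c(pos, at)
    gap <- if (runif(1) < window_frac) round(runif(1, 200, 310))
           else 50 + ceiling(rexp(1, site_density))
    at <- at + gap
  }
  if (!length(pos)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  site <- strsplit(PSTI_SITE, "", fixed = TRUE)[[1]]
  for (p in pos) chars[p:(p + 5)] <- site
  paste(chars, collapse = "")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d genomes, %d genera (%d without genus), %s bp total\n",
              nrow(x$taxonomy), length(unique(na.omit(x$taxonomy$genus))),
              sum(is.na(x$taxonomy$genus)),
              format(sum(nchar(x$sequences)), big.mark = ",")))
  invisible(x)
}

#' In silico restriction digestion of a genome
#'
#' Cuts a sequence at every occurrence of the recognition site, placing the
#' cut between `cut_offset - 1` and `cut_offset` within the site (PstI:
#' `CTGCA^G`).  The concatenation of the returned fragments reproduces the
#' input.  Fragments flanked by a cut site at both ends are flagged
#' `internal`; the leading and trailing fragments are terminal.
#'
#' @param sequence a single DNA string.
#' @param site recognition sequence (default PstI `CTGCAG`).
#' @param cut_offset cut position within the site, in `[0, nchar(site)]`.
#' @return data.frame with columns `seq`, `start`, `end`, `internal`;
#'   zero rows for an empty sequence.
#' @export
digest_genome <- function(sequence, site = PSTI_SITE,
                          cut_offset = PSTI_CUT_OFFSET) {
  stopifnot(length(sequence) == 1L)
  if (cut_offset < 0 || cut_offset > nchar(site))
    stopf("cut_offset must be in [0, %d]", nchar(site))
  n <- nchar(sequence)
  if (n == 0) {
    return(data.frame(seq = character(0), start = integer(0),
                      end = integer(0), internal = logical(0)))
  }
  hits <- gregexpr(site, sequence, fixed = TRUE)[[1]]
  cuts <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L + cut_offset
  cuts <- cuts[cuts > 0 & cuts < n]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  k <- length(starts)
  data.frame(seq = substring(sequence, starts, ends),
             start = starts, end = ends,
             internal = seq_len(k) > 1L & seq_len(k) < k)
}

#' Size-select restriction fragments
#'
#' Retains internal fragments (cut site at both ends, hence ligatable at both
#' ends) whose length plus any adapter length lies inside the selection
#' window, emulating gel-based size selection of the amplified library.
#'
#' @param fragments data.frame as returned by [digest_genome()].
#' @param min_len,max_len inclusive bounds of the selection window in bp
#'   (defaults 193 and 318).
#' @param adapter_len extra length added by adapters/barcodes before size
#'   selection; `0` selects on the raw fragment length.
#' @return the retained rows of `fragments`.
#' @export
size_select <- function(fragments, min_len = 193, max_len = 318,
                        adapter_len = 0) {
  if (min_len > max_len) stopf("min_len must be <= max_len")
  len <- nchar(fragments$seq) + adapter_len
  fragments[fragments$internal & len >= min_len & len <= max_len, ,
            drop = FALSE]
}

#' Write a reference database to FASTA plus a taxonomy table
#'
#' @param refdb a `reference_db`.
#' @param fasta,taxonomy output paths (FASTA and tab-separated taxonomy).
#' @return invisibly, the two paths.
#' @export
write_reference <- function(refdb, fasta, taxonomy) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(refdb$sequences), fasta)
  write.table(refdb$taxonomy, taxonomy, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta, taxonomy))
}

#' Read a reference database from FASTA plus a taxonomy table
#'
#' @param fasta,taxonomy paths written by [write_reference()] (or equivalent
#'   user-supplied files: FASTA of genomes, TSV with `genome_id` and the
#'   ranks domain...species).
#' @return a `reference_db`.
#' @export
read_reference <- function(fasta, taxonomy) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  tax <- read.table(taxonomy, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  v <- as.character(seqs)
  names(v) <- sub("\\s.*", "", names(seqs))
  if (!all(tax$genome_id %in% names(v)))
    stopf("taxonomy lists genomes missing from the FASTA")
  structure(list(taxonomy = tax, sequences = v[tax$genome_id]),
            class = "reference_db")
}
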