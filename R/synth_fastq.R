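## Rendering barcoded RE-RRS reads from a reference plus abundance truth.

#' Render barcoded single-end RE-RRS reads
#'
#' Digests every reference genome, size-selects internal fragments, and for
#' each sample draws `reads_per_sample` reads multinomially across all
#' selectable fragments with per-fragment weight `exp(latent)` of the
#' fragment's taxon (so a genome's sampling weight is proportional to
#' `exp(latent) * fragments-per-genome`).  Each read is
#' `barcode + TGCAG + fragment sequence after the cut`, truncated to
#' `read_len`; Phred qualities follow a constant baseline with optional
#' linear 3' decay and substitution errors are applied at `error_rate`.
#'
#' @param reference a `reference_db`.
#' @param truth an `abundance_truth` for the same design.
#' @param design the `study_design` the truth was simulated on.
#' @param reads_per_sample reads emitted per sample (exact).
#' @param read_len read length in bp (default 101); must exceed the barcode
#'   plus cut-site remnant.
#' @param error_rate per-base substitution error probability.
#' @param quality baseline Phred quality.
#' @param decay_len,decay_to optional 3' quality decay: the final
#'   `decay_len` cycles decline linearly to `decay_to`.
#' @param min_len,max_len,adapter_len size-selection window passed to
#'   [size_select()].
#' @param taxa optional character vector naming, for each genome of the
#'   reference (in taxonomy order), the truth column it belongs to; by
#'   default genera are matched to truth columns in order of first
#'   appearance (genomes without a genus fall back to their family).
#' @param seed integer seed.
#' @return named list (one element per library) of data.frames with columns
#'   `id`, `seq`, `qual` (Phred+33).  Read ids encode
#'   `library:sample:genome:fragment:serial` so read origin is recoverable
#'   in tests.
#' @export
render_fastq <- function(reference, truth, design, reads_per_sample = 1000,
                         read_len = 101, error_rate = 0, quality = 40,
                         decay_len = 0, decay_to = 20,
                         min_len = 193, max_len = 318, adapter_len = 0,
                         taxa = NULL, seed = 1) {
  stopifnot(inherits(reference, "reference_db"),
            inherits(truth, "abundance_truth"),
            inherits(design, "study_design"))
  set.seed(seed)
  tax <- reference$taxonomy

  if (is.null(taxa)) {
    key <- ifelse(is.na(tax$genus), paste0("unk_", tax$family), tax$genus)
    lev <- unique(key)
    if (length(lev) > ncol(truth$latent))
      stopf("reference has %d taxa but truth only %d columns", length(lev),
            ncol(truth$latent))
    taxa <- colnames(truth$latent)[match(key, lev)]
  }
  if (!all(taxa %in% colnames(truth$latent)))
    stopf("taxa must name columns of the truth matrix")

  ## fragment table across all genomes
  frag <- do.call(rbind, lapply(seq_len(nrow(tax)), function(i) {
    f <- size_select(digest_genome(reference$sequences[[tax$genome_id[i]]]),
                     min_len, max_len, adapter_len)
    if (!nrow(f)) return(NULL)
    data.frame(genome = tax$genome_id[i], taxon = taxa[i], seq = f$seq,
               frag = seq_len(nrow(f)), stringsAsFactors = FALSE)
  }))
  if (is.null(frag) || !nrow(frag))
    stopf("no size-selectable fragments in the reference")

  s <- design$samples
  bc_len <- nchar(s$barcode)
  if (any(read_len < bc_len + nchar(PSTI_REMNANT)))
    stopf("read_len shorter than barcode plus cut-site remnant")

  ## read content before barcoding: remnant + fragment after the cut
  content <- paste0(PSTI_REMNANT, substring(frag$seq, 2))

  out <- list()
  for (k in seq_len(nrow(s))) {
    w <- exp(truth$latent[s$sample_id[k], frag$taxon])
    counts <- as.vector(rmultinom(1, reads_per_sample, w))
    idx <- base::rep(seq_len(nrow(frag)), counts)
    seqs <- paste0(s$barcode[k],
                   substr(content[idx], 1L, read_len - bc_len[k]))
    if (error_rate > 0) seqs <- add_substitutions(seqs, error_rate)
    lens <- nchar(seqs)
    qual <- quality_string(lens, quality, decay_len, decay_to)
    ids <- sprintf("%s:%s:%s:%d:%06d", s$library[k], s$sample_id[k],
                   frag$genome[idx], frag$frag[idx], seq_along(idx))
    lib <- s$library[k]
    out[[lib]] <- rbind(out[[lib]],
                        data.frame(id = ids, seq = seqs, qual = qual,
                                   stringsAsFactors = FALSE))
  }
  out
}

## Phred+33 quality strings for a vector of read lengths under the constant
## baseline + linear 3' decay model.
quality_string <- function(lens, quality, decay_len, decay_to) {
  mk <- function(l) {
    q <- base::rep(quality, l)
    if (decay_len > 0) {
      d <- min(decay_len, l)
      q[(l - d + 1):l] <- round(seq(quality, decay_to, length.out = d))
    }
    intToUtf8(as.integer(q) + 33L)
  }
  map <- vapply(sort(unique(lens)), mk, character(1))
  names(map) <- sort(unique(lens))
  unname(map[as.character(lens)])
}

## Independent per-base substitution errors.
add_substitutions <- function(seqs, rate) {
  vapply(seqs, function(sq) {
    ch <- strsplit(sq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(DNA_ALPHABET, ch[i]), 1)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write / read reads as FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path FASTQ path (uncompressed).
#' @return invisibly `path`; `read_fastq()` returns the data.frame form.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$id)
  lines[seq(2, length(lines), 4)] <- reads$seq
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- reads$qual
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialise an abundance truth record to JSON
#'
#' @param truth an `abundance_truth`.
#' @param path output JSON path.
#' @param seed the seed(s) used upstream, stored for provenance.
#' @return invisibly, `path`.
#' @export
write_truth <- function(truth, path, seed = NULL) {
  obj <- list(latent = truth$latent, g = truth$g, pe = truth$pe,
              group_effects = truth$group_effects,
              cohort_effects = truth$cohort_effects,
              params = truth$params, seed = seed)
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor",
                       dataframe = "columns")
  invisible(path)
}
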