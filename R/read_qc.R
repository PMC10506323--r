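## Demultiplexing, quality trimming and sample-level QC.

#' Demultiplex barcoded reads
#'
#' A read is assigned to a sample if and only if it begins with that
#' sample's exact barcode immediately followed by the exact cut-site remnant
#' (no mismatches in barcode or cut site).  The barcode is removed and the
#' remnant retained, so assigned reads begin at the cut site.  Everything
#' else is counted as unassigned.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param barcode_table data.frame with columns `sample_id`, `barcode`;
#'   barcodes must be unique and prefix-free within the library.
#' @param remnant the cut-site remnant expected after the barcode.
#' @return list with `samples` (named list of per-sample read data.frames)
#'   and `unassigned` (count).
#' @export
demultiplex <- function(reads, barcode_table, remnant = PSTI_REMNANT) {
  if (anyDuplicated(barcode_table$barcode))
    stopf("duplicate barcodes in barcode table")
  bc <- barcode_table$barcode
  if (length(bc) > 1) {
    pre <- outer(bc, bc, function(a, b) startsWith(b, a)) & !diag(length(bc))
    if (any(pre)) stopf("barcode table is not prefix-free")
  }
  samples <- setNames(vector("list", length(bc)), barcode_table$sample_id)
  assigned <- rep(FALSE, nrow(reads))
  for (i in seq_along(bc)) {
    key <- paste0(bc[i], remnant)
    sel <- !assigned & startsWith(reads$seq, key)
    keep <- reads[sel, , drop = FALSE]
    keep$seq <- substring(keep$seq, nchar(bc[i]) + 1L)
    keep$qual <- substring(keep$qual, nchar(bc[i]) + 1L)
    samples[[i]] <- keep
    assigned <- assigned | sel
  }
  list(samples = samples, unassigned = sum(!assigned))
}

#' Quality-trim reads at the 3' end
#'
#' Implements the partial-sum rule used by BWA and Cutadapt: qualities are
#' replaced by `q - quality`, partial sums are accumulated from the 3' end,
#' and the read is cut where that sum is maximal (no cut if the maximum is
#' not positive).  Reads shorter than `min_len` after trimming are
#' discarded.  Only the 3' end is trimmed: the 5' end is barcode plus
#' remnant and has already been validated exactly.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (Phred+33).
#' @param q quality threshold (default 20).
#' @param min_len minimum retained length (default 40).
#' @return the trimmed reads (discarded rows removed), with attribute
#'   `n_discarded`.
#' @export
quality_trim <- function(reads, q = 20, min_len = 40) {
  if (!nrow(reads)) return(structure(reads, n_discarded = 0L))
  ## reads share few distinct quality strings; trim each pattern once
  uq <- unique(reads$qual)
  keep_len <- vapply(uq, function(s) {
    qs <- utf8ToInt(s) - 33L
    run <- cumsum(rev(q - qs))
    m <- max(run)
    if (m <= 0) length(qs) else length(qs) - which.max(run)
  }, integer(1))
  len <- keep_len[match(reads$qual, uq)]
  out <- reads
  out$seq <- substr(out$seq, 1L, len)
  out$qual <- substr(out$qual, 1L, len)
  drop <- len < min_len
  structure(out[!drop, , drop = FALSE], n_discarded = sum(drop))
}

#' Sample-level pass/fail rule
#'
#' A sample fails when fewer than `min_reads` reads survive quality control.
#' The boundary is inclusive: exactly `min_reads` passes.
#'
#' @param n_kept reads surviving QC.
#' @param min_reads threshold (default 100000; configurable for toy scale).
#' @return `"pass"` or `"fail"`.
#' @export
sample_pass <- function(n_kept, min_reads = 100000) {
  stopifnot(n_kept >= 0)
  ifelse(n_kept < min_reads, "fail", "pass")
}

#' Demultiplex and trim one library, with a QC report
#'
#' @param reads raw library reads (data.frame `id`, `seq`, `qual`).
#' @param barcode_table as in [demultiplex()].
#' @param q,min_len trimming parameters, see [quality_trim()].
#' @param min_reads pass/fail threshold, see [sample_pass()].
#' @return list with `samples` (per-sample trimmed reads), `report`
#'   (data.frame: sample, n_raw, n_kept, mean_length, status) and
#'   `unassigned`.
#' @export
run_qc <- function(reads, barcode_table, q = 20, min_len = 40,
                   min_reads = 100000) {
  dm <- demultiplex(reads, barcode_table)
  trimmed <- lapply(dm$samples, quality_trim, q = q, min_len = min_len)
  report <- data.frame(
    sample = names(trimmed),
    n_raw = vapply(dm$samples, nrow, integer(1)),
    n_kept = vapply(trimmed, nrow, integer(1)),
    mean_length = vapply(trimmed, function(x)
      if (nrow(x)) mean(nchar(x$seq)) else NA_real_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  report$status <- sample_pass(report$n_kept, min_reads)
  list(samples = trimmed, report = report, unassigned = dm$unassigned)
}
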