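# Per-cell quality-control gate on precomputed sample metrics.

#' QC thresholds
#'
#' The per-cell gate: total reads > 0.25 million, percentage of reads
#' mapping to known exons > 40, genes detected > 6000, and ratio of reads
#' mapping to ERCC spike-ins < 0.6. All comparisons are strict.
#'
#' @param min_total_reads,min_pct_exonic,min_genes,max_ercc_ratio thresholds.
#' @return a list of class `tcr_qc_thresholds`.
#' @export
qc_thresholds <- function(min_total_reads = 250000, min_pct_exonic = 40,
                          min_genes = 6000, max_ercc_ratio = 0.6) {
  stopifnot(min_total_reads > 0, min_pct_exonic > 0, min_genes > 0,
            max_ercc_ratio > 0)
  structure(list(min_total_reads = min_total_reads,
                 min_pct_exonic = min_pct_exonic, min_genes = min_genes,
                 max_ercc_ratio = max_ercc_ratio),
            class = "tcr_qc_thresholds")
}

#' Apply the per-cell QC gate
#'
#' @param metrics data.frame with columns `sample_id`, `total_reads`,
#'   `pct_exonic`, `genes_detected`, `ercc_ratio`.
#' @param thr a [qc_thresholds()].
#' @return list: `pass` (passing rows), `fail` (failing rows with a
#'   `reasons` column listing every violated criterion).
#' @export
qc_filter <- function(metrics, thr = qc_thresholds()) {
  need <- c("sample_id", "total_reads", "pct_exonic", "genes_detected",
            "ercc_ratio")
  if (!all(need %in% names(metrics)))
    stop("metrics must have columns: ", paste(need, collapse = ", "))
  m <- metrics
  if (any(is.na(m[need])) ||
      any(m$total_reads < 0) || any(m$pct_exonic < 0) ||
      any(m$pct_exonic > 100) || any(m$genes_detected < 0) ||
      any(m$ercc_ratio < 0) || any(m$ercc_ratio > 1))
    stop("malformed metrics row(s)")
  viol <- cbind(
    low_total_reads = !(m$total_reads > thr$min_total_reads),
    low_pct_exonic = !(m$pct_exonic > thr$min_pct_exonic),
    low_genes_detected = !(m$genes_detected > thr$min_genes),
    high_ercc_ratio = !(m$ercc_ratio < thr$max_ercc_ratio))
  ok <- rowSums(viol) == 0
  fail <- m[!ok, , drop = FALSE]
  fail$reasons <- apply(viol[!ok, , drop = FALSE], 1, function(v)
    paste(colnames(viol)[v], collapse = ","))
  rownames(fail) <- NULL
  pass <- m[ok, , drop = FALSE]
  rownames(pass) <- NULL
  list(pass = pass, fail = fail)
}

#' Read a QC metrics TSV
#'
#' @param path TSV with the [qc_filter()] metric columns.
#' @return the metrics data.frame.
#' @export
read_qc_metrics <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
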