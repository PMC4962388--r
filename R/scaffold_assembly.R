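# V-C scaffold construction, read-pair-anchored gap filling, chain
# annotation, and output writing.

#' Gap-filling configuration
#'
#' Maps the classic gap-filler semantics onto native parameters: base
#' agreement ratio 0.7, minimum supporting reads tied to the consensus
#' minimum coverage, realized-gap tolerance of plus or minus 50 percent, and
#' a minimum anchoring overlap of 20 bases (auto-reduced for very short
#' reads).
#'
#' @param min_overlap minimum read/contig-edge overlap for anchoring;
#'   effectively `min(min_overlap, max(10, median_read_length - 15))`.
#' @param min_reads_per_base reads required to call an extension base
#'   (`NULL`: use the consensus `min_coverage`).
#' @param base_agreement_ratio required majority fraction for the called base.
#' @param gap_tolerance accepted relative deviation of the realized gap from
#'   the scaffold gap estimate.
#' @param insert_size_mean library insert size (bp); bounds read-pair
#'   recruitment distance from the gap edge. Dataset-specific (e.g. 148 for
#'   Jurkat-like, 175 for C1 mouse-like libraries; simulations use the
#'   simulated fragment mean).
#' @param max_rounds improvement rounds for anchoring/extension.
#' @param max_mismatch mismatches tolerated in an anchoring overlap.
#' @return a list of class `tcr_gapfill_config`.
#' @export
gapfill_config <- function(min_overlap = 20L, min_reads_per_base = NULL,
                           base_agreement_ratio = 0.7, gap_tolerance = 0.5,
                           insert_size_mean = 175L, max_rounds = 3L,
                           max_mismatch = 2L) {
  stopifnot(base_agreement_ratio >= 0.5, base_agreement_ratio <= 1,
            min_overlap >= 5)
  structure(list(min_overlap = as.integer(min_overlap),
                 min_reads_per_base = min_reads_per_base,
                 base_agreement_ratio = base_agreement_ratio,
                 gap_tolerance = gap_tolerance,
                 insert_size_mean = as.integer(insert_size_mean),
                 max_rounds = as.integer(max_rounds),
                 max_mismatch = as.integer(max_mismatch)),
            class = "tcr_gapfill_config")
}

#' Build gapped V-C scaffolds
#'
#' Each V contig is concatenated to each C contig of the locus with three
#' junction-facing bases trimmed from either side (`end_trim`) and an N-run
#' of the estimated mean gap length in between.
#'
#' @param v_contigs,c_contigs lists of `tcr_contig` objects (one locus).
#' @param gap a `tcr_gap_estimate` for the locus.
#' @param end_trim bases trimmed from the V 3' and C 5' junction-facing ends.
#' @param locus locus label.
#' @return list of `tcr_scaffold` objects, ordered by (V name, C name).
#'   Empty V or C input gives an empty list.
#' @export
build_scaffolds <- function(v_contigs, c_contigs, gap, end_trim = 3L,
                            locus = NA_character_) {
  if (length(v_contigs) == 0 || length(c_contigs) == 0) return(list())
  stopifnot(gap$mean_gap >= 0)
  vord <- order(vapply(v_contigs, `[[`, "", "gene_name"))
  cord <- order(vapply(c_contigs, `[[`, "", "gene_name"))
  out <- list()
  for (v in v_contigs[vord]) for (cc in c_contigs[cord]) {
    vseq <- v$sequence; cseq <- cc$sequence
    stopifnot(nchar(vseq) > end_trim, nchar(cseq) > end_trim)
    vtrim <- substr(vseq, 1L, nchar(vseq) - end_trim)
    ctrim <- substr(cseq, end_trim + 1L, nchar(cseq))
    nv <- nchar(vtrim); ng <- gap$mean_gap; nc <- nchar(ctrim)
    out[[length(out) + 1L]] <- structure(list(
      locus = locus, v_contig = v, c_contig = cc,
      v_gene = v$gene_name, c_gene = cc$gene_name,
      end_trim = as.integer(end_trim), gap_len = as.integer(ng),
      sequence = paste0(vtrim, strrep("N", ng), ctrim),
      v_flank = vtrim, c_flank = ctrim,
      v_flank_interval = c(1L, nv),
      gap_interval = c(nv + 1L, nv + ng),
      c_flank_interval = c(nv + ng + 1L, nv + ng + nc)),
      class = "tcr_scaffold")
  }
  out
}

gapfill_rejection <- function(scaffold, reason) {
  structure(list(locus = scaffold$locus, v_gene = scaffold$v_gene,
                 c_gene = scaffold$c_gene, reason = reason),
            class = "tcr_rejection")
}

# Recruit gap-filling candidate reads for a scaffold: pairs where one mate
# aligns within a flank, oriented toward the gap, within recruiting distance
# of the gap edge. Candidates are returned oriented to the scaffold forward
# strand; they comprise the anchored mates themselves (whose overhang may
# reach into the gap) and, when the fragment extends toward the gap, their
# partners.
recruit_gap_candidates <- function(scaffold, pairs, hits, cfg) {
  a <- hits$assignments
  reach <- cfg$insert_size_mean +
    max(50L, round_half_up(cfg$gap_tolerance * scaffold$gap_len)) +
    2L * scaffold$end_trim
  vlen <- nchar(scaffold$v_contig$sequence)
  idx <- match(a$read_id, pairs$id)
  mate_seq <- ifelse(a$mate == 1L, pairs$seq1[idx], pairs$seq2[idx])
  partner_seq <- ifelse(a$mate == 1L, pairs$seq2[idx], pairs$seq1[idx])
  out <- character()
  # V-flank anchors near the V 3' end
  hv <- which(a$gene_name == scaffold$v_gene & a$g_end >= vlen - reach)
  for (i in hv) {
    if (a$strand[i] == "+") {
      out <- c(out, mate_seq[i], revcomp(partner_seq[i]))
    } else {
      out <- c(out, revcomp(mate_seq[i]))
    }
  }
  # C-flank anchors near the C 5' start
  hc <- which(a$gene_name == scaffold$c_gene & a$g_start <= reach)
  for (i in hc) {
    if (a$strand[i] == "-") {
      out <- c(out, revcomp(mate_seq[i]), partner_seq[i])
    } else {
      out <- c(out, mate_seq[i])
    }
  }
  unique(out)
}

#' Close a scaffold gap by read-pair-anchored consensus extension
#'
#' Recruited candidate reads extend the V flank rightward and the C flank
#' leftward one base at a time; an extension base requires at least
#' `min_reads_per_base` supporting reads at `base_agreement_ratio` majority,
#' with reads anchored to the growing edge by an overlap of at least the
#' effective minimum with at most `max_mismatch` mismatches. The junction is
#' closed when the two extensions (or one extension and the opposite flank)
#' share an exact overlap of at least the minimum; the closure is accepted
#' iff the realized gap (junction length minus the regrown trimmed bases) is
#' within `gap_tolerance` of the scaffold gap estimate. Otherwise a
#' `tcr_rejection` with reason `no_candidates`, `extension_stalled`,
#' `no_closure` or `gap_length_out_of_tolerance` is returned.
#'
#' @param scaffold a `tcr_scaffold`.
#' @param pairs trimmed `tcr_read_pairs`.
#' @param cfg a [gapfill_config()].
#' @param hits optional `tcr_hits` for the same `pairs`; when `NULL`, the
#'   pairs are mapped against the scaffold's own contigs.
#' @return a `tcr_chain` (closed) or a `tcr_rejection`.
#' @export
fill_gap <- function(scaffold, pairs, cfg = gapfill_config(), hits = NULL) {
  if (!grepl("N", scaffold$sequence, fixed = TRUE) && scaffold$gap_len > 0)
    stop("malformed scaffold: no N-run")
  min_reads <- cfg$min_reads_per_base
  if (is.null(min_reads)) min_reads <- 5L
  if (nrow(pairs) == 0) return(gapfill_rejection(scaffold, "no_candidates"))
  if (is.null(hits)) {
    ref2 <- new_tcr_reference(data.frame(
      locus = rep(if (is.na(scaffold$locus)) "TRA" else scaffold$locus, 2),
      segment = c("V", "C"),
      gene_name = c(scaffold$v_gene, scaffold$c_gene),
      allele_id = "01",
      sequence = c(scaffold$v_contig$sequence, scaffold$c_contig$sequence),
      stringsAsFactors = FALSE), "scaffold-contigs")
    hits <- map_reads(pairs, ref2)
  }
  mo <- effective_min_overlap(cfg, pairs)
  if (nchar(scaffold$v_flank) < mo || nchar(scaffold$c_flank) < mo)
    stop("scaffold flanks shorter than the minimum anchoring overlap")
  cand <- recruit_gap_candidates(scaffold, pairs, hits, cfg)
  if (length(cand) == 0) return(gapfill_rejection(scaffold, "no_candidates"))
  gap_lower <- round_half_up((1 - cfg$gap_tolerance) * scaffold$gap_len)
  gap_upper <- round_half_up((1 + cfg$gap_tolerance) * scaffold$gap_len)
  max_ext <- gap_upper + 2L * scaffold$end_trim + mo + 30L
  vx <- cpp_extend_contig(scaffold$v_flank, cand, mo, cfg$max_mismatch,
                          min_reads, cfg$base_agreement_ratio, max_ext)
  cxr <- cpp_extend_contig(revcomp(scaffold$c_flank), revcomp(cand), mo,
                           cfg$max_mismatch, min_reads,
                           cfg$base_agreement_ratio, max_ext)
  A <- vx$seq
  B <- revcomp(cxr$seq)
  nA <- nchar(A); nB <- nchar(B)
  splice <- 0L
  kmax <- min(nA, nB)
  if (kmax >= mo) {
    for (k in seq.int(kmax, mo, by = -1L)) {
      if (substr(A, nA - k + 1L, nA) == substr(B, 1L, k)) { splice <- k; break }
    }
  }
  if (splice == 0L) {
    reason <- if (vx$n_appended == 0L && cxr$n_appended == 0L)
      "extension_stalled" else "no_closure"
    return(gapfill_rejection(scaffold, reason))
  }
  merged <- paste0(A, substr(B, splice + 1L, nB))
  nvf <- nchar(scaffold$v_flank); ncf <- nchar(scaffold$c_flank)
  junction_len <- nchar(merged) - nvf - ncf
  realized_gap <- junction_len - 2L * scaffold$end_trim
  if (junction_len < 0 || realized_gap < gap_lower || realized_gap > gap_upper)
    return(gapfill_rejection(scaffold, "gap_length_out_of_tolerance"))
  support <- c(vx$support, rev(cxr$support))
  structure(list(locus = scaffold$locus, sequence = merged,
                 v_gene = scaffold$v_gene, c_gene = scaffold$c_gene,
                 v_contig = scaffold$v_contig, c_contig = scaffold$c_contig,
                 end_trim = scaffold$end_trim,
                 junction_interval = c(nvf + 1L, nvf + junction_len),
                 junction_mean_coverage =
                   if (length(support)) mean(support) else NA_real_),
            class = "tcr_chain")
}

# auto-reduction of the anchoring overlap for very short reads; the read
# length is taken from a bounded sample of pairs
effective_min_overlap <- function(cfg, pairs) {
  n <- min(nrow(pairs), 10000L)
  med <- stats::median(c(nchar(pairs$seq1[seq_len(n)]),
                         nchar(pairs$seq2[seq_len(n)])))
  max(10L, min(cfg$min_overlap, as.integer(med) - 15L))
}

#' @export
print.tcr_chain <- function(x, ...) {
  cat(sprintf("<tcr_chain> %s %s..%s, %d bp, junction %d-%d\n", x$locus,
              x$v_gene, x$c_gene, nchar(x$sequence),
              x$junction_interval[1], x$junction_interval[2]))
  invisible(x)
}
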