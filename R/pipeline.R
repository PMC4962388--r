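# Per-cell and cohort orchestration: trim -> map -> candidates -> consensus
# -> scaffold -> gap-fill -> annotate, plus FASTQ I/O.

#' Pipeline configuration
#'
#' Bundles the stage configurations with the reference. `edge_trim =
#' "auto"` gates full-gene coverage on the alignable span of each gene: the
#' minimal E-value-significant overlap (about 23-24 bp under default
#' scoring) is excluded at the termini, because positions closer to a gene
#' end cannot receive significant aligned coverage at any depth. Set
#' `edge_trim = 0` for strict full-length gating.
#'
#' @param reference a `tcr_reference` with V, C and J (and TRB D) genes.
#' @param evalue_max mapping E-value cutoff.
#' @param trim a [trim_config()].
#' @param candidate a [candidate_config()].
#' @param gapfill a [gapfill_config()].
#' @param end_trim junction-facing bases trimmed from V/C consensus ends.
#' @param edge_trim `"auto"` or an integer for the coverage gate.
#' @param loci loci to reconstruct.
#' @param seed optional seed recorded in the config.
#' @param out_dir optional output directory for [run_cell()] artifacts.
#' @return a list of class `tcr_pipeline_config`.
#' @export
pipeline_config <- function(reference, evalue_max = 1e-8,
                            trim = trim_config(),
                            candidate = candidate_config(),
                            gapfill = gapfill_config(),
                            end_trim = 3L, edge_trim = "auto",
                            loci = NULL, seed = NULL, out_dir = NULL) {
  stopifnot(inherits(reference, "tcr_reference"))
  if (is.null(loci)) loci <- sort(unique(reference$genes$locus))
  structure(list(reference = reference, evalue_max = evalue_max,
                 trim = trim, candidate = candidate, gapfill = gapfill,
                 end_trim = as.integer(end_trim), edge_trim = edge_trim,
                 loci = loci, seed = seed, out_dir = out_dir),
            class = "tcr_pipeline_config")
}

# minimal read/gene overlap that can reach the E-value threshold: the
# alignability bound used by edge_trim = "auto"
alignable_edge <- function(hits, read_len, evalue_max) {
  n_max <- max(hits$class_len)
  lambda <- hits$params$lambda
  s_min <- log(hits$params$K * read_len * n_max / evalue_max) / lambda
  as.integer(ceiling(s_min / hits$params$match))
}

#' Run the reconstruction pipeline on an in-memory read set
#'
#' @param pairs a `tcr_read_pairs` table (untrimmed).
#' @param cfg a [pipeline_config()].
#' @return a `tcr_cell_result`: `usage` (per class), `contigs`, `chains`,
#'   `annotations`, `rejects`, `hits`, `n_pairs_in`, `n_pairs_trimmed`.
#' @export
run_cell_pairs <- function(pairs, cfg) {
  stopifnot(inherits(cfg, "tcr_pipeline_config"))
  ref <- cfg$reference
  n_in <- nrow(pairs)
  trimmed <- trim_reads(pairs, cfg$trim)
  empty <- structure(list(usage = list(), contigs = list(), chains = list(),
                          annotations = list(),
                          rejects = data.frame(locus = character(),
                                               v_gene = character(),
                                               c_gene = character(),
                                               reason = character(),
                                               stringsAsFactors = FALSE),
                          hits = NULL, n_pairs_in = n_in,
                          n_pairs_trimmed = nrow(trimmed)),
                     class = "tcr_cell_result")
  if (nrow(trimmed) == 0) return(empty)
  hits <- map_reads(trimmed, ref, evalue_max = cfg$evalue_max)
  edge <- cfg$edge_trim
  if (identical(edge, "auto")) {
    rl <- max(nchar(c(trimmed$seq1, trimmed$seq2)))
    edge <- alignable_edge(hits, rl, cfg$evalue_max) - 1L
  }
  ccfg <- cfg$candidate
  gate_cfg <- candidate_config(ccfg$candidate_fraction, ccfg$min_coverage,
                               edge_trim = edge)
  contigs <- list()
  per_locus <- list()
  for (locus in cfg$loci) {
    per_locus[[locus]] <- list(V = list(), C = list())
    for (seg in c("V", "C")) {
      cls <- paste0(locus, seg)
      cands <- select_candidates(hits, cls, ccfg)
      kept <- list()
      for (gene in cands) {
        g <- ref_genes(ref, locus, seg)
        g <- g[g$gene_name == gene, , drop = FALSE]
        ar <- assigned_reads(hits, trimmed, cls, gene)
        p <- build_pileup(ar$seq, g, ar$hits)
        if (!coverage_gate(p, gate_cfg)) next
        kept[[length(kept) + 1L]] <-
          call_consensus(p, class = cls, locus = locus, ref_seq = g$sequence)
      }
      kept <- dedupe_subsequences(kept)
      per_locus[[locus]][[seg]] <- kept
      contigs <- c(contigs, kept)
    }
  }
  chains <- list(); rejects <- list()
  for (locus in cfg$loci) {
    vt <- per_locus[[locus]]$V; ct <- per_locus[[locus]]$C
    if (length(vt) == 0 || length(ct) == 0) next
    gap <- estimate_gap_bounds(ref, locus)
    scaffolds <- build_scaffolds(vt, ct, gap, end_trim = cfg$end_trim,
                                 locus = locus)
    gf <- cfg$gapfill
    if (is.null(gf$min_reads_per_base))
      gf$min_reads_per_base <- ccfg$min_coverage
    for (sc in scaffolds) {
      res <- fill_gap(sc, trimmed, gf, hits = hits)
      if (inherits(res, "tcr_chain")) chains[[length(chains) + 1L]] <- res
      else rejects[[length(rejects) + 1L]] <- res
    }
  }
  # deduplicate identical closed chains (e.g. homologous C contigs)
  if (length(chains) > 1) {
    seqs <- vapply(chains, `[[`, "", "sequence")
    chains <- chains[!duplicated(seqs)]
  }
  annotations <- lapply(chains, annotate_chain, ref = ref)
  usage <- list()
  for (cl in mapping_classes(ref)) usage[[cl]] <- tally_usage(hits, cl)
  rej_df <- if (length(rejects)) {
    do.call(rbind, lapply(rejects, function(r)
      data.frame(locus = r$locus, v_gene = r$v_gene, c_gene = r$c_gene,
                 reason = r$reason, stringsAsFactors = FALSE)))
  } else empty$rejects
  out <- empty
  out$usage <- usage; out$contigs <- contigs; out$chains <- chains
  out$annotations <- annotations; out$rejects <- rej_df; out$hits <- hits
  if (!is.null(cfg$out_dir)) {
    write_chain_outputs(chains, contigs, annotations, rej_df, cfg$out_dir)
    write_counts_tsv(hits, file.path(cfg$out_dir, "counts.tsv"))
  }
  out
}

#' @export
print.tcr_cell_result <- function(x, ...) {
  cat(sprintf("<tcr_cell_result> %d/%d pairs after trimming, %d contig(s), %d chain(s)\n",
              x$n_pairs_trimmed, x$n_pairs_in, length(x$contigs),
              length(x$chains)))
  invisible(x)
}

#' Read paired FASTQ files into a read-pair table
#'
#' @param r1,r2 FASTQ paths (gzip transparent). Records must be in matching
#'   order; ids are taken from R1 with any `/1` suffix and description
#'   stripped.
#' @return a `tcr_read_pairs` table.
#' @export
read_fastq_pairs <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(s1) != length(s2)) stop("R1/R2 record counts differ")
  ids <- sub("/[12]$", "", sub("[[:space:]].*$", "", names(s1)))
  read_pairs(ids, as.character(s1), as.character(S4Vectors::mcols(s1)$qualities),
             as.character(s2), as.character(S4Vectors::mcols(s2)$qualities))
}

#' Write a read-pair table as paired FASTQ
#'
#' @param pairs a `tcr_read_pairs` table.
#' @param r1,r2 output FASTQ paths.
#' @export
write_fastq_pairs <- function(pairs, r1, r2) {
  fq <- function(id, seq, qual, suffix)
    as.vector(rbind(paste0("@", id, suffix), seq, "+", qual))
  writeLines(fq(pairs$id, pairs$seq1, pairs$qual1, "/1"), r1)
  writeLines(fq(pairs$id, pairs$seq2, pairs$qual2, "/2"), r2)
  invisible(c(r1, r2))
}

#' Run the pipeline on one cell's FASTQ files
#'
#' @param fastq_r1,fastq_r2 paired FASTQ paths.
#' @param cfg a [pipeline_config()]; when `cfg$out_dir` is set, all
#'   artifacts (chains/contigs FASTA, annotation, rejects, counts) are
#'   written there.
#' @return a `tcr_cell_result`.
#' @export
run_cell <- function(fastq_r1, fastq_r2, cfg) {
  pairs <- read_fastq_pairs(fastq_r1, fastq_r2)
  run_cell_pairs(pairs, cfg)
}

#' Run the pipeline over a cohort manifest
#'
#' Applies the QC gate first, then runs each passing sample, collecting
#' per-sample V-usage percentages, V-class totals, the paired (top TRBV,
#' top TRAV) table, and a recovery summary. Missing files or per-sample
#' errors are reported in the summary and do not abort the cohort.
#'
#' @param manifest data.frame with `sample_id`, `r1`, `r2`.
#' @param cfg a [pipeline_config()].
#' @param metrics QC metrics data.frame ([qc_filter()] columns); `NULL`
#'   skips the gate.
#' @param thr a [qc_thresholds()].
#' @return list: `qc`, `usage` (long data.frame sample/class/gene/count/pct),
#'   `totals`, `paired_top`, `summary`, `results` (per-sample cell results).
#' @export
run_cohort <- function(manifest, cfg, metrics = NULL, thr = qc_thresholds()) {
  stopifnot(all(c("sample_id", "r1", "r2") %in% names(manifest)))
  qc <- NULL
  keep <- manifest
  if (!is.null(metrics)) {
    qc <- qc_filter(metrics, thr)
    keep <- manifest[manifest$sample_id %in% qc$pass$sample_id, , drop = FALSE]
  }
  results <- list(); usage_rows <- list(); summary_rows <- list()
  for (i in seq_len(nrow(keep))) {
    sid <- keep$sample_id[i]
    res <- tryCatch(run_cell(keep$r1[i], keep$r2[i], cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      summary_rows[[sid]] <- data.frame(
        sample_id = sid, status = paste0("error: ", conditionMessage(res)),
        n_chains = 0L, n_productive_alpha = 0L, n_productive_beta = 0L,
        top_trav = NA_character_, top_trbv = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    results[[sid]] <- res
    for (cl in names(res$usage)) {
      u <- res$usage[[cl]]
      if (nrow(u)) usage_rows[[length(usage_rows) + 1L]] <-
          data.frame(sample_id = sid, class = cl, u, stringsAsFactors = FALSE)
    }
    prod <- vapply(res$annotations, function(a) isTRUE(a$productive), logical(1))
    loci <- vapply(res$chains, `[[`, "", "locus")
    no_c <- vapply(c(TRA = "TRA", TRB = "TRB"), function(lc)
      length(res$contigs) > 0 &&
        !any(vapply(res$contigs, function(ct)
          identical(ct$class, paste0(lc, "C")), logical(1))), logical(1))
    status <- if (any(no_c)) paste0("no_c_contig:",
                                    paste(names(no_c)[no_c], collapse = "+"))
    else "ok"
    summary_rows[[sid]] <- data.frame(
      sample_id = sid, status = status, n_chains = length(res$chains),
      n_productive_alpha = sum(prod & loci == "TRA"),
      n_productive_beta = sum(prod & loci == "TRB"),
      top_trav = attr(res$usage[["TRAV"]], "top_gene") %||% NA_character_,
      top_trbv = attr(res$usage[["TRBV"]], "top_gene") %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  usage <- if (length(usage_rows)) do.call(rbind, usage_rows)
  else data.frame(sample_id = character(), class = character(),
                  gene_name = character(), count = integer(), pct = numeric())
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows)
  else data.frame(sample_id = character(), status = character(),
                  n_chains = integer(), n_productive_alpha = integer(),
                  n_productive_beta = integer(), top_trav = character(),
                  top_trbv = character())
  rownames(summary) <- NULL
  totals <- if (nrow(usage)) stats::aggregate(count ~ sample_id + class,
                                              usage, sum)
  else data.frame(sample_id = character(), class = character(),
                  count = integer())
  paired_top <- summary[summary$status != "error" &
                          !is.na(summary$top_trav) & !is.na(summary$top_trbv),
                        c("sample_id", "top_trbv", "top_trav"), drop = FALSE]
  list(qc = qc, usage = usage, totals = totals, paired_top = paired_top,
       summary = summary, results = results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a pipeline configuration to a flat key-value file
#'
#' All scalar stage parameters are written as `key = value` lines (the
#' reference itself is not embedded; supply it again on load). Loading and
#' re-serializing is lossless.
#'
#' @param cfg a [pipeline_config()].
#' @param path output path.
#' @export
save_pipeline_config <- function(cfg, path) {
  fmt <- function(x) {
    if (is.null(x)) "NULL"
    else if (is.character(x)) x
    else paste(format(x, digits = 17, scientific = TRUE, trim = TRUE),
               collapse = ",")
  }
  kv <- c(
    evalue_max = fmt(cfg$evalue_max),
    trim.quality_cutoff = fmt(cfg$trim$quality_cutoff),
    trim.adapter_min_overlap = fmt(cfg$trim$adapter_min_overlap),
    trim.adapter_sequence = fmt(cfg$trim$adapter_sequence),
    trim.min_length_after_trim = fmt(cfg$trim$min_length_after_trim),
    candidate.candidate_fraction = fmt(cfg$candidate$candidate_fraction),
    candidate.min_coverage = fmt(cfg$candidate$min_coverage),
    candidate.edge_trim = fmt(cfg$candidate$edge_trim),
    gapfill.min_overlap = fmt(cfg$gapfill$min_overlap),
    gapfill.min_reads_per_base = fmt(cfg$gapfill$min_reads_per_base),
    gapfill.base_agreement_ratio = fmt(cfg$gapfill$base_agreement_ratio),
    gapfill.gap_tolerance = fmt(cfg$gapfill$gap_tolerance),
    gapfill.insert_size_mean = fmt(cfg$gapfill$insert_size_mean),
    gapfill.max_rounds = fmt(cfg$gapfill$max_rounds),
    gapfill.max_mismatch = fmt(cfg$gapfill$max_mismatch),
    end_trim = fmt(cfg$end_trim),
    edge_trim = fmt(cfg$edge_trim),
    loci = paste(cfg$loci, collapse = ","),
    seed = fmt(cfg$seed))
  writeLines(paste(names(kv), kv, sep = " = "), path)
  invisible(path)
}

#' Load a pipeline configuration from a flat key-value file
#'
#' @param path file written by [save_pipeline_config()].
#' @param reference the `tcr_reference` to attach.
#' @return a [pipeline_config()].
#' @export
load_pipeline_config <- function(path, reference) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  num <- function(k) {
    v <- vals[[k]]
    if (identical(v, "NULL")) NULL else as.numeric(v)
  }
  int <- function(k) {
    v <- num(k)
    if (is.null(v)) NULL else as.integer(v)
  }
  edge <- vals[["edge_trim"]]
  if (!identical(edge, "auto")) edge <- as.integer(as.numeric(edge))
  pipeline_config(
    reference, evalue_max = num("evalue_max"),
    trim = trim_config(int("trim.quality_cutoff"),
                       int("trim.adapter_min_overlap"),
                       vals[["trim.adapter_sequence"]],
                       int("trim.min_length_after_trim")),
    candidate = candidate_config(num("candidate.candidate_fraction"),
                                 int("candidate.min_coverage"),
                                 int("candidate.edge_trim")),
    gapfill = gapfill_config(int("gapfill.min_overlap"),
                             int("gapfill.min_reads_per_base"),
                             num("gapfill.base_agreement_ratio"),
                             num("gapfill.gap_tolerance"),
                             int("gapfill.insert_size_mean"),
                             int("gapfill.max_rounds"),
                             int("gapfill.max_mismatch")),
    end_trim = int("end_trim"), edge_trim = edge,
    loci = strsplit(vals[["loci"]], ",", fixed = TRUE)[[1]],
    seed = num("seed"))
}
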