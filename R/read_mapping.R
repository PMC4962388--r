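# Read trimming and class-wise gene assignment by significant local alignment.

#' Construct a paired-read table
#'
#' The in-memory read-pair container used throughout: one row per pair with
#' `id`, `seq1`, `qual1`, `seq2`, `qual2`. Mates must match their quality
#' strings in length.
#'
#' @param id read-pair identifiers (unique).
#' @param seq1,seq2 mate sequences (DNA).
#' @param qual1,qual2 Phred+33 quality strings.
#' @return a data.frame of class `tcr_read_pairs`.
#' @export
read_pairs <- function(id, seq1, qual1, seq2, qual2) {
  stopifnot(length(id) == length(seq1), length(seq1) == length(seq2))
  if (any(nchar(seq1) != nchar(qual1)) || any(nchar(seq2) != nchar(qual2)))
    stop("sequence/quality length mismatch")
  structure(data.frame(id = as.character(id), seq1 = seq1, qual1 = qual1,
                       seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE),
            class = c("tcr_read_pairs", "data.frame"))
}

#' Trimming configuration
#'
#' Defaults follow standard whole-transcript scRNA-seq preprocessing: 3'
#' quality trimming at Phred 20 and adapter removal at a minimum
#' suffix/prefix overlap of 5 bases.
#'
#' @param quality_cutoff Phred cutoff for 3' quality trimming.
#' @param adapter_min_overlap minimum read-suffix/adapter-prefix overlap.
#' @param adapter_sequence adapter to remove; `""` disables adapter trimming.
#' @param min_length_after_trim pairs with either mate shorter than this
#'   after trimming are dropped as a pair.
#' @return a list of class `tcr_trim_config`.
#' @export
trim_config <- function(quality_cutoff = 20L, adapter_min_overlap = 5L,
                        adapter_sequence = "AGATCGGAAGAGC",
                        min_length_after_trim = 20L) {
  stopifnot(quality_cutoff >= 0, adapter_min_overlap >= 1)
  structure(list(quality_cutoff = as.integer(quality_cutoff),
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 adapter_sequence = adapter_sequence,
                 min_length_after_trim = as.integer(min_length_after_trim)),
            class = "tcr_trim_config")
}

#' Trim paired reads
#'
#' 3' bases are removed where the running sum of (cutoff - quality) over a
#' suffix is maximal and positive; a 3' adapter contamination is removed when
#' the read suffix matches the adapter prefix over at least
#' `adapter_min_overlap` bases. Pairs where either mate falls below
#' `min_length_after_trim` are dropped as a pair.
#'
#' @param pairs a `tcr_read_pairs` table.
#' @param cfg a [trim_config()].
#' @return the trimmed `tcr_read_pairs` table.
#' @export
trim_reads <- function(pairs, cfg = trim_config()) {
  if (nrow(pairs) == 0) return(pairs)
  t1 <- cpp_trim(pairs$seq1, pairs$qual1, cfg$quality_cutoff,
                 cfg$adapter_sequence, cfg$adapter_min_overlap)
  t2 <- cpp_trim(pairs$seq2, pairs$qual2, cfg$quality_cutoff,
                 cfg$adapter_sequence, cfg$adapter_min_overlap)
  keep <- nchar(t1$seq) >= cfg$min_length_after_trim &
    nchar(t2$seq) >= cfg$min_length_after_trim
  out <- data.frame(id = pairs$id[keep], seq1 = t1$seq[keep], qual1 = t1$qual[keep],
                    seq2 = t2$seq[keep], qual2 = t2$qual[keep],
                    stringsAsFactors = FALSE)
  structure(out, class = c("tcr_read_pairs", "data.frame"))
}

# gene classes used by the mapper for the loci present in a reference
mapping_classes <- function(ref) {
  loci <- sort(unique(ref$genes$locus))
  cls <- as.vector(t(outer(loci, c("V", "C"), paste0)))
  for (cl in cls) {
    locus <- substr(cl, 1, 3); seg <- substr(cl, 4, 4)
    if (nrow(ref_genes(ref, locus, seg)) == 0)
      stop("reference has no ", seg, " genes for locus ", locus)
  }
  cls
}

#' Map reads to germline V and C gene classes
#'
#' Each mate is aligned locally (seed-and-extend, affine-gap Smith-Waterman,
#' match +2 / mismatch -3 / gap 5 + 2 per base) against every gene of each
#' class (TRAV/TRBV/TRAC/TRBC) on both strands. A hit is recorded when its
#' Karlin-Altschul expectation value \eqn{E = K m n e^{-\lambda S}} (m =
#' read length, n = total class database length) is at most `evalue_max`.
#' Per (mate, class) the best hit - lowest E-value, ties by score then
#' lexicographic gene name - becomes the assignment and increments that
#' gene's read count.
#'
#' @param pairs a `tcr_read_pairs` table (trimmed).
#' @param ref a `tcr_reference` with V and C genes for its loci.
#' @param evalue_max expectation-value cutoff (default `1e-8`).
#' @param seed_len exact seed length for the seed-and-extend search.
#' @param match,mismatch,gap_open,gap_ext scoring scheme.
#' @return a `tcr_hits` object: `counts` (class, gene_name, count over all
#'   database genes), `assignments` (one row per retained mate/class best
#'   hit), `evalue_max`, and the per-class database lengths.
#' @export
map_reads <- function(pairs, ref, evalue_max = 1e-8, seed_len = 11L,
                      match = 2L, mismatch = -3L, gap_open = 5L, gap_ext = 2L) {
  cls <- mapping_classes(ref)
  gene_tab <- do.call(rbind, lapply(cls, function(cl) {
    g <- ref_genes(ref, substr(cl, 1, 3), substr(cl, 4, 4))
    data.frame(class = cl, gene_name = g$gene_name, sequence = g$sequence,
               stringsAsFactors = FALSE)
  }))
  gene_tab <- gene_tab[order(gene_tab$class, gene_tab$gene_name), , drop = FALSE]
  class_levels <- unique(gene_tab$class)
  class_len <- vapply(class_levels,
                      function(cl) sum(nchar(gene_tab$sequence[gene_tab$class == cl])),
                      numeric(1))
  reads <- c(pairs$seq1, pairs$seq2)
  read_id <- c(pairs$id, pairs$id)
  mate <- rep(c(1L, 2L), each = nrow(pairs))
  lambda <- karlin_lambda(match, mismatch)
  # extension gate: safely below the minimal E-value-feasible score (slack
  # of two gap openings for gapped rescue of split ungapped segments)
  s_min <- log(KA_K_DEFAULT * max(nchar(reads), 1) * max(class_len) /
                 evalue_max) / lambda
  gate <- max(26L, as.integer(ceiling(s_min)) - 2L * (gap_open + gap_ext))
  hits <- cpp_map_reads(reads, gene_tab$sequence,
                        as.integer(match(gene_tab$class, class_levels)) - 1L,
                        as.numeric(class_len), lambda, KA_K_DEFAULT,
                        evalue_max, as.integer(seed_len), match, mismatch,
                        gap_open, gap_ext, gate = gate)
  assignments <- data.frame(
    read_id = read_id[hits$read], mate = mate[hits$read],
    class = class_levels[hits$class], gene_name = gene_tab$gene_name[hits$gene],
    strand = hits$strand, score = hits$score, evalue = hits$evalue,
    r_start = hits$r_start, r_end = hits$r_end,
    g_start = hits$g_start, g_end = hits$g_end, cigar = hits$cigar,
    read_index = hits$read, stringsAsFactors = FALSE)
  cnt <- table(factor(paste(assignments$class, assignments$gene_name, sep = "\r"),
                      levels = paste(gene_tab$class, gene_tab$gene_name, sep = "\r")))
  counts <- data.frame(class = gene_tab$class, gene_name = gene_tab$gene_name,
                       count = as.integer(cnt), stringsAsFactors = FALSE)
  structure(list(counts = counts, assignments = assignments,
                 evalue_max = evalue_max, class_len = class_len,
                 params = list(seed_len = seed_len, match = match,
                               mismatch = mismatch, gap_open = gap_open,
                               gap_ext = gap_ext, lambda = lambda,
                               K = KA_K_DEFAULT)),
            class = "tcr_hits")
}

#' @export
print.tcr_hits <- function(x, ...) {
  cat("<tcr_hits>", nrow(x$assignments), "assignments, evalue <=",
      format(x$evalue_max), "\n")
  nz <- x$counts[x$counts$count > 0, , drop = FALSE]
  print(utils::head(nz[order(-nz$count), ], 10))
  invisible(x)
}

#' Per-gene usage summary for one gene class
#'
#' @param hits a `tcr_hits` object.
#' @param class gene class, e.g. `"TRBV"`.
#' @return data.frame (gene_name, count, pct) ordered by descending count;
#'   attributes `top_gene` and `top_pct` name the modal gene. Empty classes
#'   give an empty summary.
#' @export
tally_usage <- function(hits, class) {
  cc <- hits$counts[hits$counts$class == class & hits$counts$count > 0, , drop = FALSE]
  if (nrow(cc) == 0 || sum(cc$count) == 0) {
    out <- data.frame(gene_name = character(), count = integer(), pct = numeric())
    attr(out, "top_gene") <- NA_character_
    attr(out, "top_pct") <- NA_real_
    return(out)
  }
  cc <- cc[order(-cc$count, cc$gene_name), , drop = FALSE]
  out <- data.frame(gene_name = cc$gene_name, count = cc$count,
                    pct = 100 * cc$count / sum(cc$count), stringsAsFactors = FALSE)
  attr(out, "top_gene") <- out$gene_name[1]
  attr(out, "top_pct") <- out$pct[1]
  out
}

#' Write the per-sample counts table
#'
#' @param hits a `tcr_hits` object.
#' @param path output TSV path (class, gene_name, read_count).
#' @export
write_counts_tsv <- function(hits, path) {
  df <- hits$counts
  names(df)[3] <- "read_count"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
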