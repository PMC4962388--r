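# Candidate gene selection, pileup construction, the full-gene coverage gate,
# consensus calling, and substring de-duplication of candidate contigs.

#' Candidate/consensus configuration
#'
#' @param candidate_fraction a gene becomes a candidate when it attracts
#'   strictly more than this fraction of the reads mapping to its class.
#' @param min_coverage minimum pileup depth required at every position of
#'   the gene (the full-gene coverage gate; inclusive, depth >= 5 passes).
#' @param edge_trim number of bases at each gene terminus excluded from the
#'   gate. The default 0 gates the entire gene strictly; pipeline runs may
#'   raise it to the minimal E-value-significant overlap, below which gene
#'   termini cannot receive aligned coverage at any depth.
#' @return a list of class `tcr_candidate_config`.
#' @export
candidate_config <- function(candidate_fraction = 0.10, min_coverage = 5L,
                             edge_trim = 0L) {
  stopifnot(candidate_fraction > 0, candidate_fraction <= 1, min_coverage >= 1,
            edge_trim >= 0)
  structure(list(candidate_fraction = candidate_fraction,
                 min_coverage = as.integer(min_coverage),
                 edge_trim = as.integer(edge_trim)),
            class = "tcr_candidate_config")
}

#' Select candidate genes of a class by read fraction
#'
#' Returns the genes whose read count strictly exceeds
#' `candidate_fraction` of the class total (a gene at exactly the threshold
#' is excluded), ordered by descending count then gene name.
#'
#' @param hits a `tcr_hits` object.
#' @param class gene class, e.g. `"TRAV"`.
#' @param cfg a [candidate_config()].
#' @return character vector of candidate gene names (possibly empty).
#' @export
select_candidates <- function(hits, class, cfg = candidate_config()) {
  cc <- hits$counts[hits$counts$class == class, , drop = FALSE]
  total <- sum(cc$count)
  if (total == 0) return(character())
  cc <- cc[cc$count > cfg$candidate_fraction * total, , drop = FALSE]
  cc <- cc[order(-cc$count, cc$gene_name), , drop = FALSE]
  cc$gene_name
}

#' Reads assigned to one gene
#'
#' Extracts the mates whose best hit in `class` is `gene`, together with
#' their alignment records, for pileup construction and debugging.
#'
#' @param hits a `tcr_hits` object.
#' @param pairs the `tcr_read_pairs` table that was mapped.
#' @param class gene class.
#' @param gene gene name.
#' @return list with `seq` (mate sequences, as read) and `hits` (alignment
#'   rows: strand, r_start, g_start, cigar, ...).
#' @export
assigned_reads <- function(hits, pairs, class, gene) {
  a <- hits$assignments
  a <- a[a$class == class & a$gene_name == gene, , drop = FALSE]
  if (nrow(a) == 0) return(list(seq = character(), hits = a))
  seq <- ifelse(a$mate == 1L,
                pairs$seq1[match(a$read_id, pairs$id)],
                pairs$seq2[match(a$read_id, pairs$id)])
  list(seq = unname(seq), hits = a)
}

#' Build a reference pileup from assigned reads
#'
#' Read bases are placed at reference coordinates via the recorded hit
#' alignment: alignment columns that consume only the read (insertions) are
#' skipped, reference-only columns (deletions) add no count, and
#' reverse-strand hits contribute reverse-complemented bases.
#'
#' @param reads character vector of mate sequences (as read).
#' @param gene a single-row gene data.frame (from [ref_genes()]) or a list
#'   with `gene_name` and `sequence`.
#' @param hits alignment rows matching `reads` positionally (columns
#'   `strand`, `r_start`, `g_start`, `cigar`).
#' @return a `tcr_pileup`: gene_name, length, 4 x L base count matrix
#'   (rows A,C,G,T) and per-position depth.
#' @export
build_pileup <- function(reads, gene, hits) {
  stopifnot(length(reads) == nrow(hits))
  gseq <- gene$sequence[[1]]
  counts <- cpp_pileup(gseq, reads, hits$strand, hits$r_start, hits$g_start,
                       hits$cigar)
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(gene_name = gene$gene_name[[1]], length = nchar(gseq),
                 base_counts = counts, depth = colSums(counts)),
            class = "tcr_pileup")
}

#' Full-gene coverage gate
#'
#' A candidate passes iff its pileup depth is at least `min_coverage` at
#' every gene position (optionally excluding `edge_trim` terminal bases).
#' Candidates failing the gate are false positives: reads mapping to a
#' similar gene cover only the shared region and leave the diverged region
#' at zero or low depth.
#'
#' @param pileup a `tcr_pileup`.
#' @param cfg a [candidate_config()].
#' @return logical: accepted.
#' @export
coverage_gate <- function(pileup, cfg = candidate_config()) {
  L <- pileup$length
  span <- seq.int(1L + cfg$edge_trim, L - cfg$edge_trim)
  if (length(span) == 0 || span[1] > L) return(FALSE)
  all(pileup$depth[span] >= cfg$min_coverage)
}

#' Call the consensus sequence of a pileup
#'
#' Per position the consensus base is the count-argmax, ties broken by the
#' fixed base order A < C < G < T. Positions of zero depth (possible only at
#' gene termini when the gate runs with `edge_trim > 0`) fall back to the
#' reference base when `ref_seq` is supplied, and are an error otherwise.
#'
#' @param pileup a `tcr_pileup`.
#' @param class,locus optional annotations carried onto the contig.
#' @param ref_seq optional reference gene sequence for zero-depth fallback.
#' @return a `tcr_contig`: gene_name, class, locus, sequence, mean_coverage,
#'   min_depth.
#' @export
call_consensus <- function(pileup, class = NA_character_, locus = NA_character_,
                           ref_seq = NULL) {
  m <- pileup$base_counts
  zero <- pileup$depth == 0
  if (any(zero) && is.null(ref_seq))
    stop("zero-depth position(s) in pileup; gate the pileup first")
  idx <- max.col(t(m), ties.method = "first")  # row order A,C,G,T
  bases <- c("A", "C", "G", "T")[idx]
  if (any(zero)) bases[zero] <- strsplit(ref_seq, "")[[1]][zero]
  structure(list(gene_name = pileup$gene_name, class = class, locus = locus,
                 sequence = paste(bases, collapse = ""),
                 mean_coverage = mean(pileup$depth),
                 min_depth = min(pileup$depth)),
            class = "tcr_contig")
}

#' @export
print.tcr_contig <- function(x, ...) {
  cat(sprintf("<tcr_contig> %s (%s) %d bp, mean cov %.1f\n", x$gene_name,
              x$class, nchar(x$sequence), x$mean_coverage))
  invisible(x)
}

#' Remove substring-redundant candidate contigs
#'
#' A contig whose sequence is a contiguous substring of another surviving
#' contig is removed (the two read sets map to the same gene); exact
#' duplicates collapse to the copy with the highest mean coverage. Survivor
#' order is preserved. Idempotent.
#'
#' @param contigs list of `tcr_contig` objects (one locus and class).
#' @return the filtered list.
#' @export
dedupe_subsequences <- function(contigs) {
  n <- length(contigs)
  if (n <= 1) return(contigs)
  seqs <- vapply(contigs, `[[`, "", "sequence")
  cov <- vapply(contigs, `[[`, 0, "mean_coverage")
  drop <- logical(n)
  for (i in seq_len(n)) {
    if (drop[i]) next
    for (j in seq_len(n)) {
      if (i == j || drop[j]) next
      if (seqs[i] == seqs[j]) {
        # exact duplicates: keep highest coverage, ties keep the earlier
        if (cov[j] > cov[i] || (cov[j] == cov[i] && j < i)) { drop[i] <- TRUE; break }
      } else if (grepl(seqs[i], seqs[j], fixed = TRUE)) {
        drop[i] <- TRUE; break
      }
    }
  }
  contigs[!drop]
}

#' Dump a pileup as a TSV table
#'
#' @param pileup a `tcr_pileup`.
#' @param path output path (position, A, C, G, T, depth).
#' @export
write_pileup_tsv <- function(pileup, path) {
  df <- data.frame(position = seq_len(pileup$length),
                   t(pileup$base_counts), depth = pileup$depth)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
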