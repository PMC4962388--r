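# Light native chain annotation: J/D segment identification inside the
# closed junction, junction insertions/deletions, and a frame/stop-codon
# productivity call.

aln_mat <- function() Biostrings::nucleotideSubstitutionMatrix(
  match = 2, mismatch = -3, baseOnly = TRUE)

# local alignment of each pattern into subject; returns best index + details
best_local_aln <- function(patterns, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = aln_mat(),
    gapOpening = 5, gapExtension = 2)
  sc <- Biostrings::score(aln)
  i <- which.max(sc)  # patterns pre-sorted by name: ties resolve to name order
  a <- aln[i]
  list(index = i, score = sc[i],
       nmatch = Biostrings::nmatch(a),
       p_start = Biostrings::start(Biostrings::pattern(a)),
       p_end = Biostrings::end(Biostrings::pattern(a)),
       s_start = Biostrings::start(Biostrings::subject(a)),
       s_end = Biostrings::end(Biostrings::subject(a)))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Annotate a closed receptor chain
#'
#' Identifies the J gene by best local alignment of the germline J genes
#' into the junction region (ties by score then name), the D gene (TRB)
#' within the V-J interspace (reported `"undetermined"` below 8 exactly
#' matching bases), the non-templated inserted nucleotides between aligned
#' germline segment boundaries, junction-edge deletions, and productivity:
#' the J segment must lie in frame with the V reading frame (codons from
#' chain position 1) and the translation from the last complete V codon
#' through the junction into the first C codon must be free of stop codons.
#' Segment sequences are assumed to be supplied in frame.
#'
#' @param chain a `tcr_chain`.
#' @param ref a `tcr_reference` carrying J (and, for TRB, D) genes.
#' @return a `tcr_annotation`: v_gene, d_gene, j_gene, c_gene, junction_nt,
#'   inserted_vj (alpha) or inserted_vd/inserted_dj (beta), deletions
#'   (v3, j5), productive, frame_offset, unannotatable.
#' @export
annotate_chain <- function(chain, ref) {
  locus <- chain$locus
  ann <- list(locus = locus, v_gene = chain$v_gene, d_gene = NA_character_,
              j_gene = NA_character_, c_gene = chain$c_gene,
              junction_nt = NA_character_, inserted_vj = NA_character_,
              inserted_vd = NA_character_, inserted_dj = NA_character_,
              deletions_v3 = NA_integer_, deletions_j5 = NA_integer_,
              productive = FALSE, frame_offset = NA_integer_,
              unannotatable = FALSE)
  class(ann) <- "tcr_annotation"
  js <- chain$junction_interval[1]; je <- chain$junction_interval[2]
  junction <- substr(chain$sequence, js, je)
  ann$junction_nt <- junction
  jg <- ref_genes(ref, locus, "J")
  if (nrow(jg) == 0) stop("reference carries no J genes for locus ", locus)
  if (nchar(junction) < 10) { ann$unannotatable <- TRUE; return(ann) }
  jb <- best_local_aln(setNames(jg$sequence, jg$gene_name), junction)
  if (jb$nmatch < 8) { ann$unannotatable <- TRUE; return(ann) }
  ann$j_gene <- jg$gene_name[jb$index]
  j_chain_start <- js - 1L + jb$s_start
  ann$deletions_j5 <- jb$p_start - 1L
  # end of the germline V segment within the chain: align the V tail into
  # the chain prefix around the junction start
  vseq <- chain$v_contig$sequence
  vtail_len <- min(45L, nchar(vseq))
  vtail <- substr(vseq, nchar(vseq) - vtail_len + 1L, nchar(vseq))
  win_start <- max(1L, js - vtail_len - 10L)
  window <- substr(chain$sequence, win_start, min(nchar(chain$sequence), je))
  vb <- best_local_aln(vtail, window)
  v_chain_end <- win_start - 1L + vb$s_end
  ann$deletions_v3 <- vtail_len - vb$p_end
  ann$frame_offset <- (j_chain_start - 1L) %% 3L
  if (locus == "TRB") {
    dg <- ref_genes(ref, locus, "D")
    inter <- if (j_chain_start - 1L >= v_chain_end + 1L)
      substr(chain$sequence, v_chain_end + 1L, j_chain_start - 1L) else ""
    ann$d_gene <- "undetermined"
    if (nrow(dg) > 0 && nchar(inter) >= 4) {
      db <- best_local_aln(setNames(dg$sequence, dg$gene_name), inter)
      if (db$nmatch >= 8) {
        ann$d_gene <- dg$gene_name[db$index]
        ann$inserted_vd <- substr(inter, 1L, db$s_start - 1L)
        ann$inserted_dj <- substr(inter, db$s_end + 1L, nchar(inter))
      }
    }
    if (identical(ann$d_gene, "undetermined")) {
      ann$inserted_vd <- inter
      ann$inserted_dj <- ""
    }
  } else {
    ann$inserted_vj <- if (j_chain_start - 1L >= v_chain_end + 1L)
      substr(chain$sequence, v_chain_end + 1L, j_chain_start - 1L) else ""
  }
  # productivity: J in frame with V (frame from chain position 1), and no
  # stop codon from the last complete V codon through the junction into C
  in_frame <- ann$frame_offset == 0L
  c_start <- je - chain$end_trim + 1L  # first germline C base (regrown trim)
  cod_start <- v_chain_end - ((v_chain_end - 1L) %% 3L) - 3L
  cod_start <- max(1L, cod_start)
  cod_end <- min(nchar(chain$sequence), c_start + 2L)
  span <- substr(chain$sequence, cod_start, cod_end)
  span <- substr(span, 1L, (nchar(span) %/% 3L) * 3L)
  codons <- substring(span, seq(1L, nchar(span), 3L), seq(3L, nchar(span), 3L))
  ann$productive <- in_frame && !any(codons %in% STOP_CODONS)
  ann
}

annotation_row <- function(ann, chain) {
  data.frame(locus = ann$locus, v_gene = ann$v_gene, d_gene = ann$d_gene,
             j_gene = ann$j_gene, c_gene = ann$c_gene,
             junction_nt = ann$junction_nt,
             inserted_vj = ann$inserted_vj, inserted_vd = ann$inserted_vd,
             inserted_dj = ann$inserted_dj,
             deletions_v3 = ann$deletions_v3, deletions_j5 = ann$deletions_j5,
             productive = ann$productive, frame_offset = ann$frame_offset,
             unannotatable = ann$unannotatable,
             junction_mean_coverage = chain$junction_mean_coverage,
             stringsAsFactors = FALSE)
}

#' Write chain, contig and annotation outputs
#'
#' Writes `chains.fasta` (closed receptor sequences), `contigs.fasta`
#' (candidate V/C consensus sequences with mean coverage in the header),
#' `annotation.tsv` and `rejects.tsv`, deterministically ordered.
#'
#' @param chains list of `tcr_chain`.
#' @param contigs list of `tcr_contig`.
#' @param annotations list of `tcr_annotation` matching `chains`.
#' @param rejects data.frame of rejections (locus, v_gene, c_gene, reason).
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_chain_outputs <- function(chains, contigs, annotations, rejects, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ord <- order(vapply(chains, `[[`, "", "locus"),
               vapply(chains, `[[`, "", "v_gene"),
               vapply(chains, `[[`, "", "c_gene"))
  chains <- chains[ord]; annotations <- annotations[ord]
  chains_fa <- file.path(out_dir, "chains.fasta")
  if (length(chains)) {
    ss <- Biostrings::DNAStringSet(vapply(chains, `[[`, "", "sequence"))
    names(ss) <- vapply(chains, function(ch)
      paste(ch$locus, ch$v_gene, ch$c_gene, sep = "|"), "")
    Biostrings::writeXStringSet(ss, chains_fa, width = 60L)
  } else writeLines(character(), chains_fa)
  contigs_fa <- file.path(out_dir, "contigs.fasta")
  if (length(contigs)) {
    cord <- order(vapply(contigs, `[[`, "", "class"),
                  vapply(contigs, `[[`, "", "gene_name"))
    contigs <- contigs[cord]
    ss <- Biostrings::DNAStringSet(vapply(contigs, `[[`, "", "sequence"))
    names(ss) <- vapply(contigs, function(ct)
      sprintf("%s|%s|mean_cov=%.2f", ct$gene_name, ct$class, ct$mean_coverage), "")
    Biostrings::writeXStringSet(ss, contigs_fa, width = 60L)
  } else writeLines(character(), contigs_fa)
  ann_tsv <- file.path(out_dir, "annotation.tsv")
  ann_df <- if (length(annotations)) {
    do.call(rbind, Map(annotation_row, annotations, chains))
  } else {
    data.frame(locus = character(), v_gene = character(), d_gene = character(),
               j_gene = character(), c_gene = character(),
               junction_nt = character(), inserted_vj = character(),
               inserted_vd = character(), inserted_dj = character(),
               deletions_v3 = integer(), deletions_j5 = integer(),
               productive = logical(), frame_offset = integer(),
               unannotatable = logical(), junction_mean_coverage = numeric(),
               stringsAsFactors = FALSE)
  }
  utils::write.table(ann_df, ann_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rej_tsv <- file.path(out_dir, "rejects.tsv")
  utils::write.table(rejects, rej_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(chains_fa, contigs_fa, ann_tsv, rej_tsv))
}
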