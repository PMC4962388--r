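# Germline TRA/TRB reference handling: loading IMGT-dialect FASTA, gap-size
# estimation from J / D-J lengths, and synthetic reference generation.

SEGMENTS <- c("V", "D", "J", "C")
LOCI <- c("TRA", "TRB")

new_tcr_reference <- function(genes, provenance = "") {
  rownames(genes) <- NULL
  structure(list(genes = genes, provenance = provenance),
            class = "tcr_reference")
}

#' @export
print.tcr_reference <- function(x, ...) {
  cat("<tcr_reference>", x$provenance, "\n")
  tab <- table(x$genes$locus, x$genes$segment)
  print(tab)
  invisible(x)
}

# parse "GENE*ALLELE" from a FASTA header: IMGT pipe-delimited dialect
# (field 2) or a plain first-word token
parse_gene_token <- function(header) {
  fields <- strsplit(header, "|", fixed = TRUE)[[1]]
  tok <- if (length(fields) >= 2 && grepl("*", fields[2], fixed = TRUE)) {
    fields[2]
  } else {
    strsplit(trimws(fields[1]), "[[:space:]]+")[[1]][1]
  }
  tok <- trimws(tok)
  if (!nzchar(tok)) return(NULL)
  parts <- strsplit(tok, "*", fixed = TRUE)[[1]]
  gene <- parts[1]
  if (!nzchar(gene)) return(NULL)
  allele <- if (length(parts) >= 2 && nzchar(parts[2])) parts[2] else NA_character_
  list(gene_name = gene, allele_id = allele, has_star = grepl("*", tok, fixed = TRUE))
}

#' Load germline genes of one segment class from a FASTA file
#'
#' Reads a germline reference FASTA in IMGT dialect (pipe-delimited headers
#' with the gene*allele token in the second field) or with plain
#' `GENE*ALLELE` first-word headers. Only the first allele encountered per
#' gene name is retained; sequences are uppercased and IMGT gap characters
#' (`.`) are stripped. Functionality flags (F/ORF/P), when present, are
#' carried through but never filtered on.
#'
#' @param path FASTA file (plain or gzip).
#' @param locus `"TRA"` or `"TRB"`.
#' @param segment `"V"`, `"D"`, `"J"` or `"C"`.
#' @return a `tcr_reference` holding the loaded segment class.
#' @export
load_germline_fasta <- function(path, locus, segment) {
  locus <- match.arg(locus, LOCI)
  segment <- match.arg(segment, SEGMENTS)
  if (!file.exists(path)) stop("reference file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty reference file: ", path)
  headers <- names(seqs)
  genes <- character(length(seqs))
  alleles <- character(length(seqs))
  for (i in seq_along(headers)) {
    tok <- parse_gene_token(headers[i])
    if (is.null(tok) || !tok$has_star)
      stop("header without a parsable GENE*ALLELE token: ", headers[i])
    genes[i] <- tok$gene_name
    alleles[i] <- tok$allele_id
  }
  keep <- !duplicated(genes)  # first-allele rule, file order
  seq_chr <- gsub(".", "", toupper(as.character(seqs[keep])), fixed = TRUE)
  bad <- grepl("[^ACGTN]", seq_chr)
  if (any(bad)) stop("non-DNA characters in reference sequence(s): ",
                     paste(genes[keep][bad], collapse = ", "))
  if (any(!nzchar(seq_chr))) stop("empty reference sequence after gap stripping")
  df <- data.frame(locus = locus, segment = segment,
                   gene_name = genes[keep], allele_id = alleles[keep],
                   sequence = unname(seq_chr), stringsAsFactors = FALSE)
  if (locus == "TRA" && segment == "D") stop("TRA has no D segments")
  new_tcr_reference(df, provenance = paste0("loaded:", path))
}

#' Combine reference fragments into one reference set
#'
#' @param ... `tcr_reference` objects (e.g. one per locus/segment file).
#' @return a single `tcr_reference`; duplicate (locus, segment, gene_name)
#'   entries beyond the first are dropped (first-allele rule across files).
#' @export
combine_references <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "tcr_reference")))
  genes <- do.call(rbind, lapply(parts, `[[`, "genes"))
  key <- paste(genes$locus, genes$segment, genes$gene_name)
  new_tcr_reference(genes[!duplicated(key), , drop = FALSE],
                    provenance = paste(unique(vapply(parts, `[[`, "", "provenance")),
                                       collapse = ";"))
}

#' Extract genes from a reference set
#'
#' @param ref a `tcr_reference`.
#' @param locus,segment optional filters.
#' @return a data.frame of genes, ordered by gene name.
#' @export
ref_genes <- function(ref, locus = NULL, segment = NULL) {
  stopifnot(inherits(ref, "tcr_reference"))
  g <- ref$genes
  if (!is.null(locus)) g <- g[g$locus %in% locus, , drop = FALSE]
  if (!is.null(segment)) g <- g[g$segment %in% segment, , drop = FALSE]
  g[order(g$gene_name), , drop = FALSE]
}

#' Estimate the V-C junction gap size from germline J (and D) lengths
#'
#' The gap between the V and C consensus contigs is sized by the mean length
#' of the germline J genes (alpha) or the mean D plus mean J lengths (beta),
#' with a tolerance of plus or minus 50 percent. Means are rounded half-up
#' to integer bp before applying the tolerance.
#'
#' @param ref a `tcr_reference` containing J (and, for TRB, D) genes.
#' @param locus `"TRA"` or `"TRB"`.
#' @return a `tcr_gap_estimate`: list with `mean_gap`, `lower`, `upper` (bp).
#' @export
estimate_gap_bounds <- function(ref, locus) {
  locus <- match.arg(locus, LOCI)
  j <- ref_genes(ref, locus, "J")
  if (nrow(j) == 0) stop("no J genes for locus ", locus)
  mg <- mean(nchar(j$sequence))
  if (locus == "TRB") {
    d <- ref_genes(ref, locus, "D")
    if (nrow(d) == 0) stop("no D genes for locus TRB")
    mg <- mg + mean(nchar(d$sequence))
  }
  mean_gap <- round_half_up(mg)
  structure(list(mean_gap = as.integer(mean_gap),
                 lower = as.integer(round_half_up(0.5 * mean_gap)),
                 upper = as.integer(round_half_up(1.5 * mean_gap))),
            class = "tcr_gap_estimate")
}

#' Generate a synthetic germline reference set
#'
#' Builds a randomized but reproducible germline gene set for both loci with
#' systematic gene names (`TRAVs1`, `TRBDs2`, ...). Same-segment genes are
#' kept mutually divergent (pairwise edit distance at least 20 percent of
#' the shorter length) so that candidate genes are distinguishable. Segment
#' lengths are rounded down to multiples of three and sequences are drawn
#' codon-wise from the 61 sense codons, so that segments concatenate in
#' frame and stop-free like real coding germline segments.
#'
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @param n_per_segment named counts per segment (`V`, `D`, `J`, `C`).
#' @param length_ranges named list of `c(min, max)` lengths per segment (bp).
#' @param loci loci to generate.
#' @return a `tcr_reference` with segments V/J/C for TRA and V/D/J/C for TRB.
#' @export
make_synthetic_reference <- function(seed = 1L,
                                     n_per_segment = c(V = 8L, D = 2L, J = 6L, C = 2L),
                                     length_ranges = list(V = c(282L, 309L),
                                                          D = c(12L, 15L),
                                                          J = c(51L, 63L),
                                                          C = c(402L, 549L)),
                                     loci = c("TRA", "TRB")) {
  stopifnot(all(c("V", "J", "C") %in% names(n_per_segment)),
            all(n_per_segment[c("V", "J", "C")] >= 1))
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases,
                            paste0))
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  rand_cds <- function(len) {
    paste(sample(sense, len %/% 3L, replace = TRUE), collapse = "")
  }
  with_seed(seed, {
    rows <- list()
    for (locus in loci) {
      segs <- if (locus == "TRA") c("V", "J", "C") else c("V", "D", "J", "C")
      for (seg in segs) {
        n <- as.integer(n_per_segment[[seg]])
        rng <- as.integer(length_ranges[[seg]])
        if (rng[1] < 1) stop("minimum length must be >= 1 for segment ", seg)
        lens <- pmax(3L, (sample(seq(rng[1], rng[2]), n, replace = TRUE) %/% 3L) * 3L)
        seqs <- character(n)
        for (i in seq_len(n)) {
          ok <- FALSE
          for (try in 1:50) {
            cand <- rand_cds(lens[i])
            ok <- i == 1 ||
              min(utils::adist(cand, seqs[seq_len(i - 1)])) >=
                0.2 * min(lens[seq_len(i)])
            if (ok) break
          }
          if (!ok) stop("could not satisfy divergence constraints for segment ", seg)
          seqs[i] <- cand
        }
        rows[[length(rows) + 1L]] <- data.frame(
          locus = locus, segment = seg,
          gene_name = paste0(locus, seg, "s", seq_len(n)),
          allele_id = "01", sequence = seqs, stringsAsFactors = FALSE)
      }
    }
    new_tcr_reference(do.call(rbind, rows), provenance = paste0("synthetic:seed=", seed))
  })
}

#' Write reference genes to FASTA
#'
#' Headers are `GENE*ALLELE|LOCUS|SEGMENT`, re-loadable by
#' [load_germline_fasta()]. Sequences are wrapped at 60 columns.
#'
#' @param ref a `tcr_reference`.
#' @param path output FASTA path.
#' @param locus,segment optional subset filters.
#' @export
write_reference_fasta <- function(ref, path, locus = NULL, segment = NULL) {
  g <- ref_genes(ref, locus, segment)
  if (nrow(g) == 0) stop("no genes selected for writing")
  ss <- Biostrings::DNAStringSet(g$sequence)
  names(ss) <- paste0(g$gene_name, "*", ifelse(is.na(g$allele_id), "01", g$allele_id),
                      "|", g$locus, "|", g$segment)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Reference manifest table
#'
#' @param ref a `tcr_reference`.
#' @return data.frame: locus, segment, gene_name, allele_id, length.
#' @export
reference_manifest <- function(ref) {
  g <- ref$genes
  data.frame(locus = g$locus, segment = g$segment, gene_name = g$gene_name,
             allele_id = g$allele_id, length = nchar(g$sequence),
             stringsAsFactors = FALSE)
}
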