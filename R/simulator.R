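# In-silico TCR read simulation: random V(D)JC chain concatenation with
# junction insertions, paired-end reads under a per-cycle substitution error
# profile, background mixing, and the recovery benchmark harness.

#' Per-cycle substitution error profile
#'
#' A linear ramp across cycles (error-rich 3' ends, as on Illumina
#' platforms), scaled to a requested mean per-base rate. The unscaled shape
#' runs 0.1 percent to 1 percent.
#'
#' @param read_len read length (cycles).
#' @param mean_rate mean per-base substitution probability.
#' @return numeric vector of per-cycle probabilities.
#' @export
ramp_error_profile <- function(read_len, mean_rate = 0.0055) {
  base <- seq(0.001, 0.01, length.out = read_len)
  base * (mean_rate / mean(base))
}

#' Simulation configuration
#'
#' Defaults reproduce the benchmark design: 100 bp paired reads from
#' 300 +/- 30 bp fragments, junction insertions of 0/3/6/9 bp, TCR reads
#' mixed with background at 3:997, coverages 10/50/100, and 30 chain pairs
#' per condition. Each chain is embedded in flanking transcript context
#' (`utr5_len`/`utr3_len`) so that gene bodies are covered like genes
#' interior to an mRNA.
#'
#' @param read_len read length in bp.
#' @param frag_mean,frag_sd fragment length distribution (bp).
#' @param coverages coverage grid for benchmarks.
#' @param insertion_lengths junction insertion grid (bp).
#' @param tcr_background_ratio two integers, TCR:background read ratio.
#' @param error_profile per-cycle substitution probabilities
#'   (default [ramp_error_profile()] at its default mean).
#' @param n_chain_pairs simulated alpha/beta chain pairs per condition.
#' @param utr5_len,utr3_len flanking transcript context around each chain.
#' @param seed benchmark seed.
#' @return a list of class `tcr_sim_config`.
#' @export
sim_config <- function(read_len = 100L, frag_mean = 300L, frag_sd = 30L,
                       coverages = c(10, 50, 100),
                       insertion_lengths = c(0L, 3L, 6L, 9L),
                       tcr_background_ratio = c(3L, 997L),
                       error_profile = ramp_error_profile(read_len),
                       n_chain_pairs = 30L, utr5_len = 150L, utr3_len = 300L,
                       seed = 1L) {
  stopifnot(frag_mean >= read_len, all(tcr_background_ratio > 0),
            all(error_profile >= 0), all(error_profile < 1))
  structure(list(read_len = as.integer(read_len),
                 frag_mean = as.integer(frag_mean),
                 frag_sd = as.integer(frag_sd), coverages = coverages,
                 insertion_lengths = as.integer(insertion_lengths),
                 tcr_background_ratio = as.integer(tcr_background_ratio),
                 error_profile = error_profile,
                 n_chain_pairs = as.integer(n_chain_pairs),
                 utr5_len = as.integer(utr5_len),
                 utr3_len = as.integer(utr3_len), seed = seed),
            class = "tcr_sim_config")
}

#' Simulate one receptor chain from germline segments
#'
#' Segments are drawn uniformly at random from the reference; `ins_len`
#' i.i.d. uniform bases are inserted at the V-J junction (alpha) or at both
#' the V-D and D-J junctions (beta). The truth record carries the segment
#' names and the junction (all bases between the last V and first C base).
#'
#' @param ref a `tcr_reference` complete for the locus.
#' @param locus `"TRA"` or `"TRB"`.
#' @param ins_len inserted bases per junction.
#' @return a `tcr_sim_chain` with fields locus, v/d/j/c_gene, inserted,
#'   sequence, junction_interval, junction_nt.
#' @export
simulate_chain <- function(ref, locus, ins_len = 0L) {
  locus <- match.arg(locus, LOCI)
  pick <- function(seg) {
    g <- ref_genes(ref, locus, seg)
    if (nrow(g) == 0) stop("reference has no ", seg, " genes for ", locus)
    g[sample.int(nrow(g), 1L), , drop = FALSE]
  }
  v <- pick("V"); j <- pick("J"); cc <- pick("C")
  rand_ins <- function() if (ins_len > 0)
    as.character(cpp_random_dna(1L, as.integer(ins_len))) else ""
  if (locus == "TRB") {
    d <- pick("D")
    ins1 <- rand_ins(); ins2 <- rand_ins()
    junction <- paste0(ins1, d$sequence, ins2, j$sequence)
    d_gene <- d$gene_name
    inserted <- c(vd = ins1, dj = ins2)
  } else {
    ins1 <- rand_ins()
    junction <- paste0(ins1, j$sequence)
    d_gene <- NA_character_
    inserted <- c(vj = ins1)
  }
  seqn <- paste0(v$sequence, junction, cc$sequence)
  js <- nchar(v$sequence) + 1L
  structure(list(locus = locus, v_gene = v$gene_name, d_gene = d_gene,
                 j_gene = j$gene_name, c_gene = cc$gene_name,
                 inserted = inserted, sequence = seqn,
                 junction_interval = c(js, js + nchar(junction) - 1L),
                 junction_nt = junction),
            class = "tcr_sim_chain")
}

phred_string <- function(profile, len) {
  p <- profile[pmin(seq_len(len), length(profile))]
  q <- pmin(41L, as.integer(round(-10 * log10(pmax(p, 1e-9)))))
  intToUtf8(q + 33L)
}

#' Simulate paired-end reads from a template
#'
#' `ceiling(coverage * len(template) / (2 * read_len))` pairs are drawn;
#' fragment lengths are Normal(`frag_mean`, `frag_sd`) truncated to
#' `[read_len, len(template)]`, fragment starts uniform. Mate 1 reads
#' forward from the fragment 5' end, mate 2 is the reverse complement of the
#' fragment 3' end. Each base is substituted with the per-cycle probability
#' of `cfg$error_profile`; qualities encode the per-cycle error rate as
#' Phred scores.
#'
#' @param template template DNA string.
#' @param cfg a [sim_config()].
#' @param coverage target mean per-base coverage.
#' @param id_prefix read-pair id prefix.
#' @return a `tcr_read_pairs` table with extra columns `n_err1`, `n_err2`.
#' @export
simulate_read_pairs <- function(template, cfg, coverage, id_prefix = "sim") {
  L <- nchar(template); rl <- cfg$read_len
  if (L < rl) stop("template shorter than the read length")
  n <- as.integer(ceiling(coverage * L / (2 * rl)))
  f <- pmin(pmax(round_half_up(stats::rnorm(n, cfg$frag_mean, cfg$frag_sd)), rl), L)
  s <- floor(stats::runif(n, min = 1, max = L - f + 1 + 1))
  s <- pmin(pmax(s, 1), L - f + 1)
  m1 <- substring(template, s, s + rl - 1)
  m2 <- as.character(cpp_revcomp(substring(template, s + f - rl, s + f - 1)))
  if (all(cfg$error_profile == 0)) {
    e1 <- list(seq = m1, n_err = integer(n))
    e2 <- list(seq = m2, n_err = integer(n))
  } else {
    e1 <- cpp_mutate_reads(m1, cfg$error_profile)
    e2 <- cpp_mutate_reads(m2, cfg$error_profile)
  }
  q <- phred_string(cfg$error_profile, rl)
  out <- data.frame(id = paste0(id_prefix, "_", seq_len(n)),
                    seq1 = e1$seq, qual1 = q, seq2 = e2$seq, qual2 = q,
                    n_err1 = e1$n_err, n_err2 = e2$n_err,
                    stringsAsFactors = FALSE)
  structure(out, class = c("tcr_read_pairs", "data.frame"))
}

#' Mix TCR read pairs with background
#'
#' Adds `round(n_tcr * ratio[2] / ratio[1])` background pairs - drawn from
#' random loci of a background FASTA when supplied, otherwise i.i.d. uniform
#' DNA - and shuffles the output order deterministically under the current
#' RNG stream. A manifest labels every pair's origin.
#'
#' @param tcr_pairs a `tcr_read_pairs` table of TCR-derived pairs.
#' @param cfg a [sim_config()].
#' @param ratio TCR:background ratio (two positive numbers).
#' @param background optional background FASTA path or `DNAStringSet`.
#' @param n_background optional explicit background pair count, overriding
#'   the ratio (benchmark scaling).
#' @return list: `pairs` (shuffled `tcr_read_pairs`), `manifest`
#'   (data.frame id, origin).
#' @export
mix_with_background <- function(tcr_pairs, cfg,
                                ratio = cfg$tcr_background_ratio,
                                background = NULL, n_background = NULL) {
  stopifnot(all(ratio > 0))
  n_tcr <- nrow(tcr_pairs)
  n_bg <- if (!is.null(n_background)) as.integer(n_background)
  else as.integer(round_half_up(n_tcr * ratio[2] / ratio[1]))
  rl <- cfg$read_len
  q <- phred_string(cfg$error_profile, rl)
  if (n_bg > 0) {
    if (is.null(background)) {
      # uniform background; the substitution pass is distribution-invariant
      # on uniform noise and is skipped
      seqs <- cpp_random_dna(2L * n_bg, rl)
      bg <- data.frame(id = paste0("bg_", seq_len(n_bg)),
                       seq1 = seqs[seq_len(n_bg)], qual1 = q,
                       seq2 = seqs[n_bg + seq_len(n_bg)], qual2 = q,
                       n_err1 = NA_integer_, n_err2 = NA_integer_,
                       stringsAsFactors = FALSE)
    } else {
      src <- if (inherits(background, "DNAStringSet")) background
      else Biostrings::readDNAStringSet(background)
      src <- src[Biostrings::width(src) >= cfg$frag_mean + 4 * cfg$frag_sd]
      if (length(src) == 0) stop("background sequences shorter than the fragment length")
      w <- Biostrings::width(src)
      si <- sample.int(length(src), n_bg, replace = TRUE, prob = w)
      f <- pmin(pmax(round_half_up(stats::rnorm(n_bg, cfg$frag_mean, cfg$frag_sd)), rl),
                w[si])
      s <- floor(stats::runif(n_bg, 1, w[si] - f + 2))
      frag <- as.character(Biostrings::subseq(src[si], start = s, width = f))
      m1 <- substr(frag, 1, rl)
      m2 <- as.character(cpp_revcomp(substring(frag, f - rl + 1, f)))
      e1 <- cpp_mutate_reads(m1, cfg$error_profile)
      e2 <- cpp_mutate_reads(m2, cfg$error_profile)
      bg <- data.frame(id = paste0("bg_", seq_len(n_bg)),
                       seq1 = e1$seq, qual1 = q, seq2 = e2$seq, qual2 = q,
                       n_err1 = e1$n_err, n_err2 = e2$n_err,
                       stringsAsFactors = FALSE)
    }
  } else {
    bg <- tcr_pairs[0, , drop = FALSE]
  }
  tp <- tcr_pairs
  if (!"n_err1" %in% names(tp)) { tp$n_err1 <- NA_integer_; tp$n_err2 <- NA_integer_ }
  all_pairs <- rbind(tp[, c("id", "seq1", "qual1", "seq2", "qual2",
                            "n_err1", "n_err2")],
                     bg[, c("id", "seq1", "qual1", "seq2", "qual2",
                            "n_err1", "n_err2")])
  origin <- c(rep("tcr", n_tcr), rep("background", nrow(bg)))
  ord <- sample.int(nrow(all_pairs))
  out <- all_pairs[ord, , drop = FALSE]
  rownames(out) <- NULL
  list(pairs = structure(out, class = c("tcr_read_pairs", "data.frame")),
       manifest = data.frame(id = out$id, origin = origin[ord],
                             stringsAsFactors = FALSE))
}

#' Score recovery of a simulated chain
#'
#' A chain counts as recovered iff some closed chain contains the true
#' junction with its 10 flanking germline bases on each side as an exact
#' substring, and the annotated V, J and C genes equal the truth.
#'
#' @param result a `tcr_cell_result` (from [run_cell_pairs()]).
#' @param truth a `tcr_sim_chain`.
#' @return list: `recovered` (logical), `reason`.
#' @export
evaluate_recovery <- function(result, truth) {
  js <- truth$junction_interval[1]; je <- truth$junction_interval[2]
  target <- substr(truth$sequence, max(1L, js - 10L),
                   min(nchar(truth$sequence), je + 10L))
  chains <- result$chains
  if (length(chains) == 0) return(list(recovered = FALSE, reason = "no_chain"))
  junction_ok <- FALSE
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    if (ch$locus != truth$locus) next
    if (!grepl(target, ch$sequence, fixed = TRUE)) next
    junction_ok <- TRUE
    ann <- result$annotations[[i]]
    if (identical(ch$v_gene, truth$v_gene) &&
        identical(ann$j_gene, truth$j_gene) &&
        identical(ch$c_gene, truth$c_gene))
      return(list(recovered = TRUE, reason = "recovered"))
  }
  list(recovered = FALSE,
       reason = if (junction_ok) "segment_mismatch" else "junction_mismatch")
}

#' Simulate one cell (one alpha and one beta chain) and its read set
#'
#' @param ref a `tcr_reference`.
#' @param cfg a [sim_config()].
#' @param coverage target TCR coverage.
#' @param ins_len junction insertion length.
#' @param background,n_background see [mix_with_background()].
#' @return list: `pairs`, `manifest`, `truth` (list of two `tcr_sim_chain`).
#' @export
simulate_cell <- function(ref, cfg, coverage, ins_len = 0L,
                          background = NULL, n_background = NULL) {
  truth <- list(simulate_chain(ref, "TRA", ins_len),
                simulate_chain(ref, "TRB", ins_len))
  pairs <- list()
  for (k in 1:2) {
    tmpl <- paste0(cpp_random_dna(1L, cfg$utr5_len), truth[[k]]$sequence,
                   cpp_random_dna(1L, cfg$utr3_len))
    pairs[[k]] <- simulate_read_pairs(tmpl, cfg, coverage,
                                      id_prefix = c("tra", "trb")[k])
  }
  tcr <- rbind(pairs[[1]], pairs[[2]])
  mixed <- mix_with_background(structure(tcr, class = c("tcr_read_pairs", "data.frame")),
                               cfg, background = background,
                               n_background = n_background)
  list(pairs = mixed$pairs, manifest = mixed$manifest, truth = truth)
}

#' Run the recovery benchmark grid
#'
#' For each (read length, coverage) cell, simulates `n_chain_pairs` cells
#' per insertion length, runs the full per-cell pipeline, and scores
#' recovery per locus. Pipeline errors count as non-recovery and never
#' abort the grid.
#'
#' @param ref a `tcr_reference`.
#' @param cfg a [sim_config()]; `cfg$seed` makes the grid reproducible.
#' @param read_lens read lengths to run.
#' @param coverages coverages to run.
#' @param n_chain_pairs chain pairs per insertion length.
#' @param background,n_background background source / per-cell pair count
#'   override (`NULL` keeps the configured ratio).
#' @param pipeline pipeline configuration template (`NULL`: defaults with
#'   `insert_size_mean = cfg$frag_mean`).
#' @return data.frame: read_len, coverage, locus, n, n_recovered, fraction.
#' @export
run_benchmark <- function(ref, cfg = sim_config(), read_lens = c(50L, 75L, 100L),
                          coverages = cfg$coverages,
                          n_chain_pairs = cfg$n_chain_pairs,
                          background = NULL, n_background = NULL,
                          pipeline = NULL) {
  with_seed(cfg$seed, {
    rows <- list()
    for (rl in read_lens) {
      cfg_rl <- cfg
      cfg_rl$read_len <- as.integer(rl)
      cfg_rl$error_profile <- ramp_error_profile(rl, mean(cfg$error_profile))
      for (cov in coverages) {
        rec <- c(TRA = 0L, TRB = 0L); n <- 0L
        for (ins in cfg$insertion_lengths) {
          for (i in seq_len(n_chain_pairs)) {
            cell <- simulate_cell(ref, cfg_rl, cov, ins, background, n_background)
            pcfg <- if (is.null(pipeline))
              pipeline_config(ref, gapfill = gapfill_config(
                insert_size_mean = cfg$frag_mean)) else pipeline
            res <- tryCatch(run_cell_pairs(cell$pairs, pcfg),
                            error = function(e) NULL)
            n <- n + 1L
            if (!is.null(res)) {
              for (tr in cell$truth) {
                ev <- evaluate_recovery(res, tr)
                if (ev$recovered) rec[tr$locus] <- rec[tr$locus] + 1L
              }
            }
          }
        }
        for (locus in LOCI) {
          rows[[length(rows) + 1L]] <- data.frame(
            read_len = rl, coverage = cov, locus = locus, n = n,
            n_recovered = rec[[locus]], fraction = rec[[locus]] / n,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
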