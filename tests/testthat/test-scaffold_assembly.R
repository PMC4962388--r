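# Scaffold construction, read-pair-anchored gap filling, annotation, outputs.

mkc <- function(name, seq, class = "TRAV", locus = "TRA", cov = 50) {
  structure(list(gene_name = name, class = class, locus = locus,
                 sequence = seq, mean_coverage = cov, min_depth = 5L),
            class = "tcr_contig")
}

gapest <- function(mean_gap) structure(
  list(mean_gap = as.integer(mean_gap),
       lower = as.integer(round(0.5 * mean_gap)),
       upper = as.integer(round(1.5 * mean_gap))), class = "tcr_gap_estimate")

test_that("scaffolds concatenate trimmed flanks across the N-run", {
  v <- mkc("V1", strrep("A", 10))
  cc <- mkc("C1", strrep("T", 10), class = "TRAC")
  sc <- build_scaffolds(list(v), list(cc), gapest(4), end_trim = 3L,
                        locus = "TRA")
  expect_length(sc, 1L)
  expect_equal(sc[[1]]$sequence, paste0(strrep("A", 7), "NNNN", strrep("T", 7)))
  expect_equal(sc[[1]]$gap_interval, c(8L, 11L))
  expect_equal(sc[[1]]$v_flank_interval, c(1L, 7L))
  expect_equal(sc[[1]]$c_flank_interval, c(12L, 18L))

  v2 <- mkc("V2", strrep("G", 10))
  expect_length(build_scaffolds(list(v, v2), list(cc), gapest(4)), 2L)
  c2 <- mkc("C2", strrep("C", 10), class = "TRAC")
  v3 <- mkc("V3", strrep("GA", 5))
  s6 <- build_scaffolds(list(v2, v, v3), list(c2, cc), gapest(4))
  expect_length(s6, 6L)
  expect_equal(vapply(s6, `[[`, "", "v_gene"),
               rep(c("V1", "V2", "V3"), each = 2))
  expect_equal(vapply(s6, `[[`, "", "c_gene"), rep(c("C1", "C2"), 3))
  expect_length(build_scaffolds(list(), list(cc), gapest(4)), 0L)
})

# paired reads tiling a transcript, error-free
tile_pairs <- function(truth, rl = 50L, frag = 120L, step = 2L) {
  s <- seq(1L, nchar(truth) - frag + 1L, by = step)
  m1 <- substring(truth, s, s + rl - 1L)
  m2 <- rc(substring(truth, s + frag - rl, s + frag - 1L))
  pairs_from_seqs(m1, m2)
}

test_that("a degenerate zero-length gap closes to exactly the trimmed bases", {
  set.seed(31)
  v <- random_dna(1, 100); cc <- random_dna(1, 100)
  truth <- paste0(v, cc)
  sc <- build_scaffolds(list(mkc("Vx", v)), list(mkc("Cx", cc, class = "TRAC")),
                        gapest(0), locus = "TRA")[[1]]
  res <- fill_gap(sc, tile_pairs(truth), gapfill_config(insert_size_mean = 120L,
                                                        min_reads_per_base = 5L))
  expect_s3_class(res, "tcr_chain")
  expect_equal(res$sequence, truth)
  expect_equal(res$junction_interval, c(98L, 103L))
  expect_equal(substr(res$sequence, 98, 103), substr(truth, 98, 103))
  # flank invariants: trimmed V prefix and trimmed C suffix are preserved
  expect_true(startsWith(res$sequence, substr(v, 1, 97)))
  expect_true(endsWith(res$sequence, substr(cc, 4, 100)))
})

test_that("a known junction is regrown exactly from read pairs", {
  set.seed(32)
  ref <- fixture_reference()
  ch <- simulate_chain(ref, "TRB", 9L)
  vg <- ref_genes(ref, "TRB", "V"); cg <- ref_genes(ref, "TRB", "C")
  vseq <- vg$sequence[vg$gene_name == ch$v_gene]
  cseq <- cg$sequence[cg$gene_name == ch$c_gene]
  sc <- build_scaffolds(list(mkc(ch$v_gene, vseq, "TRBV", "TRB")),
                        list(mkc(ch$c_gene, cseq, "TRBC", "TRB")),
                        estimate_gap_bounds(ref, "TRB"), locus = "TRB")[[1]]
  res <- fill_gap(sc, tile_pairs(ch$sequence),
                  gapfill_config(insert_size_mean = 120L))
  expect_s3_class(res, "tcr_chain")
  expect_equal(res$sequence, ch$sequence)
  js <- res$junction_interval
  expect_equal(substr(res$sequence, js[1] + 3L, js[2] - 3L), ch$junction_nt)

  # with no read pairs at all the scaffold is rejected for lack of candidates
  none <- fill_gap(sc, tile_pairs(ch$sequence)[0, ], gapfill_config())
  expect_s3_class(none, "tcr_rejection")
  expect_equal(none$reason, "no_candidates")
})

test_that("rejection reasons are exhaustive and mutually exclusive", {
  set.seed(33)
  v <- random_dna(1, 100); cc <- random_dna(1, 100)

  # candidates recruited but nothing extends: reads end at the flank edge
  sc0 <- build_scaffolds(list(mkc("Vx", v)), list(mkc("Cx", cc, "TRAC")),
                         gapest(40), locus = "TRA")[[1]]
  inert <- pairs_from_seqs(substring(v, 31, 80), random_dna(1, 50))
  res <- fill_gap(sc0, inert, gapfill_config(insert_size_mean = 120L))
  expect_equal(res$reason, "extension_stalled")

  # junction much shorter than the estimate: closure out of tolerance
  mid <- random_dna(1, 30)
  truth_short <- paste0(v, mid, cc)
  sc1 <- build_scaffolds(list(mkc("Vx", v)), list(mkc("Cx", cc, "TRAC")),
                         gapest(100), locus = "TRA")[[1]]
  res1 <- fill_gap(sc1, tile_pairs(truth_short),
                   gapfill_config(insert_size_mean = 120L))
  expect_s3_class(res1, "tcr_rejection")
  expect_equal(res1$reason, "gap_length_out_of_tolerance")

  # junction far beyond the reachable extension: no closure
  long <- random_dna(1, 250)
  truth_long <- paste0(v, long, cc)
  sc2 <- build_scaffolds(list(mkc("Vx", v)), list(mkc("Cx", cc, "TRAC")),
                         gapest(10), locus = "TRA")[[1]]
  res2 <- fill_gap(sc2, tile_pairs(truth_long),
                   gapfill_config(insert_size_mean = 120L))
  expect_s3_class(res2, "tcr_rejection")
  expect_equal(res2$reason, "no_closure")
})

test_that("loosening overlap or agreement never loses a closed gap", {
  set.seed(34)
  ref <- fixture_reference()
  for (locus in c("TRA", "TRB")) {
    ch <- simulate_chain(ref, locus, 3L)
    vg <- ref_genes(ref, locus, "V"); cg <- ref_genes(ref, locus, "C")
    sc <- build_scaffolds(
      list(mkc(ch$v_gene, vg$sequence[vg$gene_name == ch$v_gene],
               paste0(locus, "V"), locus)),
      list(mkc(ch$c_gene, cg$sequence[cg$gene_name == ch$c_gene],
               paste0(locus, "C"), locus)),
      estimate_gap_bounds(ref, locus), locus = locus)[[1]]
    pairs <- tile_pairs(ch$sequence)
    base <- fill_gap(sc, pairs, gapfill_config(insert_size_mean = 120L))
    expect_s3_class(base, "tcr_chain")
    looser <- fill_gap(sc, pairs, gapfill_config(
      min_overlap = 15L, base_agreement_ratio = 0.6, insert_size_mean = 120L))
    expect_s3_class(looser, "tcr_chain")
    expect_equal(looser$sequence, base$sequence)
  }
})

test_that("chains annotate with the correct J, insertions and frame", {
  ref <- fixture_reference()
  vg <- ref_genes(ref, "TRA", "V")[1, ]
  jg <- ref_genes(ref, "TRA", "J")[2, ]
  cg <- ref_genes(ref, "TRA", "C")[1, ]
  mkchain <- function(ins) {
    seqn <- paste0(vg$sequence, ins, jg$sequence, cg$sequence)
    nv <- nchar(vg$sequence)
    structure(list(
      locus = "TRA", sequence = seqn, v_gene = vg$gene_name,
      c_gene = cg$gene_name,
      v_contig = mkc(vg$gene_name, vg$sequence),
      c_contig = mkc(cg$gene_name, cg$sequence, "TRAC"),
      end_trim = 3L,
      junction_interval = c(nv - 2L, nv + nchar(ins) + nchar(jg$sequence) + 3L),
      junction_mean_coverage = 50), class = "tcr_chain")
  }
  ann <- annotate_chain(mkchain("GGG"), ref)
  expect_equal(ann$j_gene, jg$gene_name)
  expect_equal(ann$inserted_vj, "GGG")
  expect_equal(ann$deletions_v3, 0L)
  expect_equal(ann$deletions_j5, 0L)
  expect_equal(ann$frame_offset, 0L)
  expect_true(ann$productive)
  expect_false(ann$unannotatable)

  # a 4-base insertion shifts J out of frame: not productive
  ann4 <- annotate_chain(mkchain("GGGG"), ref)
  expect_equal(ann4$j_gene, jg$gene_name)
  expect_equal(ann4$frame_offset, 1L)
  expect_false(ann4$productive)

  # an in-frame stop codon in the junction is not productive either
  ann_stop <- annotate_chain(mkchain("TGA"), ref)
  expect_equal(ann_stop$frame_offset, 0L)
  expect_false(ann_stop$productive)
})

test_that("beta chains report the D gene or mark it undetermined", {
  ref <- fixture_reference()
  vg <- ref_genes(ref, "TRB", "V")[1, ]
  dg <- ref_genes(ref, "TRB", "D")[1, ]
  jg <- ref_genes(ref, "TRB", "J")[1, ]
  cg <- ref_genes(ref, "TRB", "C")[1, ]
  mkb <- function(mid) {
    seqn <- paste0(vg$sequence, mid, jg$sequence, cg$sequence)
    nv <- nchar(vg$sequence)
    structure(list(
      locus = "TRB", sequence = seqn, v_gene = vg$gene_name,
      c_gene = cg$gene_name,
      v_contig = mkc(vg$gene_name, vg$sequence, "TRBV", "TRB"),
      c_contig = mkc(cg$gene_name, cg$sequence, "TRBC", "TRB"),
      end_trim = 3L,
      junction_interval = c(nv - 2L, nv + nchar(mid) + nchar(jg$sequence) + 3L),
      junction_mean_coverage = 50), class = "tcr_chain")
  }
  ann <- annotate_chain(mkb(paste0("GG", dg$sequence, "TT")), ref)
  expect_equal(ann$d_gene, dg$gene_name)
  expect_equal(ann$inserted_vd, "GG")
  expect_equal(ann$inserted_dj, "TT")
  # too little D sequence to call: undetermined
  ann2 <- annotate_chain(mkb("GGTTAA"), ref)
  expect_equal(ann2$d_gene, "undetermined")
})

test_that("chain outputs round-trip through FASTA/TSV deterministically", {
  ref <- fixture_reference()
  set.seed(35)
  out <- tempfile("chains_out")
  empty_rejects <- data.frame(locus = character(), v_gene = character(),
                              c_gene = character(), reason = character())
  write_chain_outputs(list(), list(), list(), empty_rejects, out)
  expect_true(file.exists(file.path(out, "chains.fasta")))
  expect_equal(length(Biostrings::readDNAStringSet(file.path(out, "chains.fasta"))), 0L)
  ann_tab <- read.delim(file.path(out, "annotation.tsv"))
  expect_equal(nrow(ann_tab), 0L)

  # two chains from two V candidates, ordered by V gene name
  vg <- ref_genes(ref, "TRA", "V"); jg <- ref_genes(ref, "TRA", "J")
  cg <- ref_genes(ref, "TRA", "C")
  mk1 <- function(vi) {
    seqn <- paste0(vg$sequence[vi], jg$sequence[1], cg$sequence[1])
    nv <- nchar(vg$sequence[vi])
    structure(list(locus = "TRA", sequence = seqn, v_gene = vg$gene_name[vi],
                   c_gene = cg$gene_name[1],
                   v_contig = mkc(vg$gene_name[vi], vg$sequence[vi]),
                   c_contig = mkc(cg$gene_name[1], cg$sequence[1], "TRAC"),
                   end_trim = 3L,
                   junction_interval = c(nv - 2L,
                                         nv + nchar(jg$sequence[1]) + 3L),
                   junction_mean_coverage = 12.5), class = "tcr_chain")
  }
  chains <- list(mk1(2), mk1(1))
  anns <- lapply(chains, annotate_chain, ref = ref)
  contigs <- c(lapply(1:2, function(i) mkc(vg$gene_name[i], vg$sequence[i])),
               list(mkc(cg$gene_name[1], cg$sequence[1], "TRAC")))
  write_chain_outputs(chains, contigs, anns, empty_rejects, out)
  fa <- Biostrings::readDNAStringSet(file.path(out, "chains.fasta"))
  expect_equal(length(fa), 2L)
  expect_equal(names(fa)[1], paste("TRA", vg$gene_name[1], cg$gene_name[1],
                                   sep = "|"))
  expect_equal(as.character(fa[[1]]), chains[[2]]$sequence)
  cfa <- Biostrings::readDNAStringSet(file.path(out, "contigs.fasta"))
  expect_equal(length(cfa), 3L)
  expect_match(names(cfa)[1], "mean_cov=")
  ann_tab <- read.delim(file.path(out, "annotation.tsv"))
  expect_equal(nrow(ann_tab), 2L)
  expect_equal(ann_tab$v_gene, sort(vg$gene_name[1:2]))
})
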