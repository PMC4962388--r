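# Candidate selection, pileups, the 5x full-gene gate, consensus calling,
# and substring de-duplication.

test_that("candidate selection applies the strict 10% rule", {
  h <- counts_only_hits(rep("TRBV", 3), c("TRBV1", "TRBV2", "TRBV3"),
                        c(50L, 6L, 44L))
  expect_equal(select_candidates(h, "TRBV"), c("TRBV1", "TRBV3"))

  h1 <- counts_only_hits("TRAV", "TRAV1", 1L)
  expect_equal(select_candidates(h1, "TRAV"), "TRAV1")
  expect_equal(select_candidates(h1, "TRBV"), character())

  # exactly 10.0% is excluded (strictly greater required)
  hb <- counts_only_hits(rep("TRAV", 2), c("TRAV1", "TRAV2"), c(90L, 10L))
  expect_equal(select_candidates(hb, "TRAV"), "TRAV1")
})

make_gene <- function(name, seq) data.frame(gene_name = name, sequence = seq,
                                            stringsAsFactors = FALSE)

# map reads against a db holding only `gene` and pile them on it
pileup_on <- function(reads, gene_name, gene_seq) {
  ref1 <- tcrecon:::new_tcr_reference(data.frame(
    locus = "TRA", segment = rep(c("V", "C"), c(1, 1)),
    gene_name = c(gene_name, "TRACdummy"), allele_id = "01",
    sequence = c(gene_seq, strrep("ACGGT", 60)), stringsAsFactors = FALSE))
  h <- map_single(reads, ref1)
  ar <- assigned_reads(h, pairs_from_seqs(reads), "TRAV", gene_name)
  build_pileup(ar$seq, make_gene(gene_name, gene_seq), ar$hits)
}

test_that("pileups place read bases at reference coordinates", {
  set.seed(21)
  gene <- random_dna(1, 100)
  # a single read covering positions 1..50
  p1 <- pileup_on(substr(gene, 1, 50), "TRAVx", gene)
  expect_equal(unname(p1$depth), rep(c(1L, 0L), c(50, 50)))

  # error-free tiling at depth >= 5 everywhere; consensus equals the gene
  reads <- unlist(lapply(0:9, function(o)
    tiling_reads(gene, 50L, 10L)))
  p <- pileup_on(reads, "TRAVx", gene)
  expect_true(all(p$depth >= 5))
  expect_true(coverage_gate(p, candidate_config()))
  expect_equal(call_consensus(p)$sequence, gene)
})

test_that("reverse-strand reads contribute reverse-complemented bases", {
  set.seed(22)
  gene <- random_dna(1, 90)
  p <- pileup_on(rc(substr(gene, 11, 70)), "TRAVx", gene)
  expect_equal(unname(p$depth), rep(c(0L, 1L, 0L), c(10, 60, 20)))
  counts <- p$base_counts
  hit_pos <- which(p$depth == 1)
  bases <- rownames(counts)[apply(counts[, hit_pos], 2, which.max)]
  expect_equal(paste(bases, collapse = ""), substr(gene, 11, 70))
})

test_that("reads from a second allele leave its bases in the pileup and consensus", {
  set.seed(23)
  a1 <- random_dna(1, 120)
  diffs <- c(20L, 60L, 100L)
  v <- strsplit(a1, "")[[1]]
  for (d in diffs) v[d] <- setdiff(c("A", "C", "G", "T"), v[d])[1]
  a2 <- paste(v, collapse = "")
  # 50x coverage of allele *02 piled on the *01 reference
  reads <- unlist(lapply(1:10, function(i) tiling_reads(a2, 60L, 12L)))
  p <- pileup_on(reads, "TRAVal", a1)
  for (d in diffs) {
    expect_gt(p$base_counts[substr(a2, d, d), d], 0)
    expect_equal(unname(p$base_counts[substr(a1, d, d), d]), 0L)
  }
  expect_true(coverage_gate(p, candidate_config()))
  expect_equal(call_consensus(p)$sequence, a2)
})

test_that("the full-gene 5x gate is inclusive at the boundary", {
  p <- structure(list(gene_name = "g", length = 10L,
                      base_counts = matrix(0L, 4, 10,
                                           dimnames = list(c("A","C","G","T"), NULL)),
                      depth = rep(5L, 10)), class = "tcr_pileup")
  expect_true(coverage_gate(p, candidate_config()))
  p$depth[4] <- 4L
  expect_false(coverage_gate(p, candidate_config()))
  # edge_trim excludes termini only
  p$depth <- c(0L, rep(6L, 8), 1L)
  expect_false(coverage_gate(p, candidate_config()))
  expect_true(coverage_gate(p, candidate_config(edge_trim = 1L)))
})

test_that("a cross-mapping false positive fails the gate over its unique region", {
  set.seed(24)
  core <- random_dna(1, 120)             # shared core
  uniqA <- random_dna(1, 90)
  uniqB <- random_dna(1, 90)
  geneA <- paste0(uniqA, core)
  geneB <- paste0(core, uniqB)
  # reads drawn from gene A only, piled on similar gene B
  reads <- unlist(lapply(1:6, function(i) tiling_reads(geneA, 60L, 10L)))
  pB <- pileup_on(reads, "TRAVb", geneB)
  expect_false(coverage_gate(pB, candidate_config()))
  expect_true(all(pB$depth[150:210] == 0))   # B's unique tail: zero depth
  expect_true(any(pB$depth[1:120] >= 5))     # apparent coverage on the core
  pA <- pileup_on(reads, "TRAVa", geneA)
  expect_true(coverage_gate(pA, candidate_config()))
})

test_that("consensus ties break by the fixed base order A < C < G < T", {
  m <- matrix(0L, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", 1] <- 7L; m["G", 1] <- 3L        # clear majority
  m["C", 2] <- 5L; m["T", 2] <- 5L        # tie -> C
  m["G", 3] <- 2L; m["T", 3] <- 2L        # tie -> G
  p <- structure(list(gene_name = "g", length = 3L, base_counts = m,
                      depth = colSums(m)), class = "tcr_pileup")
  expect_equal(call_consensus(p)$sequence, "ACG")
  # zero-depth positions error without a reference fallback
  m2 <- m; m2[, 2] <- 0L
  p2 <- structure(list(gene_name = "g", length = 3L, base_counts = m2,
                       depth = colSums(m2)), class = "tcr_pileup")
  expect_error(call_consensus(p2), "zero-depth")
  expect_equal(call_consensus(p2, ref_seq = "TTT")$sequence, "ATG")
})

test_that("consensus is invariant under read order and pileups are additive", {
  set.seed(25)
  gene <- random_dna(1, 80)
  reads <- unlist(lapply(1:6, function(i) tiling_reads(gene, 40L, 8L)))
  perm <- sample(length(reads))
  p1 <- pileup_on(reads, "TRAVx", gene)
  p2 <- pileup_on(reads[perm], "TRAVx", gene)
  expect_equal(p1$base_counts, p2$base_counts)
  half <- seq_len(length(reads) %/% 2)
  pa <- pileup_on(reads[half], "TRAVx", gene)
  pb <- pileup_on(reads[-half], "TRAVx", gene)
  expect_equal(pa$base_counts + pb$base_counts, p1$base_counts)
})

mk_contig <- function(seq, cov = 10, name = "g") {
  structure(list(gene_name = name, class = "TRBV", locus = "TRB",
                 sequence = seq, mean_coverage = cov, min_depth = 5L),
            class = "tcr_contig")
}

test_that("substring-redundant contigs are removed, idempotently", {
  a <- mk_contig("ACGTACGT", 10, "a")
  b <- mk_contig("GTAC", 20, "b")
  expect_equal(dedupe_subsequences(list(a, b)), list(a))
  expect_equal(dedupe_subsequences(list(b, a)), list(a))

  # exact duplicates collapse to the highest-coverage copy
  c1 <- mk_contig("TTTTCCCC", 5, "c1")
  c2 <- mk_contig("TTTTCCCC", 9, "c2")
  expect_equal(dedupe_subsequences(list(c1, c2)), list(c2))

  # pairwise non-containing sets are untouched; a second pass is a no-op
  x <- list(mk_contig("ACGTACGTAC"), mk_contig("TGCATGCATG"),
            mk_contig("GGGGGAAAAA"))
  once <- dedupe_subsequences(x)
  expect_equal(once, x)
  expect_equal(dedupe_subsequences(once), once)
  expect_lte(length(dedupe_subsequences(list(a, b, c1, c2))), 4L)
})

test_that("an end-to-end single-gene cell selects exactly its source gene", {
  # error-free reads from one V gene: that gene alone survives selection and
  # gating, and its consensus equals the template
  ref <- fixture_reference()
  g <- ref_genes(ref, "TRB", "V")
  tmpl <- g$sequence[2]
  reads <- unlist(lapply(1:5, function(i) tiling_reads(tmpl, 60L, 4L)))
  h <- map_single(reads, ref)
  cands <- select_candidates(h, "TRBV")
  kept <- character()
  for (gene in cands) {
    gi <- g[g$gene_name == gene, , drop = FALSE]
    ar <- assigned_reads(h, pairs_from_seqs(reads), "TRBV", gene)
    p <- build_pileup(ar$seq, gi, ar$hits)
    if (coverage_gate(p, candidate_config()))
      kept <- c(kept, call_consensus(p)$sequence)
  }
  expect_equal(length(kept), 1L)
  expect_equal(kept, tmpl)
})
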