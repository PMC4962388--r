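# Recipe: Jurkat replicate subsampling (network; downloads GSE45428 FASTQs).
#
# Inputs:
#   jurkat/rep{1,2,3}_R{1,2}.fastq.gz   (GEO GSE45428 read sets)
#   refs/                               (IMGT human references, see imgt_benchmark.R)

library(tcrecon)

parts <- list()
for (locus in c("TRA", "TRB")) for (seg in c("V", "D", "J", "C")) {
  f <- file.path("refs", paste0(locus, seg, ".fasta"))
  if (file.exists(f))
    parts[[length(parts) + 1L]] <- load_germline_fasta(f, locus, seg)
}
ref <- do.call(combine_references, parts)

cfg <- pipeline_config(ref,
                       gapfill = gapfill_config(insert_size_mean = 148L))

depths <- c(50e3, 100e3, 500e3, 1e6, 5e6)
dir.create("repro_out", showWarnings = FALSE)
rows <- list()
for (rep in 1:3) {
  pairs <- read_fastq_pairs(sprintf("jurkat/rep%d_R1.fastq.gz", rep),
                            sprintf("jurkat/rep%d_R2.fastq.gz", rep))
  for (d in depths) for (seed in 1:6) {
    set.seed(seed)
    sub <- pairs[sample.int(nrow(pairs), min(d, nrow(pairs))), , drop = FALSE]
    res <- run_cell_pairs(sub, cfg)
    loci <- vapply(res$chains, `[[`, "", "locus")
    rows[[length(rows) + 1L]] <- data.frame(
      rep = rep, depth = d, seed = seed,
      alpha = "TRA" %in% loci, beta = "TRB" %in% loci)
  }
}
write.table(do.call(rbind, rows), "repro_out/jurkat_subsample.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
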