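# Shared fixtures for the test suite. All data is generated in code.

# small shared synthetic reference (memoised per session)
fixture_reference <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- make_synthetic_reference(seed = 7L)
    ref
  }
})

# constant-quality read-pair table from raw sequences
pairs_from_seqs <- function(seq1, seq2 = seq1, q = "I", id = NULL) {
  if (is.null(id)) id <- paste0("r", seq_along(seq1))
  read_pairs(id, seq1, strrep(q, nchar(seq1)), seq2, strrep(q, nchar(seq2)))
}

# error-free reads tiling a template at a given step, padded to read_len by
# wrapping within the template (reads fully inside the template)
tiling_reads <- function(template, read_len = 50L, step = 5L) {
  L <- nchar(template)
  starts <- seq(1L, max(1L, L - read_len + 1L), by = step)
  starts <- unique(c(starts, L - read_len + 1L))
  substring(template, starts, starts + read_len - 1L)
}

random_dna <- function(n, len) as.character(tcrecon:::cpp_random_dna(n, as.integer(len)))

rc <- function(x) as.character(tcrecon:::cpp_revcomp(x))

# default pipeline config used for simulated cells (fragment mean 300)
fixture_pipeline <- function(ref, ...) {
  pipeline_config(ref, gapfill = gapfill_config(insert_size_mean = 300L), ...)
}

# map a set of single-end reads (mate 2 is inert random filler, drawn once)
MATE2_FILLER <- "TGACCATGGTCGAGTCAACGGTTAGCCATAGGCTTACGCTAAGGCTCAAT"
map_single <- function(reads, ref, ...) {
  map_reads(pairs_from_seqs(reads, rep(MATE2_FILLER, length(reads))), ref, ...)
}

# minimal hits object carrying only a counts table (for candidate selection)
counts_only_hits <- function(class, gene_name, count) {
  structure(list(counts = data.frame(class = class, gene_name = gene_name,
                                     count = as.integer(count),
                                     stringsAsFactors = FALSE),
                 assignments = NULL, evalue_max = 1e-8),
            class = "tcr_hits")
}
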