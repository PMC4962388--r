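# Reproduction recipes (network required — not run by the test suite)

The scripts in this directory reproduce the published-scale analyses on real
references and data. They require downloads (IMGT germline databases, a
reference genome/transcriptome for background simulation, and the public
Jurkat and mouse T-helper read sets) and hours of compute, so they are
shipped as recipes only; the package's test suite and acceptance script run
entirely on the bundled synthetic generator.

- `imgt_benchmark.R` — build human TRA/TRB references from IMGT F+ORF+P
  V/D/J/C FASTA downloads (first allele per gene), verify the 33-99 bp
  beta-junction insert estimate, and run the full simulation benchmark
  (read lengths 25/50/75/100 bp, coverages 10/50/100x, insertions 0/3/6/9 bp,
  30 chain pairs, 3:997 mixing against genome-derived background).
- `jurkat_subsample.R` — run the pipeline on the Jurkat replicate read sets
  (GEO GSE45428) subsampled to 50 k / 100 k / 500 k / 1 M / 5 M read pairs at
  six seeds each (seqtk-style sampling via the simulator's RNG), with the
  Jurkat-like preset (insert size 148).
- `mouse_cohort.R` — QC-gate the 91 mouse T-helper cells (ArrayExpress
  E-MTAB-2512) on a precomputed metrics table and run the cohort pipeline
  with the C1 mouse-like preset (insert size 175), producing V-usage,
  paired-top and recovery-summary tables.

Each script documents its expected inputs at the top and writes its outputs
under `repro_out/`.
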