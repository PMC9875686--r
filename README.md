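# isoforge

Low-abundance-aware detection of full-length transcript isoforms from
spliced long-read RNA alignments (nanopore direct RNA-seq), plus the
benchmarking metrics and a synthetic read simulator to validate every
stage.

## Why

Nanopore direct RNA sequencing reads single native transcripts, but its
throughput is modest: in a run of *N* ≈ 10⁶ reads, a transcript expressed
at 1 TPM receives *X* ~ Binomial(N, 10⁻⁶) reads, and

> P(X ≤ 2) = `pbinom(2, 1e6, 1e-6)` ≈ 0.92.

Assemblers that filter isoform candidates by read coverage therefore
systematically discard real low-abundance isoforms. isoforge replaces the
coverage filter with per-cluster evidence checks:

1. **Splice-junction correction** — each donor/acceptor not on an
   annotated site is snapped to the nearest annotated same-kind site if
   the offset is ≤ 40 bp.
2. **Intron-chain collapsing** — corrected reads sharing an identical
   intron chain form one candidate isoform; single-exon reads cluster by
   reciprocal overlap ≥ 0.5.
3. **Gaussian-mixture boundary estimation** — per cluster, TSS and TES
   are the rounded mean of the highest-weight component of a 1-D GMM
   (k selected by BIC over 1..3; median fallback below 3 reads).
4. **Three-step filtering** — novel junctions need ≥ 2 supporting reads;
   novel chains need ≥ 1 polyadenylated read (a completed sequencing
   event); every cluster's TSS needs annotation or CAGE support within
   50 bp. Survivors are emitted as high-consensus full-length isoforms —
   including those backed by a single qualifying read.

Evaluation utilities score assemblies by intron-chain equality
(precision = TP/(TP+FP), recall = TP/(TP+FN)), compute ±25 bp orthogonal
TSS/TES support rates, SQANTI-style structural categories
(FSM/ISM/NIC/NNC), expression-stratified recall, and read-support CDFs.

## Worked example

Simulate a noisy run (12 genes, 800 reads, 20% 5'-truncation, splice
jitter, imperfect poly(A) calling), then call isoforms:

```r
library(isoforge)

cfg   <- sim_config(n_genes = 12, n_reads = 800, seed = 7)
truth <- generate_annotation(cfg)
expr  <- assign_expression(truth, cfg)
sim   <- simulate_reads(truth, expr, cfg, out_dir = "demo")

res <- call_isoforms(
  bam     = sim$sam_path,      # demo/reads.sam
  gtf     = sim$gtf_path,      # demo/truth.gtf
  polya   = sim$polya_path,    # demo/polya.tsv (nanopolish dialect)
  cage    = sim$cage_path,     # demo/cage.bed
  out_gtf = "demo/isoforms.gtf",
  verbose = TRUE)

idx <- build_reference_index(truth)
pr  <- precision_recall(res$isoforms, idx)
```

Output:

```
[isoforge] 800 reads, 43 reference transcripts
[isoforge] 1138 junction sides corrected
[isoforge] 101 clusters (18 single-exon)
[isoforge] filter 1 (novel junction support): 101 kept, 0 dropped
[isoforge] filter 2 (poly(A) evidence): 69 kept, 32 dropped
[isoforge] filter 3 (TSS support): 37 kept, 32 dropped
precision 1.000  recall 0.860 (TP 37, FP 0, FN 6)
isoforms with <= 2 supporting reads: 8
```

All 37 emitted isoforms are correct (precision 1.0); the 64 clusters
formed by truncated or artifact reads were removed by the poly(A) and TSS
filters, not by a coverage cutoff — which is why 8 of the emitted isoforms
have ≤ 2 supporting reads. The 6 missed transcripts received no
full-length read at this depth.

A thin CLI wraps the same functions
(`<pkg>/exec/isoforge call|eval|simulate`):

```sh
isoforge simulate --out-dir sim --seed 42
isoforge call --bam sim/reads.sam --gtf sim/truth.gtf \
              --polya sim/polya.tsv --cage sim/cage.bed --out isoforms.gtf
isoforge eval --assembly isoforms.gtf --reference sim/truth.gtf \
              --cage sim/cage.bed --report report.tsv
```

## Documentation

See the methods vignette (`vignettes/isoform-detection.Rmd`) for the
model, parameter rationale, the simulator's scope, and known limitations.
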