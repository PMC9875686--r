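---
title: "Detecting full-length isoforms from long-read RNA alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting full-length isoforms from long-read RNA alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nanopore direct RNA sequencing (DRS) reads single native RNA molecules from
the 3' poly(A) tail toward the 5' cap, so in principle one read spans one
full transcript. In practice three artifact classes corrupt the signal:
splice-site jitter from basecalling and alignment error, 5'-truncated reads
from RNA fragmentation and pore blocking, and chimeric or spurious splice
patterns. Assemblers that filter candidates purely by read coverage throw
the baby out with the bathwater: at typical DRS throughput (about 1M reads),
a transcript expressed at 1 TPM receives two or fewer reads with
probability `pbinom(2, 1e6, 1e-6)` ≈ 0.92, so a "need ≥ 3 reads" rule
discards most genuinely expressed low-abundance isoforms.

isoforge instead judges *evidence quality per read cluster*: is each splice
junction credible, did the molecule finish sequencing (poly(A) call), and
does the inferred 5' end look like a real transcription start site? A
transcript backed by a single full-length, polyadenylated, TSS-supported
read survives.

## Pipeline

1. **Parsing.** Primary alignments are converted to strand-aware exon
   blocks by walking the CIGAR (`M`/`=`/`X`/`D` extend a block, `N` opens a
   new one). Internal coordinates are 0-based half-open everywhere;
   GTF/SAM conventions are converted only at file boundaries. The
   transcript strand comes from the aligner's `ts` tag when present, else
   from the alignment strand.
2. **Junction correction.** Each junction side (donor/acceptor, assigned
   by strand) that does not already sit on an annotated site is moved to
   the nearest annotated same-kind site if the genomic offset is at most
   `max_shift` = 40 bp. Donor and acceptor are corrected independently;
   equidistant ties go to the smaller coordinate; a move that would shrink
   an exon below 1 bp or close an intron is cancelled rather than merging
   exons, because merging would silently change the intron chain.
   Correction is idempotent.
3. **Collapsing.** Corrected spliced reads are partitioned exactly by
   (chrom, strand, intron chain) — correction has already absorbed jitter,
   so chain comparison is exact, with no tolerance. Single-exon reads are
   clustered separately by single-linkage reciprocal overlap ≥ 0.5.
4. **Boundary estimation.** Per cluster, the 5' start and 3' end positions
   of all member reads are modeled independently with a one-dimensional
   Gaussian mixture fitted by EM in raw genomic coordinates. The number of
   components (k = 1..3) is selected by BIC; a variance floor of 1 bp²
   prevents singular components on duplicated positions; initialization is
   deterministic (quantile-spread means), so results are bit-reproducible.
   The reported boundary is the rounded mean of the highest-weight
   component, clamped into the observed range and constrained so every
   exon keeps ≥ 1 bp; minor components with weight ≥ 0.2 are kept as
   metadata (they often mark truncation modes), but one isoform is emitted
   per chain — emitting per-component isoforms would inflate false
   positives. Clusters with fewer than 3 reads use the median instead; EM
   on fewer points is ill-posed, and the low-abundance path must still
   produce boundaries.
5. **Three-step filter.**
   * *Junction support*: a cluster is discarded iff any junction absent
     from the annotation has fewer than `min_sj_reads` = 2 supporting
     reads (counted over all corrected reads, pre-collapse). Annotated
     junctions are exempt regardless of support.
   * *Poly(A) evidence*: a cluster whose chain is not in the annotation
     needs at least `min_polya_reads` = 1 member with a confirmed poly(A)
     call. One confirmed poly(A) read is the weakest evidence consistent
     with requiring "a completed sequencing process", and the threshold is
     configurable. Reads absent from the poly(A) table count as not
     polyadenylated. Annotated chains are exempt.
   * *TSS support*: every cluster (annotated or not) must place its
     primary TSS within `tss_window` = 50 bp of an annotated TSS or inside
     a CAGE peak extended by the same window. This window is a filtering
     parameter, deliberately distinct from the ±25 bp window used when
     *evaluating* termini against orthogonal peak data
     (`boundary_support_rate`).

   The filters are per-cluster predicates, so they commute; the order
   (junction → poly(A) → TSS) only affects which step gets attributed in
   the logs. Single-exon clusters skip the junction step and are emitted
   only when polyadenylated and TSS-supported — they are the
   highest-risk artifact class.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_shift` | 40 bp | junction correction bound |
| `min_sj_reads` | 2 | read support required for a novel junction |
| `min_polya_reads` | 1 | poly(A) reads required for a novel chain |
| `tss_window` | 50 bp | TSS filter window |
| `eval_window` | 25 bp | evaluation window for orthogonal peaks |
| `min_gmm_reads` | 3 | cluster size below which the median is used |
| `min_component_weight` | 0.2 | weight floor for reported minor components |
| `min_mapq` | 1 | drop unmapped/ambiguous alignments |
| `seed` | 42 | reproducibility of every stochastic step |

The MAPQ default is a package choice (drop only ambiguous alignments);
whether low-MAPQ reads should be excluded is data-dependent and the flag is
exposed. "Low-confidence splice sites" are operationalized as *any*
non-annotated site — the most conservative reading — so correction is
attempted for every such site within the bound.

## Evaluation metrics

Assemblies are scored by intron-chain equality against the reference
(the gffcompare-style `=` convention: terminal ends are not compared),
with each reference transcript consumable once; precision = TP/(TP+FP),
recall = TP/(TP+FN); undefined ratios are NaN, never silently 0.
Structural categories follow SQANTI semantics: FSM (chain equals a
reference chain), ISM (proper *contiguous* sub-chain — skipping internal
junctions is NIC/NNC, not ISM), NIC (only annotated sites, unseen chain),
NNC (≥ 1 unannotated site). ISM truncation sides and relative start-exon /
intron positions are computed in transcript orientation (strand-aware).

## What the simulator emulates — and what it does not

`sim_config()` defaults describe a realistic DRS run: 20 genes with 2–4
isoforms each (exon-skipping variants sharing the gene's first junction),
log-normal expression (meanlog 1, sdlog 1.5) normalized to 1e6 TPM,
multinomial read sampling, 20% of reads 5'-truncated by an exponential
length (mean 800 bp), per-junction jitter (probability 0.15, ≤ 30 bp, never
crossing an exon midpoint), Gaussian terminal noise (σ = 5 bp), poly(A)
detection probability 0.9 for full-length and 0.3 for truncated reads, and
5% poly(A)-call dropout. Truncation is 5'-only by default because the
motor sequences 3'→5'; a `truncate_3p` switch emulates degraded samples.

Deliberate simplifications: no base-level sequence or error simulation
(alignment geometry is what the pipeline consumes); genes do not overlap;
distinct same-kind splice sites are separated by at least an exon plus an
intron, so any jitter within `max_shift` is unambiguously correctable.
Passing tests on simulated data therefore demonstrate the pipeline's
logic — correction, collapsing, boundary estimation, filtering — but not
robustness to overlapping loci, paralog mismapping, or aligners whose
errors exceed 40 bp; on real data those cases surface as NNC calls or
dropped clusters.

## Numerical choices and degenerate inputs

* EM convergence: relative log-likelihood tolerance 1e-8, ≤ 500
  iterations; BIC = −2·logL + (3k−1)·log n; k capped at the number of
  distinct positions. Ties in BIC go to the smaller k.
* Components are ranked by weight, then mean (ascending) — deterministic
  primary selection.
* Median fallback rounds to the nearest integer position.
* A cluster of identical positions yields k = 1 with the floor variance.
* Empty inputs: empty read sets give empty cluster lists; an empty
  surviving set writes a valid empty GTF with a warning; empty site sets
  make `nearest_site` return nothing, leaving junctions uncorrected.

## Problem sizes used by the test-suite

Simulation-based tests use 5–20 genes and 300–10,000 reads with fixed
seeds; oracle-equivalence checks use 1,000 randomized instances per
primitive. These sizes give stable pass/fail behavior while keeping the
whole suite fast on a laptop.

## Known limitations

* One isoform per intron chain: alternative TSS/TES isoforms sharing a
  chain are reported only as minor mixture components, not separate calls.
* Gene assignment is by maximal exonic overlap; read-through transcripts
  can be attributed to either parent gene.
* The poly(A) dialect defaults to the nanopolish-polya column layout
  (`readname`, `qc_tag`, pass value `"PASS"`); both are configurable for
  other callers.
* Expression quantification, differential analyses, and short-read
  integration are out of scope; TPM tables are consumed as input only.
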