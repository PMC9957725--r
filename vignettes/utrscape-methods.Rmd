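---
title: "Methods: promoter architecture and the 5'UTR translational landscape"
author: "utrscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter architecture and the 5'UTR translational landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Most genes are transcribed from more than one transcription start site
(TSS), and the choice of TSS rewrites the 5' untranslated region (5'UTR)
of the mRNA without touching the protein it encodes. Because the 5'UTR
carries the regulatory elements that translation initiation reads — 5'
terminal oligopyrimidine (TOP) motifs, pyrimidine-rich translational
elements (PRTEs), upstream open reading frames (uORFs), secondary
structure — a TSS shift of a few nucleotides can change how efficiently an
mRNA is translated and whether it answers to mTORC1 nutrient signalling.
`utrscape` quantifies this layer from CAGE-style CTSS count data (a table
of capped 5'-end positions with tag counts) plus a genome, and carries the
analysis through to polysome-fraction translational-efficiency readouts
and isoform-level patient survival stratification.

## Models and statistics

**Promoter architecture.** CTSS positions on the same chromosome and
strand are clustered whenever consecutive positions are at most `maxdist`
(default 20 bp) apart — simple distance clustering, deliberately not
density-based. A cluster's width is the inclusive distance between the
positions where the cumulative tag fraction (accumulated in transcription
direction) first reaches 0.1 and 0.9; promoters with width < 10 bp are
*sharp*, all others *broad*. A single-position cluster has width 1.

**TOP status and TOPscore.** A TOP motif is a C at the +1 (cap-adjacent)
base followed by an unbroken run of at least 4 pyrimidines. The gene-level
TOPscore aggregates over TSS heterogeneity:

$$\mathrm{TOPscore} = \sum_i f_i \cdot \min(L_i, 16)$$

where \(f_i\) is the tag fraction at TSS \(i\) and \(L_i\) the pyrimidine
run length starting at that 5' end (0 for a purine start). The upstream
script the score originates from is not reproduced in the literature we
derive from; our functional form directly encodes "run length weighted by
peak height", and `topscore(..., transform = )` accepts an alternative
per-position transform should parity with the original implementation be
needed. The cap at 16 mirrors the upper bound of the motif definition; we
treat runs longer than 16 as still TOP (a longer pyrimidine tract cannot
plausibly abolish TOP behaviour) and cap only the score contribution.
Scores above 2 mark homogeneous TOP usage. Reporting is restricted to
genes averaging strictly more than 500 raw tags across samples; the
source does not say whether that average is over raw tags or tpm, and we
assume raw tags.

**TOP-like.** The class is used but never defined upstream. Our rule: a C
start followed by 1–3 pyrimidines, or a U start followed by at least 4.
It is a documented stand-in, configurable at the call site by
reclassifying from `run_length`.

**PRTE score.** A PRTE is 9 consecutive pyrimidines with an invariant
U at position 6, anywhere in the 5'UTR. Each CAGE tag is modelled as the
75-nt genomic sequence on the transcript strand starting at its 5' end
(sequencing errors not modelled); a tag counts toward its gene when that
read contains at least one PRTE. Per-gene counts are normalised to counts
per million mapped reads, and genes with score strictly above 10 are
flagged PRTE-containing.

**Polysome readouts.** Heavy (≥4 ribosomes) over light (≤3) polysome
CAGE signal per region proxies translational efficiency. Replicates are
tags-per-million normalised and averaged *before* the ratio (the design
this emulates averaged two independent experiments). Classes are exactly
low (ratio < 1), middle (1–3 inclusive) and high (> 3).

**Gene-level TE.** TE = ribosome-profiling RPKM / RNA-seq RPKM, with the
strict RNA RPKM > 1 filter and an optional base-mean > 25 filter (its
upstream placement is ambiguous, so it is an explicit flag rather than a
default). Distributions are compared with a two-sample Kolmogorov–Smirnov
test; the p-value uses the asymptotic Kolmogorov distribution with
effective size \(n_x n_y/(n_x+n_y)\), which is adequate at the sample
sizes involved (the exact small-sample distribution is only used as a test
oracle).

**Differential cluster usage.** The upstream pipeline used a
negative-binomial count model here. We deliberately substitute a
self-contained exact procedure: per cluster, a 2×2 Fisher exact test of
cluster tags versus remaining library tags between conditions (replicates
summed), log2 fold changes on tpm with pseudocount 0.5, and
Benjamini–Hochberg adjustment implemented as the standard step-up rule.
The substitution trades dispersion modelling for exact testability; with
only two replicate libraries per condition a fitted NB dispersion would be
poorly identified anyway. All outputs of this stage are labelled
accordingly.

**mTORC1 dependency.** For reporter data,
\((\mathrm{SCC}_{ctrl}-\mathrm{SCC}_{torin}) /
(\mathrm{SCC}_{ctrl}-\mathrm{WT}_{torin})\); 1 is a full Torin-1 effect, 0
none. The denominator is guarded at relative tolerance 1e-9.

**Isoform survival.** PSI of a transcript is its TPM over its gene's
total TPM (missing when the gene is silent in a patient; such patients
are excluded from stratification for that feature). Patients are split
into nearest-rank bottom/top quartiles (⌊n/4⌋ each, ties broken by stable
patient-id order — the upstream tie convention is unstated, and a
rank-based split also makes the TPM-versus-log-TPM question immaterial).
Kaplan–Meier curves use the product-limit estimator with median survival
at the first event time where \(S \le 0.5\); groups are compared by the
standard log-rank chi-square; hazard ratios come from a univariate Cox
partial likelihood maximised by Newton–Raphson (score tolerance 1e-8,
at most 100 iterations), with Breslow tie handling by default (Efron
available; the upstream convention is unstated, and the simulated data
have continuous times where the two coincide).

## The synthetic-data generator

There is no desk-scale route to the original sequencing libraries, so the
package ships a generator whose defaults *are* the stated world of the
analyses: four promoter classes (sharp TOP with a planted C + 4–16
pyrimidine tract; sharp non-TOP with a purine start; PRTE-plus with a
purine start and a valid PRTE 9-mer planted inside the UTR; broad mixed
with three TSS components 15 bp apart, one TOP-planted, with
condition-dependent mixture weights emulating a TSS-window switch of
0.7 → 0.2 on window 3); 5'UTR lengths uniform on 30–300 nt (the mammalian
range analysed); library depth 1e6 tags with exact multinomial
conservation; 2 replicates; heavy-polysome log-odds with a 3-fold TOP
effect (`beta_top = log(3)`), a 2-fold PRTE effect, and mild negative
length and GC effects; negative-binomial counts with dispersion 0.1 and
log-normal expression with sdlog 1 (conventional bulk-RNA-seq magnitudes,
chosen once and documented); a 519-patient cohort (the cohort size of the
survival analyses) with exponential survival tied to the risk isoform's
PSI, baseline median survival 60 months (between the 48- and 89-month
quartile medians reported upstream) and uniform censoring calibrated to
50% (a typical TCGA-like fraction).

What a green test on this world establishes: definitional and algorithmic
correctness, conservation laws, and unbiased recovery of planted effects
at stated depths. What it does not establish: robustness to mapping
artefacts, sequencing error, promoter classes outside the four simulated
archetypes, or NB dispersion misspecification — real CAGE libraries have
position-level noise structure this generator does not attempt.

Two generator details matter for interpretation. First, background
sequence is i.i.d. uniform, so spurious PRTE 9-mers occur in ~6% of 75-nt
reads; PRTE *sensitivity* on planted genes is the calibrated quantity,
not specificity. Second, `simulate_ribo_rna` returns its known
normalisation constants (`lib_ribo`, `lib_rna`); using observed column
sums instead would impose a composition bias on TE fold changes whenever
a planted shift moves total ribosome occupancy, which is a property of
library-size normalisation, not of the estimator.

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive internally (the R/Bioconductor
  convention); CTSS files are 1-based, BED6 is converted at I/O. Minus
  strand sequences are reverse-complemented before any motif scan, and
  cumulative quantiles run in transcription direction.
- N bases are never pyrimidines, never part of any motif, and break runs;
  they count in GC denominators only.
- The folding proxy is a Nussinov maximum-pairing dynamic programme
  (Watson–Crick + G·U, hairpin loops ≥ 3, −1 pseudo-energy per pair),
  deterministic and dependency-free; a thermodynamic engine can be
  plugged in via `fold_proxy(engine = )` and its values are flagged
  `"engine"`. Default uORF count is the NUG count (the upstream proxy);
  the stop-verified count is a separately named metric.
- Quantile positions use a 1e-12 tolerance on cumulative fractions so an
  exact 0.1/0.9 boundary is included.
- Empty CTSS tables, zero-tag profiles/clusters, zero light-polysome
  signal, zero-TPM genes, constant Cox covariates, event-free log-rank
  inputs and near-zero mTORC1 denominators all raise or propagate typed
  missing values rather than silently producing numbers.

## Known limitations

Power-law tag normalisation, paraclu-style density clustering, BAM
ingestion, NB-GLM differential testing, multivariate or stratified Cox
models, and thermodynamically parameterised folding are out of scope.
Isoform-level TE deconvolution is intentionally absent: the gene-level
ratio is what the upstream design measures.
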