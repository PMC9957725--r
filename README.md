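# utrscape

Promoter architecture and the 5'UTR-isoform translational landscape from
CAGE-style transcription start site (CTSS) data.

Most genes use several transcription start sites (TSSs), and shifting the
TSS by even a few nucleotides rewrites the mRNA's 5'UTR — exposing or
hiding the 5' terminal oligopyrimidine (TOP) motifs, pyrimidine-rich
translational elements (PRTEs), upstream ORFs and secondary structure
that set translational efficiency and mTORC1 sensitivity. `utrscape` is
for transcriptome and translation researchers who have per-position
capped-5'-end tag counts (CAGE CTSS tables), a genome and annotation, and
want to carry that data through promoter and 5'UTR analysis to polysome
readouts and patient survival.

What it computes:

- **Promoter architecture** — distance clustering of CTSS positions
  (`maxdist` 20 bp), 0.1–0.9 quantile promoter widths, sharp (< 10 bp) vs
  broad classes.
- **TOPscore** — per gene, `sum_i f_i * min(L_i, 16)` where `f_i` is the
  tag fraction at TSS `i` and `L_i` the pyrimidine run length starting at
  that 5' end; a TOP motif itself is a +1 C followed by ≥ 4 pyrimidines.
- **PRTE score** — tags whose 75-nt transcript-strand read contains a
  9-pyrimidine stretch with invariant U at position 6, per gene, in
  counts per million (flagged at > 10).
- **Translation readouts** — heavy/light polysome tpm ratios with
  low/middle/high classes (cuts at 1 and 3), gene-level TE
  (ribo RPKM / RNA RPKM, RNA RPKM > 1 filter), two-sample KS comparison,
  Fisher-exact differential tag-cluster usage with Benjamini–Hochberg
  correction, and the mTORC1-dependency reporter statistic
  `(SCC − SCC_torin) / (SCC − WT_torin)`.
- **5'UTR features** — length, GC, NUG sites (AUG/CUG/GUG/UUG) and strict
  uORFs, plus a Nussinov maximum-pairing folding proxy (pluggable
  thermodynamic engine).
- **Isoform survival** — PSI per transcript (TPM over gene TPM), splice
  event ratios, nearest-rank quartile stratification, Kaplan–Meier,
  log-rank and univariate Cox hazard ratios.
- **Synthetic data** — a generator that plants promoter classes, motifs,
  polysome odds and survival effects, so the whole pipeline is testable
  without downloads.

## Worked example

```r
library(utrscape)

classify_top_status("CUUUUCGGA")
#> $label
#> [1] "TOP"
#> $run_length
#> [1] 6
```

A C at +1 followed by five pyrimidines: a TOP motif with run length 6.
Now a full synthetic dataset and pipeline run:

```r
cfg <- sim_config(n_genes = c(sharp_top = 10L, broad_mixed = 10L,
                              sharp_nontop = 10L, prte_plus = 10L),
                  depth = 2e5, seed = 7L)
world <- make_genome(cfg)
tabs  <- simulate_ctss(world)
dir   <- tempfile()
write_simulation(world, dir, tables = tabs,
                 cohort = simulate_survival(cfg))
report <- run_pipeline(dir)

# median TOPscore per planted promoter class (WT condition)
#>           cls  topscore
#> 1  broad_mixed 1.7014791
#> 2    prte_plus 0.1048620
#> 3 sharp_nontop 0.1007678
#> 4    sharp_top 9.3690259
```

Genes planted with a TOP tract score high (9.4), purine-start classes
score near 0, and broad promoters that mix TOP and non-TOP TSSs land in
between (1.7) — the score reads TSS heterogeneity, not annotation.

```r
head(subset(report$widths, condition == "WT",
            c(chrom, start, end, total_tags, width, shape)), 4)
#>    chrom start  end total_tags width shape
#> 41 chrS1  1119 1122       3554     3 sharp
#> 42 chrS1  2433 2437      11745     3 sharp
#> 43 chrS1  4057 4061       6165     3 sharp
#> 44 chrS1  5466 5468        703     3 sharp

subset(report$survival, transcript_id == "tx_risk")
#>   transcript_id n_low n_high median_low median_high logrank_chisq
#> 1       tx_risk   129    129         NA    28.20152      79.87787
#>      logrank_p   cox_hr        cox_p
#> 1 3.982816e-19 19.71015 2.275485e-21
```

Patients in the top PSI quartile of the planted risk isoform have a
28-month median survival while the bottom quartile never reaches its
median (`NA`); the log-rank test and the Cox hazard ratio (per unit PSI,
hence large) both recover the planted effect.

## Command line

```sh
Rscript inst/cli/utrscape.R simulate --out data/ --seed 1
Rscript inst/cli/utrscape.R run-all  --dir data/ --out results/
Rscript inst/cli/utrscape.R topscore --dir data/   # TSV to stdout
```

Subcommands: `simulate`, `fixtures`, `run-all`, `topscore`, `prte`,
`width`, `windows`, `features`, `survival`. Exit codes: 0 success, 2
configuration error, 3 data error.

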