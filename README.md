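# posclip

Positional analysis of protein–RNA cross-linking (iCLIP) data, from
cross-link sites to five-region transcript occupancy, consensus
positional clustering, enrichment and overlap statistics — plus the
quantitative assay fits (binding K_D, mRNA half-life, unwinding
velocity, qPCR, cell-cycle deconvolution) that typically accompany such
a study. A synthetic-data module generates every input with planted
ground truth, so the whole pipeline runs and is tested end to end
without any external data.

## Who it is for

Anyone analysing iCLIP/eCLIP-style data who wants to know not just
*which* transcripts a protein binds, but *where* on each mRNA — and
whether that positional preference forms coherent gene classes (e.g.
5'UTR-binders vs. stop-codon binders such as the replication-dependent
histone mRNAs, which carry a 3' stem-loop instead of a poly(A) tail).

## The core model

* **Cross-link sites.** Reverse transcription truncates at the
  protein contact, so the site is the base immediately 5' of a read's
  5' end. Per-gene peaks are called against a uniform permutation null
  with a read-weighted FDR `(E[null exceedances]+1)/(obs exceedances+1)`;
  peaks within 20 nt merge into binding regions (kept if > 20 reads).
* **Enrichment.** Per gene, iCLIP cross-link reads vs. total-RNA counts
  under a negative-binomial model (variance `mu + alpha mu^2`) with a
  signal-masked median-of-log-ratios size factor and a trended,
  outlier-robust dispersion estimate; Wald test, BH adjustment.
  `enriched` = fold > 2 and adjusted p < 0.05.
* **Five regions.** Each transcript position is 5'UTR, start (+-50 nt of
  the start codon), CDS, stop (+-50 nt of the CDS/3'UTR junction) or
  3'UTR; per-region RPKM feeds a consensus k-means (k = 5, 200 rounds,
  1 − Pearson distance, median centres) that assigns a gene only when it
  co-clusters in ≥ 70% of rounds.
* **Assays.** One-site binding `FP(c) = FP_free + ΔFP·c/(K_D + c)`;
  one-phase decay `y(t) = (1 − plateau)·e^(−kt) + plateau`,
  `t_1/2 = ln 2 / k`; linear-phase unwinding velocity; ΔΔCt with
  efficiency 2; Watson pragmatic G1/S/G2-M deconvolution.

## Worked example

```r
library(posclip)

cfg <- sim_config(seed = 1, n_genes = 500, n_histone_like = 20)
dir <- tempfile()
tr  <- simulate_transcriptome(cfg, dir = dir)
cl  <- simulate_clip(cfg, tr, dir = dir)

rc  <- run_config(gtf = tr$gtf, sites_bed = cl$sites_path,
                  rna_counts_tsv = cl$rna_path,
                  stemloop_bed = tr$stemloop_bed, seed = 42)
res <- run_pipeline(rc, file.path(dir, "out"))

table(res$enrichment$status)
#>      enriched indeterminate    non_binder
#>           137           258           105

table(res$clustering$assignments$label)
#>             cds  five_prime_utr           start            stop three_prime_utr
#>              11              30              39              36              21

res$stemloop$upstream_fraction
#> [1] 1
```

The generator planted 140 bound genes among the 500; 137 come out
`enriched` and cluster into the five positional archetypes — the `stop`
cluster contains the histone-like genes — and all of the stem-loop
profile mass lies upstream of the stem-loop, as planted. Fitting a
simulated binding curve:

```r
fit <- fit_one_site(simulate_binding_curve(kd = 100, fp_free = 50,
        fp_bound = 200, concentrations = c(8, 16, 31, 63, 125, 250, 500,
        1000, 2000, 90, 45, 22), sd = 3, n_reps = 3, seed = 2))
round(c(kd = fit$kd, se = fit$se_kd), 1)
#>   kd   se
#> 94.6  5.5
```

## Acceptance script

`scripts/acceptance.R` regenerates the 2000-gene synthetic world from
the given seed, runs every pipeline stage on it (sites → peaks →
regions → enrichment → occupancy → clustering → profiles → motif
export), fits the binding, decay and cell-cycle models on freshly
simulated assay data, and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
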