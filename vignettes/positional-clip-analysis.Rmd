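---
title: "Positional CLIP binding analysis: models, assumptions and design choices"
author: "posclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional CLIP binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posclip)
```

# What the package computes

An iCLIP experiment maps where an RNA binding protein contacts its
transcripts: reverse transcription aborts at the cross-linked
nucleotide, so the position immediately 5' of a read's 5' end is the
contact site. `posclip` takes such read alignments (or pre-computed
sites) together with a transcript annotation and answers the positional
questions that motivate this kind of study: which genes are bound above
their expression level, *where* on the mRNA the protein sits (5'UTR,
start codon, CDS, stop codon or 3'UTR), whether genes fall into
consistent positional classes, how binding relates to a landmark such as
the histone 3' stem-loop, and whether binding regions overlap another
protein's sites more than chance allows. Companion fitters cover the
quantitative assays that usually accompany such a study: equilibrium
binding (K~D~ from fluorescence polarization), mRNA decay after
transcription shut-off (half-life), helicase progress curves (unwinding
velocity), qPCR relative quantification, RIP enrichment, and cell-cycle
deconvolution of DNA-content histograms.

Everything can be exercised end to end on synthetic data with planted
ground truth; that is how the test suite validates each stage.

# Transcript coordinates and the five regions

All positional analysis happens in transcript coordinates: the spliced
mRNA, 0-based, 5' to 3'. `genomic_to_transcript()` /
`transcript_to_genomic()` convert exactly (property-tested against a
brute-force enumeration of the spliced sequence on random multi-exon
models of both strands). One representative model is kept per gene: the
longest coding transcript, ties broken by CDS length and then transcript
id — a deterministic generalization of "longest coding mRNA" that does
not depend on any annotation source's status flags.

Each transcript is partitioned into five regions: 5'UTR (more than 50 nt
upstream of the start codon), **start** (50 nt on each side of the start
codon), CDS interior, **stop** (50 nt on each side of the CDS/3'UTR
junction) and 3'UTR. Two conventions were open and are fixed here:

* windows are half-open `[anchor - 50, anchor + 50)` and truncated at
  the transcript ends (a 10-nt 5'UTR leaves a 60-nt start window and an
  empty 5'UTR region);
* the stop anchor is the first 3'UTR base (the CDS/3'UTR junction), so
  the +-50 window is symmetric about the junction; for CDSs shorter than
  100 nt the two windows overlap and each overlapping position goes to
  the strictly closer anchor, ties to stop, leaving a zero-length CDS
  region.

`classify_position()` is tested against a literal re-implementation of
these sentences, including the short-UTR/short-CDS corners.

# Peaks, regions and enrichment

`call_peaks()` scores every position by its read count within +-3 nt and
compares against a null that redistributes the gene's reads uniformly
over its positions (100 permutations by default). The position-level FDR
is `(mean null exceedances + 1) / (observed exceedances + 1)` with
*read-weighted* exceedances: an exceedance is a read at a position whose
window score reaches the score under evaluation. Read weighting matters:
with position counting, a single position carrying every read of the
gene could never drop below `1/(window size + 1)`, which contradicts the
intended behaviour that maximal concentration is maximally significant.
Seeds are derived per gene, so results do not depend on the order or
subset of genes processed. Peaks within 20 nt merge into binding
regions and only regions with strictly more than 20 reads survive.

`enrichment_test()` asks, per gene, whether the iCLIP signal exceeds
what the total-RNA abundance predicts. The pipeline feeds it total
per-gene cross-link reads: reads-in-peaks (also computed and written)
are structurally zero for background genes, which would starve a
ratio-based size factor of null genes; gene totals keep the
normalization anchored while peaks still gate the motif and region
stages. Callers can equally pass reads-in-peaks together with explicit
`library_sizes` when the true depths are known. The model is two negative
binomial counts with a shared dispersion and a library-size offset; the
Wald statistic is the normalized log fold change over its delta-method
standard error. Three estimation choices deserve explanation:

* **Size factor.** A plain total-count ratio is absorbed by the planted
  signal itself whenever a non-negligible fraction of genes is bound.
  The factor is therefore the median of per-gene log ratios, re-estimated
  after masking genes that look like signal (|z| > 2.5). The mask is
  symmetric and built from a negation-invariant dispersion estimate, so
  swapping the two count tables negates every log2 fold change exactly —
  a tested invariant.
* **Dispersion trend.** Genes are binned on the swap-invariant geometric
  mean count; the null scale per bin comes from the lower-tail quantile
  spread (Q05 to Q30) of the log ratios, which tolerates a one-sided
  excess of enriched genes, with genes flagged as apparent enrichment
  masked out iteratively. A parametric trend `alpha(mu) = a0 + a1/mu` is
  fitted across bins (the standard hyperbolic shape of count-model
  dispersion trends), floored at 0.01.
* **Status.** `enriched` means fold change > 2 *and* BH-adjusted
  p < 0.05; `non_binder` means |log2FC| < 0.2 and p > 0.1; everything
  else (including genes with both counts zero, which are not tested) is
  `indeterminate`.

On a 2000-gene null with dispersion 0.05 the fraction of p < 0.05 sits
within [0.03, 0.07]; 4-fold planted genes with adequate counts are
recovered at or above 90% sensitivity with median log2FC near 2 — both
are acceptance-tested.

# Occupancy, clustering and profiles

`compute_occupancy()` produces, per enriched gene with more than 20
reads, the read count and RPKM of each of the five regions (RPKM uses
the region length and the total site reads of the considered genes as
the library). `consensus_cluster()` then repeats k-means (k = 5) 200
times with random initial centres, distance 1 - Pearson correlation and
component-wise *median* centres, on rows normalized to proportions.
Rounds are aligned to the first round by greedy centre-correlation
matching and a gene is assigned only if it lands in the same aligned
cluster in at least 70% of rounds; clusters are labelled by their
centre's dominant region. The "occurrence" statistic is defined
operationally as this modal-cluster frequency, since the consensus
support of the original GUI tool is not documented. Constant-occupancy
rows (Pearson undefined) fall back to Euclidean distance and are
flagged; in practice they end up unassigned, which is the correct
behaviour for a gene with no positional preference. Tie-breaks
(nearest-centre ties to the lowest raw cluster index, iteration cap 100,
empty clusters re-seeded with the worst-fitting row) are fixed so runs
are reproducible under a seed.

`metagene_profile()` normalizes each gene's site counts to sum one over
the transcript and averages per-offset densities across the genes
covering that offset; `stemloop_profile()` does the same in a +-100 nt
window anchored at the stem-loop's first base and reports the fraction
of profile mass upstream. With the per-gene-proportion normalization
(the published profile's normalization is stated to be arbitrary), a
histone-like simulation places its mass in the 30 nt upstream of the
stem-loop, and symmetric uniform input gives an upstream fraction of
100/201.

# Motifs and interval overlap

`select_motif_regions()` exports, per enriched gene, the binding region
with the most peaks (ties: more reads, then 5'-most), trimmed to 20 nt
around its centre; background regions are all surviving regions of
non-binder genes. `kmer_enrichment()` scores 4/6/8/10-mers by
presence/absence per sequence with a one-sided hypergeometric test, BH
adjusted within each size — presence rather than occurrence counts
because the windows are only ~40 nt. This replaces external motif
discovery; the FASTA export remains available for such tools.

`overlap_randomization()` measures the nucleotide overlap between query
and reference intervals and re-places the query segments uniformly in
the workspace (lengths preserved, segments kept disjoint by sequential
rejection sampling) to get an empirical p with the standard
`(exceedances + 1)/(n + 1)` correction. Two caveats are inherent and
documented rather than hidden: the p-value is discrete (its floor is
`1/(n_samples + 1)`), and when interval sets are sparse the overlap
statistic has a large atom at zero, so p cannot be uniform under the
null — calibration is therefore tested in a dense regime where the
statistic is effectively continuous.

# Assay fitters

**One-site binding.** `FP(c) = FP_free + (FP_bound - FP_free) c/(K_D + c)`,
least squares with data-driven starts. The fit never throws: failures
and K~D~ beyond 10x the largest concentration return
`converged = FALSE` (flag `weak_binding`). The model uses total protein
concentration; the ligand-depletion quadratic is unnecessary at probe
concentrations far below K~D~. `compare_kd()` runs one-way ANOVA across
condition groups of fitted K~D~s, excluding groups with non-converged
members.

**One-phase decay.** `y(t) = (1 - plateau) e^{-kt} + plateau` with
`y(0) = 1` fixed, `k >= 0`, `plateau` in `[0, 1)`; replicates pool into
one fit; `t_half = ln 2 / k`, and rates below 10^-3^/h are reported as
stable (infinite half-life). Starting values come from profiling the
rate on a log grid (the plateau is linear in the model given `k`), which
makes the fit immune to bad initialization. By default an
extra-sum-of-squares F test (alpha = 0.05) decides whether the free
plateau is warranted: over a typical 4-half-life time course a free
plateau is weakly identified and nearly doubles the variance of the rate
estimate, while the F-test default recovers a genuine plateau exactly
when the data support it. `plateau_mode = "free"` / `"zero"` override
the choice.

**Unwinding velocity.** If the whole progress curve is linear
(r^2^ >= 0.98) its slope is the velocity. Otherwise the search starts
where the signal first exceeds baseline + 3 baseline-sd and selects the
longest window with r^2^ above threshold (ties: earliest); if none
qualifies, the best minimal window is used and flagged. Note that with
noise-free data extending well past the plateau, the longest qualifying
window can legitimately include the plateau corner — the r^2^ criterion,
not the generating process, defines "linear part".

**qPCR.** Delta-delta-Ct with amplification efficiency fixed at 2
(configurable; no standard curves are modelled), calibrated to the 0-h
sample; RIP enrichment normalizes IP to input and expresses the result
relative to the IgG control. Both are tested against independent
spreadsheet-style arithmetic on random tables.

**Cell cycle (Watson pragmatic).** G1 and G2/M are Gaussians, the G2
mean constrained to 1.8-2.2x the G1 mean, and S phase is the residual
between the two means — no parametric S model. Pure one-sided flank
fits turned out to sit on an amplitude/mean/sd ridge whose variance
alone exceeds the recovery tolerance, so the implementation estimates a
pragmatic S background (flat between the means, edges blurred with the
measurement CV) from the inter-peak region, subtracts it, and fits each
Gaussian on a symmetric +-3 sd window with Poisson weights, iterating
four times. The S count is the clipped residual between the means plus
the modelled blur of the S background just beyond them. A lone
high-channel peak with no mass at half its position is interpreted as a
pure G2 population. Debris/doublet gating is out of scope; input is
assumed pre-gated.

# The synthetic world

`sim_config()` fixes the generator's defaults once:

* 500 genes (2000 in the end-to-end fixture), log-normal UTR/CDS lengths
  around 200/1200/400 nt, CDS at least 150 nt so the codon windows
  cannot overlap; 1-4 exons, both strands, five chromosomes.
* bound genes split across the five positional archetypes in the
  proportions of the reported positional clusters (164/199/56/125/124),
  with 75% of genes unbound — roughly the share of expressed genes
  without binding in the study this emulates — so library normalization
  stays anchored on a null majority; histone-like genes (20 by default)
  carry a 16-nt stem-loop segment (6-base stem + 4-nt loop + 6-base
  stem) near the 3' end and place their sites uniformly in the 30 nt
  upstream of it.
* cross-link placement is Gaussian with sd 15 nt around the archetype
  centre — comparable to the 50-nt region half-width, so clustering is
  noisy but solvable; unbound genes place sites uniformly.
* counts are negative binomial with variance `mu + alpha mu^2`
  (alpha = 0.05), 4-fold planted enrichment, and library sizes of
  2 x 10^5^ reads.
* assay noise: 5 mP polarization sd, 0.1 cycle Ct sd, cv 0.05 DNA-content
  histograms binned over `[0, 3 x G1 mean]` in 256 channels (typical
  cytometer resolution).

The generator emulates the statistical structure the pipeline assumes —
position-biased truncation counts, NB count pairs, one-site/one-phase
curves, Gaussian-plus-uniform DNA content. It does *not* emulate
sequence-dependent cross-linking bias, PCR duplication, mappability,
isoform mixtures, or real histone sequence content; a green test
establishes that the algorithms recover what they claim from data
matching their model, not that the model is a complete account of real
libraries.

# Reproducibility

Every stochastic operation takes an explicit seed; pipeline stages
derive their seeds from the global seed hashed with the stage name, so
inserting a stage does not shift the randomness of the others. Running
the pipeline twice with the same configuration produces byte-identical
outputs, and the manifest records the configuration hash, input hashes
and per-stage record counts.

# Known limitations

* Alignment ingestion is BED-based; convert BAM with
  `bedtools bamtobed` first.
* The enrichment test models pooled counts (one iCLIP, one RNA column);
  replicate-aware differential binding is out of scope.
* Binding regions live in transcript coordinates throughout the
  positional stages; they are lifted to genomic coordinates only where
  interval comparison requires it.
* The k-mer scorer ranks exact matches; degenerate motifs and position
  weight matrices are deliberately left to dedicated motif tools via the
  FASTA export.
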