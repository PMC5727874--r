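---
title: "Models and methods behind vomeroseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vomeroseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vomeroseq re-implements, as one tested toolkit, the downstream analyses
of a multi-strain, both-sex bulk RNA-seq design: negative-binomial
differential expression across all pairwise strain contrasts, a
cross-strain sex-dimorphism screen with X/Y dosage accounting, a
sliding-window Poisson scan for genomic DE hotspots, strain-exclusive
expression patterns, variant-aware pseudogene ORF reconstruction, and
bootstrap expression dendrograms. This vignette records the models, the
parameters that matter, and the design choices made where the design was
genuinely open.

## The count model and the DE core

Counts are modelled as negative binomial in the mean–dispersion
parameterization, `Var(K) = mu + alpha * mu^2`, one `alpha` per gene.
The package deliberately implements a *documented simplified core*
rather than wrapping an existing DE engine:

* **Size factors** are plain median-of-ratios: for genes positive in
  every sample, `s_j = median_g(K_gj / geomean_g(K))`, then rescaled to
  geometric mean 1 so normalized counts live on a stable common scale.
  There is no pseudo-reference fallback; a matrix in which no gene is
  positive everywhere is refused with an explicit error, because silently
  switching estimators changes the meaning of "normalized count > 1"
  thresholds used downstream.
* **Dispersion** is method-of-moments: with groups defined by
  strain x sex, `alpha_hat = max(0, (v - m) / m^2)` where `v` is the
  pooled within-group variance and `m` the grand mean of normalized
  counts. No trend fitting and no shrinkage — at desk scale (tens of
  samples, thousands of genes) the pooled estimator is identifiable and
  keeps the implementation auditable. The cost is a noisier `alpha_hat`;
  the two places where that bites (test calibration, outlier masking)
  are handled explicitly below.
* **The Wald test** uses `LFC = log2((mean_A + c)/(mean_B + c))` with
  pseudocount `c = 0.5` normalized counts (keeps all-zero groups finite
  and stabilizes low means), a delta-method standard error from the NB
  variance of each group mean, and a **t reference** with
  `df = n_samples - n_cells` (cells = strain x sex), the degrees of
  freedom of the pooled variance. A standard-normal reference was the
  initial design, but with 32 samples and 8 cells (24 df) its null
  fraction of `p < 0.01` sits at ~0.017–0.021 — at or beyond the upper
  edge of the package's own calibration target of [0.005, 0.02] on 5000
  null genes. The t tail restores calibration (~0.009–0.012 measured by
  the acceptance suite) without any tuned constant. The same reference
  is used by the dimorphism screen.
* **Independent filtering** flags genes with a sample whose
  Cook's-distance analogue `D = (y - mu)^2 / (k * (mu + alpha*mu^2))`
  exceeds the `F(k, n-k)` 99th percentile. With unshrunk per-gene
  moment dispersion a gross outlier inflates its own gene's `alpha_hat`
  and masks itself, so `mu`, the pooled variance and `alpha` entering
  `D` are computed *leave-one-out* for the sample being tested (the
  variance stays pooled across groups, keeping `n - k - 1` df and the F
  cutoff meaningful), and the residual is rescaled by `(n_g - 1)/n_g`
  to the within-group scale. On clean NB data roughly 5–10% of genes
  still get filtered — the honest price of heavy NB tails without
  shrinkage; the recovery tests show sensitivity for planted 4-fold
  effects remains ~0.85–0.9 with false discovery proportion ~0.01–0.02.
* **Classification**: DE = (passes filtering) and (`|LFC| > 1` and
  BH `q < 0.05`) in at least one of the six pairwise strain contrasts.
  BH is applied per contrast, mirroring per-contrast testing.

Two "expressed" notions are exposed because both are in common use:
raw count > 0 in any sample ("expressed anywhere", used to build scan
windows) and strain-mean normalized count > 1 ("expressed in a strain",
used for presence patterns and dendrogram gene sets). Both thresholds
are arguments, not constants.

## Sex dimorphism and dosage compensation

"Weighted fold change" is implemented as the sample-size-weighted
geometric mean of per-strain male/female fold changes:
`wFC = 2^(sum(w_s * LFC_s)/sum(w_s))`, `w_s` = strain sample count
(configurable to equal weights). It is symmetric, scale-free, and
reduces to the plain fold change for balanced designs. The dimorphic
flag requires `|wFC| > 2`, `p < 0.01` (a plain p cutoff, not FDR — the
screen is confirmatory across strains, not exploratory), and the same
direction in all strains; the direction rule operationalizes
"consistently observed across all strains" and can be toggled off. The
dispersion entering the per-strain variances can be pooled across all
samples (default) or re-estimated within each strain — both are exposed
because the pooled/per-strain choice is genuinely open at these sample
sizes.

The dosage report is pure accounting on normalized means: female X vs
male X + male Y per homolog pair, with the identity
`combined_male = x_male + y_male` kept exact and a validation error on
nonzero female Y counts (a biological impossibility that indicates
mis-annotation or sample swaps). The within-strain analysis reruns the
Wald test inside each strain, so a sex effect confined to one strain
(the Simpson's-paradox case) is reported with its strain label while
correctly failing the cross-strain screen.

## The hotspot scan

Windows contain exactly 25 expressed genes and slide one gene at a time
within each chromosome; 25 balances resolution against Poisson-tail
granularity (with `lambda = 25 * 0.128 = 3.2`, counts of 9–11 are
already deep in the tail). The test is the inclusive upper tail
`P(X >= k)`; inclusivity matters because the observed count itself is
the evidence. BH runs genome-wide over all windows — a single FDR
statement about the whole scan — and significant windows sharing at
least one gene on a chromosome merge, with the hotspot interval spanning
its member genes. Because significance implies enrichment, every
reported hotspot's %DE exceeds the genome rate; the suite asserts this
directly. The genome rate defaults to (total DE)/(total expressed) over
the same expressed set used to build the windows, so the null is
self-consistent.

Report tables round span to 2 decimals (Mb) and percentages to 1
decimal, **half-up** — matching how such tables are printed; R's
banker's rounding would disagree on exact .5 boundaries.

## Pseudogene functionalization

Variants are applied right-to-left so positions always refer to the
original reference; SNVs substitute, insertions add bases after their
position (VCF style, `alt` extends `ref`). Only SNVs and biallelic
insertions are supported — deletions and multi-allelic records raise an
"unsupported variant class" error rather than being skipped, because a
silently dropped variant would corrupt the ORF call. ORF search covers
the three forward frames only (inputs are per-gene, sense-strand
sequences), takes the longest ATG-to-first-stop ORF, ties broken by the
earliest start. Translation uses the standard code via Biostrings; the
codon table used by the synthetic-homolog builder is the plain
`GENETIC_CODE` lookup, since `translate()` on a lone codon applies the
initiator rule (CTG/TTG read as M) — a subtlety that the acceptance
suite caught as off-by-one identity percentages.

"Functional" means the edited sequence's longest ORF reaches at least
95% of the homolog ORF length while the reference's does not. The 95%
threshold is explicit configuration: "full-length" has no numeric
definition in the source material, and 95% tolerates small terminal
differences while excluding genuinely truncated products. Percent
identity comes from global (Needleman–Wunsch) alignment with fixed,
documented scoring — nt: match +1 / mismatch −1, gap 5 open / 1 extend;
aa: BLOSUM62, gap 11/1 — and equals `100 * matches / alignment columns`,
so results are bit-reproducible. Local alignment would inflate identity
for partially restored ORFs; global alignment is the conservative
choice and is validated on synthetic constructions where the planted
identity is known exactly.

## Correlation and dendrograms

Spearman correlation is computed as average-tie ranks followed by the
Pearson formula, written out in full (it is the statistic under test)
and checked against `stats::cor` to 1e-12. Constant genes have no rank
variance; their correlations are recorded as missing and flagged, never
silently zeroed. Average-linkage (UPGMA) agglomeration is likewise
hand-written with a deterministic tie-break — among equal-distance
pairs, the pair whose lexicographically smallest leaf label is smallest
merges first — so trees are reproducible across platforms; it returns a
standard `hclust` object and is verified against `stats::hclust` on
random matrices (ties have measure zero there).

Expression dendrograms cluster **strains** using per-strain mean
profiles of normalized counts, genes as observations, distance
`1 - rho`. Per-sample profiles are available but strain means are the
default: the trees of interest have strains as leaves, and averaging
removes replicate-level noise that the bootstrap is meant to quantify
at the gene level. Bootstrap support resamples genes with replacement
(default `n_boot = 1000` at desk scale; 10,000 by argument); bp of a
node is the fraction of bootstrap trees containing the same leaf set.
AU support uses the standard multiscale-bootstrap probit fit: for scale
`r` in 0.5–1.4, resample `ceil(r * n)` genes, record bp(r), fit
`qnorm(1 - bp(r)) = v*sqrt(r) + c/sqrt(r)` by least squares over
non-degenerate scales, and report `au = 1 - pnorm(v - c)`. Nodes with
bp exactly 0 or 1 at every scale keep that value as au and are flagged
`degenerate` — the probit fit has no information there.

## What the generator emulates — and what it does not

`simulate_counts()` reproduces the statistical structure the analyses
assume: 4 strains x 2 sexes x 4 replicates, ~10,000 genes, log-normal
baseline means and dispersions, per-sample library factors uniform on
[0.7, 1.3], a genome-wide planted DE rate of 0.128 with 12 contiguous
clusters at local rate 0.42 (cluster sizes 25–122 expressed genes, the
range reported for real DE hotspots), each DE gene shifted `2^±2` in one
strain. Augmentations add dosage-compensated X/Y pairs
(female X mean = male X + male Y exactly, Y silent in females), a
female-only Xist-like gene, and lncRNA/receptor blocks with
proportional (Spearman +1) or rank-reversed (−1) strain profiles.
Background DE probability is lowered so the *overall* planted rate
equals 0.128 despite the enriched clusters.

Real data differ in ways the generator does not model: batch effects,
library-preparation artefacts, isoform switching, correlated gene-gene
noise beyond the planted blocks, annotation errors, and mapping
ambiguity. Passing recovery tests therefore demonstrates that the
*methods* recover what they claim under their own model — not that any
particular biological dataset satisfies that model.

Problem sizes in the test and acceptance suites are the package's desk
scale: 10,000-gene genomes for the hotspot scan (50 seeds), 5000 null
genes for calibration, 500 planted-LFC genes for recovery, 50–200 seeds
for the dimorphism/dosage/pseudogene Monte-Carlo checks, and 1000
bootstrap replicates for dendrogram support. These run the full suite
in a couple of minutes while leaving every estimator identifiable.

## Known limitations

* No GLM with covariates, no shrunken LFCs, no likelihood-ratio tests;
  results will not numerically match shrinkage-based DE engines, and
  are not meant to — recovery against planted truth is the contract.
* The moment dispersion is per-gene and unshrunk; very low counts give
  `alpha_hat = 0` often, and the independent filter inherits NB-tail
  false positives (~5–10% of clean genes at the 99% F cutoff).
* The Poisson window null treats genes as exchangeable within the
  genome rate; correlated expression along chromosomes beyond the
  planted clusters would inflate the scan's optimism.
* ORF logic is splice-unaware and forward-strand only; deletions and
  structural variants are out of scope.
* AU values come from an ordinary least-squares probit fit; they are
  recovery-grade, not a numerical replica of any particular multiscale
  implementation.
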