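---
title: "Models and methods behind ctvtsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctvtsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctvtsig)
```

`ctvtsig` analyzes serial-biopsy studies of regressing canine transmissible
venereal tumors (CTVT): paired expression time courses across the
progressive (P), stationary (S) and regressive (R) clinical phases,
contrasted between dogs whose tumors regress after vincristine and dogs
whose tumors do not. This vignette explains the models the package fits,
the parameters that matter, the synthetic data that backs the test suite,
and the numerical and design choices made where more than one reasonable
convention exists.

## The count model

Gene-level counts are modeled as negative binomial with a quadratic
mean–variance relationship,

$$ y_{gs} \sim \mathrm{NB}(\mu_{gs}, \alpha_g), \qquad
   \mathrm{Var}(y_{gs}) = \mu_{gs} + \alpha_g \mu_{gs}^2, $$

with a log link,
$\log \mu_{gs} = x_s^\top \beta_g + \log \mathit{sf}_s$. The size factors
$\mathit{sf}_s$ are median-of-ratios estimates (median across reference
genes of the sample's count over the gene's geometric mean), rescaled to
geometric mean one. The reference set is genes positive in every sample;
if that set is empty the estimator falls back, with a warning, to genes
positive in at least half of the samples.

Two designs are supported:

* **paired within-cohort**: `~ dog + biopsy`. The dog factor absorbs every
  animal-level offset (tumor size, sequencing depth structure, genetic
  background), so biopsy coefficients are within-animal time effects.
  Phase contrasts are read off the coefficients: S/P is the biopsy-2
  effect, R/P the biopsy-3 effect, R/S their difference.
* **two-cohort interaction**: `~ regression + regression:dog + regression:time`
  with dogs re-indexed within regression status (the standard nested
  encoding for individuals within groups). The interaction statistic is
  the Wald contrast between the two arms' biopsy-2 time effects — the
  "difference of within-dog fold changes" comparison.

Fold changes are defined as $2^{\hat\beta}$ from the model coefficients,
not as ratios of normalized means, because the study-style cutoffs
(FC > 10, BH-adjusted p < 0.01, both strict) are applied to model output.
No shrinkage is applied to fold-change point estimates.

### Filtering

Genes whose total count across all samples falls in the lowest 40 % of the
row-sum distribution are removed before any estimation, and removed genes
never enter BH denominators. Ties at the cutoff are retained: with ties
the "lowest 40 %" is ill-defined, and retaining keeps the rule monotone
(adding reads never removes a gene). Filtered or never-converged genes
carry an explicit not-tested marker (`tested = FALSE`, numeric `NA`)
rather than fabricated values.

### Dispersion estimation

With two or three biopsies per dog the residual degrees of freedom per
gene are very small (two for three dogs × two biopsies), so raw per-gene
dispersion estimates are extremely noisy and naive plug-in values make
Wald statistics anticonservative. The package therefore:

1. fits Poisson GLMs to get initial means and a single pooled dispersion
   from the generalized-Pearson equation
   $\sum_s (y_s-\mu_s)^2 / (\mu_s + \alpha \mu_s^2) = \mathrm{df}$,
   then refits the means at the pooled value so the residuals see
   approximately correct weights;
2. solves the same Pearson equation per gene (monotone in $\alpha$, solved
   by bisection on $[0, 10]$);
3. pools genes into expression bins (20 bins, at least 20 genes each) and
   solves the pooled equation per bin, giving a mean–dispersion trend that
   is nearly unbiased because pooling removes the truncation-at-zero
   noise of per-gene estimates;
4. uses $\max(\text{gene-wise}, \text{trend})$, clamped to
   $[10^{-8}, 10]$, as each gene's working dispersion.

The maximum rule is deliberately conservative: a gene whose dispersion is
underestimated by sampling noise would otherwise get an inflated Wald
statistic, and at genome scale the far tail of thousands of such genes is
exactly what false-discovery control depends on. The test suite verifies
the resulting calibration directly: across 20 null studies (2,000 genes,
3 dogs × 2 biopsies, dispersion 0.05) the mean false-discovery proportion
at adjusted p < 0.01 must stay below 0.05, and the interaction test's
empirical size at p < 0.05 must stay within [0.03, 0.07].

### IRLS details

Per-gene fits use iteratively reweighted least squares with weights
$\mu/(1+\alpha\mu)$, vectorized across genes (all genes share one design
matrix, so each sweep is a handful of dense matrix products plus small
per-gene solves). Convergence is declared when the largest coefficient
change drops below $10^{-8}$; at most 50 sweeps; the linear predictor is
clipped to $\pm 30$ to avoid overflow on degenerate genes; non-converged
genes are marked not-tested and counted in a warning. Wald p values use
the normal reference; the conservative dispersion rule (not a heavier
reference distribution) is what keeps the tails calibrated at these
sample sizes.

### The interaction cut

The regression-status interaction is reported at **raw** p < 0.05 by
default, matching the study convention of a plain "p < 0.05" for this
secondary screen (it conditions on genes already clearing the much
stricter FC > 10 / adj-p < 0.01 primary cut); `call_interaction(...,
adjusted = TRUE)` switches to BH-adjusted values.

## Temporal classes and signatures

Significant genes are classified by the first phase contrast that carries
them over the fold cutoff: **early** = significant in S/P; **late** =
significant in R/S but not S/P; **progressive** = significant in R/P but
in neither R/S nor S/P. The classes are disjoint by construction. The
direction suffix comes from the qualifying contrast; a gene whose
direction differs in another contrast keeps its label and is flagged
(`conflict = TRUE`) rather than dropped — such genes are rare and there is
no principled reason to discard them.

The candidate signature is the intersection of the regressing-cohort
significant set with the interaction set; the core signature additionally
intersects the regressing index case and subtracts the non-regressing
one. Direction-discordant genes are again flagged and retained.

Heatmap matrices are $\log_2(x + pc)$ relative to the mean of the logs of
the baseline (pre-treatment) samples — i.e. expression over the baseline
geometric mean. The pseudocount defaults to 1 on normalized counts because
log ratios of zero counts are otherwise undefined; rows are sorted
descending by the final biopsy's relative expression (three-biopsy
designs) or by the mean relative biopsy-2 expression of the sort samples
(two-biopsy designs). Venn percentages are reported as the percent of the
*first* set shared, truncated (not rounded) to one decimal — the
convention under which 648/1,016 prints as 63.7 %.

The signature-enrichment score (mean within-gene z-score over the set,
groups compared by two-sided Wilcoxon rank-sum) is a generic screening
statistic: the field reports "relative enrichment" without a formula, so
this is a documented surrogate, not a reproduction of any specific method.
Outlier ranking regresses one tumor's log2 mean expression on the other's
and ranks by absolute OLS residual; whether published outlier callouts
used residuals, ratios, or visual inspection is not recoverable, and the
residual is the convention that respects the best-fit line shown in such
plots.

## Origin assignment and qPCR burden

A somatic site is informative when its read depth reaches `min_depth`
(default 8 — "sufficient depth" is a free parameter here, declared rather
than inferred). An informative site votes TUMOR (or HOST) when that
allele's fraction reaches `majority` (default 0.8, tolerating sequencing
error without letting mixed-origin transcripts vote). A gene is called
only when at least `min_variants = 2` informative sites exist and all
votes agree; unanimity, rather than majority-of-sites, mirrors the
conservative manual review the call replaces. Everything else is
AMBIGUOUS, including genes with zero sites (not an error). Swapping the
allele labels at every site exactly swaps HOST and TUMOR calls, which the
tests assert.

qPCR standard curves are least-squares fits of Ct on $\log_{10}$ quantity;
amplification efficiency is $10^{-1/\text{slope}} - 1$. Triplicate Cts
are arithmetically averaged before inversion (aggregation detail
unspecified in practice; the arithmetic mean of Cts is the field's usual
choice). Tumor burden per dog is the tumor-marker quantity normalized to
ACTB, and the B2/B1 ratio of those normalized values is the fraction of
tumor DNA remaining; a zero pre-treatment ratio yields `NA` with a
warning.

## Meta-gene methylation profiles

Each gene is decomposed into seven transcription-ordered features —
≤2 kb upstream flank, first exon, first intron, internal exons, internal
introns, last exon, ≤2 kb downstream flank — strand-aware, with flanks
clipped at chromosome bounds. There is no separate promoter feature; the
upstream flank is the promoter proxy. Single-exon genes define only the
flanks and their one exon; two-exon genes lack internal features. Absent
features are excluded from list-level means, never zero-filled.

Each feature's concatenated length $L$ is split into 20 bins of exactly
$L/20$ — boundaries are real-valued and mapped back through the interval
concatenation, so bins may straddle exon–intron junctions and features
shorter than 20 bp get fractional-base bins (keeping the 7 × 20 grid
rectangular for every gene). Per-bin values are length-weighted means of
the piecewise-constant coverage, with uncovered stretches contributing
zero. Two exactness properties pin the arithmetic down: bin means must
match a per-base brute-force integration to $10^{-9}$, and the
length-weighted mean of the 20 bins must equal the feature-wide mean.
Reflecting a gene and its track through any genomic pivot while flipping
strand leaves its 140-vector unchanged.

Profiles are normalized by subtracting, per biopsy and bin, the arithmetic
mean profile of the non-expressed genes (strict zero counts in all scoped
samples; a CPM-threshold variant and a median baseline are available
behind flags). The per-gene demethylation score for a feature is
**minus** the mean of its 20 normalized bin values, so lower methylation
than the background reads as a higher demethylation score — chosen so that
demethylation of upregulated genes plots upward, the natural reading of
the published boxplots; the algebraic definition is declared here, not
recovered from any source. Boxplots pool per-gene feature means (not
per-bin values), use type-7 interpolated quartiles, and place whiskers at
the most extreme points within 1.5 IQR. Tracks are scaled to mean genome
signal 1 before profiling by default, putting samples of different depths
on a common scale; the baseline subtraction then removes residual level
differences.

## The synthetic-study generator

The generator exists so every stage has a known-answer surface. Its
defaults are the study conditions: 2–6 dogs per arm with 2–3 serial
biopsies, NB counts with gene-wise trajectories planted only in
regressive dogs, per-dog log-normal offsets (SD 0.3) as the paired
nuisance, size factors uniform on [0.5, 2], and planted |log2FC| of 4 —
large enough that the FC > 10 cutoff is meaningful, as in the study's
strongly induced genes. Trajectories follow the class definitions: early
genes shift fully at biopsies 2 and 3, late genes at biopsy 3 only, and
progressive genes half at biopsy 2 and fully at biopsy 3 — the half/full
ramp is chosen so a progressive gene crosses 10-fold only in the R/P
contrast, which is what makes the three classes separable. Planted
directions are random with equal probability.

Methylation tracks are 50 bp steps with Normal(10, 2) background signal;
planted lists lose `demeth_effect` (default 2, i.e. one background SD) at
their target feature via a linear ramp reaching the full effect at the
final biopsy — emulating progressive feature-local demethylation of
responding genes, with early lists targeting the first exon, late lists
the last exon and progressive lists internal exons. Variant pileups give
each gene 2–5 exonic biallelic sites at depths 10–60 with a 1 %
allele-error default; qPCR tables emit triplicate dilution-series
standards plus per-dog B1/B2 wells in which regressive dogs retain 2 % of
tumor DNA at B2.

What the generator does **not** emulate matters for interpreting green
tests: no batch effects beyond dog offsets, no read-level artifacts
(mapping, duplicates, GC), no correlated genes, no CpG-density structure
in methylation, no partial regression phenotypes. Passing tests
demonstrate that the algorithms are correct and calibrated under the
stated statistical structure, not that biological confounders are
handled.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen to
keep full runs at a few minutes while leaving comfortable statistical
margins: 1,000–2,000 genes per simulated study, 20 replicates for
calibration rates, 60-gene lists for methylation detection, 120 genes for
origin calling. Every simulation is seeded; identical configurations are
bit-identical, `run_pipeline()` reruns byte-identically, and the
acceptance script derives all its seeds from a single `--seed`.

## Known limitations

* Wald inference with 2–4 residual degrees of freedom is calibrated here
  by a conservative dispersion rule, not by exact small-sample theory;
  power is correspondingly conservative near the significance boundary.
* The interaction test supports the two-biopsy two-cohort design (the
  setting where the comparison is defined); three-biopsy interaction
  patterns would need an explicit longitudinal model.
* The enrichment score and the demethylation-score sign are declared
  conventions (see above), suitable for screening and comparison within
  this package, not cross-study effect sizes.
* `set_overlap` truncates percentages to one decimal by convention;
  downstream consumers wanting full precision should recompute from the
  returned counts.
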