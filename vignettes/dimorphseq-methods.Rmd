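---
title: "Models and methods behind dimorphseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dimorphseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimorphseq)
```

# The problem

Male and female mammals diverge transcriptionally long before gonadal
hormones act: in the mouse, sex-biased expression is detectable as soon
as the embryonic genome activates. Characterising that dimorphism across
development raises a chain of analysis problems that this package
implements as one tested pipeline:

1. **Sex calling** — individual embryos are not externally sexable, so
   sample sex must be inferred from the data itself.
2. **Signature definition** — genes differentially expressed between the
   sexes must be called from small numbers of noisy, low-input RNA-seq
   libraries.
3. **Cross-stage comparison** — a signature defined at one stage is
   interrogated in other datasets that are too small to support de novo
   calling.
4. **Chromatin dosage correction** — comparing female against male
   ChIP-seq signal on chrX is confounded by the two-fold difference in X
   copy number, which must be modelled away before enrichment is
   meaningful.
5. **Set enrichment** — overlaps between signatures, and against curated
   gene sets, need calibrated significance under explicitly chosen
   backgrounds.

A synthetic-data generator reproduces the statistical structure these
methods assume, with ground-truth labels, so every stage is exercised by
recovery and calibration tests rather than by fixture files.

# Sex calling from marker genes

`call_sex()` uses two markers with essentially binary sex specificity:
*Xist* (X-linked, the inactivation-driving lncRNA, female-biased by
orders of magnitude) and *Eif2s3y* (Y-linked, male-only). Counts are
size-factor normalised and `log2(x + 1)` transformed; samples are then
split into two groups in this 2-D marker space.

The grouping is deliberately not a seeded k-means: centres are
initialised at the two mutually farthest samples, followed by one
assignment pass, one centre update and one reassignment. With markers
this strongly separated, the procedure is equivalent to reading the
scatterplot, but it is deterministic and therefore testable. The group
with higher mean male-marker expression is labelled male. A per-sample
`margin` (difference of distances to the two centres) is reported so
ambiguous samples can be flagged; no rejection threshold is imposed,
because no principled one exists at these sample sizes.

# Negative-binomial dimorphism testing

`test_dimorphism()` implements a two-group NB comparison in the standard
RNA-seq parameterisation: counts for gene *i* in sample *j* are modelled
as NB with mean `mu_ij = s_j * q_ig` and variance
`mu + alpha_i * mu^2`, where `s_j` is the median-of-ratios size factor
(`size_factors()`, rescaled to geometric mean 1), `q_ig` the
concentration in sex group *g*, and `alpha_i` the gene-wise dispersion.

* **Dispersion** is estimated by method of moments on normalised counts
  with group-specific means (residual variance on `n - 2` degrees of
  freedom), floored at `1e-8`, then moderated by a 50:50 weighted
  average with a fitted `a0 + a1/mean` trend. The moderation stabilises
  the handful of genes whose moment estimate collapses to the floor or
  explodes, which is what makes the Wald test calibrated at six samples
  per sex (the type-I error at nominal 0.05 sits inside [0.03, 0.07] in
  the package's own null simulations).
* **Fitting**: with a saturated two-group design the GLM decouples into
  two one-dimensional profile fits, solved by Fisher scoring; the Wald
  statistic uses the observed information of each group mean. The
  reported `log2fc` is male over female, so female-biased genes
  (including *Xist*) are negative.
* **All-zero sexes**: the NB group-mean MLE diverges when one sex has no
  counts at all. Such genes get a 0.5 pseudocount added to every sample
  (that gene only), which yields a finite, strongly signed estimate — a
  female-only gene with a few hundred normalised counts lands near
  log2FC −9, the magnitude such markers show in practice.
* **Testing universe**: the expression filter (default: non-zero in
  every sample, the literal reading of "expressed across all samples")
  defines the tested set; Benjamini–Hochberg adjustment runs over tested
  genes only. Untested genes keep their estimates and raw p but carry no
  `padj`, so they can never enter a signature.

`define_signature()` applies the conventional thresholds strictly:
`padj < 0.1` and `|log2fc| > 0.5`, both exclusive, with the thresholds
recorded on the result. Exact DESeq2 parity (empirical-Bayes dispersion
shrinkage, logFC priors, independent-filtering heuristics) is explicitly
not claimed; the scientific content is the design and thresholds, not a
particular implementation's internals.

# Projection and consistency across stages

`project_logfc()` evaluates a fixed signature in another dataset as the
difference of group means of `log2(normalised count + 1)` (the package's
variance-stabilising transform). Refitting the NB model per target was
rejected by design: several comparison datasets of interest have two to
five samples per sex, where GLM fits are unstable, and the quantity of
interest is the log fold change, not per-target significance. A
conservation flag marks `|log2fc| > 0.5` in the target.

`directional_consistency()` reduces two log2FC tables to sign agreement
over shared genes and tests the (same, opposite) split against 50:50
with a one-sample chi-square goodness-of-fit (1 df, no continuity
correction): for counts `(a, b)` the statistic is `(a - b)^2 / (a + b)`.
The dimorphism floor defaults to 0 — every shared signed gene counts;
exact zeros carry no direction and are excluded. `correlate_logfc()`
exposes both Spearman and Pearson and records which was used, since both
conventions circulate for replicate-concordance reporting.

`x_autosome_ratio()` computes the mean normalised expression of
expressed X genes over that of expressed autosomal genes within one sex
(Y genes excluded throughout) — the classic Ohno-hypothesis diagnostic.

# The chromosome dosage model for ChIP-seq

Comparing female to male ChIP-seq signal at X-linked TSSs conflates
chromatin state with X copy number. The model builds the pure-dosage
expectation from the male track: with `N_i` the male window signal at X
gene *i*, `N_total` the male total over all TSS windows excluding chrY,
and `N_x` the male chrX total, the scaled male density is

    S_i = 2 * N_i / (N_total + N_x)

— the density a female library would show if it were exactly a male
library with a doubled X. The observed female density is

    A_i = N_i_female / N_ftotal

with `N_ftotal` the female total excluding chrY. Both are scale
invariant, and `A_i = S_i` identically when female X signal is exactly
twice the male with matched totals — the package's exact and Monte-Carlo
tests verify this identity and its convergence under Poisson sampling.

Window signal comes from `average_over_tss()`: mean coverage over
`TSS ± 1500` bp by interval-overlap weighting of a bedGraph track, with
the TSS at the annotated start (`+` strand) or end (`-` strand), windows
truncated at position 0 (mean over the covered width), and replicate
tracks averaged per gene before totals are formed. Window totals and
means differ by a constant that cancels in every enrichment ratio; the
per-gene table records which was used.

Gene-set enrichment beyond dosage is `FE_female = sum(A_i) / sum(S_i)`
over the set. The read-weighted ratio-of-sums was chosen over the mean
of per-gene ratios because it is robust to near-zero `S_i`; this
aggregation is this package's definition. Significance comes from
`permutation_pvalue()`: same-size sets drawn uniformly from the fitted
background (X genes with `S_i > 0`), `p = (b + 1) / (n_perm + 1)` with
`b` the number of null sets at least as extreme (two-sided on
`|log FE|` by default, since both female-enriched and female-depleted
marks are of interest). The `+1` convention keeps p away from 0 and
makes the null distribution exactly discrete-uniform under
exchangeability.

# Overlap and pathway enrichment

`overlap_fold_enrichment()` reports observed over expected overlap
(`|A||B|/|background|`) with an upper-tail permutation p, and
`pathway_enrichment()` the one-sided hypergeometric upper tail with
Bonferroni correction over pathways that intersect the background. The
background is always caller-supplied — detected X genes, detected
autosomal genes, or all expressed genes are deliberately different
universes, and silently inferring one invites misleading enrichments.
Pathway definitions are user-supplied GMT files; no pathway database is
bundled (licensing and version drift). Both the hypergeometric p and the
BH construction are cross-checked against brute-force enumeration in the
test suite.

# The synthetic-data generator

`sim_config()` / `simulate_counts()` invert the analysis model: NB
counts with per-gene log-normal baseline means, gene-wise dispersion,
log-normal library-size multipliers, and planted structure recorded as
ground truth. Defaults are fixed once to emulate the study design the
pipeline targets:

| parameter | default | rationale |
|---|---|---|
| `n_male`, `n_female` | 6, 6 | discovery-scale design of individual embryos |
| `baseline_log_mean_mu/sd` | log(100), 1.5 | spans the observed baseMean range (~5 to ~17000) |
| `dispersion` | 0.05 | typical inbred-line bulk/low-input RNA-seq |
| `x_dosage_log2` | 1.0 | full 2x female X before inactivation; tune toward 0 to emulate XCI with an escape subset |
| `dimorphic_fraction`, `effect_size_log2` | 0.05, 2.0 | a small planted autosomal component with clearly detectable effects |
| `library_size_mu/cv` | 1.0, 0.2 | realistic depth spread; exercises size-factor estimation |
| `xist_log2fc`, `eif2s3y_log2fc` | −9.01, +5.94 | marker separations at the magnitudes observed in eight-cell embryos |

Y genes emit exactly zero in females (no leaky noise), which makes
sex-calling tests deterministic; *Eif2s3y* is male-only and *Xist*
female-biased at the configured magnitude. Planted autosomal effects are
balanced in sign. `simulate_tss_coverage()` generates the dosage model's
inputs: Poisson window counts whose female X expectation is a tunable
multiple of the male one, with an optional additionally enriched set.

What the generator does **not** emulate: litter/batch structure (a
`batch_effect_log2` hook exists but is off by default), allele-specific
expression and escape from imprinted X inactivation, gene-length and GC
biases, read-level error, and microarray targets. Passing recovery tests
therefore demonstrates correctness of the statistical machinery under
the stated model, not robustness to every artefact of real libraries.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally (BED native; GTF
  converted on read); the TSS of a `-` strand gene is the annotated end.
* Dispersion floor `1e-8`; Fisher-scoring steps clamped to ±5 on the log
  scale; convergence tolerance `1e-8`.
* Strict inequalities at both signature thresholds; a gene exactly at
  `padj = 0.1` or `|log2fc| = 0.5` is excluded.
* Genes with zero counts everywhere are never tested; an all-zero track,
  an empty class after filtering, a constant marker space, or a gene set
  with zero scaled density each raise an informative error rather than
  propagating NaN.
* All simulation entry points take explicit seeds and restore the
  caller's RNG state; identical config + seed is bit-identical.

The package's own validation runs at desk scale, chosen as the smallest
sizes at which the calibration quantities are stable: 2000-gene null
simulations at 6 vs 6 for type-I error, 12 vs 12 with 60 planted
|log2FC| = 2 effects for recovery, 400-gene X backgrounds with 500
replicate draws for permutation-p uniformity, and 20 seeds for
sex-calling concordance.

# Known limitations

* No multi-factor designs, interaction terms, outlier replacement or
  surrogate-variable correction in the NB test.
* No BAM/peak-level ChIP-seq processing: the dosage model consumes
  window signal from coverage tracks, not reads; no input/IgG
  correction.
* Numeric parity with any specific DESeq2 version, or with external
  coverage utilities' binning, is not claimed.
* The sex caller assumes a clean XX/XY dichotomy; sex-chromosome
  aneuploidies are out of scope.
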