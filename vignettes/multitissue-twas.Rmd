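---
title: "Multi-tissue TWAS: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tissue TWAS: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A transcriptome-wide association study (TWAS) links genes to a trait in
two stages: first a predictive model of gene expression is learned from
an eQTL panel (genotypes plus measured expression), then expression is
*imputed* from genotype into a GWAS cohort and the imputed values are
tested against the trait.  When expression has been measured in several
related tissues, the prediction stage can borrow strength across
tissues.  `mttwas` implements four predictors spanning the single-task
/ multi-task and linear / non-linear axes, the association tests of the
second stage, a colocalisation filter for significant hits, and a
simulation harness that measures power and type-I error of the whole
pipeline under controlled causal scenarios.

## Expression predictors

**Penalized linear models (single-task).**  Lasso, ridge and elastic
net fits go through `glmnet`, with the penalty chosen by internal
10-fold cross-validation along a path computed from a master fit
(minimum-CV-error rule; the one-standard-error rule is not used).
Expression is standardized per tissue to mean 0, variance 1 before
single-task fits.  A fit whose selected penalty removes every SNP is a
legitimate outcome — a *null model* — and is flagged rather than
treated as an error: it still counts in multiple-testing denominators
(below).

**Joint lasso (multi-task, L2 fusion).**  For tissue groups
$g = 1..G$ with designs $X_g$ and centered (not rescaled) expression
$y_g$, the joint lasso minimizes

$$\sum_g \frac{\|y_g - X_g \beta_g\|^2}{2 n_g}
  + \lambda \sum_g \|\beta_g\|_1
  + \gamma \sum_{g<g'} \tau_{gg'} \|\beta_g - \beta_{g'}\|_2^2 .$$

The fusion term pulls coefficient vectors of similar tissues together;
$\tau_{gg'}$ weights pairs by tissue similarity.  The solver is block
coordinate descent over SNPs: for one SNP the $G$ coefficients solve a
small L1-penalized quadratic program exactly (feature-sign search),
which keeps every step monotone in the objective and remains fast when
$\gamma$ is large and plain per-coordinate descent crawls.  Data enter
in Gram form, so solver cost does not grow with sample size along the
penalty path.  Two limits pin the implementation down and are asserted
numerically in the tests: $\gamma = 0$ reproduces independent
per-tissue `glmnet` fits, and $\gamma \to \infty$ with uniform $\tau$
reproduces the pooled lasso.

Tuning is nested: $\gamma$ by external 5-fold cross-validation,
$\lambda$ by internal 10-fold cross-validation at each $\gamma$, all
folds grouped by individual so that no individual contributes to both
sides of a split.  The $\lambda$ path is geometric, 100 values from the
smallest null-model penalty down to $10^{-3}$ of it.  The $\gamma$ grid
is $\{0\} \cup 10^{-3..2}$ (8 points): the upper end is already
indistinguishable from the pooled limit at these data scales, because
with standardized genotypes the fusion coupling $2\gamma\sum\tau$
dominates the unit curvature of the loss well before $\gamma = 100$.

For real expression panels the pair weights default to
`tissue_penalty_matrix()`: the between-tissue expression correlation
divided by the strongest off-diagonal correlation, with negative
correlations clipped to zero (a negative weight would reward
divergence) and a uniform fallback of 1 when a pair has fewer than two
shared samples.  In the *simulation harness* the weights default to
uniform 1 instead: under the null scenarios the test tissue is
generated independently of the background tissues, so weights estimated
from the simulated traits would disconnect exactly the tissue whose
cross-tissue borrowing the simulation is designed to measure, and
constant weights are also what the original joint-lasso work reports as
an adequate default.

**Random forests.**  Single-task forests (`ranger`) use 500 trees,
minimum terminal node size 5, and `mtry` of one third of the SNPs.
The multi-task forest stacks the tissues: expression vectors are
concatenated, genotype rows are repeated per tissue, and a categorical
tissue identifier is added that is *always* in the candidate set at
every split, on top of the `mtry`-sampled SNPs (partition splitting
over level subsets).  Homogeneous tissues are then pooled — the
identifier is simply not used — while strongly diverging tissues are
separated by early splits on the identifier; `tissue_split_fraction()`
reports how often it is used.  Each individual contributes up to $G$
stacked rows treated as independent observations, which is tolerable
because the design is balanced across tissues.

**Prediction.**  `predict()` maps back to the original expression
scale, matches SNPs by id, imputes SNPs missing from the prediction
panel at their training-mean dosage (with a warning), refuses to
predict with zero shared SNPs, and returns a constant (flagged) vector
for null models.

## Association stage

Quantitative traits are tested by linear regression of the trait on
imputed expression (two-sided slope t-test).  Case/control designs
genotyped on multiple chips use a Cochran-Armitage trend test with the
imputed expression as a continuous score, stratified in the Mantel
fashion: per stratum $U_s = \sum_{\text{cases}} (x_i - \bar x_s)$ with
permutation variance
$n_{1s} n_{0s} \sum_i (x_i - \bar x_s)^2 / (n_s (n_s - 1))$, summed
over strata and referred to a standard normal.  The variance is the
exact randomization variance of $U_s$ under within-stratum label
permutation — the tests verify agreement with a brute-force permutation
oracle — so no binning of the score is needed.

Multiple testing uses Benjamini-Hochberg, run separately per method and
tissue, with the denominator equal to the *total* number of fitted
models including null ones.  Sparse linear methods produce null models
that are never tested; counting them keeps the lasso family comparable
with forests, which always produce a testable prediction.

## Colocalisation filter

A significant TWAS hit shows that imputed expression correlates with
the trait, not that the same variants drive both signals.  The filter
tests *proportionality* of the two traits' regression coefficients on a
common basis: SNPs with GWAS or eQTL scan $p < 10^{-4}$ seed the set,
their LD pockets ($r^2 > 0.2$ with any seed, one expansion round, no
transitive closure) are added, the selected dosages are reduced to
principal components (smallest number of PCs reaching 80% variance,
capped at six), and each trait is regressed on its own samples' scores
in the shared basis.  Under the colocalisation null $b_2 = \theta b_1$,
the profile statistic

$$\min_\theta \; (b_2 - \theta b_1)^\top
  (\Sigma_2 + \theta^2 \Sigma_1)^{-1} (b_2 - \theta b_1)$$

is $\chi^2_{k-1}$; $\theta$ is profiled through $\arctan\theta$ so the
infinite-slope limit is handled continuously.  Because the two traits
come from disjoint samples the joint covariance is block-diagonal,
which the $\theta$-dependent variance exploits; calibration under this
convention is checked by simulation in the test suite.  A hit *passes*
(is kept as an "SP-hit", significant and proportional) when
$p_f \ge 0.05$; hits whose locus has no SNP below the seeding threshold
cannot be tested and are dropped with a flag.  All thresholds use
strict inequalities.

## Simulation design

`build_haplotype_pool()` is a seedable synthetic stand-in for a phased
reference panel.  A first-order Markov copying process drives LD: each
SNP's latent uniform is copied from its left neighbour with probability
`ld_decay` or redrawn, and the allele is the indicator of the latent
falling below the SNP's target frequency (drawn uniformly from
`maf_range`).  Marginal frequencies are exact by construction; adjacent
correlation is `ld_decay` attenuated by allele-frequency mismatch, so
LD decays geometrically with distance in blocks of a few SNPs.

Each simulated data set samples 400 diplotype individuals (two pool
haplotypes with replacement, summed to dosages) independently for the
eQTL and the GWAS cohort.  Six causal scenarios form a 2 x 3 grid: the
GWAS trait and the *test* expression trait either share causal variant
A or use distinct variants (the test trait then gets its own variant C,
kept distinct from both A and the background variant), while the four
*background* expression traits have no causal variant, share their own
variant B, or share the GWAS variant A.  One effect size per *variant*
is drawn as the maximum of five mean-zero Gaussians with variance 0.04
— the maximum skews effects positive and away from zero — and is shared
by every trait assigned that variant.  Traits are unit-variance
Gaussians around $\sum_i \beta_i G_i$.  A data set is retained only if
the smallest per-SNP regression p-value over all five expression traits
is below $10^{-7}$, implemented as rejection sampling with a retry cap
(default 100; the harness raises it to 400 because with 400 individuals
a single draw is retained a few percent of the time).

Choices where the design was genuinely open, made once and kept:

* **Pool geometry.**  Desk-scale runs use 600 haplotypes x 60 SNPs with
  `ld_decay = 0.7`.  The copying probability was chosen so that two
  *randomly sampled* causal variants are rarely in strong LD — the
  regime a real reference panel produces, in which the single-task
  lasso's false-positive rate in the distinct-variant row sits near its
  nominal level — while LD pockets still
  span several SNPs so the colocalisation machinery (pocket expansion,
  PC reduction) is exercised.  Larger regions (e.g. 200 SNPs) behave
  the same but make the nested-CV joint lasso several times slower.
* **Causal variants** are restricted to sample MAF >= 0.05 so that
  simulated signals are detectable at n = 400.
* **Replicate counts** are per-method desk-scale: the acceptance script
  uses 25 replicates/cell for the four-method cells and 50 for
  lasso-only cells, and reports every proportion together with its
  replicate count.  They are chosen to fit a single-CPU run, not to
  match the (unstated) replicate count of the original study; binomial
  noise at these sizes is acknowledged wherever proportions are
  compared.

## What the synthetic data do and do not emulate

The generator reproduces the *structure* of the study conditions —
haplotype-derived dosages with tunable block LD, scenario-controlled
sharing of causal variants, the effect-size law, the retention filter —
but not real genome features: no recombination-map hotspots, no
population structure, no allele-frequency spectrum beyond the uniform
MAF draw, one causal variant per trait, purely additive generative
effects.  Passing grid tests therefore demonstrate that the pipeline's
relative behaviour (which method over-borrows, what filtering removes)
is reproduced under controlled conditions; they do not certify absolute
power numbers for any particular real region, which depend on the LD of
the actual reference panel used.

## Numerical choices and degenerate inputs

* Fused-lasso convergence is declared at a maximum coefficient change
  below `tol` in a sweep (1e-4 during cross-validation solves, 1e-7 for
  the final refit); the iteration cap raises an error rather than
  returning silently.
* Monomorphic SNPs standardize to zero columns and keep zero
  coefficients; `ld_r2_matrix()` flags them `NA` rather than erroring.
* Zero-variance expression is an error for standardization
  (single-task linear), while the forest accepts a constant response
  and degenerates to the constant predictor.
* Constant imputed expression cannot be tested: the association test
  returns p = 1 with a flag, and null models contribute untested slots
  to the BH denominator.
* Ties at thresholds: every cut (1e-7, 1e-4, r² 0.2, 0.05) is strict,
  so boundary values fall on the conservative side.
* Grid seeds: each cell x replicate derives its own seed from the
  master seed with fixed large-prime strides, so per-replicate datasets
  are identical across method subsets and runs are bit-reproducible.

## Known limitations

The joint lasso's nested cross-validation (5 outer folds x 8 gamma
values x 10 inner folds) dominates runtime; grid replicate counts are
correspondingly modest, and proportions from the harness carry binomial
error of a few percentage points.  The proportionality filter uses a
single shared PC basis (no model averaging over SNP subsets).  The
stacked forest treats repeated individuals as independent, which is the
intended design but mildly optimistic for out-of-bag error.  Binary
GWAS traits appear only in the association stage; the simulation
harness generates quantitative GWAS traits.
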