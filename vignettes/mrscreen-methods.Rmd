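---
title: "Methods: two-stage MR screening with Bayesian model averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage MR screening with Bayesian model averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Metabolite panels measured by NMR in biobank-scale cohorts yield hundreds
of quantitative traits — triglyceride and cholesterol content of fourteen
lipoprotein subclasses, fatty-acid saturation indices, amino acids and
other small molecules. When each trait is tested one at a time against a
disease outcome by two-sample Mendelian randomization, many reach
significance at once, because the traits share large fractions of their
genetic instruments: the same lipid loci drive whole families of measures.
A univariable screen therefore answers "which trait families show causal
signal", not "which trait carries it". `mrscreen` implements both halves:
the screen, and a Bayesian model-averaging multivariable MR (MR-BMA) stage
that treats exposure subsets as competing models and ranks individual
traits by how often the data demand their inclusion.

Two-sample MR rests on the usual instrumental-variable assumptions: the
instruments associate with the exposure (enforced here by the significance
and F filters), are independent of confounders, and affect the outcome
only through the exposure. The sensitivity estimators relax the third
assumption in specific directions — MR-Egger allows directional pleiotropy
with an InSIDE-type assumption, the weighted median allows up to half the
instrument weight to be invalid.

## Instrument selection

Three filters, in order, with their defaults:

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 5e-8 | genome-wide significance of the SNP-exposure association |
| `r2_threshold` | 0.001 | maximum squared LD correlation between retained SNPs |
| `window_kb` | 10000 | clumping distance window (kb, same chromosome) |
| `f_threshold` | 10 | minimum instrument strength F = (beta/se)^2 |

Clumping is greedy by ascending p-value; ties break lexicographically on
SNP id so the output is independent of row order and platform. SNPs absent
from the supplied LD matrix are treated as independent but reported: an
incomplete reference panel should not silently delete instruments. The F
statistic is the squared Wald z of the exposure association rather than a
sample-size approximation, because beta and se are the only fields
guaranteed present in summary data. Note that with Wald-consistent
p-values the genome-wide filter already implies F ≈ 30, so the F filter
only bites when stated p-values come from a different test than beta/se.

## Harmonization

Exposure and outcome records are aligned to the exposure's effect allele:
matching alleles pass through, swapped alleles negate the outcome beta and
reflect its frequency, strand-complement alleles (A<->T, C<->G) are
complemented and re-matched. Palindromic SNPs cannot be resolved from
letters alone; by default their orientation is inferred from allele
frequency agreement when both frequencies lie outside 0.5 ± 0.08
(`eaf_window`), and they are dropped otherwise — the standard conservative
practice in two-sample MR. Records with missing frequency, indels and
multi-allelic sites are dropped with an explicit reason. Harmonization
never touches the exposure effects; only the outcome beta's sign and
frequency can change.

## Univariable estimators

All three estimators consume per-SNP Wald ratios b_j = beta_Yj / beta_Xj
with first-order weights w_j = (beta_Xj / se_Yj)^2; the second-order term
of the ratio variance is deliberately omitted so that closed-form oracles
match the implementation exactly.

The IVW default is the multiplicative random-effects model: the
fixed-effects standard error is scaled by max(1, sqrt(Q/(n-1))), so
heterogeneity can widen but never narrow the interval. The point estimate
is identical under both effect models. MR-Egger reorients every instrument
to a positive exposure effect (the estimate is invariant to this), fits
weighted least squares with intercept, applies the same multiplicative
scaling with n-2 degrees of freedom, and uses the t reference for its
p-values. The weighted median interpolates the inverse cumulative weight
function at 0.5 with each sorted ratio placed at the midpoint of its
weight mass; its standard error comes from a parametric bootstrap
(default `n_boot = 1000`) that resamples both exposure and outcome effects
from their reported normal errors. The bootstrap seed is mandatory so
stochastic standard errors are reproducible.

Estimates are reported per 1 SD of the exposure and as odds ratios on the
outcome, matching the scale of SD-standardized metabolite GWAS against
log-odds disease GWAS.

## The model-averaging stage

Traits with univariable IVW p < 0.05 (uncorrected — see below) enter the
stage together. Their instruments are pooled, strictly re-clumped
(r2 < 0.001 within 10,000 kb, greedy on each SNP's minimum p across the
included exposures), and assembled into an m x K matrix of exposure
associations aligned to a common effect allele per SNP, with the outcome
vector and its standard errors. An exposure with no measured association
at a retained SNP contributes zero to its column (counted and reported); a
`drop_incomplete` mode discards such SNPs instead.

On the inverse-variance standardized scale (ỹ = beta_Y/se_Y, X̃ =
beta_X/se_Y) the weighted multivariable regression has unit error
variance. Columns of X̃ are further scaled to unit root mean square so
that inclusion probabilities are comparable between strongly and weakly
instrumented traits; reported estimates are back-transformed. For each
subset S up to `max_model_size` (default min(K, 12)):

- marginal likelihood: ỹ ~ N(0, I + sigma^2 X̃_S X̃_S') in closed form,
  with an independent Gaussian shrinkage prior N(0, sigma^2) on the
  standardized subset effects (`prior_sigma`, default 0.5), evaluated via
  the Woodbury identity on the K_S x K_S inner system;
- prior: independent Bernoulli inclusion with `prior_inclusion_prob`
  (default 0.1);
- per-model causal estimates: unpenalized weighted least squares with
  normal Wald p-values. Model averaging therefore uses Bayesian weights
  over maximum-likelihood estimates, the same hybrid the usual MIP/MACE
  reporting convention implies; the shrinkage prior shapes model
  probabilities, not the reported effects.

Posterior probabilities are normalized over the evaluated space — the full
enumeration in exhaustive mode (required for K <= 20), or the distinct
models visited by a seeded shotgun search (add/delete/swap neighborhoods,
moves sampled proportionally to posterior) in stochastic mode. A subset
with a singular design (e.g. perfectly collinear exposures) has no
identifiable effects and is excluded with log-marginal -Inf and a count.

Each trait is ranked by its marginal inclusion probability (MIP, the sum
of posterior probabilities of models containing it) and summarized by the
model-averaged causal estimate (MACE, the posterior-weighted sum of its
model-specific estimates, zero when excluded). The "best model" columns
report, per trait, the highest-posterior model containing it; individual
models at or above `pp_threshold` (default 0.02) form the best-models
table.

### Influence diagnostics

For every best model the per-SNP Cochran Q contribution (squared
standardized residual) and Cook's distance are computed from the weighted
fit. An instrument exceeding `q_threshold` (default 10, i.e. roughly
|residual| > 3.2 standard errors) or the Cook's cutoff (default: median of
the F(|S|, m-|S|) reference) in any best model is removed, and posteriors
and rankings are recomputed once. A single remove-and-refit round mirrors
the usual published workflow; iterating to convergence is a caller-level
loop if wanted. A fit whose residual sum of squares is numerically zero
(below 1e-10 relative to ||ỹ||²) flags nothing, avoiding 0/0 artifacts on
exact synthetic data.

### P-values for the ranking tables

Published MR-BMA rankings print a p-value per trait without a standard
construction. Two surfaces are provided: the asymptotic Wald p-value of
the best-model estimate (always emitted alongside the estimate), and
`permutation_pvalues()`, which permutes the (beta_Y, se_Y) pairs across
instruments, reruns the entire posterior computation, and reports the
fraction of permutations whose MIP reaches the observed one, floored at
1/(n_permutations + 1). The permutation route is the default surface for
inference on MIP because MIP has no usable asymptotic distribution;
it is opt-in in the pipeline (`permute = TRUE`) since it multiplies the
run time by the permutation count.

### Multiple testing

Inclusion into the model-averaging stage deliberately uses uncorrected
two-sided p < 0.05. The traits are strongly dependent through shared
instruments, so a correction calibrated for independence would screen out
valid exposures before the stage designed to disentangle them; the
model-averaging posterior is the multiplicity control. An FDR column is
emitted in the screen table for users who want the orthodox view.

## The synthetic-data generator

The generator emulates the summary-statistic structure the analysis
consumes, at the scale of a biobank metabolite study:

- K = 10 correlated exposures measured in 115,078 individuals; each
  exposure has 26 causal variants, half drawn from a pool shared by all
  exposures (`sharing = 0.5`). Shared loadings get exposure-specific
  multipliers N(1, 0.2), so correlated traits are similar but not
  identical. The resulting union of instruments after clumping is ~100-140
  SNPs, matching the order of magnitude of a lipid-trait category.
- per-allele loadings drawn uniformly from 0.05-0.25 SD with random sign —
  the range spanned by genome-wide-significant NMR metabolite loci; with
  these sample sizes the weakest loadings at low MAF hover at the
  significance boundary, so a realistic fraction of true instruments is
  missed, as in real data.
- exposure standard errors follow 1/sqrt(2 maf (1-maf) n); MAF is uniform
  on 0.05-0.5 (metabolite instruments are common variants).
- the binary outcome uses the log-odds approximation
  se = sqrt((1/n_cases + 1/n_controls) / (2 maf (1-maf))) with a default
  imbalance of 3,022 cases / 195,144 controls; per-SNP outcome effects are
  the loading-weighted sum of the true causal effects plus optional
  pleiotropy and noise. The default truth is a single causal exposure at
  0.3 log-odds per SD, the magnitude typical of the causal estimates such
  screens report.
- directional pleiotropy adds a constant offset to a configurable fraction
  of causal variants, anchored to the exposure-increasing allele of the
  variant's dominant loading. Anchoring matters: an allele-agnostic offset
  cancels under the estimators' orientation convention and becomes
  balanced pleiotropy in disguise.
- optional LD blocks are block-diagonal in r2 and placed within 100 kb;
  independent loci are spaced 25,000 kb apart across 22 chromosomes so
  only deliberate LD is within any clumping window.

Everything is a deterministic function of the seed; scenario files
(summary TSVs, LD matrix, truth JSON with loadings and pleiotropy
assignments) are byte-identical across runs.

What the generator does **not** emulate: genotype-level sampling,
realistic LD beyond rectangular blocks, recombination maps, sample overlap
between exposure and outcome GWAS, allele-frequency drift between cohorts,
population stratification, or non-linear exposure-outcome relationships.
Passing tests on this generator therefore demonstrate the statistical
machinery under the model's own assumptions, not robustness to the
artifacts of real GWAS data.

## Numerical choices

- p-values are clamped at 1e-300 when the normal tail underflows; the
  read-time consistency check (stated p within 10% of the Wald p on the
  -log10 scale) is applied only where both are between 1e-1 and 1e-290.
- Clumping tie-breaks, trait ordering and rank ties are all lexicographic
  or `ties.method = "first"` — deterministic across platforms.
- The marginal likelihood drops the constant -m/2 log(2 pi), common to all
  models, and normalizes with a max-subtraction before exponentiation.
- Weighted-median interpolation places sorted values at the midpoints of
  their weight mass; endpoints clamp to the extreme ratios.
- Bootstrap draws that produce a zero exposure effect (probability ~0)
  fall back to the observed effect rather than dividing by zero.

## Simulation sizes

The test suite and the acceptance script use 2,000 replicates for null
calibration checks (type-I error, Q against chi-square), 200 replicates
for the recovery study (one causal trait of 0.3 SD among 8 exposures with
50% instrument sharing at full study sample sizes), 100 seeded fixtures
for outlier-flagging sensitivity, and 120 replicates for the
directional-pleiotropy power check with a deliberately well-instrumented
single exposure (250 instruments, offset 0.2 on 30% of them) — the Egger
intercept test has low power at typical instrument counts, and the power
check is meant to verify the detection machinery, not to claim power where
there is none.

## Known limitations

- LD is consumed, never estimated; the quality of clumping is bounded by
  the supplied panel, and instruments missing from it are assumed
  independent (loudly).
- The model-averaging likelihood assumes instruments independent after
  strict clumping; residual LD is not modelled.
- One outlier-removal round is the default workflow; pathological data can
  need more, and `influence_diagnostics()` can be iterated by the caller.
- MR-PRESSO, mode-based estimators, Steiger filtering, SIMEX-corrected
  Egger and general multivariable MR variants are out of scope.
- Estimates assume lifelong linear exposure effects on the log-odds scale;
  as in any MR the direction is more trustworthy than the magnitude.
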