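---
title: "Joint Bayesian fine mapping of genes across mixed-type phenotypes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Bayesian fine mapping of genes across mixed-type phenotypes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofm)
```

## The problem

Transcriptome-wide association studies (TWAS) test whether genetically
regulated expression (GReX) of a gene is associated with a trait. Because
linkage disequilibrium (LD) and shared regulatory architecture correlate the
imputed GReX of nearby genes, a significant TWAS hit does not localize the
causal gene: fine mapping must weigh all genes in an LD block jointly.
Phenome-wide resources add a second axis — tens to hundreds of correlated
phenotypes of mixed types (continuous measurements, binary diagnoses, event
counts) — where per-trait fine mapping both multiplies the testing burden
and ignores pleiotropy.

`phenofm` addresses both axes at once: within each LD block it jointly
models all candidate genes against *sparse latent phenotype factors*, so a
gene is selected when it moves one or more factors that in turn load on a
sparse subset of phenotypes. The outputs are posterior inclusion
probabilities (PIPs) per gene (factor-specific and omnibus), a
Bayesian-FDR-controlled gene list, and the phenotype loadings of the
factors each selected gene targets.

## Model

For one genomic region with $p$ candidate genes, $q$ phenotypes and $n_2$
GWAS individuals:

**Expression training (reference panel, $n_1$ individuals).** For gene $j$
with $g_j$ cis-SNPs,
$$x_j = Z_j^R \gamma_j + \varepsilon_j, \qquad
  \gamma_d \sim I_d\,\delta_0 + (1 - I_d)\, N(0, v_j^2 \sigma_j^2),\quad
  I_d \sim \mathrm{Ber}(\pi^{(\gamma)}),$$
with $\pi^{(\gamma)} \sim \mathrm{Unif}(0,1)$ and Jeffreys priors on
$v_j^2$ and $\sigma_j^2$. Note the indicator orientation: $I_d = 1$ selects
the *spike* (a zero effect). GReX is imputed into the GWAS cohort as
$\hat x_j = Z_j^G \hat\gamma_j$ with $\hat\gamma_j$ the posterior mean,
then standardized.

**Gene effects on latent factors.** Factor $l$ obeys
$$f_l = \sum_{j=1}^p \beta_{jl}\, \hat x_j + \epsilon_l, \qquad
  \epsilon_l \sim N(0, \omega_l^2 I),$$
with the two-level indicator (spike-and-slab) prior
$$\beta_{jl} = I_j\, U_{jl}\, b_{jl}, \qquad
  b_{jl} \sim N(0, s^2 \omega_l^2),\quad
  I_j \sim \mathrm{Ber}(\pi_1),\quad U_{jl} \sim \mathrm{Ber}(\pi_2).$$
$I_j$ switches the gene on or off globally; $U_{jl}$ routes an active gene
to specific factors. Both inclusion probabilities carry uniform priors and
$s^2, \omega_l^2$ carry Jeffreys priors, so sparsity is learned from the
data.

**Sparse factor loadings.** The (transformed) phenotypes satisfy
$\tilde y_i = \Lambda F_i + e_i$ with diagonal residual covariance for
continuous columns. Loadings carry a multiplicative gamma-process prior,
$$\lambda_{kl} \sim N\!\big(0, \phi_{kl}^{-1} \eta_l^{-1}\big), \qquad
  \phi_{kl} \sim \mathrm{Ga}(3/2, 3/2), \qquad
  \eta_l = \prod_{r \le l} \vartheta_r,$$
with $\vartheta_1 \sim \mathrm{Ga}(a_1, 1)$,
$\vartheta_h \sim \mathrm{Ga}(a_2, 1)$ and $a_1, a_2 > 1$, so the prior
precision of later columns increases stochastically and the effective
number of factors is data-determined (see *Adaptive truncation*).

**Mixed outcome types.** Discrete phenotypes enter by Pólya-Gamma
augmentation. With $\xi_{ik} = 1$ for a binary outcome and
$\xi_{ik} = y_{ik} + r_k$ for a count (negative binomial with dispersion
$r_k$), the auxiliary $\psi_{ik} \sim \mathrm{PG}(\xi_{ik}, \cdot)$ yields
the conditionally Gaussian pseudo-datum
$$\tilde y_{ik} = \frac{y_{ik} - 0.5\,\xi_{ik}}{\psi_{ik}}$$
with precision $\psi_{ik}$; continuous entries are untransformed with
precision $\tau_k^{-2}$. For counts the transform reduces to
$(y - r)/(2\psi)$, the standard negative-binomial pseudo-response. In the
Gibbs conditional, $\psi_{ik}$ is drawn from the *tilted*
$\mathrm{PG}(\xi_{ik}, \lambda_k' F_i)$ — tilting by the current linear
predictor is what makes the augmented sampler leave the posterior
invariant. The dispersion $r_k$ is updated by Chinese-restaurant-table
latent counts with a $\mathrm{Ga}(1, 0.01)$ prior, drawing $(r_k, \psi)$
as a partially collapsed block.

## Inference and selection

All conditionals are conjugate and the model is fitted by a systematic-scan
Gibbs sampler (`run_chain()`), implemented in C++ via Rcpp. Indicators are
drawn with the underlying effect integrated out (collapsed Bernoulli odds),
then the effect is redrawn — this moves $(I_j, b_{j\cdot})$ and
$(U_{jl}, b_{jl})$ as blocks and avoids sticky joint states.

From stored draws, `compute_pips()` reports
$\mathrm{PIP}_{jl} = P(\beta_{jl} \ne 0 \mid \text{data})$ and the omnibus
$\mathrm{PIP}_j = P(\cup_l\, \beta_{jl} \ne 0 \mid \text{data})$, and
`bfdr_select()` controls the Bayesian FDR: for threshold $z$ the selected
set is $\{j : \mathrm{PIP}_j \ge z\}$, its BFDR is the mean of
$1 - \mathrm{PIP}$ over the set, and the reported threshold is the smallest
$z$ meeting the nominal level (largest selection). Factor-specific
selection applies the same operator per factor, each factor with its own
threshold; a shared-threshold variant can be obtained by applying
`bfdr_select()` to the pooled factor-PIP matrix. Factor-indexed summaries
are computed after aligning draws to the last burn-in loading matrix by
greedy column matching with sign flips (`align_draws()`); omnibus
quantities are alignment-invariant and use raw draws.

### Adaptive truncation

The truncation level $m$ starts at `m_init` and adapts only during burn-in,
with probability $\exp(-\alpha_0 - \alpha_1 t)$ at sweep $t$: columns whose
loadings are all below `adapt_eps` in absolute value are deleted (never
below one column); if none qualify and $m < m_{\max}$, a fresh column is
appended from the prior. Two practical points, both visible in the
package's tests:

* `adapt_eps` must sit **above the posterior noise floor of a dead
  column**, roughly $(\sum_i w_{ik} F_{il}^2)^{-1/2} \approx 0.02$–$0.06$
  at $n_2 = 1000$ on standardized phenotypes. The classical choice of
  $10^{-2}$ (kept as the `chain_config()` default for fidelity to common
  practice) then almost never deletes, and the append step ratchets $m$ to
  `m_max`; the simulation-study driver therefore uses `adapt_eps = 0.1` —
  a column whose every loading is below 0.1 explains under 1% of any
  standardized phenotype's variance and is scientifically negligible.
* With appends enabled, $m$ oscillates around the effective rank rather
  than settling exactly at it; capping `m_max` (the driver uses 12) bounds
  the cost without constraining the fit in practice.

### Numerical choices

* **Pólya-Gamma sampling** uses exact Devroye-type rejection for unit
  shapes, summed for integer shapes $\le 2$; fractional remainders and
  larger shapes use a two-moment gamma match (PG is right-skewed and
  infinitely divisible, so a gamma with matched mean and variance is a
  close surrogate; relative skewness error is $\sim$15% at shape 5 and
  shrinks as $b^{-1/2}$), and shapes above 170 use a normal approximation.
  A truncated sum-of-gammas sampler (200 terms, exact mean tail
  correction) is retained as `method = "series"` and used as an
  independent cross-check in the tests. The approximation thresholds trade
  a negligible perturbation of the count-column augmentation for an
  order-of-magnitude speedup on the $n_2 \times q$ draws needed each
  sweep; the simulation-consistency (Geweke) test, which exercises count
  columns, passes with these choices.
* **Initialization** is a warm start for the factor block: loadings and
  factors from a truncated SVD of the initial pseudo-data (prior-mean
  Pólya-Gamma weights), underlying gene effects by ridge regression,
  variances by method of moments. Gene-level indicators start **off**
  (the empty model, as is conventional for spike-and-slab samplers): the
  collapsed Bernoulli update switches a gene on within one sweep when its
  Bayes factor warrants it, whereas an all-on start lets early factor
  updates align factors with GReX directions and can temporarily lock a
  spurious inclusion in under null data.
* **Jeffreys priors** are the $a = b = 0$ limit of inverse-gamma
  conditionals; when a conditional would be degenerate (a slab scale with
  zero active coordinates) the current value is retained for that sweep.
  Validation against forward simulation uses proper hyperparameters,
  since improper priors cannot be forward-sampled.
* **Degenerate inputs**: zero-variance SNP columns are dropped with a
  warning before training; genes whose posterior-mean weights are all zero
  are dropped from imputation with a warning; missing phenotype entries
  are rejected (the model assumes complete outcome rows). Optional
  covariates are residualized out of GReX and continuous phenotypes only —
  residualizing a discrete outcome is not meaningful under the link, and
  this limitation is messaged at run time.

## The synthetic-data generator

`simulate_study()` emulates the study design the method targets, with
every ingredient controlled by `sim_config()`:

* **Genotypes**: dosages are sums of two haplotypes obtained by
  thresholding a latent Gaussian AR(1) process (lag-1 correlation
  `ld_rho`, default 0.8 so adjacent genes' cis-windows are correlated and
  fine mapping is non-trivial) at per-SNP MAFs drawn from
  `maf_range`; reference and GWAS panels share MAFs and LD structure but
  are independent samples. Realized pairwise dosage correlation is
  validated against numerical integration of the thresholded bivariate
  normal.
* **Expression**: 10 cis-SNPs per gene, of which 3 are causal with
  N(0,1) effects rescaled so cis-SNPs explain `h2_expr = 0.3` of
  expression variance — a deliberately favorable but typical cis
  architecture.
* **Phenotypes**: `q = 50` phenotypes from `m` latent factors; per region
  1–2 causal genes (uniform); homogeneous, heterogeneous, or null causal
  assignment across factors. Each factor's genetic component is rescaled
  to sample variance `h2` and each phenotype's idiosyncratic noise is set
  so the GReX-explained fraction of its latent predictor equals `h2`
  (exactly this fraction is reported in `truth$realized_h2`). For binary
  and count outcomes the calibration is on the latent linear-predictor
  scale — observed-scale heritability has no closed form under the link.
  Predictors are standardized to unit variance; binary outcomes are
  Bernoulli through the logistic link and counts are negative binomial
  with dispersion `r_nb = 2` and mean $r e^{\text{pred}}$, matching the
  augmented likelihood exactly.

What the generator does *not* emulate: real LD panels (haplotype-level
structure, long-range LD), imputation uncertainty in the weights,
population structure and relatedness, phenotype missingness, and
model-misspecified outcome links. Passing tests therefore demonstrate
correctness of the algorithm under its own generative assumptions and
calibrated false-discovery behavior in a realistic-scale design — not
robustness to the full messiness of biobank data.

## Validation strategy

The test suite ties every component to an independent oracle:

* spike-pattern posteriors versus exhaustive enumeration with closed-form
  marginal likelihoods (expression model and gene-inclusion block);
* a Geweke-style simulation-consistency test of the full sampler at tiny
  dimensions, with bounded tracked functionals and proper priors;
* Pólya-Gamma draws versus closed-form moments, the independent series
  sampler, and a quadrature-checked logistic posterior;
* the thresholded-bivariate-normal LD oracle, Fisher's method against the
  chi-square reference, AUC against an independent rank implementation,
  and BFDR operator invariants (monotonicity, nesting, union bound).

The headline study sizes were chosen to keep a laptop-scale run
practical: 50 null replicates at $n_2 = 1000$, 5 regions $\times$ 10
genes, $q = 20$ mixed phenotypes, with 500-sweep chains (250 burn-in,
thinning 2) — about ten minutes end to end — and a 20-replicate recovery
study at $n_2 = 2000$, one region, $q = 50$ continuous phenotypes. Chain
lengths are short because the SVD warm start and the collapsed indicator
updates mix quickly at these dimensions; the conjugate-oracle tests use
20k-plus draws where Monte-Carlo error must be small.

## Known limitations

* Inference is per-region; cross-region joint modeling and
  summary-statistic input are out of scope.
* Fisher's method over correlated phenotypes yields screening scores, not
  calibrated p-values; regions are ranked, not tested.
* The factor model's label/sign ambiguity is resolved only up to greedy
  matching; factor-specific summaries inherit that approximation (omnibus
  gene-level results do not).
* Whether imputation should use the posterior mean of $\gamma$ or its
  slab-conditional mean is a modeling choice; the package uses the
  posterior mean.
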