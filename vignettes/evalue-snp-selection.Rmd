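---
title: "Quantile e-value SNP selection in family GWAS: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile e-value SNP selection in family GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Family-based genome-wide association studies genotype nuclear pedigrees —
two parents plus monozygotic (MZ) twins, dizygotic (DZ) twins, adoptees, or
ordinary siblings — and measure quantitative traits. Standard practice tests
one SNP at a time, which wastes power when several SNPs in a gene act
jointly, and model-selection alternatives that refit a model per candidate
subset are prohibitively expensive under a mixed-model likelihood. This
package implements a *single-fit* selection procedure: the multi-SNP mixed
model is estimated once, a fast generalized bootstrap perturbs its
estimating equations to approximate the sampling distribution of the
coefficient vector, and each SNP is judged by how much the distribution
degrades when its coordinate is forced to zero.

## The ACE linear mixed model

For family $i$ with $n_i$ members, trait vector $y_i$, genotype matrix
$G_i \in \{0,1,2\}^{n_i \times p_g}$ and covariates $C_i$:

$$y_i = \alpha + G_i \beta_g + C_i \beta_c + \epsilon_i, \qquad
\epsilon_i \sim N(0, V_i),$$

$$V_i = \sigma_a^2 \Phi_i + \sigma_c^2 \mathbf{1}\mathbf{1}^\top +
\sigma_e^2 I_{n_i}.$$

$\Phi_i$ holds twice the kinship coefficients (1 on the diagonal, 1/2 for
parent–biological-child and DZ/sibling pairs, 1 for MZ twins, 0 for pairs
involving adoptees), $\sigma_c^2$ is a shared-environment variance common to
the whole household, and $\sigma_e^2$ is individual noise. `fit_ace_lmm()`
maximizes the Gaussian likelihood with the fixed effects profiled out by
GLS, optimizing the three variance components on the log scale with
`L-BFGS-B` (Nelder–Mead fallback) from an equal-thirds split of the OLS
residual variance. Only per-family matrices (typically $4\times 4$) are ever
formed; families sharing a covariance structure are batched through
member-wise crossproducts, so one likelihood evaluation costs a handful of
$p \times p$ accumulations.

Numerical choices: maximum likelihood is the default (REML is a switch) —
the bootstrap reuses the fixed-effect caches, which are identical under
both; $\sigma_e^2$ is floored at $10^{-6}$ times the total phenotypic
variance so every $V_i$ stays invertible; $\sigma_a^2$ or $\sigma_c^2$
reaching zero is flagged, not an error. With identity kinship throughout
(all-adoptee data) $\sigma_a^2$ and $\sigma_e^2$ are confounded by design;
only their sum is interpretable.

## Generalized bootstrap

Refitting the model per bootstrap sample would defeat the purpose. Instead,
for i.i.d. positive weights $w_1, \dots, w_m$ with mean 1 and standard
deviation $s$, a draw solves the reweighted estimating equations

$$\hat\beta_w = \Big(\sum_i w_i X_i^\top \hat V_i^{-1} X_i\Big)^{-1}
\sum_i w_i X_i^\top \hat V_i^{-1} y_i,$$

with $X_i = [\,1 \mid G_i \mid C_i\,]$ and $\hat V_i$ frozen at the fitted
variance components. The per-family crossproducts are cached at fit time, so
an ensemble of draws is two matrix products plus one small Cholesky solve
per draw — embarrassingly parallel and far cheaper than refitting.

Design choices:

* **Weight law.** Gamma with shape $1/s^2$ and scale $s^2$ (mean 1, sd $s$,
  strictly positive), which keeps every weighted crossproduct positive
  definite. Multinomial ($m$-out-of-$m$) weights are available as an
  alternative, in which case the effective scale is fixed near 1.
* **Family-level weights.** Families are the independent sampling units;
  weighting individuals would break the within-family covariance logic.
* **Calibration.** With sd$(w) = s$, a first-order expansion gives
  bootstrap spread $\approx s \times$ the GLS standard error in every
  coordinate (verified as a test at $B = 2000$: ratios within
  $[0.8, 1.2]$). The scale $s$ is thus the unit in which "synthetic noise"
  is measured, and moving $s$ across $[0.1, 2]$ moves the procedure from
  aggressive to conservative.
* **Two independent ensembles.** A *reference* ensemble supplies the
  moments that standardize the evaluation map; an independent *evaluation*
  ensemble supplies the points being scored, avoiding self-evaluation
  bias. Both default to 500 draws.

## E-values and the quantile selection rule

An evaluation map scores a point $x$ against a distribution with mean
vector $\mu$ and coordinate standard deviations $\sigma$ via
$z = (x - \mu)/\sigma$:

$$E_1 = \frac{1}{1 + \|z\|^2}, \qquad E_2 = \exp(-\|z\|).$$

Both live in $(0, 1]$, equal 1 at the reference mean, and are invariant to
coordinate-wise location–scale changes (a property the tests enforce);
algebraically $E_1 \ge E_2$ everywhere. For each evaluation draw
$\theta_b$, the full-model e-value sample is $E(\theta_b)$ and the
leave-one-SNP-out sample for SNP $j$ is $E(\theta_b^{(j)})$ with coordinate
$j$ zeroed. Zeroing a coordinate whose estimate is many bootstrap standard
deviations from zero drags the e-value down — that is the detection signal.

Selection compares tail quantiles rather than means: SNP $j$ is flagged
when

$$c_q(\mathbb{E}_{-j}) < t\, c_q(\mathbb{E}_{*}) \quad \text{for every }
q \in \{0.5, 0.6, 0.7, 0.8, 0.9\},$$

with strict inequality (ties lose) and $t \in (0,1)$. The all-$q$
conjunction is deliberately conservative; the mean-functional rule
(`select_snps_mean()`) is provided for comparison and is markedly more
liberal in weak-signal regimes. Empirical quantiles use the inverse-CDF
convention with linear interpolation (R type 7) throughout — the rule only
ever compares quantiles of equal-size samples, so any fixed convention
works, but conventions must not be mixed. A variant rule that shifts the
quantile level ($c_q(\mathbb{E}_{-j}) < c_{tq}(\mathbb{E}_{*})$) instead of
scaling the threshold is available via `rule = "shifted_quantile"`; because
the noise scale $s$ is tuned (below), the two variants largely coincide
after tuning, the tuned $s$ absorbing the difference.

## Tuning (s, t) by holdout prediction error

The procedure's operating point depends on $s$: too small and every
coordinate looks significant when zeroed, too large and nothing does.
`run_selection()` fits the full model once, then for each $s$ on a grid
draws one ensemble pair and evaluates the rule at each $t$; each candidate
set is scored by the fixed-effect prediction error
$\sum (y_{\text{test}} - X_{\text{test}} \hat\beta_{\hat S})^2$ over all
individuals of held-out families, and the grid minimum wins (first minimum
in grid order — i.e. smallest $s$ — on ties). The refitted
$\hat\beta_{\hat S}$ is the restricted GLS estimate (intercept, covariates
and selected SNPs, variance components frozen): zeroed-out full-model
estimates are available as an option, but carry omitted-variable bias in
correlated blocks. Prediction includes the intercept and covariate
contributions. An instrumented counter verifies the one-fit-per-dataset
contract in the tests.

Default grids: in simulation studies $s \in \{0.1, 0.15, \dots, 0.95, 2\}$
with $t$ fixed per experiment; for data analysis
$s \in \{0.2, 0.4, \dots, 3\}$, $t \in \{0.1, 0.15, \dots, 0.8\}$ with a
75/25 family-level holdout.

## The synthetic generator

`simulate_dataset()` emulates a twin-study design: $m = 250$ four-member
MZ-twin families by default, $p_g = 50$ SNPs in independent blocks of
6, 4, 6, 4, 30 with minor allele frequencies 0.2, 0.4, 0.4, 0.25, 0.25 and
within-block correlation 0.7. Parental haplotype vectors are correlated
Bernoulli draws from a Gaussian copula whose *latent* equicorrelation is
calibrated by bisection on the bivariate-normal orthant probability so that
the *binary-scale* correlation hits 0.7; genotypes are sums of two
haplotypes, children inherit one haplotype per parent (MZ twins share the
transmitted pair, DZ twins redraw, adoptees get fresh haplotypes).
Phenotypes follow the ACE model with $(\sigma_a^2, \sigma_c^2, \sigma_e^2)
= (4, 1, 1)$ and zero intercept; the first SNP of each of the first four
blocks is causal.

**Effect-size calibration.** The per-SNP heritability parameter $h$ is
defined so that a causal SNP explains $h/(\sigma_a^2+\sigma_c^2+\sigma_e^2)$
percent of the total trait variability; with the genotype variance
$2\,\mathrm{MAF}(1-\mathrm{MAF})$ this gives
$\beta_k = \sqrt{h / (100 \cdot 2\,\mathrm{MAF}_k(1-\mathrm{MAF}_k))}$,
the package default (`h_convention = "total_variance"`). An alternative
scaling that divides additionally by the variance total
($\beta_k = \sqrt{h / (100\, (\sigma_a^2+\sigma_c^2+\sigma_e^2) \cdot
2\,\mathrm{MAF}_k(1-\mathrm{MAF}_k))}$, effects smaller by $\sqrt 6$ at the
defaults) is kept as `"error_scaled"`. The two conventions differ
materially: under the default, an $h = 10$ causal SNP at $m = 250$ sits in
the regime where single-SNP scans find it routinely but not always (the
test suite exercises exactly this); under the alternative the same SNP's
effect is weaker by a factor of $\sqrt 6$ and is essentially below the
detection floor of every method at this sample size. The default is the
convention consistent with the heritability definition above and is used
throughout the benchmarks.

What the generator does *not* emulate: realistic linkage-disequilibrium
decay (blocks are equicorrelated, real LD decays with distance), allele
frequency spectra, missing genotypes, non-Gaussian traits, parental
phenotype ascertainment effects, or population stratification. Passing
benchmarks here therefore demonstrates the machinery under idealized
familial dependence, not performance on any real cohort.

## Baselines

* `single_snp_scan()` fits the one-SNP-at-a-time ACE model by **exact**
  GLS with variance components estimated once on the null model and reused
  (a per-SNP re-estimation switch exists), Wald $t$-tests, and
  Benjamini–Hochberg correction at FDR 0.05. Note that fast industrial
  scanners built on rapid GLS approximations can run anti-conservative
  relative to this exact reference on strongly familial data; exact GLS is
  the defensible implementation, and its power at a given effect size is
  what it is.
* `mbic2_backward()` ignores the family covariance entirely (the
  no-dependence baseline) and performs OLS backward deletion under
  mBIC2, $n\log(\mathrm{RSS}/n) + k\log n + 2k\log(p_g/4) - 2\log k!$ —
  a criterion adopted from the model-selection literature, as a multiple
  testing-aware BIC. Under clustered errors its OLS statistics are
  overdispersed, so it retains a handful of false positives per panel on
  strongly familial data; this is a property of the baseline, not a bug.

## Benchmark problem sizes

The packaged benchmarks and the acceptance script use 100 replications per
setting (binomial Monte Carlo standard error on a rate around 0.02–0.04),
$m = 250$ families, ensembles of 500 draws, and the simulation $s$-grid
above — sizes chosen so a full benchmark runs in minutes on a laptop while
keeping the Monte Carlo noise below the effects being measured. The
metrics are TP (proportion of causal SNPs detected), TN (proportion of
non-causal SNPs undetected), RTP (proportion of causal *blocks* with at
least one detection — credit for hitting a correlated neighbour) and RTN
(proportion of signal-free-block SNPs undetected).

## Known limitations

Nuclear four-member pedigrees only (no loops, no three-generation
families); no missing-data handling; Gaussian traits only; $n > p$
required (the full-model fit must be well posed); no false-discovery-rate
calibration of the e-value procedure itself — the threshold $t$ trades TP
against TN empirically rather than targeting a nominal error rate; and the
e-value machinery presumes the full-model estimator has a regular sampling
distribution, which fails in high-dimensional regimes.
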