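---
title: "The multi-trait multi-environment model behind mtmenue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multi-trait multi-environment model behind mtmenue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`mtmenue` fits plot-level data from lattice variety trials evaluated in
several environments (here: soil N levels) for several traits (here: the
nitrogen use efficiency components NUpE and NUtE) with the linear mixed
model

$$ y = X\beta + Z_1 r + Z_2 b + Z_3 u + \varepsilon, $$

where $y$ stacks every non-missing plot-by-trait observation. The columns
of each incidence matrix are indexed by *trait-by-environment combination*,
ordered trait-major with the environment fastest: for the default labels,
`NUpE:LN, NUpE:HN, NUtE:LN, NUtE:HN`.

* $\beta$ — one systematic mean per combination, independent flat normals
  $N(0, 10^8)$. The model deliberately keeps replication out of $\beta$:
  replicate effects are random, so $\beta$ is strictly the four cell means.
* $u$ — genotype effects with $u \sim N(0, I \otimes \Sigma_u)$. Under the
  **full** model $\Sigma_u$ is the unstructured covariance over all
  combinations, so a genotype's effect differs between environments: this
  *is* the G×E model. Under the **null** model genotype effects are indexed
  by genotype-by-trait and shared across environments ($\Sigma_u$ reduces
  to a trait-by-trait matrix). This is the standard no-interaction
  reduction; everything else in the model is unchanged, which keeps the DIC
  comparison between the two meaningful. Lines are treated as unrelated
  ($I$, no kinship).
* $r$, $b$, $\varepsilon$ — replicate-within-environment,
  block-within-replicate and plot residual effects. Each carries a
  per-environment trait covariance matrix ($\Sigma_r$, $\Sigma_b$,
  $\Sigma_e$, one $K \times K$ block per environment). Cross-environment
  cells of these structures are *structurally zero*: no replicate, block or
  plot exists in two environments, so such covariances would not be
  identifiable. (Printed 4×4 layouts of these matrices in the literature
  cover the same parameters; the off-environment cells carry no data
  information.) $\Sigma_u$ stays full because genotypes are shared across
  environments.

All covariance matrices get inverse-Wishart priors. Hyperparameters are
rarely reported in applied work and none are prescribed here, so
`default_priors()` uses a weakly informative default: $\nu = d + 1$ per
structure of dimension $d$, and scale matrix $S$ equal to the diagonal of
the empirical phenotypic variances of the combinations the structure
covers, divided by the number of variance structures in the model (four in
the complete model) — i.e. the prior scales partition the phenotypic
variance evenly. Every summary that matters should be screened with the
prior-sensitivity sweep `default_priors(design, scale_factor = 0.1)` /
`scale_factor = 10`; the acceptance checks do exactly that before calling a
banded deviation a failure. With only two replicates per environment the
replicate variance is the one component whose posterior stays visibly
prior-sensitive.

# The sampler

`run_chain()` alternates:

1. **Location block.** All of $\beta, r, b, u$ are drawn *jointly* from
   their Gaussian full conditional by solving the mixed-model equations
   $C\theta = W'R^{-1}y$ with
   $C = W'R^{-1}W + \mathrm{blockdiag}(B^{-1}, \ldots, I \otimes
   \Sigma_u^{-1})$, then adding correlated noise through the Cholesky
   factor of $C$. A joint draw avoids the slow mixing that one-at-a-time
   updates show when effects are confounded (e.g. $\beta$ with replicate
   means). `sample_location_conditional()` is the same update in plain R,
   kept as the testable single-step operation: its limits are the OLS fit
   (flat prior, no random terms) and the GLS fit (residual variance
   $\to 0$), which the test suite checks against closed forms.
2. **Missing-data augmentation.** A plot with one trait missing gets its
   residual drawn from the conditional normal given the observed trait;
   the stacked response itself only ever contains observed cells.
3. **Covariance blocks.** Each structure is updated from its conjugate
   conditional $\mathrm{IW}(\nu + n, S + \sum_\ell e_\ell e_\ell')$ over
   its level effects (genotypes for $\Sigma_u$; replicates, blocks and
   augmented plot residuals per environment for the others). A $1 \times 1$
   structure is exactly the scaled-inverse-chi-square update, and the test
   suite verifies the chain's marginal against that closed form by a KS
   test.

The loop is compiled (RcppArmadillo) and uses R's RNG, so a
`chain_config(seed = )` makes whole fits bit-reproducible. Retention
follows the usual schedule arithmetic: `floor((n_iter - burn_in) / thin)`
draws (a 1,000,000 / 500,000 / 5 schedule retains exactly 100,000).

Numerical choices: coefficient-matrix Cholesky failures are repaired by
symmetrization plus an escalating diagonal jitter starting at
$10^{-10}\,\mathrm{tr}(C)/q$, and every repair is counted in
`fit$n_psd_repair`; repeated failure aborts. Chains are initialized at the
empirical cell means with diagonal covariance matrices at half (residual)
or a quarter (other structures) of the phenotypic variance — initialization
only affects the transient, which the burn-in discards.

# Deviance and DIC

The recorded deviance is **conditional on the location effects**:
$D = -2\log p(y \mid \beta, r, b, u, \Sigma_e)$, summed per plot over the
observed traits with the observed sub-block of that environment's residual
covariance. `compute_dic()` reports
$\mathrm{DIC} = D(\bar\theta) + 2 p_D$, $p_D = \bar D - D(\bar\theta)$.
This is the convention of the animal-model MCMC software family; absolute
DIC values are therefore comparable only *within* this implementation, and
model choice should use the ordering (`compare_models()`), never published
absolute values computed under unknown conventions. Ties prefer the null
model (parsimony).

# Posterior summaries

* **HPD intervals** use the Chen–Shao shortest-empirical-interval
  construction (`coda::HPDinterval`), which assumes unimodality.
* **Posterior modes** come from a Gaussian KDE with the normal reference
  bandwidth (`bw.nrd`) on a fixed 512-point grid spanning the draw range
  (the rule-of-thumb bandwidth `bw.nrd0` oversmooths skewed posteriors).
  Because the KDE is nearly flat around its maximum, the raw grid argmax
  wanders by several grid cells between seeds; the estimate is therefore
  refined by fitting a parabola to the contiguous peak neighbourhood
  (points within 2% of the maximum density) and taking its vertex, which
  keeps the mode within 0.05 of the analytic value for a Gamma(2, 1)-shaped
  posterior at $10^6$ draws. Mode, mean and median coincide on symmetric
  posteriors; their
  divergence on heritability draws is expected and is reported rather than
  hidden.
* **Heritability** is the per-draw plug-in ratio
  $\sigma_g^2 / (\sigma_g^2 + \sigma_r^2 + \sigma_b^2 + \sigma_e^2)$,
  which lies in $[0, 1]$ by construction and is invariant to trait
  rescaling.
* **CV indices** follow the convention of scaling by the observed
  phenotypic mean of the combination, with variances taken as posterior
  means: $CV_g = 100\sqrt{E[\sigma_g^2 \mid y]} / \bar y$, likewise
  $CV_e$. Note that for weakly informed, right-skewed variance posteriors
  (few plots per genotype) the posterior *mean* can sit well above both
  the posterior mode and the realized effect scatter, and CV indices
  inherit that: they are estimator summaries, not realized-variance
  summaries.
* **Convergence** is screened with the Geweke single-chain z-score
  (`coda::geweke.diag`, first 10% vs last 50% windows, spectral variance
  at frequency zero), the diagnostic of the CODA package;
  `summarize_genetics()` warns when any variance-component chain fails
  $|z| < 1.96$.
* **Selection**: breeding values are posterior means of $u$ with HPD
  intervals; rankings break ties lexicographically by genotype label so
  reports are deterministic; top-$k$ coincidence is
  $100\,|A \cap B| / k$, order-free. Larger breeding values are better for
  both NUpE and NUtE (both are benefit traits).

# The synthetic-data generator

`simulate_trial()` draws from exactly the model above: genotype effects
once per genotype from $N(0, \Sigma_u)$, replicate/block/residual effects
per environment, phenotype $= \mu + r + b + u + \varepsilon$. The lattice
randomization is a fresh random partition of the genotypes into blocks per
replicate — not a combinatorially resolvable lattice-square construction;
the model does not require resolvability, and the partition exercises the
same estimability structure. Raw measurement columns are back-derived from
the simulated traits (`plant_n = nupe * n_supply`, with soil N supply an
explicit per-environment input, 30/180 kg/ha by default, never
hard-coded), so simulated tables round-trip through the trait
construction.

`make_default_truth()` pins the simulation scenario to published posterior
estimates for a 64-line tropical maize panel under contrasting N: genetic
variances 0.183/0.095 (NUpE at LN/HN) and 27.534/40.323 (NUtE), means
2.103/0.499/30.318/28.842, zero genetic covariances between traits. Only
the heritability-implied *total* non-genetic variance is recoverable from
such summaries; the split is a package choice — replicate and block each
get 10%, the residual 80% — and is fully overridable through
`variance_truth()`.

`nue_reference_trial()` goes one step further and is the package's
regression target: effects are drawn once under a fixed internal seed and
then linearly recoloured so the *realized sample moments* equal the
calibration exactly (cell means, genotype-effect covariance, block and
residual covariances; the two replicate effects per environment are
$\pm a$ patterns with exact variance, which degenerates their cross-trait
correlation to $\pm 1$ — a harmless nuisance artifact). Residual variances
come from published CVe values, the replicate-plus-block remainder is
back-solved from published posterior-mean heritabilities and split equally,
within-environment genetic correlations are the published near-zero values,
and the unreported cross-environment genetic correlations are set to 0.95
(NUtE) and 0.20 (NUpE), mirroring the reported top-10 ranking coincidence
across N levels. The trial is fully synthetic and is labelled as such; it
is *not* the original field data.

What passing tests on these data do and do not show: the generator is
exactly Gaussian, balanced (unless you delete cells), spatially
unstructured and free of measurement error in the raw columns. Real lattice
trials have field trends, outliers, moisture-correction noise and
occasionally lost plots; agreement on the synthetic data demonstrates
correctness of the machinery and recoverability of the encoded parameters,
not robustness to those field artifacts. One estimand subtlety matters when
comparing against the encoded targets: matching the *realized* genotype
scatter to a published variance does not force the posterior-mean variance
to land on that number (see the CV note above) — with two plots per
genotype per environment the genetic-variance posterior is strongly
right-skewed, so ratio summaries built from posterior means (CVg/CVe) land
above the encoded value even for a correct sampler, while
heritability (whose numerator and denominator inflate together), means,
correlations and rankings are recovered.

# Problem sizes used by the tests and the acceptance script

All checks run on the 256-plot default trial. The reference-trial
end-to-end checks use a scaled chain of 100,000 iterations / 20,000
burn-in / thin 10 for the full multi-trait fit and 50,000 / 10,000 / 10
for the single-trait and null fits; the DIC preference study uses 20
simulated replicates at 2,500 iterations, and parameter-recovery uses 20
replicates at 3,000 — short chains are adequate there because only
orderings and interval coverage are asserted. The acceptance script uses
100,000 / 20,000 / 10 (full multi-trait), 60,000 / 12,000 / 10
(single-trait full fits) and 50,000 / 10,000 / 10 (null fits). These sizes are the package's own reproducibility
choices; production analyses of real trials should use the full
1,000,000 / 500,000 / 5 schedule and check Geweke diagnostics.

# Prior sensitivity of weakly identified variance components

With two replicates per environment, each genotype contributes only two
plots to every trait-by-environment cell, so genetic variances are weakly
identified and their posteriors depend visibly on the inverse-Wishart
hyperparameters. Two failure modes bracket the choice of scale. With the
default scales (phenotypic variance over the number of structures) the
prior keeps almost no mass below a genetic variance whose per-plot
heritability is near 0.02, so near-zero components (NUpE in this crop
system) are pushed upward and their credible intervals can exclude a small
simulated truth. With much smaller scales the IW marginal's $x^{-2}$ spike
at zero creates a second, often dominant posterior mode near zero that can
capture even moderately heritable components; a chain may transition into
that mode after hundreds of iterations and legitimately stay there — this
is a property of the posterior, not a sampler defect (the location and
covariance updates check out against closed forms, and a REML fit of the
same joint model brackets the likelihood's answer). Consequences drawn in
this package: default scales stay at the phenotypic-variance recipe (they
behave best for the moderately heritable components), every report should
run the `scale_factor` 0.1/10 sweep, simulation-based coverage of genetic
variances should not be expected to reach nominal levels for components
with per-plot heritability of a few percent at this design size, and NUpE
heritability statements should always carry the sweep.

# Known limitations

* No kinship/pedigree covariance among lines; no spatial field-trend
  modelling; no multi-year or multi-location structures beyond the
  environments given.
* DIC uses the conditional deviance; marginal-likelihood variants are out
  of scope, as is REML estimation.
* Single-chain Geweke screening only; no multi-chain Gelman–Rubin
  diagnostics.
* HPD and mode estimators assume unimodal posteriors.
* The NUpE heritability posterior is weakly informed in trials of this
  size; its mode/mean/median differ noticeably and prior sensitivity
  should always be reported for it.
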