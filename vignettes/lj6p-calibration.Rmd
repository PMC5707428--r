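---
title: "Bayesian calibration of the Lennard-Jones 6-p potential"
author: "ljbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian calibration of the Lennard-Jones 6-p potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ljbayes)
```

## The model

Pairs of noble-gas atoms are modelled with the generalized Lennard-Jones
6-p potential

$$V(r) = 4\varepsilon\left[\left(\frac{\sigma}{r}\right)^p -
  \left(\frac{\sigma}{r}\right)^6\right],$$

with well-depth scale $\varepsilon$ (kcal/mol), zero-crossing distance
$\sigma$ (Å), and repulsion exponent $p$. The attractive $r^{-6}$ tail
has a physical justification (dispersion forces); the conventional
$p = 12$ was chosen historically for computational convenience, and this
package exists to treat $p$ as an inferable, continuous parameter
($p > 6$) rather than a constant. For condensed-phase observables the
potential is truncated to exactly zero beyond $r_c = 3\sigma$, with no
energy shift; the resulting discontinuity at the cutoff is irrelevant
for curve fitting. The Boltzmann constant is fixed at
`kB = 0.0019872041` kcal/(mol K).

An observable curve $d$ on a grid of separations (a radial distribution
function $g(r)$, or a dimer binding-energy scan $E(r)$) is linked to the
model curve $f(\theta)$ through an i.i.d. Gaussian data model,
$d \sim N(f(\theta), \sigma_n^2 I)$, with a single noise scale
$\sigma_n$ per dataset inferred jointly with the physical parameters.
So the full parameter vector is $\theta = (\varepsilon, \sigma,
\sigma_n)$ for the classical 6-12 form and $(\varepsilon, \sigma, p,
\sigma_n)$ for 6-p. Bins are deliberately unweighted: features with
large squared-error leverage (the first RDF peak, the repulsive wall of
a dimer scan) dominate the posterior naturally, which is why $\sigma$
— which sets the peak location — is always identified much more
sharply than $\varepsilon$.

Priors are wide uniform boxes: $[0.05, 3] \times [3, 4] \times
[10^{-6}, 1]$ for 6-12 and $[0.05, 10] \times [3, 4] \times [6.01, 15]
\times [10^{-6}, 1]$ for 6-p (the wider $\varepsilon$ range
accommodates the strong $\varepsilon$–$p$ correlation). $\sigma_n$ is
sampled on its natural scale to match the stated uniform bounds.

## Forward models at desk scale

A molecular-dynamics engine is the physically faithful forward model
for condensed-phase RDFs, but it is far too expensive for a test suite.
The package therefore ships two closed-form models and an adapter:

* **Dimer binding energy** (`dimer_energy_model`): the pair potential
  itself, evaluated *untruncated*. A quantum dimer scan probes the
  attractive tail beyond $3\sigma$, where a hard zero would be
  unphysical; the cutoff belongs to the condensed-phase convention.
  Which convention the gas-phase fit should use was genuinely open; we
  resolved it by keeping each model faithful to its data's physics.
* **Dilute-gas RDF** (`dilute_rdf_model`):
  $g(r) = \exp(-V_{trunc}(r) / k_B T)$, the low-density limit of the
  radial distribution function, using the truncated potential to mirror
  the MD convention. This is declared openly as a surrogate physics
  model: it is exact only at vanishing density and has no oscillatory
  liquid structure beyond the first peak, but it preserves the
  parameter sensitivities that drive the calibration ($\sigma$ sets the
  peak location, $\varepsilon$ its height) while evaluating in
  microseconds. Its exponent is clipped at $\pm 50$ so that deep-well
  proposals stay finite and ordered rather than overflowing.
* **External engine adapter** (`register_external_engine`): a command
  template with parameter placeholders, returning a forward model that
  shells out per evaluation and validates the returned grid. The
  documented reference protocol (666 atoms, periodic boundaries, NPT
  equilibration of $5 \times 10^6$ 2-fs steps, NVE production of
  $10^5$ steps, 100 RDF bins) is recorded on the adapter; the package
  never implements the engine itself.

Consequently, passing tests demonstrate correct *inference machinery*
on data whose statistical structure (smooth LJ-governed curve plus
i.i.d. Gaussian noise) matches the likelihood exactly; they do not
demonstrate that an MD-computed liquid RDF is well fit, and the
published liquid/vapor posterior tables are declared non-reproducible
at desk scale (`non_desk_targets()`).

## The sampler

`run_tmcmc()` implements transitional MCMC: the posterior is approached
through the tempered family $p_j(\theta) \propto p(\theta)
L(\theta)^{q_j}$ with $0 = q_0 < \dots < q_m = 1$. Each stage
reweights the current ensemble by $L^{\Delta q}$, accumulates
$\log p(d)$ as the log mean incremental weight, resamples
multinomially, and moves the chains by Gaussian random-walk
Metropolis-Hastings steps whose covariance is $\beta^2$ times the
weighted ensemble covariance.

Numerical choices, all exposed in `tmcmc_control()`:

* **Stage control.** $\Delta q$ is the largest step for which the
  coefficient of variation of the incremental weights stays at or below
  `target_cov = 1`, found by bisection to $10^{-10}$ and clamped at
  $q = 1$. Identical log-likelihoods therefore jump straight to 1.
* **Proposal scale** $\beta = 0.2$; proposals that leave the prior box
  are rejected outright, which truncates the posterior correctly
  (reflection would need Jacobian bookkeeping for no benefit).
* **Sweeps.** Each stage applies `n_mh = 5` parallel MH sweeps — one
  proposal per chain per sweep — instead of a single move per resampled
  leader. Low-noise dimer posteriors occupy a thin curved ridge in
  $(\varepsilon, p)$; with a single sweep the resampled ensemble
  decorrelates too slowly, the 5–95% intervals come out visibly
  narrower than the posterior, and the most probable value can sit
  outside its own interval. Five sweeps restore nominal-looking
  coverage at modest cost. This replaces the single-step-per-leader
  variant that a minimal implementation would use; chain-length-based
  variants would couple likelihood evaluations sequentially, which we
  avoided to keep evaluations order-independent and batchable.
* **Randomness.** All draws of a sweep are generated before any
  likelihood evaluation, so results depend only on the seed and sample
  indices; identical seeds give bit-identical ensembles.
* **Defaults** of 2000 samples per stage (three-parameter model) and
  4000 (four-parameter model) follow the calibration sizes; `mpv()`
  ties are broken at the lowest index; quantiles use linear
  interpolation (`type = 7`).
* **Failure modes.** An all-`-Inf` stage-0 likelihood raises a typed
  degenerate-likelihood error; exceeding `max_stages` raises a
  non-convergence error carrying the partial state.

The batched objective (`vectorized` attribute) lets the built-in
forward models evaluate a whole proposal block as matrix arithmetic;
this is what makes 4000-sample calibrations run in seconds.

## The hierarchical layer

Across thermodynamic conditions the per-dataset parameters
$\theta_i$ share a conditional prior $p(\theta | \psi)$. Two factorized
families ship: independent truncated normals (default; smooth shrinkage
with per-parameter location and scale) and a uniform sub-box
parameterized by center and half-width, clipped to the global box and
renormalized. The center/half-width parameterization — rather than raw
lower/upper bounds — keeps the hyper-parameter support rectangular
(which the sampler needs) and makes the base-box reduction exact: a
half-width equal to the full box width recovers the base uniform prior
to machine precision. The noise scale $\sigma_n$ is never tied across
datasets: noise is condition-specific.

`lj_hb()` runs three stages: (1) independent per-dataset calibrations
under the base prior; (2) a TMCMC run over $\psi$ whose likelihood
$\sum_i \log p(d_i | \psi)$ is estimated by self-normalized importance
sampling over the stage-1 ensembles (re-running the forward model per
$\psi$ would be prohibitive with a real engine; the estimator's
effective sample size is tracked and warned on); (3) a per-dataset
refresh that reweights stage-1 samples by the hyper-marginalized prior
ratio, marginalizing over the full $\psi$ posterior rather than its
point estimate, then resamples. The hyperprior is uniform: locations
range over the base box, scales and half-widths over $(10^{-3} w, w)$
per parameter — wide and scale-aware, since nothing sharper is known a
priori. Refreshed ensembles contain only stage-1 support points by
construction.

## The kriging surrogate

For expensive objectives the sampler can consult a local ordinary
kriging interpolant of the *log-likelihood* (the scalar the sampler
actually consumes, not the raw curve). For each chain leader a box of
width one quarter of the sampling domain per dimension is centred on
the leader, clipped to the domain, and trained on all truly-evaluated
points inside. A prediction replaces a true evaluation only when

1. the box holds at least $2d + 1$ training points,
2. the kriging standard error is at most 5% of the predicted value's
   magnitude (values near zero therefore auto-reject — safe), and
3. the prediction lies inside the 5–95% quantile band of all true
   objective values seen so far (read on the objective scale).

Every rejected prediction falls back to exactly one true evaluation,
which then enriches the archive. The kernel is squared-exponential on
box-scaled coordinates with a relative nugget of $10^{-8}$; the single
lengthscale is refit in each box by maximizing the concentrated kriging
marginal likelihood, with training capped at the 25 points nearest the
leader to bound the cost. A singular correlation matrix produces a
`too_few_points` decision, never a sampler error.

## Model selection and prediction

`bayes_factor()` compares two calibrations through
$\exp(E_2 - E_1)$ of their log-evidences, computed in log space.
Evidence comparisons use the per-dataset, non-hierarchical evidences.
`robust_predict()` propagates posterior uncertainty into an observable
by evaluating the forward model at the most probable value and at 100
posterior draws (with replacement when the request exceeds the ensemble;
individual failures are dropped and counted, more than half is an
error), reporting the MPV curve with pointwise 5–95% bands. Scalar
predictions are scored with the relative squared error
$\frac{1}{N}\sum_k ((g_k - r_k)/r_k)^2$ and RDF curves with the
mean-squared error averaged over conditions. Density and diffusion
quantities of interest pass through the same generic forward-model
interface but need an MD engine, so no built-in implementation is
provided.

## Synthetic data

`generate()` draws datasets with exactly the statistical structure the
likelihood assumes — a noiseless forward curve plus i.i.d.
$N(0, \sigma_n^2)$ perturbations from a known, recorded truth — so
parameter recovery is a meaningful end-to-end check.
`argon_presets()` anchors the truths at published posterior
most-probable values (the gas-phase dimer row
$\varepsilon = 0.252$, $\sigma = 3.370$, $p = 12.703$,
$\sigma_n = 0.006$; liquid-like RDF rows with $p \approx 6.3$–$6.6$)
at the six calibration state points, so the fixtures have realistic
magnitudes without claiming to reproduce data-dependent posteriors.
The dimer grid spans $0.9\sigma$ to $2.5\sigma$ over 40 points
(repulsive wall, well, and tail; the original quantum scan's grid is
not published), and RDF grids use the standard 100 bins over
2.5–12 Å.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run everything at the sizes
the method defaults prescribe where a size is part of the study design
(4000 samples per stage for the dimer exponent-recovery check, 2000 for
conjugate evidence), and at smaller ensembles chosen as this package's
own design where only a direction or an invariance is asserted:
1000/2000 samples per stage for the model-selection direction runs,
1500-sample stage-1 ensembles with a 1000-sample hyper stage for the
hierarchical shrinkage check, and 1000-sample single-sweep runs for
surrogate neutrality. The conjugate-Gaussian closed forms
($\log p(d) = \log(1/\sqrt{4\pi})$ for the unit model), brute-force
grid searches, and hand-evaluated density formulas serve as the
independent oracles throughout.

## Known limitations

* The dilute-gas RDF model cannot represent liquid packing structure;
  conclusions about real liquid argon require the engine adapter.
* The hierarchical hyper-likelihood is an importance-sampling estimate;
  when a $\psi$ concentrates far from a stage-1 cloud its ESS degrades
  (tracked, floor-warned at 50).
* Evidence estimates at a few thousand samples carry Monte-Carlo error
  of order 0.1–1 nat on sharp posteriors; Bayes-factor *directions* are
  stable, their magnitudes fluctuate.
* The surrogate's 5% rule is relative to the predicted magnitude; on
  objectives crossing zero it degenerates to always-true evaluation,
  by design.

## A worked example

```{r example, eval = FALSE}
library(ljbayes)

spec <- argon_presets()$Q          # gas-phase dimer preset
d <- generate(spec)                # 40-point synthetic scan
fit <- lj_calibrate(d, "lj6-p", seed = 1)
summary(fit)
confint(fit)                       # 5-95% posterior intervals
pred <- predict(fit)               # robust posterior prediction
plot(fit)
```
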