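---
title: "Methods: simultaneous Bayesian co-refinement of small-angle scattering data"
author: "corefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous Bayesian co-refinement of small-angle scattering data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corefit)
```

## The problem

Small-angle X-ray and neutron scattering (SAXS/SANS) measure the
orientationally averaged intensity $I(q)$ of particles in solution.  A
single curve rarely determines a multi-parameter structural model
uniquely; combining curves measured under different contrast conditions
(e.g. a synchrotron SAXS curve plus a SANS curve in which some regions
are nearly matched out) constrains complementary parts of the structure.
`corefit` refines one analytic model simultaneously against several such
curves by minimizing

$$Q = \sum_j w_j\, \chi^2_j \;+\; \alpha S, \qquad
\chi^2_j = \sum_i \frac{\bigl(I_{ij} - I_{\mathrm{model}}(q_{ij})\bigr)^2}
{\sigma_{ij}^2},$$

where $w_j$ is a per-dataset weight, $S$ is a Gaussian prior penalty
$\sum_k [(x_k - \mu_{\mathrm{prior},k})/\sigma_{\mathrm{prior},k}]^2$,
and $\alpha$ sets the weight of the prior.  The package's purpose is
twofold: it is a working co-refinement tool, and it is a benchmarking
framework that measures — by replicated simulation with known ground
truth — which weighting scheme and which kind of prior recover model
parameters most accurately.

## Weighting schemes

Three schemes are implemented (`scheme_weights()`):

* **naive** — $w_j = 1$: every point counts with its own statistical
  error; larger, better-measured datasets carry proportionally more
  weight.
* **reduced** — $w_j = 1/M_j$: every dataset carries the same total
  weight regardless of its number of points $M_j$, akin to summing
  reduced chi-squares.
* **information** — $w_j = N_{g,\mathrm{BIFT},j}/M_j$: each dataset is
  weighted by its estimated information content per point, with
  $N_{g,\mathrm{BIFT}}$ the number of good parameters from the embedded
  Bayesian indirect Fourier transformation (`bift()`).

Weights are realized by scaling each dataset's errors with
$1/\sqrt{w_j}$ before an ordinary bounded least-squares fit, which
minimizes $\sum_j w_j \chi^2_j$ exactly and keeps one optimizer path for
all schemes.  Multiplying all $w_j$ by a common constant leaves the
minimizer unchanged, and for equal-size datasets the naive and reduced
schemes coincide.

The replicated benchmarks in this package (see `run_condition()` and the
acceptance script) reproduce, at a few hundred replicates, the central
finding that the naive scheme is the most accurate, followed closely by
the information-based scheme, with the reduced scheme clearly worse —
increasingly so as the size ratio between the datasets grows.

## Models

* `coreshell3`: a spherical core with three concentric shells.  The
  amplitude is the contrast-weighted sum of successive-shell differences
  of volume-weighted sphere amplitudes
  $\Phi(qR) = 3[\sin qR - qR\cos qR]/(qR)^3$, squared and normalized to
  $P(0) = 1$, so $I = aP + b$ and only contrast *ratios* relative to the
  core matter.  Shared structural parameters: the four radii; per
  dataset: three relative contrasts, scale $a$ and background $b$
  (9 parameters for one dataset, 14 for two).
* `stackedcyl3`: three coaxial cylinders of common radius stacked
  contiguously, with per-cylinder lengths and relative contrasts.  The
  coherent amplitude at orientation $\beta$ carries a complex phase
  $e^{iq\cos\beta\,d_j}$ with $d_j$ the centre-to-centre offset of
  cylinder $j$ ($d_1 = 0$); the modulus squared is averaged over
  $\beta \in [0, \pi/2]$ with the $\sin\beta$ Jacobian by fixed
  128-node Gauss–Legendre quadrature (a self-convergence test doubles
  the node count and requires agreement to $10^{-6}$).  The complex
  phase is kept because a stack with unequal lengths has no mirror
  symmetry; a real cosine form would be wrong.  Note on parameter
  counts: with all of $R, L_1, L_2, L_3$ free plus two relative
  contrasts, scale and background per dataset, this model has 8 (one
  dataset) or 12 (two dataset) parameters; the published description of
  an equivalent model quotes one fewer per configuration, which is only
  consistent with tying one length — we keep the fully general geometry.
* `mixture`: $I = s\,[f_1 I_1 + (1-f_1) I_2]$ for two tabulated
  component curves per dataset, with a shared fraction $f_1$ and a
  per-dataset scale.  A `lognormal_ratio` prior on $f_1$ places a
  log-normal prior on the component ratio $(1-f_1)/f_1$ centred on a
  50:50 mixture; its width defaults to one decade-e (sigma = 1 in log
  space) in the synthetic recovery test, a deliberately weak choice.
* A Percus–Yevick hard-sphere structure factor (`hardsphere_sq()`)
  multiplies the form factor when interparticle interference matters;
  the benchmark condition uses the outermost radius as the interaction
  radius and a volume fraction of 0.2 (the published benchmark states
  neither, so these are package defaults).
* Gaussian resolution smearing (`smear_model()`): per-point widths
  $\sigma_q$, kernel truncated at $\pm 3\sigma_q$ on a 5-nodes-per-width
  oversampled grid and renormalized over its positive-$q$ support.
  Truncation error is below $10^{-4}$ of the kernel mass; conservation
  of a flat curve and linearity are asserted by tests.

## The synthetic-data generator

`simulate_dataset()` emulates reduced experimental curves:

* Uniform $q$ grids, $q \in [10^{-3}, 0.5]\ \mathrm{\AA^{-1}}$ for the
  sphere benchmarks; 400-point SAXS-like and 50-point SANS-like curves
  by default, with $a = 0.5$ / $0.8\ \mathrm{cm^{-1}}$ and
  $b = 10^{-5}$ / $10^{-4}\ \mathrm{cm^{-1}}$.
* Point-wise errors from an empirical counting-statistics model
  (`sedlak_sigma()`): with $I_s(q) = s\,I_{\mathrm{model}}(q)/I(0)$ the
  normalized-and-scaled intensity ($I(0)$ taken at the smallest
  simulated $q$, background included),
  $$\sigma_s(q_i) = \sqrt{\frac{I_s(q_i) + \tfrac{2c}{1-c} I_s(0)}
  {k\,q_i}},$$
  converted back to the data scale via $I(0)/s$.  The $1/q$ reflects
  the growing number of detector pixels per $q$ bin, and the
  $2c/(1-c)$ term the buffer-subtraction contribution, with $c$ the
  buffer-to-sample intensity ratio.  SAXS-like data use $s = 100$,
  $c = 0.85$; SANS-like data $s = 10$, $c = 0.95$, giving SAXS the
  higher signal-to-noise ratio.  The global constant $k$ (default
  $5 \times 10^6\ \mathrm{\AA}$) was calibrated once so that the paired
  50:400 benchmark recovers the core radius with an RMS error of about
  1.5 Å — the documented accuracy regime of the benchmark — and is kept
  fixed for every condition thereafter.
* Intensities are drawn independently as
  $I_i \sim N(I_{\mathrm{model}}(q_i), \sigma_i)$; negative draws are
  kept, as appropriate for background-subtracted data.
* A `noise_factor` multiplies the variance before sampling (noise
  sweeps), and `misscale_errors()` multiplies the *reported* errors
  after sampling, so that reported uncertainties no longer reflect the
  actual fluctuations (over/under-estimated-error experiments; the mean
  squared z-score becomes $1/m^2$).
* `synth_sigma_q()` provides a synthetic stand-in for an instrumental
  resolution column: affine in $q$ (floor $10^{-4}\ \mathrm{\AA^{-1}}$,
  slope 0.05, a typical velocity-selector wavelength spread) with a
  multiplier hook for the x2/x3 severe-smearing conditions.  It is a
  smooth synthetic emulation, not an imported instrument column.

What the generator does *not* emulate: count-based (Poisson)
statistics, correlated points from data-reduction rebinning, beamstop
artefacts, or real instrument resolution kernels.  Benchmarks that pass
on these synthetic curves therefore validate the estimator logic under
idealized independent Gaussian noise, not robustness to every artefact
of real data.

## Priors and the evidence-weighted alpha scan

Truncated priors are per-parameter (`prior_set()`): Gaussian
($\mu, \sigma$, bounds $\mu \pm 5\sigma$, floored at zero for positive
quantities), uniform (bounds only; the stored width is a surrogate scale
of one tenth of the bound width used for Hessian normalization and
start perturbations), or log-normal on a fraction ratio.  The packaged
fixtures (`load_priors()`) cover the benchmark table: uniform bounds
narrowing from $\pm 5\sigma$ to $\pm \tfrac12\sigma$ and three Gaussian
sets of increasing quality.

With uniform priors the penalty is quenched at $\alpha = 10^{-10}$ —
bounded maximum likelihood with the prior means as starting values.
With Gaussian priors, 11 log-spaced $\alpha$ values are scanned; the
solution probability at each $\alpha$ is a Laplace (Gauss–Newton)
approximation

$$\log p(\alpha) = -\tfrac12 Q(\hat x) + \tfrac{K}{2}\log\alpha -
\tfrac12 \log\det\bigl(\Sigma^{1/2} A \Sigma^{1/2}\bigr) + \text{const},$$

with $A$ the Gauss–Newton Hessian of $Q/2$ (data plus prior rows) and
$\Sigma^{1/2}$ the prior-width normalization.  Probabilities are
renormalized over the scan, so constant offsets are irrelevant.  Each
parameter is reported as the probability-weighted average over the
scan.  If the evidence maximum lands on a scan boundary the whole range
shifts by half its width and the scan repeats (bounded number of
shifts).  When the prior mean already fits the data as well as any
refinement — e.g. a prior centred on the truth — the evidence
legitimately plateaus as $\alpha \to \infty$; a flat upper end is
detected and accepted rather than chased indefinitely.

Numerical choices worth knowing:

* Every $\alpha$ is fitted by bounded Levenberg–Marquardt
  (`minpack.lm::nls.lm`) on the stacked residual vector, started at the
  prior means **and** warm-started from the neighbouring stronger-prior
  solution, keeping the lower-$Q$ minimum; an ascending pass then lets a
  data-driven basin found at weak regularization propagate back.  At the
  weak-regularization anchor a small adaptive multistart (up to 24
  prior-width-scale jitters, stopping after 10 consecutive
  non-improvements) guards against prior means that sit in a poor basin
  of the likelihood — without it, a poor prior occasionally converges to
  a degenerate "homogeneous ball" solution with crossed shell radii.
* A parameter pinned at a truncation bound contributes a zero row to
  the Gauss–Newton Hessian; the evidence determinant is regularized in
  that case.
* Non-finite model values during line searches are replaced by large
  residuals so the optimizer can retreat; non-finite parameter vectors
  are never propagated.

## Information content, BIFT and degrees of freedom

`bift()` inverts $I(q) = \sum_j T_{ij} p_j$ (sine-kernel transform,
plus an optional flat background column) for the pair-distance
distribution on 100 grid points, under a second-difference smoothness
prior with weight selected by maximizing the Laplace evidence, and
non-negativity enforced by a Lawson–Hanson active-set solver (fast
settle-from-full path with a provably convergent from-empty fallback,
plus a feasible-reference safeguard carried along the $\alpha$ search).
The smoothness weight is expressed in data-normalized units ($\alpha=1$
balances prior and data curvature), making the scanned range
$10^{-3}$–$10^9$ meaningful for any error scale.  The maximum dimension
is selected by evidence over a coarse grid plus golden-section
refinement; the *reported* `dmax` is where the reconstructed $p(r)$ has
decayed to zero, since the evidence-selected grid envelope can extend
beyond the particle without penalty.  The number of good parameters
$N_{g,\mathrm{BIFT}} = \mathrm{tr}(A^{-1} T^{\mathsf T} W T)$ counts the
eigendirections the data actually determine and decreases as the noise
grows; it feeds the information weighting scheme (recomputed per
replicate by default) and falls back to Shannon channels
($N_s = (q_{\max}-q_{\min})D_{\max}/\pi$) when BIFT flags a boundary
solution.

For model fits, `numeric_hessian()` builds the chi-square Hessian by
one-sided forward differences (mirroring the reference convention; a
central-difference cross-check is in the test suite),
`ng_from_hessian()` counts $N_g = \sum_k \lambda_k/(\lambda_k+\alpha)$
over the prior-normalized eigenspectrum, and `dof_partition()`
distributes the joint-fit $N_g$ across datasets in proportion to their
stand-alone upper limits so the parts sum to the total exactly, giving
per-dataset degrees of freedom $M_j - N_{g,j}$ and reduced chi-squares
that centre on one for correct-model fits.

## The evaluation framework

`run_condition()` repeats simulate-and-refit `n_rep` times (all fitting
modes see the same simulated data within a replicate, as in the source
benchmark), collects the refined structural parameters, and condenses
them into the RMS deviation from truth
$\Delta x = [\sum_r (x_r - x_{\mathrm{true}})^2/n_{\mathrm{rep}}]^{1/2}$
(denominator $n_{\mathrm{rep}}$, since the truth is known) and the
average relative deviation $\overline{\Delta x/|x_{\mathrm{true}}|}$ in
percent over the structural parameters only (radii for the
core-multishell model; nuisance contrasts, scales and backgrounds are
excluded).  A percentile bootstrap over replicates gives 99 percent
intervals.  Replicate seeds are derived deterministically from the base
seed, the replicate index and a hash of the condition label, so any
grid cell can be reproduced in isolation.

The package's standard problem sizes are a few hundred replicates per
condition (200–500 in the acceptance script, less in the unit tests)
against 50000 in the full-scale study; at that scale the bootstrap 99
percent intervals on the average relative deviation are a few tenths of
a percentage point, which is the resolution at which the published
averages can be reproduced.  Full-scale runs are a matter of raising
`n_rep`.

## Known limitations

* The error-model constant $k$ is a single global calibration; the
  relative SAXS:SANS noise balance is fixed by $s$ and $c$ alone.  The
  accuracy of single-dataset refinements of weakly identified
  parameters (the core radius from SAXS alone) is sensitive to this
  balance and to optimizer behaviour at truncation bounds, and is the
  least faithfully reproduced quantity at desk scale.
* The evidence plateau for truth-centred priors means the best-prior
  benchmark collapses almost entirely onto the prior, slightly
  exaggerating the (real) advantage of good Gaussian priors.
* BIFT assumes unsmeared curves; resolution effects are handled in the
  model fit, not in the inversion.
* The stacked-cylinder model is validated by oracles and reductions but
  not benchmarked at full replication; the raspberry-surface condition
  of the source study is out of scope (its geometry is unspecified).

## A worked example

```{r example, eval = FALSE}
m <- sas_model("coreshell3")
truth <- truth_coreshell()
curves <- list(
  simulate_dataset(m, truth, 1, make_qgrid(1e-3, 0.5, 400),
                   noise_spec("saxs"), seed = 11, label = "SAXS"),
  simulate_dataset(m, truth, 2, make_qgrid(1e-3, 0.5, 50),
                   noise_spec("sans"), seed = 12, label = "SANS"))
fit <- corefit(curves, m, load_priors("Uniform_5s"), scheme = "naive")
summary(fit)
plot(fit)

# benchmark a weighting scheme
ev <- run_condition(cond_coreshell(), modes = c("naive", "reduced"),
                    n_rep = 100, seed = 1)
ev
```
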