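# corefit

Simultaneous Bayesian co-refinement of small-angle scattering (SAXS /
SANS) curves, with benchmarked dataset-weighting schemes and
truncated-Gaussian priors.

## The problem

A single small-angle scattering curve rarely determines a
multi-parameter structural model; curves measured under complementary
contrast conditions (synchrotron SAXS plus SANS with selective
match-out, or several SANS contrasts) constrain different parts of the
structure and are best refined *together*.  That raises two practical
questions this package addresses quantitatively:

1. **How should each dataset be weighted?**  `corefit` minimizes
   `Q = sum_j w_j * chi2_j + alpha * S` with three selectable schemes:
   naive (`w_j = 1`), reduced (`w_j = 1/M_j`), and information-based
   (`w_j = N_g,BIFT,j / M_j`, using the number of good parameters from
   an embedded Bayesian indirect Fourier transformation).  Replicated
   simulate-and-refit benchmarks with known ground truth show the naive
   scheme recovers structural parameters most accurately, with the
   information scheme a close second and the reduced scheme clearly
   worse — increasingly so for unequal dataset sizes.
2. **Do Gaussian priors beat plain parameter bounds?**  `S` is a
   truncated-Gaussian penalty whose weight `alpha` is selected by
   scanning 11 log-spaced values and weighting each solution by its
   Laplace-approximation evidence; refined parameters are
   probability-weighted averages over the scan.  Even mediocre Gaussian
   priors recover the weakly determined parameters better than uniform
   bounds of any width.

The package bundles: core–multishell and stacked-cylinder form factors,
a Percus–Yevick hard-sphere structure factor, Gaussian resolution
smearing, a two-component mixture model with a log-normal stoichiometry
prior, a synthetic-data generator with an empirical counting-statistics
error model, an embedded BIFT (`p(r)`, Dmax, information content), DOF
partitioning for per-dataset reduced chi-squares, and the replicated
evaluation framework (RMS parameter deviations, bootstrap intervals,
error-misscaling and prior-quality sweeps).

## Worked example

```r
library(corefit)

m     <- sas_model("coreshell3")        # core + 3 shells, radii 10/30/50/70 A
truth <- truth_coreshell()              # benchmark ground truth
curves <- list(
  simulate_dataset(m, truth, 1, make_qgrid(1e-3, 0.5, 400),
                   noise_spec("saxs"), seed = 11, label = "SAXS"),
  simulate_dataset(m, truth, 2, make_qgrid(1e-3, 0.5, 50),
                   noise_spec("sans"), seed = 12, label = "SANS"))

fit <- corefit(curves, m, load_priors("Uniform_5s"), scheme = "naive")
print(fit)
#> Simultaneous refinement: model 'coreshell3', 2 dataset(s), scheme 'naive'
#> Priors: uniform (bounds only, alpha quenched at 1e-10)
#> Coefficients (probability-averaged):
#>      R_c      R_1      R_2      R_3   rho1.1   rho2.1   rho3.1      a.1
#>  9.42535 35.20062 41.25304 70.40282  1.82856  3.02323  3.95186  0.50549
#>      b.1   rho1.2   rho2.2   rho3.2      a.2      b.2
#>  0.00010 -0.08367  0.13636  0.02500  0.90000 -0.00899
#> chi2 per dataset: 373.3, 53.6  (M: 400, 50)
```

The four radii (true values 10/30/50/70 Å) are recovered within the
scatter expected for one noisy replicate; the per-dataset chi-squares
sit near their point counts (400 and 50), i.e. the model fits to within
the simulated errors.  `summary(fit)` adds standard errors, the number
of good parameters, the information-based DOF partition and per-dataset
reduced chi-squares; `plot(fit)` overlays data and fits with a
normalized-residual panel.

Benchmarking a weighting scheme is one call:

```r
ev <- run_condition(cond_coreshell(M_saxs = 400, M_sans = 50),
                    modes = c("naive", "reduced"), n_rep = 100, seed = 1)
ev
#> <sas_eval 'coreshell_400:50', n_rep = 100>
#>   naive        avg rel dev =  5.77%  (99% CI [5.27, 6.37], n = 100)
#>   reduced      avg rel dev =  6.55%  (99% CI [5.91, 7.27], n = 100)
```

(Average relative deviation of the refined radii from truth, in
percent; lower is better.)

Other entry points: `bift()` (pair-distance distribution, Dmax and
information content of one curve), `misscale_sweep()` (effect of over-
or under-estimated errors), `prior_sweep()` (uniform vs Gaussian prior
quality), and a thin command-line wrapper (`inst/exec/corefit`,
subcommands `simulate | fit | bift | evaluate`, YAML run configs via
`read_config()`).

The methods vignette (`vignettes/corefinement-methods.Rmd`) documents
the model formulas, the empirical noise model and its calibration, the
evidence machinery, numerical safeguards, and known limitations.

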