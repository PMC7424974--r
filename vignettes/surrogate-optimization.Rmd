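---
title: "Surrogate modeling and multi-objective optimization of somatic embryogenesis media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate modeling and multi-objective optimization of somatic embryogenesis media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seoptim)
```

## The problem

Somatic embryogenesis — the formation of embryo-like structures from ordinary
plant tissue in vitro — is the gateway step for chrysanthemum transformation
and regeneration work, and its efficiency depends strongly on the
concentrations of plant growth regulators in the medium. `seoptim` implements
a complete surrogate-modeling workflow for a three-factor design: the auxin
2,4-D, the cytokinin kinetin (KIN) and the nitric-oxide donor sodium
nitroprusside (SNP), each applied at four levels (a 4 x 4 x 4 factorial, 64
treatments, 9 replicates per treatment), with three responses per replicate:
callogenesis rate (%), embryogenesis rate (%) and the number of somatic
embryos per explant.

The workflow is: reconstruct replicate-level data from the published
treatment summaries, fit two regression surrogates (epsilon-SVR and a small
neural network) to predict each response from the three concentrations,
compare them, rank the inputs by a remove-and-retrain sensitivity measure,
and finally search the concentration space with the elitist multi-objective
genetic algorithm NSGA-II, using the fitted SVR surfaces as objectives and an
ideal-point rule to reduce the Pareto front to a single recommended medium.

## Data: the bundled fixture and replicate reconstruction

The packaged treatment table carries, for each of the 64 regulator
combinations, the mean and standard error (n = 9) of the three responses.
Only these summaries are published, so the replicate-level records the models
are fitted to are *reconstructed*: for each treatment and response we draw 9
standard-normal values, affinely standardize them so the sample mean equals
the printed mean and the sample standard error equals the printed SE exactly,
and then clip rates into [0, 100] and counts to be non-negative.

Clipping is the one place this construction can fail: when `mean + 2 * SE`
crosses a bound (e.g. a callogenesis mean of 93.33 with SE 3.33), no set of 9
in-range values can match both moments, and the achieved deviation is logged
on the returned table (attribute `clip_deviations`) and summarized in a
warning rather than silently repaired — a re-projection would have to trade
off the two moments arbitrarily. Roughly 40 of the 192 treatment/response
cells are affected, with mean deviations of a few percentage points at most;
all acceptance-bearing quantities tolerate this.

Embryo counts are treated as continuous: the printed means (57.80, 31.71,
...) are not integers, and the downstream models are regressions, not count
models.

```{r fixture}
treatments <- load_fixture()
replicates <- suppressWarnings(expand_replicates(treatments, n_reps = 9, seed = 1))
nrow(replicates)
```

### The synthetic generator

For parameter-recovery tests the package also generates data from a known
smooth surface: each response is a Gaussian peak
`height * exp(-sum(((x - peak) / width)^2))` over the factorial design, plus
optional Gaussian noise, clipped to the valid range. Defaults mirror the real
experiment: the same factor levels and replicate count, a peak at the
observed optimum region (9.09, 4.65, 20) uM, peak heights equal to the best
observed responses (100%, 100%, 57.8 embryos), and noise standard deviations
(5%, 5%, 1 embryo) of the same order as the printed standard errors. What
this generator deliberately does *not* emulate: the on/off interaction
structure of the real data (no callus without auxin), within-treatment
moment constraints, and clipping pile-ups at 0 and 100. Recovery tests
therefore demonstrate correctness of the machinery on a well-posed smooth
truth, not fidelity to tissue-culture biology.

## Preprocessing

Inputs and targets are min-max scaled to [0, 1]; scalers are fitted on the
training partition only and predictions are mapped back to natural units
before any metric is computed, so reported RMSE and MAE are in percent (or
embryos per explant). Splitting is plain row-level random sampling. The
default training fraction is 0.75, which reproduces the documented partition
sizes n = 432 / 144 on the 576-row table; a 70/30 split (403/173) is
available through the same argument since both conventions appear in the
study this design follows. Replicates of one treatment may land in both
partitions — the split is at the level of data lines, not treatments — so
the test set measures interpolation quality at known treatments, not
generalization to new media.

## The epsilon-SVR surrogate

The core model is epsilon-insensitive support vector regression with the
Gaussian kernel `k(x, z) = exp(-gamma ||x - z||^2)`. Training solves the
dual quadratic program

```
max  sum_i t_i (a_i - a*_i) - eps sum_i (a_i + a*_i)
     - 1/2 sum_ij (a_i - a*_i)(a_j - a*_j) k(x_i, x_j)
s.t. sum_i (a_i - a*_i) = 0,   0 <= a_i, a*_i <= C
```

and predicts with the kernel expansion
`y(x) = sum_i (a_i - a*_i) k(x, x_i) + b`. The solver is a sequential
minimal optimization (SMO) written for this package: each iteration pairs
the maximal KKT violator with a partner chosen by second-order gain
(violation^2 / curvature), with libsvm-style shrinking of clearly
non-violating bound points and a full re-check of the whole problem before
convergence is declared. The bias is averaged over the KKT equalities of
free support vectors, falling back to the midpoint of the feasible interval
(with a warning) when no free vector exists. `C` follows the conventional
parameterization in which it multiplies the summed epsilon-insensitive loss;
a published formulation with a 1/n factor inside the loss differs only by
rescaling `C`.

Numerical choices worth knowing:

* The default termination tolerance on the duality violation is `1e-3`, the
  customary SMO stopping criterion (libsvm, e1071, kernlab use the same
  default). A much tighter default is counterproductive here because one
  corner of the hyperparameter grid (small `gamma`, large `C`) yields an
  almost flat kernel whose dual is so ill-conditioned that reaching `1e-6`
  takes tens of millions of iterations; at `1e-3` the fitted function is
  already converged to far below any reported digit. Everything that needs
  high-precision dual coefficients (the KKT and QP-oracle checks in the test
  suite) passes an explicit `tol` of `1e-7`–`1e-9`, which the solver honours.
* Cross-validation fits inside the grid search use the same `1e-3` tolerance
  plus an iteration cap (`cv_max_iter = 15000`); only the degenerate corners
  of the grid ever hit the cap, and the selected model is always refitted at
  full tolerance on the whole training partition.

Hyperparameters are not published for the original study, so they are tuned
by exhaustive 5-fold cross-validation over a coarse log-grid:
`C` in {1, 10, 100, 1000}, `epsilon` in {0.001, 0.01, 0.05, 0.1} (scaled
target units), `gamma` in {0.1, 0.5, 1, 2, 5}. The score is the mean
per-fold RMSE in natural units; ties break toward smaller `C`, then larger
`epsilon`, then smaller `gamma` (the smoother model). One independent model
is fitted per response.

```{r svr, eval = FALSE}
split <- split_data(replicates, 0.75, seed = 2)
tuned <- tune_svr(split$train, "emb", grid = svr_grid(seed = 3))
model <- train_svr(split$train, "emb", C = tuned$C,
                   epsilon = tuned$epsilon, gamma = tuned$gamma)
evaluate_model(model, split$test)
```

## The MLP comparison model

The baseline competitor is a three-layer feed-forward perceptron (tanh
hidden layer, identity output) trained by Levenberg-Marquardt on the
sum-of-squared-error objective: damped Gauss-Newton steps
`delta = (J'J + mu I)^{-1} J' e` with an analytic backpropagation Jacobian,
`mu` divided by 10 on accepted steps and multiplied by 10 on rejected ones.
Training stops on the epoch budget (1000), a vanishing gradient (1e-7),
exhausted damping, or 12 consecutive accepted steps without improvement on a
15% validation hold-out; the best-validation weights are returned. Weights
initialize uniformly in [-0.5, 0.5] scaled by fan-in, from the run seed.
The hidden-layer size is selected from {3, 5, 8, 12, 15} by validation RMSE
(the original study reports only the algorithm family, so these are
conventional defaults), then the chosen size is refitted on the full
training partition.

## Metrics

Models are compared by R-squared, RMSE and MAE in natural units. R-squared
is implemented as the squared Pearson correlation between observed and
predicted values: the printed formula it follows is typographically garbled
(its denominator drops the squares), and the squared correlation is the
standard statistic with the intended properties (in [0, 1], equal to 1 iff
the relationship is exactly affine). Note that a squared correlation is
invariant under affine miscalibration of the predictions; RMSE and MAE are
not, which is why all three are reported.

## Sensitivity analysis

Input importance is measured by remove-and-retrain: the baseline model
(tuned and fitted on all 576 rows, evaluated by RMSE on those same rows) is
compared with a model re-tuned from scratch without one input. The variable
sensitivity error (VSE) is the reduced model's RMSE; the variable
sensitivity ratio (VSR) is VSE / baseline RMSE; inputs are ranked by
descending VSR. "Removed" means genuinely retrained without the column —
the alternative of zeroing an input of the full model is available as
`mode = "zero"` for comparison, but retraining is the faithful reading of
removing a variable *from the model*. Because the ratio compares two fitted
RMSEs, it is only well-behaved when the baseline error is not vanishingly
small; on noiseless synthetic data the package's tests therefore check
VSR ~ 1 for irrelevant inputs rather than exact values.

On the real dataset the package reproduces 2,4-D as by far the most
important regulator for all three responses, and KIN > SNP for callogenesis.
For embryogenesis rate and embryo number it ranks KIN above SNP, whereas the
original report lists SNP second; the underlying published ratios for embryo
number (100.33 vs 99.04 vs 98.93) differ only in their second decimal and
are hard to reconcile with a ratio-of-RMSEs definition at all, so the
leading rank — not the KIN/SNP order — is the robust, reproducible part of
this analysis. Mechanistically the retrained models behave sensibly: with
KIN removed the model cannot represent the fact that no embryogenesis occurs
without cytokinin, which costs more accuracy than removing SNP's modulating
effect.

## Optimization

The optimizer is a real-coded elitist NSGA-II maximizing the two
embryogenesis objectives (predicted embryogenesis rate and predicted embryo
count) over the experimental box (2,4-D in [0, 13.63], KIN in [0, 13.94],
SNP in [0, 40] uM — surrogates are not trusted outside the region they were
fitted on). Defaults follow the study conditions: population 200, 1000
generations, crossover rate 0.7, mutation rate 0.5, and roulette-wheel
parent selection over the fitness `1 / (1 + front rank)`; the canonical
crowded binary tournament is available via configuration. Variation uses
the de-facto real-coded operators, simulated binary crossover and polynomial
mutation, both with distribution index 20. Survival is the standard
parent+child reduction by front rank, then crowding distance. The surrogates
handed to the optimizer are refitted on all 576 rows with the tuned
hyperparameters (the train-only variant is a configuration switch): the
optimization stage is a search over the model, and withholding a quarter of
the data would only degrade the surface it searches.

The Pareto front is reduced to one recommendation by the ideal-point rule:
Euclidean distance, in raw mixed units (% and embryos), to the point
combining the best *observed* embryogenesis rate and embryo count (100,
57.8); the front member at minimal distance is the recommended medium, with
ties broken toward lower 2,4-D. During the search the objectives are the raw
(unclipped) SVR predictions — clipping would flatten selection gradients at
the boundary — and only the reported optimum is clipped to the physical
range.

### A known limitation of the recovered optimum

With the cross-validation-selected kernel widths, the embryo-count RBF
surface slightly overshoots between design points: it is faithful at the
treatments themselves (57.7 predicted at the best observed treatment) but
interpolates a bump of about 66 embryos near (9.4, 5.0, 27) uM, between the
SNP levels 20 and 40. The whole Pareto front then lies beyond the observed
ideal point, and the ideal-point rule selects a medium at SNP ~ 27 uM with a
predicted count well above anything observed, where the original study
reports (9.10, 4.70, 18.73) uM predicting (99.09%, 56.23). The published
surrogate's hyperparameters are unknown and evidently produced a flatter
interpolant. The package reports what its own tuned model implies rather
than steering the tuning toward the published coordinates; the predicted
embryogenesis rate at the selected optimum (the headline claim) is
reproduced, while the embryo-count coordinate of the optimum is not — an
overshoot of the same kind any near-interpolating RBF fit of these 64 cell
means can produce.

## The full study and reproducibility

`run_study()` chains every stage — expansion, split, per-response SVR and
MLP tuning, the metrics table, per-response sensitivity, surrogate refit,
NSGA-II and ideal-point selection — and derives every stage's seed from one
master seed, so a report is reproducible end to end. Problem sizes used by
the test suite are scaled to what the checks need: recovery tests run the
generator at its default 576 rows but smaller populations and generation
counts where only correctness (not convergence quality) is at stake; the
headline optimization checks run the full population 200 x 1000 generations.

The package's functions are the interface: `run_study()` plus the stage
functions cover everything a script would, and `scripts/acceptance.R` in the
source repository is a worked command-line example that recomputes the
study's headline numbers from scratch.

## Known limitations

* Replicate reconstruction matches first and second moments only; any
  higher-moment structure of the raw data is unknowable from the published
  summaries, and clipped cells cannot match even those exactly (logged).
* Rates are modeled as continuous percentages; the underlying five-explant
  binomial structure is not modeled.
* The test partition contains replicates of training treatments, so test
  metrics measure within-design interpolation.
* The KIN/SNP sensitivity order for the embryogenesis responses, and the
  embryo-count coordinate of the selected optimum, are not reproduced (see
  above); both trace to surrogate freedom the published summaries cannot
  constrain.
* A carefully trained MLP is very nearly as accurate as the SVR on this
  dataset: on 5-seed medians the SVR wins most, but not all, of the 18
  (response x partition x metric) comparison cells, with the remaining cells
  statistical ties. A blanket "SVR dominates everywhere" should not be
  expected from these data when both model families are tuned with equal
  care.
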