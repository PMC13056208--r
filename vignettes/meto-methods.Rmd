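---
title: "Hybrid exponential-trigonometric feature selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid exponential-trigonometric feature selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metoselect)
```

# The problem

Resting-state fMRI classification studies of autism spectrum disorder (ASD)
typically reduce each subject's scan to a vector of functional-connectivity
(FC) values — Pearson correlations between the mean time series of every
pair of atlas regions — and then face a feature-selection problem: of the
thousands of connectivity values (19,900 for a 200-region parcellation),
which small subset actually discriminates patients from typical controls?
`metoselect` implements a complete desk-scale version of such a pipeline:

1. **Feature extraction**: Pearson FC, strict-upper-triangle vectorization,
   a Fisher-criterion filter keeping the top 15% of features, and a stacked
   sparse denoising autoencoder (SSDAE) whose encoders initialize a
   supervised MLP; the last hidden layer (100 units at full scale) is the
   learned representation.
2. **Wrapper feature selection**: a binary mask over the learned features is
   searched by the METO hybrid metaheuristic, scoring each mask by the
   validation error of a K-nearest-neighbour classifier.
3. **Evaluation**: accuracy, sensitivity, precision, F-score and rank-based
   AUC on a held-out test split, aggregated over independent runs.

Because the real cohort is an external download, the package ships seeded
generators that emulate both stages' inputs with recoverable ground truth.

# The optimizers

All three optimizers minimize an objective over a box `[LB, UB]^D` with a
population of `N` candidate solutions, elitist tracking of the best-so-far
solution `xb` (never replaced by a worse one), and clipping of every update
to the box. Ties for best and second-best always resolve to the lowest row
index, which makes runs bit-reproducible under a fixed seed.

## Exponential-Trigonometric Optimization (ETO)

ETO drives its moves through coefficients built from exponential and
trigonometric functions of the iteration count `t`:

* a symmetric shape pair
  `d1 = 0.1 cos(0.5 tmax (1 - t/tmax)) exp(-0.01 t)`, `d2 = -d1`. Their
  ratio is `-1` wherever defined and `0/0` at cosine zeros, so the package
  uses the guarded constant `-1` everywhere it appears
  (`tan(d1/d2) = tan(-1)`, `exp(|d1/d2| - 1.3) = exp(-0.3)`, and the
  diversity constant `c = exp(tan(-1)) = 0.21068`). This keeps every
  coefficient continuous and is exactly what the printed formulas imply.
* a changeover value `CM = 0.01 u (t/tmax)^tan(-1)` (`u` uniform) choosing
  between the two variants of each phase (`CM > 1`: variant 1), and the
  switch iteration `T = floor(1.2 + tmax/2.25)` separating exploration
  (`t <= T`) from exploitation.
* a constrained-exploration (CE) schedule whose first event is
  `floor(1 + tmax/1.55)`; at an event the sampling bounds contract around
  the best and second-best solutions. The printed recurrence for later
  events grows explosively, so at most one event normally fires; events
  that would invert the bounds (`LB > UB` in any dimension) are skipped.
  Feasibility clipping always uses the original box.

The four position updates move a solution either around the best solution
(`xb ± coeff · |xb - xi|`, phase-1 operators) or from its own position
(phase-2 operators). A property worth knowing: since
`CM <= 0.01 u (t/tmax)^{-1.557}`, the `CM > 1` branch can only be drawn
while `t/tmax` is below about 0.055. The phase-1 contractions therefore act
only in the opening iterations; afterwards exploration is an undirected
walk and exploitation a one-sided drift, and refinement relies on elitism
and (in the hybrid) on the guided-learning moves. The sphere benchmark in
`scripts/acceptance.R` quantifies the practical consequence: final
precision on a 10-dimensional sphere is of order 1, not of order machine
epsilon as for gradient-like heuristics. We implement the equations as
printed rather than substituting the original ETO reference behaviour.

## Arithmetic Optimization Algorithm (AOA)

AOA schedules its phase by the accelerated function
`MOA(t) = Min + t (Max - Min)/tmax` (defaults `0.2`/`0.9`, exposed in
`aoa_params()`) and scales its moves by the math-optimizer probability
`MOP(t) = 1 - (t/tmax)^{1/alpha}` with `alpha = 5`. Exploration applies,
per dimension, Division `xb/(MOP + eps) * scale` or Multiplication
`xb * MOP * scale`; exploitation applies Subtraction/Addition
`xb ∓ MOP ((UB - LB) mu + LB)` with `mu = 0.5`. Two faithful-but-awkward
details are kept deliberately:

* the exploration scale is printed without `mu` (`(UB - LB) + LB`); the
  canonical AOA scale can be restored with
  `aoa_params(mu_in_exploration = TRUE)`;
* `eps` is implemented as `1e-12` — a literal "small integer" would defeat
  its divide-by-zero purpose;
* on a symmetric box the exploitation step `(UB - LB) mu + LB` is exactly
  zero at `mu = 0.5`, so pure AOA refines through exploration only. On the
  `[0, 1]` feature-selection box the step is `MOP/2`, which is well-behaved.

The algorithm text and the update equations disagree about which side of
the `r2`/`r3` draws selects Division vs Multiplication and Subtraction vs
Addition; the equations (`r2 < 0.5` Division, `r3 < 0.5` Subtraction) are
authoritative here.

## Guided Learning Strategy (GLS)

Every iteration's population is appended to an experience buffer. Once the
experience counter exceeds `Cmax` (default `10 N`), the dispersion
`V0 = mean_j( sd_j * 200/(UB_j - LB_j) )` of the stored positions — a
population (1/n) standard deviation per dimension, normalized so the value
is box-scale free — decides the guidance move: heavy-tailed exploitation
around the best solution, `xb + tan(R pi)(UB - LB)/V0`, when `V0` exceeds
the threshold `alpha` (default 1), else a uniform restart over the box.
Draws with `|R - 0.5| < 1e-9` are redrawn to avoid the tangent pole. The
guided population is merged greedily (per row, keep the better), so
guidance can never worsen a solution, and the buffer is cleared. The
printed exploration branch `R (UB - LB)` is generalized to
`LB + R (UB - LB)` so non-zero lower bounds remain inside the box; on the
`[0, 1]` selection box the two coincide.

## The METO hybrid

METO keeps ETO's bookkeeping and injects AOA operators
fitness-proportionally: shares `P_i = Fit_i / sum(Fit)` and a threshold
`rp = min(P) + u (max(P) - min(P))` are computed each iteration, and any
solution with `P_i < rp` takes the AOA operator for the current phase
instead of the ETO one. Because the fitness is a minimized cost, *better*
solutions have smaller shares and are more likely to take the AOA branch —
implemented as printed, not "corrected". The phase ranges cited for the
ETO side are resolved the only way consistent with the base algorithm: the
changeover value picks the phase-1 or phase-2 variant. Guidance is
attempted whenever `t mod 10 = 0` (`gls_period`), subject to the
experience gate. Two degenerate modes are exact by construction and tested
bit-for-bit: `rp_override = -Inf` reduces METO to ETO, `rp_override = Inf`
makes every update an AOA move.

## Draw-order contract

Reproducibility and the oracle tests rest on a fixed order of uniform
draws, documented in `meto_run()`: per iteration — changeover value (1),
CE event (4: the `(r1, r2)` pair for the upper bound, then for the lower),
selection threshold (1), the phase coefficient shared by all solutions
(1 draw, or 2 for `alpha2`), then per solution in row order its branch
draws followed by one length-`D` element vector; a firing guidance event
consumes an `N x D` column-major matrix plus redraws. The test suite
replays the identical sequence through an independent straight-line
implementation and requires agreement below `1e-12`.

# Wrapper feature selection

The optimizer searches `[0, 1]^D`; a position becomes a mask by
thresholding at 0.5. The printed binarization rule is a coin flip
independent of the position, which would sever the feedback loop between
fitness and search; it is available as
`fs_config(binarization = "literal-random")` for fidelity experiments, but
the threshold rule is the default because it is the only reading under
which the search can respond to the objective. All-zero masks are repaired
by forcing the largest-position coordinate on, keeping the fitness defined
and the search smooth.

The fitness is `rho * gamma + (1 - rho) * |mask|/D` with `rho = 0.99`
(error dominates; configurable) and `gamma` the misclassification rate of
a `K = 5` nearest-neighbour classifier trained on the training split and
scored on the validation split; the test split is touched exactly once, by
the final mask. The KNN is deliberately deterministic: Euclidean
distances, neighbour ties broken by training-row index, and a strict
majority required for a positive call (vote ties, impossible at odd `K`,
would fall to the negative class). Its score — the positive fraction among
the `K` neighbours — is the only calibration-free score a KNN offers and
feeds the rank-based (Mann-Whitney, ties at 1/2) AUC.

Experiments aggregate each metric over seeds into mean, population-`sd`
(1/n convention throughout), best and worst; for feature counts, best is
the minimum.

# Synthetic data

`gen_feature_dataset()` emulates the learned representation entering the
selector: independent Gaussian features, the first `d_inf` of them shifted
by `delta` within-class standard deviations in the positive class. The
study conditions used by the tests and the acceptance script are
`n = 600`, `D = 100`, 10 informative features at `delta = 1`, balanced
classes, and a stratified 0.602/0.298/0.100 split — the fractions that
reproduce a 623/308/104 partition of a 1,035-subject cohort under
largest-remainder rounding. `gen_roi_timeseries()` plants a between-class
correlation difference on one ROI pair so the FC stack has a recoverable
signal. What these generators deliberately omit — site effects, scanner
drift, motion artifacts, correlated noise, heterogeneous effect sizes —
bounds what passing tests show: the machinery is correct and can recover
planted structure, not that any particular clinical accuracy transfers to
real cohorts. An equicorrelated variant can be emulated by post-mixing the
generated features if redundancy stress-testing is needed.

# The feature-learning stack

The SSDAE is two greedily trained denoising autoencoders (sigmoid
encoders, linear decoders, mean-squared reconstruction loss) with masking
noise at fraction 0.2, a KL sparsity penalty pulling mean activations
toward 0.05 with weight `1e-3`, dropout 0.5, learning rate `1e-3`,
mini-batches of 100, and 700/1000 epochs at full scale. The MLP stacks the
two pre-trained encoders, a final hidden layer (100 units at full scale)
and a sigmoid output trained by stochastic gradient descent on the
cross-entropy (learning rate `5e-4`, batches of 10, dropout 0.3; the
supervised epoch count is not pinned by the pipeline description and
defaults to 100). "Iterations" are read as epochs over the training split.
All sizes are configuration-driven; the test suite exercises scaled stacks
(inputs of tens of features, encoders of 5-40 units, 5-300 epochs) so the
whole pipeline runs end-to-end in seconds, and the full-scale defaults are
documented rather than executed in tests. The Fisher filter uses the
standard two-class criterion
`[(m1 - m)^2 + (m0 - m)^2] / (v1 + v0)` (class sample variances, zero
denominators scoring 0) computed on the training split only, with a floor
retention rule: 15% of 6,670 retains exactly 1,000 features; 15% of
19,900 retains 2,985.

# Numerical and design notes

* Minimization convention throughout; the selection fitness is a cost in
  `[0, 1]`.
* One master seed per run; independent child streams are derived per run
  index, and streams never touch the session RNG. A `fixed_rng()` stub
  replays injected sequences for oracle tests.
* The sphere benchmark uses the classic De Jong domain
  `[-5.12, 5.12]^10`.
* Zero-variance time series produce 0 correlations (flagged);
  zero-denominator classification ratios report 0 with a warning rather
  than aborting a sweep.
* CE-adapted bounds feed the AOA donor operators inside METO (the only
  update rules that read the box); GLS normalization and final clipping
  use the original box.
* Problem sizes in the test suite (populations of 4-20, budgets of 1-300
  iterations, feature tables up to 600 x 100) are chosen so the whole
  suite completes in a couple of minutes while still running every branch
  of every operator at least once.

# Known limitations

* The printed update rules give modest numerical precision on smooth
  benchmarks (see the ETO section); this package documents rather than
  repairs that behaviour, and the plugin registry
  (`register_optimizer()`) is the intended seam for comparing stronger
  optimizers.
* Binary labels only; the fixed three-way split is the only protocol.
* The networks are plain matrix-algebra implementations intended for the
  documented architecture sizes, not a general deep-learning framework;
  there is no GPU path.
* Comparison metaheuristics from the surrounding literature (HHO, WOA,
  and relatives) are not implemented; the registry accepts them as
  plugins.
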