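---
title: "Joint inference of mutation rate and landscape geometry from fitness decline and rebound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint inference of mutation rate and landscape geometry from fitness decline and rebound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmabc)
```

## The model

`fgmabc` treats two complementary evolution experiments in a mutator
*Escherichia coli* as draws from one generative model: Fisher's geometric
model (FGM) of a single-peaked phenotypic fitness landscape, run under the
demography of each experiment.

An individual is a vector of `n` phenotypic trait values
`x = (x1, ..., xn)`; the optimum is the origin and fitness is Gaussian in
the distance to it,

    w(x) = exp(-sum(xi^2)).

A mutation displaces every trait by an independent draw from
`N(0, sigma^2)` (full pleiotropy), and mutations arrive in each individual
as a Poisson process with rate `U` per generation. The selection
coefficient of a mutation with displacement `d` on background `x` is its
per-generation log-fitness change,

    s = log w(x + d) - log w(x) = -2 x.d - |d|^2.

Two consequences anchor everything else:

* the mean effect of a random mutation is `E[s] = -n sigma^2` on **every**
  background (the cross term has mean zero), so the mean does not reveal
  epistasis;
* the distribution around that mean widens with the distance to the peak:
  on a degraded background a sizeable fraction of mutations point back
  uphill (compensatory), and the variance of `s` grows. Pairwise epistasis
  `eps = -2 d1.d2` is symmetric around zero.

With the exponent scaled as `exp(-|x|^2)` (rather than `exp(-|x|^2 / 2)`)
and `s` defined as a log-fitness change, `E[s] = -n sigma^2` holds exactly;
this is the convention adopted throughout, and fitness is manipulated in
log space internally so that backgrounds far from the peak never underflow.

The three parameters are collected as `theta = (U, n, sigma)` and estimated
jointly by rejection-sampling approximate Bayesian computation (ABC) from a
39-statistic summary of the two experiments.

## The two demographies

**Mutation accumulation (MA).** Fifty lines descend from a founder at the
optimum through 50 cycles of single-cell bottleneck followed by 23
generations of doubling regrowth. Drift is intense: the effective size of a
cycle is taken as `Ne = 23`, the conventional harmonic-mean size for
periodic one-cell bottlenecks with doubling growth. Fitness of the
bottlenecked founder is recorded every 10 cycles. Two engines implement
this demography:

* `engine = "exact"` simulates every generation of the growth phase on
  genotype classes: offspring are assigned multinomially with weights
  (class count) x (class fitness), mutations arise Poisson(`U` x
  population size) per generation each founding a size-1 class, and the
  crash samples one cell uniformly. Its cost is exponential in the cycle
  length, so it is used at reduced cycle lengths (e.g. 10 generations) as
  the ground truth.
* `engine = "fast"` follows only the lineage that survives the crashes.
  Candidate mutations arrive at rate `U` per generation of the cycle and
  each is retained with probability `min(1, Ne * p_surv(s, Ne))`, where
  `p_surv` is Kimura's fixation probability
  `(1 - exp(-2 s)) / (1 - exp(-2 Ne s))`. Neutral candidates are always
  retained (the rate of neutral fixation equals the mutation rate), and
  the filter tilts retention toward mild and beneficial effects exactly as
  bottleneck survival does. The two engines agree on the mean and variance
  of the per-cycle log-fitness change within Monte-Carlo error (tested at
  cycle length 10 over 2000 independent cycles).

With selection switched off (`selection_on = FALSE`) every candidate is
retained and the log-fitness decline has the closed form
`E[log W] = -U T n sigma^2` after `T` generations, which the test suite
verifies against simulation.

**Fitness recovery.** Founders constructed at fitness `W0` (phenotype
`(sqrt(-log W0), 0, ..., 0)`, without loss of generality by isotropy)
evolve for 240 generations at constant `Ne = 3e5` and mean fitness is
recorded at generations 120 and 240. The exact engine is a genotype-class
Wright-Fisher simulation; clonal interference is emergent, never
approximated. Because rejection ABC needs tens of thousands of these runs,
a fast engine trades the multinomial resampling for:

* deterministic frequency dynamics `f <- f w / wbar` for established
  classes;
* stochastic *establishment*: each generation a pilot sample of candidate
  mutations estimates the establishment rate `U Ne E[p_surv]`;
  Poisson-many establishers are seeded at frequency `1 / (Ne p_surv)`, the
  expected size of a lineage conditioned on escaping drift;
* a deterministic *mutation load*: candidates that cannot escape drift
  (`s <= 0` at this `Ne`) enter as frequency-weighted classes of total
  influx `U` per generation and decay under selection, reproducing the
  segregating deleterious load (about `U` at mutation-selection balance).

Validated against the exact engine at the reference parameters
`(U, n, sigma) = (0.01, 9, 0.034)`, the fast engine matches the mean
fitness change to within about 0.01-0.025 absolute (the worst case is the
early phase of strongly degraded founders, where jackpot establishments
make the exact dynamics slightly faster); near the optimum both engines
agree that the load makes the net change slightly *negative* (~ -0.007
after 240 generations at `W0 = 0.99`), which is why the monotone-gain
property is asserted only away from the peak.

## Summary statistics

`summarize_experiments()` reduces a composite dataset to 39 numbers in a
fixed canonical order: the counts of the 50 MA lines in seven fitness bins
with edges 0.77, 0.81, 0.85, 0.89, 0.93, 0.97 at bottlenecks 10-50
(interior bins right-open, outer bins open-ended, so a value exactly on an
edge falls upward), followed by the OLS slope and intercept of the fitness
change on initial fitness at recovery generations 120 and 240. Counts sum
to the number of lines at every checkpoint, the vector is invariant to
line order, and the layout round-trips through a single-row CSV. The
observed vector ships as a plain-text fixture (`load_observed_summary()`)
protected by an md5 integrity check.

Two regression analyses accompany the summaries. `change_vs_initial()`
pairs each line's fitness at an interval start with its change over the
interval (four pairs per line in the experimental geometry), and
`change_regression()` fits the pooled OLS slope with a Spearman rank test.
`ma_slope_distribution()` repeats this per simulated dataset to build the
distribution of slopes; for that analysis the package records fitness at
**every** bottleneck (`record_every = 1`). At single-cycle resolution the
no-selection expectation is the purely multiplicative
`-U * 23 * n * sigma^2` (about -0.0024 at the reference parameters, with a
small additional negative dynamic-regressor bias because each interval's
start fitness is itself an outcome of the process), while selection during
growth roughly quintuples the negative slope - the cleanest fingerprint of
drift-filtered epistasis the MA design offers. At the coarser 10-cycle
resolution the same contrast appears scaled up roughly tenfold.

## ABC inference

Priors: `log10(U)` uniform on `[-3.5, -0.5]`; `sigma` exponential with
mean 0.1 (a deliberately flat prior over the plausible 0-0.2 range; the
rate is exposed in `prior_spec()`); `n` uniform on the integers 1-30.

`simulate_pool()` draws `M` parameter vectors and simulates one composite
dataset each (fast MA engine, fast recovery engine with one replicate per
starting fitness). `abc_reject()` standardizes every statistic by its
median absolute deviation across the pool, measures Euclidean distance to
the observed vector, and keeps the `round(M * tol)` closest draws.
Statistics whose MAD is zero across the pool (bins that are empty in most
simulations) carry no information at this scale and are excluded with a
warning; the distance is configurable to the unstandardized Euclidean.
Acceptance counts, not a kernel, define the posterior: medians and 2.5-97.5
percentiles summarize it, with `n` reported on its integer grid.

Estimator diagnostics follow the standard simulation design:
pseudo-observed datasets at known `theta` (`make_pseudo_observed()`, exact
experimental geometry, bit-identical regeneration from `(theta, seed)`),
the distribution of posterior medians across them (bracketing the truth,
no systematic bias), and `prediction_error()` = squared mean bias plus
variance of the estimates about the truths, which tightens as the
acceptance tolerance decreases from 10% through 1% to 0.1%.

**Problem sizes.** The reference analysis in the test suite uses
`M = 20,000` prior draws with the closest 0.1% accepted (20 draws). This
is the package's desk-scale design: it reproduces the location of the
posterior (medians inside the published 95% intervals) while a
full-scale run (`M` in the millions) would sharpen the intervals
themselves. The validation battery uses 20 pseudo-observed datasets for
the bias check and 50 for the prediction-error comparison.

## Competition-assay arithmetic

Fitness in both experiments is measured by 1:1 competition against a
marked reference. With initial and final counts `N_ia, N_ib, N_fa, N_fb`,
the reference elapsed `G = log2(N_fb / N_ib)` generations (assuming no
death), the per-generation selection coefficient of the test strain is
`s = [ln(N_fa / N_ia) - ln(N_fb / N_ib)] / G`, and relative fitness is
`W = 1 + s`, standardized so the common ancestor measures exactly 1.
These forms are scale-invariant in the counts and antisymmetric in the
strain roles to first order; both properties are unit-tested.
`trajectory_model_compare()` contrasts linear and quadratic OLS fits of
log mean fitness against time with `AIC = N ln(RSS / N) + 2k` (additive
constants cancel), reporting differences below 2 as indistinguishable; a
perfect linear fit short-circuits to "linear" since added curvature cannot
improve it. On data simulated at the reference parameters the quadratic
term, when it earns its penalty, has a positive coefficient - the mean
decline decelerates as compensatory mutations become available, a
curvature direction worth knowing before applying the test to real
trajectories where assay noise typically swamps it.

## Numerical choices

* Fitness is carried as `log w` everywhere internally; exponentiation
  happens at interfaces. Class fitness is computed once at class creation.
* `survival_probability()` is continuous at `s = 0` (limit `1/Ne`),
  evaluated via `expm1` for beneficial mutations, and switched to log
  space for deleterious ones so that large `Ne |s|` underflows cleanly to
  zero instead of overflowing.
* The fast recovery engine prunes classes below frequency `0.5 / Ne`
  (below any establishment seed) and caps establishment seeds at frequency
  `1e-3` per establisher to keep near-neutral establishers - whose
  conditional fixation would take far longer than the experiment - from
  being seeded at macroscopic frequency.
* All stochastic entry points take an explicit `seed`; the same seed
  replays bit-identical datasets, and no function leaves hidden RNG state
  behind the caller's back.

## What the synthetic-data generator does and does not emulate

`make_pseudo_observed()` reproduces the experimental geometry exactly: 50
MA lines recorded every 10 of 50 bottleneck cycles, and recovery founders
at `W0 = 0.77, 0.88, 0.99` (the published range endpoints and midpoint;
the actual founder fitnesses of the recovery experiment varied clone by
clone). It records genotypic fitness without measurement noise - assay
noise in the real data (plating, counting, day effects) is not modelled,
so passing the validation battery demonstrates that the *inference
machinery* is unbiased under the model, not that the model captures every
source of error in the laboratory data. Mutation-rate evolution during
the experiments (documented for this mutator strain) and death during
growth are likewise outside the model.

## Known limitations

* The fast recovery engine's ~0.01-0.025 absolute accuracy in mean fitness
  change feeds a corresponding softness into the ABC posterior location;
  the exact engine is available for any analysis where minutes per run are
  acceptable.
* MAD standardization discards statistics that are zero in most
  simulations (sparse low-fitness bins early in the MA), which wastes some
  of the information the observed vector carries in exactly those bins.
* At `M = 20,000` the accepted sample (20 draws) locates the posterior but
  its 2.5/97.5 percentiles are themselves noisy; interval *widths* from
  the desk-scale run should not be over-interpreted.
* The model is the isotropic, single-optimum, Gaussian FGM; anisotropy,
  moving optima and non-zero-mean epistasis variants are out of scope.
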