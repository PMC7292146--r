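---
title: "Modelling identity-without-location reports: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling identity-without-location reports: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locbind)
```

## The scientific problem

In a brief masked display an observer must identify a target (say, the one
letter among digits) and then report *where* it was — by choosing one of six
slots, or by clicking the exact angle on a circle. The striking empirical
phenomenon this package models is that identity can be reported correctly
while the location report carries almost no information: the distribution of
angular location errors on correct-identity trials shows a precise central
peak sitting on a flat floor, plus reports centred on distractor positions.

`locbind` implements the full analysis chain for such experiments: a
generative simulator of observers and displays, the three-component circular
mixture model that decomposes location errors, guessing corrections for
forced-choice accuracies, and the resampling and Bayesian inference built on
top of them.

## The mixture model

On trial $i$ the signed error between the reported and true target angle is
$\varepsilon_i \in (-180^\circ, 180^\circ]$. With distractor positions
$\theta_{ij}$ ($j = 1, \dots, m_i$), the likelihood of a response angle
$\theta^r_i$ is

$$
p(\theta^r_i) \;=\;
p_T \, \phi_\kappa(\theta^r_i - \theta^t_i) \;+\;
p_{NT} \, \frac{1}{m_i} \sum_{j=1}^{m_i} \phi_\kappa(\theta^r_i - \theta_{ij})
\;+\; \frac{p_U}{360},
$$

where $\phi_\kappa$ is the von Mises density per degree with concentration
$\kappa$ shared between the target and swap components, $p_T$ is the
probability of a target-centred response, $p_{NT}$ the probability of a
*swap* (a response bound to a distractor's position), and $p_U$ the
probability of a response so imprecise that it is uniform relative to the
target. $p_T + p_{NT} + p_U = 1$.

Two modelling commitments deserve comment:

* **von Mises, not Gaussian.** Circular response kernels are implemented as
  von Mises. The concentration maps to a circular standard deviation by the
  Bessel-ratio formula
  $\mathrm{SD} = \sqrt{-2 \ln\left( I_1(\kappa)/I_0(\kappa) \right)}$, which
  reproduces the conventionally reported $(\kappa, \mathrm{SD})$ pairs
  (e.g. `k_to_sd(11.78)` $= 17.07^\circ$, `k_to_sd(10.22)` $= 18.4^\circ$,
  `k_to_sd(19.79)` $= 13.04^\circ$). One published pairing in this
  literature ($\kappa = 12.37$ with $16.16^\circ$) does not satisfy the
  formula (it gives $16.64^\circ$); the package makes no attempt to force
  agreement and relies only on the three consistent pairs.
* **Uniform mixing over distractors.** The swap component weights each of
  the trial's distractors equally ($1/m_i$), with no distance weighting;
  the validation simulations likewise centre swaps on a *randomly chosen*
  distractor.

### Fitting

`fit_mixture()` maximises the likelihood by EM. The E-step computes
per-trial responsibilities, splitting the swap responsibility uniformly over
that trial's distractors; the M-step updates the weights by responsibility
means and updates $\kappa$ by solving
$A(\kappa) = I_1(\kappa)/I_0(\kappa) = \bar{R}$, where $\bar{R}$ is the
responsibility-weighted mean resultant length of target- and
distractor-aligned deviations ($A^{-1}$ by bracketed root-finding, tolerance
$10^{-10}$). Numerical choices:

* multi-start (default 10 restarts): weights drawn Dirichlet(1,1,1),
  starting concentrations cycling through SDs of 5, 15, 30, 60 degrees; a
  50-iteration burst per start, then the best start is refined until the
  relative log-likelihood change falls below $10^{-8}$ (at most 1000
  iterations);
* $\kappa$ constrained to $[0.1, 500]$; a fit ending on a bound is flagged
  (`kappa_at_bound`) and treated as unusable downstream — this is how
  degenerate data (e.g. all responses exactly at the target) surface;
* fewer than 20 trials: the fit is refused outright with an
  `exclusion_reason`, mirroring the exclusion of a subject whose data could
  not support any parameter estimate. Excluded subjects reduce the degrees
  of freedom of downstream paired tests.

The EM + multi-start scheme is our choice (the analysis tradition this
follows does not name an algorithm); a test compares its optimum against an
exhaustive grid over $(p_T, p_{NT})$ in steps of 0.02 and SD in steps of
$1^\circ$ on small datasets, and EM never falls below the grid maximum.

Fitting is exposed both pooled across subjects (for headline estimates and
error histograms) and per subject (for paired tests), and only
correct-identity trials enter location fits — that filtering happens once,
centrally, via `filter_identity_correct()`.

## Guessing corrections

Forced-choice accuracies are corrected with the standard high-threshold
guessing model: if the observer knows the answer with probability $p$ and
otherwise guesses uniformly over the alternatives,
$\mathrm{obs} = p + (1 - p)c$ with chance level $c$, so

$$
p = \frac{\mathrm{obs} - c}{1 - c}, \qquad
\text{lucky-guess share} = \frac{(1 - p)\,c}{\mathrm{obs}}.
$$

`combined_location_error()` chains these: the conditional location accuracy
is corrected for location guessing ($c_{loc} = 1/6$ for six slots), then the
share of "correct identity" trials that were lucky identity guesses
($c_{id} = 1/26$) is subtracted, since those trials' location reports carry
no information. The supplementary formula this corresponds to is not
printed in the main analysis text; the implemented chain is the unique
simple composition of the guessing model that reproduces every printed step
of the worked six-slot example (68.8, 1.7, 65.2, 63.5 and 36.5 per cent),
and it is documented here as reconstructed rather than transcribed. The
replication experiment's printed chain is reproduced only to within
rounding (its observed 64.3% appears to be a rounded 64.0%), so only its
identity correction (62.7% → 61.21%) is asserted exactly.

## The generative observer

`observer_params()` + `simulate_responses()` implement the generative model
the analyses assume:

* identity is known with probability `p_identity_known`; otherwise the
  report is uniform over the 26-letter alphabet and is correct by luck with
  probability 1/26 (targets are drawn from a 15-letter pool, but reports
  range over the full alphabet — hence chance is 1/26, not 1/15);
* when identity is known, the location report is drawn from the
  three-component mixture above; when it is guessed, the location is
  uniform. This is the conservative assumption; a lucky guesser might well
  have item-centred location information, and
  `guess_location = "item_centered"` exists for exactly that sensitivity
  analysis, but the default matches the conservative correction logic;
* kernels are selectable: von Mises (default for observers) or wrapped
  normal (`error_kernel = "wrapped_normal"`); the validation sweep always
  uses the wrapped normal with SD $18.4^\circ$, because the validation
  procedure is defined by sampling normal noise of that SD and wrapping it.

Displays are six evenly spaced slots (discrete) or 8–10 items at uniform
random angles accepted only when all pairwise separations exceed a minimum
(rejection sampling). The default minimum separation is $12.6^\circ$ of
arc: a 1-degree visual-angle gap on a display circle of $9.1^\circ$
diameter is $360/(\pi \cdot 9.1) \approx 12.6$ degrees of arc. The exact
value does not enter any model mathematics. Discrete displays reuse the
continuous response machinery and snap the response to the nearest slot, so
there is a single generative code path.

### Experiment presets and intrinsic weights

`experiment_config()` bundles the published design constants (6 slots × 96
trials; 8 items × 144 trials; 10 items × 140 trials, 20 or 60 subjects)
with generative observer parameters. One subtlety: published mixture
weights are *fitted on all correct-identity trials*, a set contaminated by
lucky identity guesses whose locations are uniform. If $L$ is the
lucky-guess share of correct-identity reports, then
$p_U^{fit} = p_U^{known}(1 - L) + L$ and
$p_{NT}^{fit} = p_{NT}^{known}(1 - L)$. The presets invert this mapping so
that simulating a preset and refitting reproduces the published fitted
values. For the colour-target profile this inversion yields an intrinsic
$p_U^{known}$ of zero — the generative counterpart of the conclusion that
with a colour-defined target the fitted uniform weight is attributable
entirely to identity guessing.

## Resampling and Bayesian inference

* **`bootstrap_ci()`** implements the percentile bootstrap: resample units
  (whole subjects, or trials) with replacement, recompute the statistic,
  take the 2.5th/97.5th percentiles of the resampled distribution. The
  analysis tradition this emulates describes "averaging the 2.5% bounds
  across bootstraps", which is not a defined estimator without an inner
  resampling level; the standard percentile interval is used instead, and
  this deviation is deliberate.
* **`power_analysis()`** reproduces the recruitment logic: from a pool of
  per-subject statistics, draw pseudo-samples of size 5/10/20 with
  replacement; bootstrap each pseudo-sample's mean; report the fraction of
  pseudo-samples whose interval excludes zero. The between-subject SD of
  the real pilot pool is not published, so tests exercise this operation on
  synthetic pools with known structure (a well-separated pool must give
  exclusion 1.0 at $n = 20$; an exactly centred pool must give roughly the
  nominal false-positive rate; the exclusion fraction must be monotone in
  sample size).
* **`paired_t_and_bf()`** runs the two-tailed paired t-test and the
  Jeffreys–Zellner–Siow default Bayes factor,
  $BF_{10} = \int t_{\nu}(t \mid \delta\sqrt{n}) \,
  \mathrm{Cauchy}(\delta; 0, \sqrt{2}/2)\, d\delta \; / \; t_{\nu}(t)$,
  computed by adaptive quadrature over the prior (scale $\sqrt{2}/2$, the
  conventional default for paired designs). A Monte-Carlo integration
  oracle in the test suite agrees with the quadrature to within 1%.

## The validation study

`generate_validation_sweep()` re-creates the model-validation simulation:
holding the stimulus geometry of a template set of trials fixed, it
replaces every response, sweeping the swap percentage over a grid (default
0–100 in steps of 1, i.e. 101 datasets) while the remaining probability
mass is split guess : target = 1 : 4 — the empirical ratio of the uniform
and target weights in the large replication dataset. Swap and target
responses are wrapped-normal noise of SD $18.4^\circ$ around a random
distractor or the target; guesses are uniform. `nt_recovery_study()` then
refits every dataset and summarises estimated-vs-actual swap rates by a
Pearson correlation and regression slope.

### Problem sizes and what the tests show

The package's own validation runs are scaled to desk size: the acceptance
suite sweeps 21 swap levels × 1000 trials (rather than 101 × 2826) and
requires $r \ge 0.95$ with slope in $[0.9, 1.1]$, and checks pointwise
recovery at the 68/16/16, SD $18.4^\circ$ validation point at the full
2826-trial size. A repeat-simulation study during development showed the
ML estimator at that size is unbiased but has a per-draw SD of about 0.03
on each mixture weight (the swap and uniform components trade off when ten
items tile the circle), so the pointwise ±0.03 recovery check is asserted
on the estimator's mean across eight seeded replicates; a single draw at
that tolerance would be uninformative either way. The swap-free boundary
(estimated swap ≤ 3% when none was generated) is likewise checked at the
full 2826-trial size, where it is attainable.

What passing these simulations does *not* show: the generator draws
component memberships independently per trial with stationary
probabilities, has no lapses, no response biases, no serial dependence, no
subject-level parameter heterogeneity beyond what the presets encode, and
its identity-guess locations are exactly uniform. Real data violate all of
these to some degree; the simulations validate the estimation machinery,
not the psychological model.

## Known limitations

* The swap/uniform trade-off limits pointwise weight recovery at realistic
  sizes (see above); claims about $p_{NT}$ or $p_U$ for a single subject's
  ~50 trials should lean on the bootstrap, not the point estimate.
* The concentration–SD map is only inverted on $\kappa \in [10^{-6}, 10^4]$
  (roughly SD 0.58°–308°); `sd_to_k()` refuses values outside that range.
* `paired_t_and_bf()` refuses zero-variance differences rather than
  reporting $t = 0$; a statistic needs variability to be defined.
* Reproducing the published real-data test statistics (e.g. a $t(19)$ of
  −2.38 with $BF_{10} = 4.35$) requires the archived raw data, which the
  package deliberately does not bundle; the CSV reader supports such a
  reanalysis but no test depends on it.
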