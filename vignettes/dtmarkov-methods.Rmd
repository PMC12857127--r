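---
title: "Discrete-time Markov models with flexible covariate effects: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-time Markov models with flexible covariate effects: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Model

dtmarkov models movement between a finite set of states in discrete time
under the Markov assumption: the probability of the next state depends only
on the current state. The package focuses on *star* topologies — one
transient origin state and N absorbing destinations — because each row of a
transition matrix can be modeled separately; users with several transient
states compose one model per row. During each unit interval an individual in
the origin state either transitions to destination $n$ with probability
$\lambda_{1n,i}$ or stays with probability
$\lambda_{11,i} = 1 - \sum_n \lambda_{1n,i}$. The subscript $i$ matters: the
package's purpose is to let these probabilities differ between individuals
through covariates.

Scores $f_{1n}(\varphi_i, \theta)$ are mapped to probabilities by a
multinomial-logistic link with the stay probability as the reference
category,
$$\lambda_{1n,i} = \frac{\exp f_{1n}(\varphi_i,\theta)}
 {1 + \sum_{j} \exp f_{1j}(\varphi_i,\theta)},$$
so any real-valued scores produce a valid probability row, and the link
reduces to the logistic function when $N = 1$. Internally the link shifts by
the maximum score before exponentiating, making it stable for scores of any
magnitude; at scores beyond roughly $\pm 36$ the resulting probabilities
saturate at the resolution of double precision.

Three score families are provided:

* **constant** — one free score per destination; covariates ignored.
* **linear** — an affine map per destination. The intercept is deliberate:
  without it the constant model would not be nested inside the linear one,
  and the paired model comparisons would conflate a location offset with a
  covariate effect.
* **ann** — a multilayer perceptron with, by default, two hidden layers of
  50 units and swish activation ($x\,\sigma(x)$ with $\beta = 1$). The
  default is a single shared-trunk network with one output unit per
  destination, so the competing scores of one row are computed jointly and
  share representation; `shared_trunk = FALSE` switches to fully separate
  per-destination networks for users who want per-transition parameter
  vectors. At the default scale the shared trunk roughly halves the
  parameter count. Weights are initialised with Glorot-uniform draws, biases
  at zero; constant and linear models start at zero so every initial row is
  uniform over its outcomes.

## Likelihood and time conventions

All contributions are geometric. The package uses a single coherent clock:
**exact times count completed intervals**. An event recorded at
$k^\ast = k$ survived $k$ whole intervals and transitioned during the next
one, so its probability mass is $\lambda_d (1-\Sigma\lambda)^{k}$, $k = 0,
1, \dots$, and the masses over all destinations and times sum to one. A
right-censored individual observed for $k$ intervals contributes only the
survival factor $(1-\Sigma\lambda)^{k}$. Interval bounds live on the *trial*
scale: an event inside $(k_1, k_2]$ may have happened on any trial
$t \in \{k_1+1, \dots, k_2\}$, contributing
$$\log \sum_{t=k_1+1}^{k_2} \lambda_d (1-\Sigma\lambda)^{t-1},$$
which telescopes exactly to
$\log[(1-\Sigma\lambda)^{k_1} - (1-\Sigma\lambda)^{k_2}]$ in the
single-risk case (trial $t$ corresponds to completed time $t-1$; the two
clocks describe the same event). The distinction is not cosmetic: mixing the
clocks adds one spurious survival factor per event and biases every hazard
estimate downward by a factor of roughly
$\Sigma k / (\Sigma k + D)$ — the package's parameter-recovery test would
catch that immediately.

Numerical choices: interval sums use the closed geometric form evaluated in
the log domain (`log1p`/`expm1`-based, accurate both when the stay
probability approaches 1 and when the interval mass approaches the total
sub-distribution mass); a stay probability of exactly 1 falls back to the
$\log(k_2-k_1)$ limit; an observed destination with probability zero yields
$-\infty$ with a warning rather than an error, flagging a degenerate model;
a censoring time of zero contributes exactly zero information. Degenerate
intervals ($k_1 \ge k_2$) are rejected at validation.

Gradients are analytic. For a score matrix $S$ with link output
$(\lambda, \text{stay})$, every observation type has the same gradient
shape, $\partial \ell_i / \partial s_{ij} = \alpha_i 1\{j = d_i\} -
(\alpha_i + r_i)\,\lambda_{ij}$, where $r_i$ is the survival exponent — the
recorded time for exact observations, and the mass-weighted mean exponent
over candidate trials for interval observations. Backpropagation through the
network is hand-written (matrix form) and verified against central finite
differences to $10^{-5}$ relative error in the test suite.

## Training

`train_predictor()` maximises the log-likelihood by ADAM
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) on minibatches of
128 individuals drawn without replacement (shuffle, partition sequentially,
keep the last short batch, reshuffle when exhausted). The minibatch loss is
the per-individual *mean*, so the learning rate does not have to track the
batch size. Runs are bitwise reproducible under the config seed, and the
caller's RNG state is restored afterwards.

Two defaults deserve justification, because the reference protocol (batch
128, 500 optimizer steps) leaves them open:

* **Base learning rate 0.05.** ADAM's step magnitude is bounded by the
  learning rate; a constant-model score typically has to travel 2–4 units
  from its zero initialisation, so at the textbook default of $10^{-3}$
  *nothing* converges within 500 steps. The default was chosen by checking
  500-step training loss against long-run and quasi-Newton optima: with
  base rate 0.05 the constant and linear models reach their full-data
  optimum to within about one nat, and the network lands within a few nats
  of its long-run plateau.
* **Cosine-annealed step size (default).** With a constant step size the
  final iterates oscillate with minibatch noise, and 500-step network fits
  end 10–50 nats above the plateau depending on the initialisation seed.
  Annealing the step size to zero over the run removes the oscillation, so
  a 500-step run finishes where a 3000-step run does; `lr_schedule =
  "constant"` restores plain ADAM.

"500 iterations" is interpreted as 500 optimizer steps (one minibatch
each), not epochs; both counts are configurable. No early stopping and no
regularisation are applied by default; an optional L2 `weight_decay` is
exposed for users who want it.

## The synthetic generator

`simulate_dataset()` emulates a three-state star study with two covariates:

* Covariates are independent uniforms on $[0.02, 0.98]$ (configurable
  bounds; a custom sampler hook covers categorical designs).
* The noise-free probabilities come from two non-linear functions of the
  covariates; both share a non-monotone cubic bump in $\varphi_2$
  ($5\varphi_2(\varphi_2-0.9)(\varphi_2-0.8)$), one adds a saturating
  Hill-type term in $\varphi_1$, the other a growing exponential. On the
  unit square both are positive and their sum stays below one. The
  non-monotone component is the part a linear model cannot capture even in
  sign, which is what makes the bundled comparison study discriminating.
* One proportional error per transition and dataset,
  $\varepsilon \sim \mathcal N(0, 0.05)$ (standard deviation, not
  variance), scales the truth functions for all individuals:
  $\lambda = g(\varphi)(1+\varepsilon)$, clipped to keep rows on the
  simplex. In the replicate study a training/validation pair shares its
  $\varepsilon$ draw — the pair describes one perturbed population, and the
  evaluation MSE compares predictions against the probabilities that
  actually generated the validation data (the noise-applied $\lambda$, not
  the noise-free $g$).
* Event times: the generator draws the time to leaving the origin as a
  geometric variable with success probability $\Sigma\lambda$ and the
  destination from the conditional categorical distribution — the exact
  closed form of repeatedly sampling a categorical outcome until the
  individual leaves. Times are capped at `max_time` ($10^4$); capped
  individuals are recorded as right-censored there.
* Censoring: each individual is right-censored with probability 0.5, at
  their event time minus a Poisson(1) draw (floored at zero). Otherwise the
  event is kept with the interval $(\max(k^\ast-\sigma_1, 0),\,
  k^\ast+\sigma_2]$, $\sigma_1,\sigma_2 \sim$ Poisson(1) independently;
  the degenerate case $\sigma_1=\sigma_2=0$ is widened to
  $(k^\ast-1, k^\ast]$. Setting `interval_censoring = FALSE` records exact
  event times instead (on the completed-interval scale), which is what the
  parameter-recovery experiments use.

One property of this design deserves emphasis: **the right-censoring is
informative**, because the censoring time is constructed from the event
time. Individuals who would have had an event lose it but keep most of
their exposure, so *every* model fitted by the standard noninformative
censored likelihood — including the network — underestimates the leaving
hazards by a roughly common factor. The generator reproduces this design
faithfully; users should not read the absolute level of fitted
probabilities on such data as unbiased. Paired model *differences* are much
less affected, which is why the bundled study reports differences.

What the generator does not emulate: correlated covariates, time-varying
covariates or probabilities, multi-hop trajectories through several
transient states, and non-geometric event-time distributions. Passing tests
on these data therefore says nothing about model adequacy under covariate
drift or non-Markov dynamics.

## Evaluation

* **Validation loss** is the same interval-censored negative log-likelihood
  used in training, summed over individuals.
* **State occupation** at time $t$ is $\pi_0 P_i^t$ per individual
  (Chapman–Kolmogorov); for star models the closed form
  $(s^t,\ \lambda_n(1-s^t)/(1-s))$ is used.
* **Brier score** at the horizon (default $t = 5$) is the squared distance
  between predicted occupation and the observed one-hot occupation, averaged
  over individuals. Interval-censored events average over their
  $k_2 - k_1$ candidate trials — candidates at or before the horizon place
  the individual in the destination, later candidates in the origin — so the
  normaliser is an exact mean over the half-open interval. Right-censored
  individuals whose censoring time precedes the horizon have an unknown
  state there and are *excluded* by default; `include_unknown = TRUE`
  scores them at their last known state instead. Exclusion was chosen over
  imputation because scoring unknown outcomes as "still in origin" rewards
  models that underestimate hazards — on this generator it reverses the
  sign of every paired comparison.
* **Per-transition MSE** (simulation only) is the mean squared difference
  between the noise-applied generating probability and the prediction, for
  the stay probability and each destination.
* **Paired comparisons** subtract the ANN's metric from each reference
  model's metric per replicate and report the across-replicate median and
  2.5/97.5 percentiles; positive values favour the network.

## Problem sizes

The bundled replicate study uses train(3000)/validation(1000) pairs — the
reference design — with five replicates in `scripts/acceptance.R` and three
in the test suite; the full acceptance run completes in well under a minute
on one CPU. Parameter-recovery experiments use 5000 individuals; the
seven-state workflow check uses 8000 individuals with an 80/20 stratified
split and a longer (2000-step) run, since its six competing events are
individually rare.

## Known limitations

* Left censoring and left truncation are not supported.
* Each model object covers one transient origin row; chained multi-state
  trajectories must be composed by the user.
* The sampling interval is fixed at one time unit; calendar-time data must
  be discretised upstream (the `ebmt2_to_long()` adapter records the chosen
  unit, but the choice itself is the user's).
* Absolute probability levels fitted under informative right censoring are
  biased for all model families; see above.
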