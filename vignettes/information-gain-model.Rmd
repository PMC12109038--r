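---
title: "Information gains of a noisy Gaussian observer: model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information gains of a noisy Gaussian observer: model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigain)
```

## The model

`epigain` models the valence of epistemic emotions — curiosity, interest,
boredom, confusion — as Bayesian information gain under free-energy
minimisation. The observer is a one-dimensional Gaussian agent: a prior
belief about a hidden state, $p(s) = N(\eta, \sigma_p^2)$, is confronted
with an observation through a Gaussian likelihood of variance
$\sigma_l^2$. Everything depends on the observation only through the
prediction error $\delta$, the distance between the prior mean and the
likelihood peak. $\sigma_p^2$ is *prediction uncertainty*
(open-mindedness); $\sigma_l^2$ is *observation uncertainty* (precision
of the senses or instrument).

Two divergences quantify what one observation is worth:

* **recognition gain** $KLD = D_{KL}(p(s) \,\|\, p(s|o))$ — the drop in
  free energy achieved by updating recognition to the posterior;
* **Bayesian surprise** $BS = D_{KL}(p(s|o) \,\|\, p(s))$ — the maximum
  information gain expected from updating the prior itself on repeated
  i.i.d. observations.

Their sum $IG = KLD + BS$ is the total epistemic value of the
observation. For the pure-Gaussian model both are quadratics of
prediction error (`kld_closed()`, `bs_closed()`, with coefficients from
`gain_coefficients()`): ever-larger prediction errors would promise
ever-larger gains, which collides with bounded cognitive resources.

The model's central modification is a uniform noise floor on the
likelihood, representing spontaneous neural firing far from the
likelihood mode:
$p_\epsilon(o|s) = \alpha\,(p(o|s) + \epsilon)$ with
$\alpha = 1/(1+\epsilon)$. The posterior becomes a two-component mixture
of the conjugate Gaussian posterior and the prior
(`mixture_posterior()`), with weights
$w_{post} = e(\delta)/(e(\delta)+\epsilon)$ set by the evidence kernel
$e(\delta) = \exp[-\delta^2 / 2(\sigma_p^2+\sigma_l^2)]$. Once the
evidence falls below the floor, the posterior collapses back onto the
prior and both gains decay to zero: each gain becomes an inverted-U
("Wundt curve") function of prediction error and of surprise, with a
finite peak (`gain_curve()`, `find_optima()`).

The two peaks differ. The Bayesian-surprise optimum
$\delta_{BS}$ always lies beyond the recognition-gain optimum
$\delta_{KLD}$, with the total-gain optimum between them. The gaps
$D_\delta = \delta_{BS}-\delta_{KLD}$ and $D_S = S_{BS}-S_{KLD}$ measure
the exploration range of an idealised inquiry cycle in which diversive
curiosity (novelty seeking, maximise $BS$) and specific curiosity
(evidence seeking, maximise $KLD$) alternate — `simulate_cycle()`
implements exactly this alternation and its settled surprise fluctuation
has amplitude $D_S$ by construction.

## Conventions

Two normalisation conventions coexist in the package, deliberately:

* **Kernel convention** (evidence, surprise, mixture weights): the
  likelihood enters as a kernel of peak height 1, so the evidence is
  $e(\delta)$ itself, surprise is $0$ at $\delta = 0$ and saturates at
  $\log((1+\epsilon)/\epsilon)$, and the mixture weights cross exactly
  where $e(\delta) = \epsilon$. This is the only convention under which
  the evidence, augmented evidence and weight formulas above are mutually
  consistent.
* **Normalised densities** (everywhere an entropy or a marginal log
  probability has intrinsic meaning): the decomposition
  $-\log p(o) = BS + U$ of `perceived_uncertainty()`, and the whole
  predictive layer — `predictive_kld()`, `mutual_information()`,
  `ambiguity()`, `risk()`, `expected_free_energy()` — use proper
  densities, since mutual information and differential entropy are
  convention-dependent.

### A scale-invariance property and what it implies for trends

Under the kernel convention the model has an exact invariance: rescaling
state units maps $(\sigma_p^2, \sigma_l^2, \delta)$ to
$(c\sigma_p^2, c\sigma_l^2, \sqrt{c}\,\delta)$ without changing
$KLD$, $BS$, or the kernel surprise. Consequently every optimal surprise
is a function of the variance *ratio* $\sigma_p^2/\sigma_l^2$ alone.
A claim that an optimal surprise increases with $\sigma_l^2$ at fixed
$\sigma_p^2$ (decreasing in the ratio) and also increases with
$\sigma_p^2$ at fixed $\sigma_l^2$ (increasing in the ratio) can
therefore never hold simultaneously. Measured, $S_{BS}$ as a function of
the ratio has an interior maximum near $\sigma_p^2/\sigma_l^2 \approx 5$,
so `trend_report()` finds the $S_{BS}$ monotonicity checks falsified
along both axes while all other trends — maximum gains versus
$\sigma_l^2$, optimal prediction errors versus both variances, $S_{KLD}$
versus both axes, $D_S$ versus both axes, and the corner ordering of the
maximum total gain — hold. The trend suite reports this honestly rather
than switching the surprise axis to a normalised convention, which would
merely move the falsified check elsewhere (the normalised $S_{KLD}$
develops a shallow interior minimum along $\sigma_p^2$).

## Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| `eps` | uniform noise floor probability | $10^{-3}$ | reference value for all analyses; small enough not to distort the small-$\delta$ regime, large enough that the gain peak is at a moderate surprise |
| `prior_var`, `lik_var` | prediction / observation uncertainty (state units²) | sweep range $[1, 50]$ | the regime analysed throughout; `sweep_cells()` default |
| `bounds` | optimisation interval for $\delta$ | $[0,\ 3\sqrt{2(\sigma_p^2+\sigma_l^2)\log(1/\epsilon)}]$ | three times the weight switch-over scale; the peaks sit near the switch-over, so they are always interior (`delta_upper()`) |
| `n` (curve grid) | points of `gain_curve()` | 400, log-spaced plus linear | resolves both the near-zero plateau and the peak region |
| `n_scan` | optimiser pre-scan points | 101 | brackets the single peak (whose width is of order `delta_upper()/3`) before golden-section/parabolic refinement |
| `tol` | optimiser tolerance on $\delta$ | $10^{-6}$ | matches the bounded scalar optimiser's meaningful precision |

All information quantities are in nats.

## Numerical choices

* **Quadrature.** The mixture divergences have no closed form
  (`kld_mixture()`, `bs_mixture()`); they are computed by adaptive
  quadrature (`kl_numeric()`, built on `stats::integrate`) over a window
  covering both mixture components to $\pm 12$ standard deviations,
  with relative tolerance $10^{-9}$ and absolute tolerance $10^{-12}$.
  Integrands are assembled from log densities with log-sum-exp to avoid
  underflow.
* **Negative round-off.** Quadrature can return tiny negative values for
  divergences that are analytically $\ge 0$; results in $[-10^{-9}, 0]$
  are clamped to zero, anything more negative raises a numerical error
  naming the offending $\delta$.
* **Optimisation.** `find_optima()` uses `stats::optimize`
  (golden-section search with parabolic interpolation — the same family
  as MATLAB's `fminbnd`) inside a bracket chosen by the pre-scan, which
  also guards the optimiser's unimodality assumption; unimodality holds
  empirically everywhere tested but is not proven. Flat maxima are
  tie-broken to the smallest $\delta$ (within $10^{-9}$); peaks at a
  bound are flagged `non_interior` with a warning.
* **Peak counting in tests.** The inverted-U checks count interior
  maxima with a prominence threshold of $10^{-8}$: past the peak the
  gains decay to $\sim 0$, where bare quadrature round-off
  ($\sim 10^{-11}$) would otherwise split or fabricate maxima.
* **The $\epsilon \to 0$ oracle.** The closed-form quadratics serve as
  an oracle for the numerical mixture gains at $\epsilon = 10^{-12}$ —
  but only in the regime where the floor stays negligible relative to
  the Gaussian posterior *across the prior's support*. When
  $\sigma_p^2 \gg \sigma_l^2$, the posterior contracts far away from the
  prior core at large $\delta$, its density under the prior drops below
  any fixed floor, and the mixture $KLD$ genuinely saturates near
  $\log(e(\delta)/\epsilon)$ instead of growing quadratically. The
  oracle comparisons therefore use variance pairs with
  $\sigma_p^2 \lesssim \sigma_l^2$, where the agreement is at the
  $10^{-8}$ level over the full tested range
  $\delta \in [0, 3\sqrt{\sigma_p^2+\sigma_l^2}]$. The saturation
  elsewhere is a property of the model, not an integration error.
* **Determinism.** Nothing in the package draws random numbers; curves,
  optima, sweeps and traces are pure functions of their parameters, and
  the CSV/JSON writers (`write_gain_csv()`, `write_gain_json()`) format
  doubles at 17 significant digits so repeated runs are byte-identical
  and round-trip losslessly. This also makes `run_sweep()`'s checkpoint
  resume exact.

## Problem sizes

The analyses in the test suite and the reproduction script use a
2,000-point $\delta$ grid for the inverted-U verification, $5\times5$
grids (variances $\{1, 5, 10, 25, 50\}$) for trend reproduction, and a
$10\times10$ grid over $[1, 50]^2$ for the ordering audit — enough to
resolve every qualitative claim while a full-density sweep
(`sweep_cells(step = 0.1)`, about 240k cells) remains available behind
an explicit call with progress logging and checkpointing.

## Design decisions that were genuinely open

* **Improper floor.** A constant $\epsilon$ over the real line is not a
  proper density; the package follows the model's formal algebra
  ($\alpha = 1/(1+\epsilon)$) and treats $\epsilon$ as a constant added
  to the height-1 kernel. The posterior over $s$ is proper regardless,
  which is all the divergences need.
* **Sign of $\delta$.** All gains depend on $\delta^2$; the API exposes
  $\delta \ge 0$ and documents the symmetry.
* **Surprise axis of the gain-versus-surprise view.** The mixture
  surprise (from the augmented evidence) is used, since its
  monotonicity in $\delta$ is what makes the reparameterisation in
  `gain_vs_surprise()` exact.
* **Cycle dynamics.** The alternation is implemented as idealised
  one-step jumps to each optimum — the only behaviour the theory
  quantifies (via $D_\delta$, $D_S$) — rather than gradient dynamics,
  and the oscillation persists rather than contracting, since $D_S$ is
  interpreted as a standing fluctuation magnitude. The start phase
  defaults to diversive below $S_{KLD}$ (climbing from boredom) and
  specific above it (descending from confusion).
* **Policies.** The predictive layer represents a policy only through
  its induced Gaussian prior; discrete policy enumeration and full
  active-inference policy search are out of scope.

## Limitations

The state space is one-dimensional and Gaussian throughout; non-Gaussian
priors, hierarchical generative models and multivariate states are not
supported. Sequential multi-observation learning (habituation as a
declining $BS$ under repeated prior updates) is reflected in the
definitions but not simulated. The model is analytic and
context-independent: nothing here touches empirical arousal or valence
data, so reproducing the model's own predictions says nothing about how
well the model fits human behaviour.
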