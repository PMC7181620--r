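---
title: "Modeling confidence reports in three-alternative categorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling confidence reports in three-alternative categorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the observer model

`triconf` models behavior in a three-alternative spatial categorization
task. On each trial the observer sees three clouds of exemplar dots, each
drawn from an isotropic Gaussian category distribution (common SD
$\sigma_s = 2$ degrees of visual angle), plus one target dot at position
$\mathbf{s}$, and reports (a) which category the target belongs to and (b)
a confidence rating on a four-point scale. Because the three categories
are equally probable and their parameters are visible on screen, the
normative part of the task is pure spatial inference.

The generative observer has two noise sources:

* **Sensory noise.** The observer measures
  $\mathbf{x} \sim \mathcal{N}(\mathbf{s}, \sigma^2 I)$ rather than
  $\mathbf{s}$ itself. With equal priors the posterior over categories is
  $$p(C \mid \mathbf{x}) \propto
    \exp\!\left(-\frac{\lVert\mathbf{x}-\mathbf{m}_C\rVert^2}
    {2(\sigma_s^2+\sigma^2)}\right),$$
  computed with log-sum-exp so distant measurements stay finite
  (`compute_posterior()`).
* **Decision noise.** The observer acts not on the true posterior
  $\mathbf{p}$ but on a corrupted version
  $\mathbf{q} \sim \mathrm{Dirichlet}(\alpha\,\mathbf{p})$, whose mean is
  $\mathbf{p}$ and whose component variances are
  $p_i(1-p_i)/(\alpha+1)$; larger concentration $\alpha$ means less
  noise, and $\alpha = \infty$ recovers the noiseless posterior
  (`sample_noisy_posterior()`). This "late" noise makes behavior
  stochastic even when the measurement is exact.

The decision is the maximum-a-posteriori category
$\hat C = \arg\max_C q(C \mid \mathbf{x})$. Confidence is read out from
$\mathbf{q}$ as a scalar variable $c^*$ under one of four rules
(`confidence_variable()`), writing $q_{(1)} \ge q_{(2)} \ge q_{(3)}$ for
the sorted components:

| rule | $c^*$ | native range | intuition |
|------|-------|--------------|-----------|
| Max | $q_{(1)}$ | $[1/3, 1]$ | probability the decision is correct |
| Difference | $q_{(1)} - q_{(2)}$ | $[0, 1]$ | margin over the runner-up |
| Entropy | $\sum_C q_C \log q_C$ | $[-\log 3, 0]$ | negative uncertainty of the whole posterior |
| Ratio | $q_{(1)} / (q_{(1)} + q_{(2)})$ | $[1/2, 1]$ | top-two contest, third option discarded |

$c^*$ is mapped to the four-point rating by three criteria
$b_1 < b_2 < b_3$ on the rule's native scale: the rating is
$1 + \#\{i : c^* > b_i\}$. Because the criteria are free parameters, any
monotone mapping from internal confidence to button presses is
accommodated, and monotone redefinitions of $c^*$ are absorbed — which is
why the Entropy rule may use the natural logarithm and why the Ratio rule
may use the two-way renormalized posterior (a strictly increasing function
of the likelihood ratio between the top two options) without loss of
generality. In two-alternative tasks Max and Difference coincide up to the
affine map $c^*_{\text{diff}} = 2c^*_{\text{max}} - 1$; only with three or
more alternatives do the rules make different predictions, which is the
scientific point of the design.

Finally, a lapse rate $\lambda$ gives the probability of a trial on which
both responses are independent uniform button presses. We read "a random
button for both responses" as two independent draws; under any correlated
alternative the joint lapse cell probabilities would change by at most a
factor 3, absorbed in practice by refitting $\lambda$.

## Parameters

| parameter | meaning | units | default / bounds |
|-----------|---------|-------|------------------|
| $\sigma$ | sensory noise SD | deg visual angle | fit on $[0, 5]$ |
| $\alpha$ | Dirichlet concentration | — | fit on $[1, 5000]$, log scale |
| $b_1, b_2, b_3$ | confidence criteria | rule's $c^*$ scale | fit as $(b_1, \Delta_2 > 0, \Delta_3 > 0)$ |
| $\lambda$ | lapse rate | — | fit on $[10^{-4}, 1]$, log scale |

The full model has 6 free parameters; the reduced variants fix
$\sigma = 0$ ("decision" noise only) or $\alpha = \infty$ ("sensory"
noise only) and have 5. The three main rules crossed with the three noise
variants give the nine-model factorial enumerated by `model_grid()`.

The lapse floor $10^{-4}$ during fitting guarantees every response cell
has probability at least $\lambda/12 > 0$, so Monte-Carlo zeros can never
produce an infinite log-likelihood. The criteria bounds span the rule's
native range; the deltas keep them ordered by construction.

## Response probabilities and model fitting

The measurement is internal to the observer, so response probabilities
must be integrated over it. `response_distribution()` follows the
simulation recipe: for a target position, simulate `n_mc` measurements
(default 10,000), push each through posterior, Dirichlet noise, decision
and rating, tabulate the $3 \times 4$ joint frequencies, and mix in the
lapse: $(1-\lambda)\,\hat f + \lambda/12$. `log_likelihood()` sums the
log probability of each trial's (category, rating) pair over the
conditionally independent trials of a subject, caching one table per
unique target position, keyed by exact coordinates; confidence-only and
decision-only modes use the corresponding marginals.

Maximum-likelihood fitting of a Monte-Carlo objective needs care:

* **Common random numbers.** Every likelihood evaluation reseeds the
  simulation identically (one seed per configuration), making the
  objective a deterministic function of the parameters. The measurement
  normals are drawn first in a parameter-independent count, so the
  sensory stage reuses literally the same draws across evaluations; the
  Dirichlet stage consumes a parameter-dependent number of variates
  (rejection sampling), so its draws are deterministic per parameter
  value rather than aligned across values.
* **Factorized search.** For fixed $(\sigma, \alpha)$ the simulated
  readouts $(\hat C_j, c^*_j)$ are fixed; criteria and lapse only re-bin
  them. `fit_subject()` therefore searches the (at most two) noise
  parameters with multi-start Nelder-Mead on logit/log-transformed
  coordinates — Latin-hypercube starting points plus one default start —
  while for each candidate it maximizes over $(b_1, \Delta_2, \Delta_3,
  \lambda)$ exactly against sorted readout arrays (binary-search
  counting, no re-simulation). The criteria start at the quantiles of the
  simulated $c^*$ distribution matching the observed rating proportions.
  The search stage runs at a reduced Monte-Carlo size (default 1,000) and
  the best point is polished at the full size; the reported `logL` equals
  `log_likelihood()` at the fitted parameters, same seed and size.
* This is a generic bounded derivative-free scheme; any such optimizer
  would do, and the fit object records per-restart log-likelihoods and
  convergence codes so optimizer trouble is visible rather than silent.

## Model comparison and recovery

`information_criteria()` computes $\mathrm{AIC} = -2\log L + 2k$ and
$\mathrm{BIC} = -2\log L + k\log n$, with $n$ the number of trials of the
fitted subject. Models are compared by summing AIC over subjects;
`group_delta()` reports the group-summed difference with a 95% percentile
bootstrap interval over subjects (default 10,000 resamples). The
percentile method is used for its simplicity and invariance under
monotone transforms; resampling subjects (rather than per-subject
differences) is equivalent for summed differences.

`model_recovery()` closes the loop: for each generator rule it simulates
one session per synthetic subject from known parameters, fits every
candidate rule, and accumulates the group-summed AIC matrix (plus
per-subject win counts). Diagonal dominance of that matrix is the
evidence that the comparison procedure can identify the true model under
the experiment's design; target-position selection alone changes the
separation between rules, which is why recovery is run per experiment
design rather than once.

## The synthetic-data generator

`generate_session()` emulates the experiment designs: four
configurations per experiment (84 trials per configuration in experiment
1; 120 in experiments 2 and 3), targets drawn by each experiment's rule —
uniform horizontal positions with a 0.2-degree extension beyond the outer
category centers (experiment 1), a uniform 2.6-degree disc (experiment
2), or category-conditional sampling with feedback recorded as the true
category (experiment 3) — randomly interleaved configurations, and eight
equal blocks. Block structure is bookkeeping only: the models treat
trials as exchangeable, and nothing downstream reads it.

`generate_cohort()` draws per-subject parameters from package-default
ranges chosen to span plausible individual differences at this stimulus
strength: $\sigma \sim U[0.1, 1]$ deg (high-contrast, unlimited-duration
displays leave little sensory noise), $\alpha$ log-uniform on $[5, 200]$
(from heavily noisy to nearly deterministic posteriors), $\lambda \sim
U[0.005, 0.05]$. Each subject's criteria sit at the quartiles of their
own simulated $c^*$ distribution, mimicking subjects who spread their
rating usage; every drawn parameter and seed is recorded in a
ground-truth ledger from which the cohort regenerates exactly.

What the generator does *not* emulate — and hence what passing tests do
not establish about human data: learning or feedback effects within a
session (the observer is stationary even in experiment 3), sequential
dependencies, reaction times, idiosyncratic criterion drift, and any
read-out rule outside the four implemented ones. Recovery results say the
pipeline identifies the true model *among the candidates considered*
under the stated parameter ranges.

## Numerical choices

* **Dirichlet degeneracy.** $\mathrm{Dirichlet}(\alpha\mathbf{p})$ is
  improper if any $\alpha p_i = 0$; components of $\mathbf{p}$ below
  $10^{-6}$ are clamped to $10^{-6}$ and $\mathbf{p}$ renormalized, which
  perturbs $E[\mathbf{q}]$ by at most the clamp itself. An all-zero gamma
  underflow (possible only for minuscule shapes) falls back to
  $\mathbf{q} = \mathbf{p}$.
* **Ties.** Exact posterior ties are broken uniformly at random; they
  have measure zero under noise but occur in noiseless reduced models at
  likelihood-equality boundaries.
* **Criterion equality.** $c^* = b_i$ resolves to the lower rating
  (measure zero under noise).
* **Sliding windows.** Windows are closed intervals of width 0.6 deg,
  stepped by 0.1 deg, evaluated per subject before across-subject
  averaging; a $10^{-9}$-degree guard absorbs floating-point drift of the
  center grid. Empty windows are reported missing, never zero; windows
  with fewer than five trials are flagged, not dropped.
* **Hexagonal maps.** Flat-top hexagons, circumradius 0.25 deg, one
  hexagon centered at the origin; "radius" is read as center-to-vertex.
  Orientation and lattice origin are cosmetic but fixed for
  reproducibility. Assignment uses exact cube rounding, so every trial
  lands in exactly one hexagon.
* **Vertical symmetry shortcut.** When all three category centers share
  one vertical position (experiments 1 and 3), the vertical measurement
  coordinate cancels in the posterior and is not simulated.

## Scale of the validation experiments

The test suite validates parameter recovery with 336-trial experiment-1
sessions (the standard session length) at 2,000 Monte-Carlo measurements
per position, 20 replicates per rule, with generating parameters
$\sigma = 0.5$, $\alpha = 30$, $\lambda = 0.02$ and quartile criteria;
model recovery uses five synthetic subjects per generator rule at the
same settings. Oracle checks run the no-decision-noise observer at
$10^5$ Monte-Carlo samples against deterministic quadrature over the
measurement density. These sizes were chosen so the whole suite runs
comfortably on a single CPU while leaving the statistical checks sharp;
all of them are package choices, re-runnable at larger sizes through the
exported functions.

## Known limitations

* The Ratio rule is specified here as the two-way renormalized top-two
  posterior; any strictly monotone transform of the top-two likelihood
  ratio is observationally equivalent under free criteria, but other
  formalizations exist.
* The Monte-Carlo likelihood is biased high in probability cells of
  order $1/n_{\mathrm{mc}}$ or smaller; the lapse floor bounds the
  damage but fits with very small lapse and extreme criteria should use
  a larger `n_mc`.
* BIC uses the per-subject trial count as $n$; other conventions exist
  for hierarchical data.
* Fitting assumes trials are conditionally independent given the
  parameters, as the models do.
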