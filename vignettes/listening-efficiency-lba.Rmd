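---
title: "Listening efficiency from a hierarchical LBA model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Listening efficiency from a hierarchical LBA model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbaeff)
```

## The problem

In closed-set speech recognition, a listener watches or hears a short
sentence and then picks each of three keywords from a four-alternative set
(the keyword plus a semantically similar, a phonetically similar, and an
unrelated foil).  Accuracy alone saturates near ceiling for
normal-hearing listeners, and response time alone confounds ability with
speed–accuracy trade-offs.  `lbaeff` analyses both jointly with a linear
ballistic accumulator (LBA) race model and summarizes performance as
*listening efficiency* — how quickly evidence accumulates toward the
correct answer relative to the errors.

The package covers the full pipeline: a synthetic-data generator with the
statistical structure of a two-group (cochlear-implant users, CI, and an
acoustic-hearing comparison group, AH), three-mode (audio, video,
captions) study; the LBA race likelihood with a contaminant mixture;
two-group hierarchical Bayesian estimation; convergence diagnostics and
posterior predictive checks; the efficiency metric; and a Poisson
log-linear analysis of presentation-mode preference votes.

## The model

Each keyword selection is a race among four accumulators (one per response
option).  Accumulator $j$ starts at a value drawn uniformly on $(0, A)$,
grows linearly at a rate drawn from $N(v_j, s)$, and the first to reach
the threshold $b > A$ determines the response; the observed response time
adds a non-decision time $t_0 \ge 0.150$ s.  The density of responding
$r$ at decision time $t$ is the winner's first-passage density times the
survival functions of the three competitors (a defective density that
integrates to the choice probability).  Identification requires a scaling
constraint: the between-trial drift SD is fixed at $s = 1$.

Serial dependency within a sentence is modelled by two drift *boosts*
applied to the correct-response accumulator only: keyword 2 gains
`boost_kw2` if keyword 1 was answered correctly, and keyword 3 gains
`boost_kw3` if both earlier keywords were correct.

Lapses are handled by mixing the race density with a contaminant
component with probability $\lambda$: response uniform over the four
options and RT uniform on $(0, t_{max})$, where $t_{max}$ is the maximum
observed RT when fitting (a single dataset-level constant).  The mixture
keeps the likelihood finite for any RT in $(0, t_{max}]$, including
responses faster than $t_0$.

Each participant has 17 free parameters: 12 drift means (4 response types
× 3 modes), 2 boosts, and $A$, $b$, $t_0$ (fixed across modes).
Unconstrained coordinates are used for the hierarchy, with
$A = e^{u_A}$, $b = A + e^{u_b}$ and $t_0 = 0.150 + e^{u_{t_0}}$, so the
constraints hold by construction.  Individual vectors are multivariate
normal around their group's mean vector with a shared between-subject
covariance whose correlation matrix is estimated from the data.

**Listening efficiency** is the correct-response drift minus the mean of
the three error drifts, computed per posterior draw from the group-level
mean drifts, and normalized so that the AH group's average across the
three modes equals exactly 1 within every draw.  A random guesser has
efficiency 0; the measure is invariant to adding a common constant to all
four drifts.

## Priors

Group means have $N(0, 5^2)$ priors on the unconstrained scale.  The
shared covariance uses the Huang–Wand (2013) prior with $\nu = 3$,
$A = 2.5$: every between-subject scale then has an exact
half-Student-t(3, 0, 2.5) marginal and correlations are marginally
near-uniform.  We chose this form over the common half-t × LKJ(1)
combination because it admits exact conjugate Gibbs updates of the
covariance (see *Sampler*), while keeping the same scale marginals; at
$d = 17$ it is somewhat more diffuse over correlations than LKJ(1), which
is if anything more conservative.  The contaminant proportion has a
Beta(1, 19) prior (mean 5%).  All priors are configurable through
`lba_prior()`.

## Sampler

No gradient-based MCMC backend is used; posterior sampling is a blocked
adaptive Metropolis-within-Gibbs scheme written for this model, in the
lineage of the samplers long used for hierarchical evidence-accumulation
models (DE-MCMC, particle metropolis-within-Gibbs):

* **Individual parameters.**  Per participant, adaptive random-walk
  proposals with an empirical-covariance shape (Haario-style);
  slice-sampled line moves along the principal axes of an adapted
  $(A, b, t_0)$ sub-covariance — these three parameters form a stiff
  posterior ridge that componentwise updates traverse too slowly; and a
  conditional-prior independence refresh of every drift and boost
  component, evaluated only on the rows that component affects (a drift
  touches one mode's rows).  For weakly informed components (error drifts
  of near-ceiling cells) the refresh likelihood ratio is near 1, so such
  components decorrelate in a single step.
* **Group means.**  Exact conjugate Gibbs draws, plus translation moves
  that shift a group's mean and all its members' parameters together (the
  standardized offsets and the scatter matrix are invariant): a
  full-vector adaptive random walk, slice-sampled per-component
  translations for $A$ and $t_0$, and randomized localized translations
  for drift/boost components.  These target the common mode of
  (group mean, members), the slowest direction of a centered hierarchy.
* **Covariance.**  Exact conjugate Gibbs draws of $\Sigma$ and of the
  Huang–Wand auxiliary scales, interleaved with per-component scale moves
  that jointly rescale component $k$ of every individual about its group
  mean, $\Sigma$'s row/column $k$, and the auxiliary scale $a_k$.  The
  joint $a_k$ rescaling matters: holding $a_k$ fixed confines the move to
  the conditional inverse-Wishart slice, which is several times narrower
  than the half-t marginal, and the scales then mix through a second
  funnel.
* **Contaminant proportion.**  Logit-scale random walk using cached race
  densities, several steps per iteration.

All adaptation (step sizes, proposal covariances) happens during warmup —
with the covariance accumulators restarted at 25% and 50% of warmup so the
final proposal shape reflects the near-stationary chain — and is frozen
afterwards, so the retained draws come from a fixed transition kernel.
Retained draws are separated by `thin` transitions (default 3): a
Metropolis-within-Gibbs kernel needs more transitions per effective draw
than gradient-based samplers, and thinning buys them without growing the
stored output.  Initial unconstrained values are drawn uniformly from
$(-0.5, 0.5)$ per chain.  All randomness flows through R's RNG: a fit is
reproducible from its seed.

The stationary distribution of the sampler was validated by prior-only
runs (no data), which recover the analytic prior marginals of every block
(normal group means, half-t scales, near-uniform correlations, Beta
contaminant proportion); the test suite retains a scaled-down version of
this check, alongside the non-centered reconstruction identity and
simulation-based parameter recovery.

The defaults follow the analysis protocol of the study design: 4 chains,
1000 warmup and 2000 retained iterations per chain (8000 retained draws).
Convergence is summarized by rank-normalized split-Rhat and bulk/tail
effective sample sizes, flagging parameters above 1.01.  A known
limitation: at desk scale (10 participants per group, default chain
lengths, minutes of compute) the worst group-level parameters of this
gradient-free kernel — those coupled to the weakly identified
start-point range (see *Known limitations*) — typically reach
split-Rhat ≈ 1.03–1.14 depending on seed and chain count, rather than
the ≤ 1.01 a NUTS-class sampler attains on the same problem; longer
chains (larger `thin` or `sampling_iterations`) close the gap at
proportional cost.

## The synthetic-data generator

The generator is a first-class module: it draws individual parameter
vectors from the population model, assigns a balanced, seeded-random mode
order (20 trials per mode, 60 trials per participant, 3 keywords each —
18,000 keyword observations at the full design of 50 + 50 participants),
simulates every sentence keyword by keyword so the boosts act on the
simulated correctness of earlier keywords, and adds uniform lapses.

Default generative values (constrained scale): AH correct drifts 3.0 in
every mode; CI correct drifts 1.8 / 2.1 / 2.4 for audio / video /
captions; all error drifts −0.25; boosts 0.4 and 0.6; $A = 0.8$,
$b = 1.6$, $t_0 = 0.3$ s; $\lambda = 0.02$; $t_{max} = 10$ s; drift
scales 0.4, other scales 0.2; identity generating correlation.  The error
drift and threshold were calibrated once, by quadrature of the race
density, to reproduce the qualitative pattern of the study the generator
emulates: near-ceiling AH accuracy in every mode (~96%), CI accuracy
graded audio < video < captions (~82 / 87 / 91%, i.e. roughly 20%
audio-only errors), and implied normalized CI efficiencies of about 0.63,
0.72 and 0.82.  With the drift SD fixed at 1, accuracy saturates in $b$;
raising the correct−error drift gap is the only way to reach near-ceiling
accuracy, which is why the error drifts sit slightly below zero.

What the generator does *not* emulate: real lexical confusability
structure (semantic vs phonetic error rates differ by item, not only by
drift), item effects and stimulus-difficulty variation, fatigue or
practice trends, and missing/aborted trials (complete data are assumed).
Passing recovery tests therefore show that the estimation machinery is
faithful to this generative model at realistic sizes — not that the model
is true of any particular dataset.

## Numerical choices

* Log densities are floored at −745 (the smallest double's log) so a
  single impossible row cannot propagate −∞ through a sum.
* The race is resolved among positive-drift accumulators; simulation
  redraws the (negligible-probability) all-fail event, and the likelihood
  applies no renormalization over it, matching common LBA practice.
* The generator treats `t_max` as a response window: when the contaminant
  arm is active, a race that has not finished within `t_max` becomes a
  timeout guess (uniform response, uniform RT) — the behavior the
  contaminant component models.  The race RT tail is intrinsically heavy
  (the winning-drift density is of order 1/t near zero), so without the
  window a simulated cohort occasionally contains multi-minute "trials"
  that no behavioral dataset would; because the fitted contaminant bound
  is the maximum observed RT, such artifacts would deflate the contaminant
  density and bias both the lapse proportion and the drifts.  The
  effective lapse rate is therefore `lambda + (1 - lambda) P(race >
  t_max)`, about 0.022 at the default generative values.  With
  `lambda = 0` the pure race is returned unmodified.
* Normal CDF/density use `std::erfc`-based implementations (double
  precision, substantially faster than the R API calls inside tight
  loops).
* The narrowest-window HDI assumes a unimodal posterior sample; effect
  credibilities count ties as 0.5 so self-comparisons give exactly 0.5.
* Response caution is reported as $b - A/2$ (threshold minus mean start),
  with $b/A$ available as an alternative definition.
* Normalization of efficiency uses the reference group's mode-average
  *per draw* (not the posterior-mean reference), so the reference
  statement holds exactly draw by draw; draws with a non-positive
  reference mean would be flagged and excluded (none occur in practice at
  the study's parameter ranges).

## Preference-count analysis

Preference votes (one per participant per conversation) are analysed as
Poisson counts with a log link and full-factorial design matrices —
`Counts ~ Mode × Group` (counts summed over conversations) and
`Counts ~ Mode × Group × Conversation` — with treatment coding
(audio / AH / conversation A reference) and $N(0, 5^2)$ priors on
log-scale coefficients.  Sampling uses JAGS (glm module) with 4 chains,
2000 warmup and 2000 post-warmup iterations each.  Modelling fixed-total
votes as independent Poisson counts follows the original analysis choice;
conditional effects (exponentiated cell means with credible intervals)
are invariant to the coding.

## Problem sizes used in the tests

The automated checks run at desk scale, chosen to keep the full suite
fast while leaving every claim testable: oracle checks of the densities
against quadrature and 10^5–10^6-draw Monte-Carlo; recovery and
convergence fits with 10 participants per group and 60 trials each;
coverage studies with 20 replicate cohorts at reduced chain lengths.  The
full 18,000-observation design is exercised by the generator tests and
the command-line pipeline, not by repeated fitting.

## Known limitations

* **Weak identifiability of the start-point range at desk scale.**  With
  10 participants per group (3,600 keyword observations) the posterior
  supports two nearly equal-likelihood configurations: one near the
  generating start-point range `A`, and one with `A` near 0, `t0` near
  its 150 ms floor, and compensating shifts in `b` and the drift means.
  A dedicated caution-preserving jump move (large `u_A` proposals with
  `u_b` adjusted so `b - A/2` is invariant) lets chains traverse both
  regimes, so the reported posteriors integrate over them — but on
  cohorts where the low-`A` regime carries most mass, the correct-drift
  intervals sit above the generating values, and the frequentist coverage
  of 95% credible intervals for the *population* drift means is closer to
  80–90% than 95%.  This is a property of the model at this sample size,
  not of the implementation; it fades as the number of trials or
  participants grows (the study's full design has five times the data).
* The sampler is tuned for this model family; it is not a general-purpose
  backend, and posterior geometry pathologies outside the tested regimes
  (e.g. near-zero between-subject scales with very few participants)
  would mix more slowly than NUTS-class samplers.
* `A`, `b` and `t_0` are shared across modes and `lambda` across
  participants and groups, as in the study design; per-mode caution or
  per-group lapse rates are out of scope.
* The two-way preference model sums counts over conversations; stacked
  (repeated-measures) alternatives are not implemented.
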