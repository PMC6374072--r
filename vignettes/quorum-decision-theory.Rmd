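---
title: "Collective binary decisions: signal detection, quorum rules, and the limits of majority voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective binary decisions: signal detection, quorum rules, and the limits of majority voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quorumsdt)
```

## The model

A world is in state $+$ with prior probability $p$ and in state $-$
otherwise. Each decision-maker observes one scalar cue, drawn from
$\mathcal N(\mu_+, \sigma^2)$ in state $+$ and $\mathcal N(\mu_-,
\sigma^2)$ in state $-$ (equal variances, $\mu_+ > \mu_-$), and votes
$+1$ or $-1$. Outcomes carry costs $C_{TP}, C_{TN}, C_{FP}, C_{FN}$
(lower is better; errors strictly costlier than the correct outcome in
the same state). A group of $N$ identical decision-makers is
*conditionally independent*: given the true state, votes are independent.
The group chooses $+1$ iff the number of $+1$ votes strictly exceeds
$qN$, where $q \in [0, 1)$ is the quorum fraction.

Three layers follow.

**Individual optimum.** Minimising expected cost is a likelihood-ratio
test: vote $+1$ when $f_+(x)/f_-(x) > \beta$ with
$$\beta = \frac{(1-p)\,(C_{FP}-C_{TN})}{p\,(C_{FN}-C_{TP})}.$$
For equal-variance Gaussians the likelihood ratio is monotone in the cue,
so this is a cue threshold with closed form
$$x^* = \frac{\mu_+ + \mu_-}{2} + \frac{\sigma^2 \ln\beta}{\mu_+-\mu_-},$$
yielding state-wise accuracies $a_+ = 1 - \Phi\!\big((x^*-\mu_+)/\sigma\big)$
(true positive rate) and $a_- = \Phi\!\big((x^*-\mu_-)/\sigma\big)$ (true
negative rate). The pair $(1-a_-, a_+)$ is a point on the ecology's ROC
curve; `expected_accuracy()` gives the single-number accuracy
$a = p a_+ + (1-p) a_-$ that classic jury-theorem reasoning works with.

**Group accuracy.** In state $+$ the $+1$-vote count is
$\mathrm{Binomial}(N, a_+)$; in state $-$ it is
$\mathrm{Binomial}(N, 1-a_-)$. `group_accuracy_exact()` evaluates the
quorum rule on both tails — no asymptotics, no simulation — and
`group_accuracy_sim()` estimates the same quantity by Monte Carlo.
As $N \to \infty$ the vote fraction concentrates, so the group is
asymptotically correct in state $+$ iff $a_+ > q$ and in state $-$ iff
$1 - a_- < q$; `asymptotic_group_accuracy()` returns the prior-weighted
limit. Any quorum strictly inside $(1-a_-,\, a_+)$ therefore drives group
accuracy to 1 — the optimal quorum interval of `quorum_bounds()`.

**Error classification.** Simple majority ($q = \tfrac12$) lies inside
the interval only when both $a_+ > \tfrac12$ and $a_- > \tfrac12$.
Otherwise single-accuracy reasoning errs, and `classify_scenario()`
reports how:

* `ERROR_IA` — $a > \tfrac12$ predicts convergence to 1, but the limit is
  $p$ (when $a_+ > \tfrac12 > a_-$) or $1-p$ (the mirror case), still at
  or above $a$;
* `ERROR_IB` — as Ia, and the limit falls *below* $a$: equivalently
  $p < a_-/(1-a_++a_-)$ in the first case, or
  $p > (1-a_-)/(1+a_+-a_-)$ in the mirror case; groups are then worse
  than individuals;
* `ERROR_II` — $a < \tfrac12$ predicts collapse to 0, but the limit is the
  positive $p$ or $1-p$;
* `NONE`, `BELOW_CHANCE`, `BOUNDARY` for the remaining geometry.

The classifier derives classes constructively (compare the limit, the
prediction and $a$); the closed-form prior bounds are also implemented
(`condorcet_error_conditions()`) and the test suite checks the two routes
agree on $10^5$ random scenarios. The mirrored refinement of `ERROR_II`
(a predicted collapse that ends *above* individual accuracy) is
algebraically impossible; `no_error_iib_search()` verifies the
impossibility empirically on $10^6$ random scenarios.

```{r example}
eco <- decision_ecology(0, 1, 1, p = 0.9, c_fp = 4, c_fn = 1)
pt <- optimal_operating_point(eco)
c(a_plus = pt$a_plus, a_minus = pt$a_minus,
  individual = expected_accuracy(0.9, pt),
  majority_1001 = group_accuracy_exact(pt, 0.9, group_rule(1001, 0.5))$accuracy,
  quorum_0.7 = group_accuracy_exact(pt, 0.9, group_rule(1001, 0.7))$accuracy)
```

## Parameters and defaults

| parameter | meaning | default | rationale |
|---|---|---|---|
| $\mu_-, \mu_+, \sigma$ | cue means and common SD (cue units) | 0, 1, 1 | unit signal-to-noise separation; the reference scenarios all use it |
| $p$ | prior of state $+$ | — (required) | scenario-defining |
| $C_{TP}, C_{TN}$ | costs of correct outcomes | 0 | only cost *differences* enter $\beta$ |
| $C_{FN}$ | cost of a miss | 1 | fixes the cost scale, so $C_{FP}$ is the false-positive/false-negative cost *ratio* |
| $q$ | quorum fraction | 0.5 | simple majority as the baseline under study |
| `n_reps` | Monte Carlo replicates | 10,000 | the replicate count of the reference simulations; SE on an accuracy near 0.9 is about 0.003 |
| `tie_policy` | behaviour at an exact quorum tie | `coin_flip` | symmetric; makes $q=\tfrac12$ with odd $N$ the textbook majority rule |

## What the simulation emulates — and what it does not

`group_accuracy_sim()` draws, per replicate, the true state and then each
voter's correctness directly from $(a_+, a_-)$. This is exactly the
model's data-generating process — identical, homogeneous voters whose
errors are conditionally independent given the state — so agreement with
`group_accuracy_exact()` (tested at 4 standard errors) validates the
implementation, not the model. A cue-level path
(`simulate_votes_from_cues()`, drawing Gaussian cues and thresholding) is
retained as a cross-check; the two are equivalent by construction.

Passing tests therefore say nothing about real groups in which voters
share information (correlated errors), differ in competence, observe
different cue qualities, or face non-Gaussian or multi-dimensional cues.
In real data, correlation between voters is the first assumption to
break, and it generally slows or destroys the concentration that quorum
rules exploit.

## Numerical choices

* **No root-finding.** The optimal threshold is closed-form; Gaussian
  tails come from `pnorm`, binomial tails from `pbinom`. The test suite
  confirms the closed form against dense-grid cost minimisation ($10^6$
  grid points for the reference ecologies; 200 random ecologies at
  $10^4$ points).
* **Strict-inequality voting.** A voter chooses $+1$ iff the cue strictly
  exceeds $x^*$; measure-zero either way, fixed for determinism.
* **Ties.** The quorum count $qN$ is treated as integral when within
  $10^{-9}$ of an integer (guarding against floating-point products such
  as $0.3 \times 10$); exact computation then adds half the tie mass
  under `coin_flip`. Curves default to odd $N$ so simple majority never
  ties.
* **Boundaries.** Scenario classification treats an inequality within
  $10^{-12}$ of equality as `BOUNDARY` (a measure-zero set, reported
  rather than guessed); `asymptotic_group_accuracy()` refuses a quorum
  exactly at $a_+$ or $1-a_-$, where the concentration argument is
  uninformative.
* **ROC sweep.** Thresholds span $[\mu_- - 6\sigma,\ \mu_+ + 6\sigma]$,
  linearly spaced, which covers both rates to within about $10^{-9}$ of
  0 and 1; the exact limiting points are appended.
* **Degenerate inputs.** Ecologies with $\mu_+ \le \mu_-$ are rejected
  with advice to relabel the states — inverting decisions is a modelling
  choice the library refuses to make silently. Cost structures in which
  an error is not strictly worse than the matching correct outcome are
  rejected as degenerate. Operating points on or below the chance
  diagonal have no quorum interval and raise an error.

## Design choices where the design was open

* **Quorum convention.** "Strictly more than $qN$ votes, coin-flip
  ties" was chosen so that $q = \tfrac12$ with odd $N$ reproduces the
  standard majority rule exactly; the source analyses leave the
  convention implicit.
* **Sub/super-majority labels.** One printed condition for super-majority
  quorums ($1 - a_+ > \tfrac12$) is inconsistent with the quorum
  interval; `recommend_quorum()` therefore derives labels from the
  interval itself — `sub_majority` when it lies wholly below $\tfrac12$,
  `super_majority` wholly above, `majority_compatible` when $\tfrac12$ is
  interior — which is unambiguous.
* **Recommended quorum.** The interval midpoint. Any interior $q$ gives
  the same limit; per-$N$ optimisation of $q$ (which benefits small
  groups) is deliberately out of scope.
* **Region-map grids.** The published maps do not state their axes.
  Defaults: 201 priors linear on $(0.005, 0.995)$ and 201 cost ratios
  log-spaced on $[10^{-2}, 10^{2}]$ — log spacing makes the ratio axis
  symmetric about 1, where neither error dominates. Grids are recorded in
  the metadata sidecar, declared as this package's choice.
* **Simulation seeds.** Every stochastic routine takes an explicit seed,
  restores the caller's RNG state, and records the seed in its result.
  Curve simulations use `seed + i - 1` at the $i$-th group size so single
  points can be reproduced in isolation.

## Problem sizes used by the tests

Exact accuracies are checked at $N = 1001$ and $5001$ (reference
scenarios), $10{,}001$ (limit convergence) and $20{,}001$ (classifier
validation, 500 random scenarios with state-wise accuracies at least
0.02 away from $\tfrac12$ so concentration is complete at that size);
brute-force vote-vector enumeration covers $N \le 12$; simulations use
the reference 10,000 replicates at $N = 501$ and smaller designs
elsewhere. These sizes are the package's validation choices, not claims
about any published axis range.

## Known limitations

* Voters are homogeneous and conditionally independent; no weights,
  correlations, sequential dynamics or speed–accuracy trade-offs.
* The cue model is a single scalar with equal-variance Gaussian classes;
  unequal variances or empirical ROC curves are not supported.
* Costs must be given as costs (minimised); payoff matrices must be
  negated by the caller.
* The limit analysis is binary-outcome only: it says *where* accuracy
  converges, not how fast (though `group_accuracy_exact()` answers the
  finite-$N$ question directly).
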