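# quorumsdt

Quorum decision rules for collective binary choice, via signal detection
theory.

## The problem

Groups of animals, people, cells or classifiers often face a binary choice
— predator present or absent, disease present or absent — and decide by
pooling votes. The Condorcet Jury Theorem, the classic guide to such
decisions, summarises each voter by a single accuracy *a* and predicts that
majority-vote accuracy converges to 1 as group size *N* grows when
*a* > ½, and to 0 when *a* < ½.

That summary hides a crucial fact: in a two-state world there are two
error types. A voter has a true positive rate *a*₊ (accuracy when the
world is in state +) and a true negative rate *a*₋ (accuracy in state −),
and an optimal voter rarely keeps them equal. With conditionally
independent voters, the fraction voting "+" concentrates on *a*₊ in state
+ and on 1 − *a*₋ in state −, so a quorum rule "choose + iff more than a
fraction *q* of votes are +" drives group accuracy to 1 for any

  1 − *a*₋ < *q* < *a*₊,

while simple majority (*q* = ½) can converge instead to *p* or 1 − *p*
(the prior of state +), sometimes below the accuracy of a single voter.

`quorumsdt` implements this theory end to end:

* **Individual optimisation** — for equal-variance Gaussian cue
  distributions, the cost-minimising decision threshold is the closed form
  *x\** = (μ₊ + μ₋)/2 + σ² ln β / (μ₊ − μ₋), with the likelihood-ratio
  criterion β = (1 − *p*)(C_FP − C_TN) / \[*p*(C_FN − C_TP)\]; plus ROC
  curves, expected accuracy and expected cost.
* **Group accuracy** — exact (binomial tails), Monte Carlo, and
  large-group limits for any quorum rule, with explicit tie handling.
* **Diagnosis** — classification of scenarios into the predictive errors
  that single-accuracy majority reasoning makes (Ia: limit below 1; Ib:
  limit below the individual; II: predicted collapse that does not
  happen), error-region maps over prior and false-positive/false-negative
  cost ratio, and sub-/super-majority quorum recommendations.

Audience: behavioural ecologists, decision scientists and ensemble-method
designers who want the quantitative case for (or against) majority voting
in a specific decision ecology.

## Worked example

A common positive state (*p* = 0.9) with costly false positives
(C_FP = 4, C_FN = 1):

```r
library(quorumsdt)

eco <- decision_ecology(mu_minus = 0, mu_plus = 1, sigma = 1,
                        p = 0.9, c_fp = 4, c_fn = 1)
pt <- optimal_operating_point(eco)
pt
#> Operating point
#>   threshold x* = -0.31093
#>   a+ (TPR) = 0.905059
#>   a- (TNR) = 0.377927   (FPR = 0.622073)

expected_accuracy(0.9, pt)
#> [1] 0.8523461

group_accuracy_exact(pt, p = 0.9, group_rule(1001, q = 0.5))$accuracy
#> [1] 0.9
group_accuracy_exact(pt, p = 0.9, group_rule(1001, q = 0.7))$accuracy
#> [1] 1

classify_scenario(pt, p = 0.9)$class
#> [1] "ERROR_IA"
recommend_quorum(pt)
#> $q
#> [1] 0.7635662
#> $label
#> [1] "super_majority"
#> $bounds
#>     lower     upper
#> 0.6220732 0.9050593
```

Each voter is individually optimal (accuracy 0.852), yet a 1001-member
simple-majority group is only 90% accurate — it is nearly always right in
state + and nearly always wrong in state −, so its accuracy converges to
the prior *p* = 0.9 rather than to 1. Any quorum inside (0.622, 0.905),
for example *q* = 0.7, restores convergence to perfect accuracy.

The same pipeline from the shell:

```sh
exec/quorumsdt optimal-rates --p 0.9 --c-fp 4
exec/quorumsdt group-accuracy --a-plus 0.905 --a-minus 0.378 --p 0.9 --q 0.7 --n 1001
exec/quorumsdt region-map --which any --out map_any.csv
```

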