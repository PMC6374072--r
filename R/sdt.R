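#' Likelihood-ratio criterion for a decision ecology
#'
#' The optimal decision-maker chooses `+1` whenever the likelihood ratio of
#' the cue, f_plus(x) / f_minus(x), exceeds the cost- and prior-weighted
#' criterion
#'
#'   beta = \[(1 - p) (c_fp - c_tn)\] / \[p (c_fn - c_tp)\].
#'
#' `beta` equals 1 in the fully symmetric case (equal priors, equal error
#' penalties) and grows as false positives become relatively costlier or the
#' positive state rarer.
#'
#' @param eco A [decision_ecology()].
#' @return The criterion `beta`, a positive number.
#' @examples
#' lr_criterion(decision_ecology(0, 1, 1, p = 0.9, c_fp = 4, c_fn = 1))  # 4/9
#' @export
lr_criterion <- function(eco) {
  stopifnot(inherits(eco, "decision_ecology"))
  (1 - eco$p) * (eco$c_fp - eco$c_tn) / (eco$p * (eco$c_fn - eco$c_tp))
}

#' Optimal cue threshold
#'
#' For equal-variance Gaussian cue distributions the likelihood ratio is
#' monotone in the cue, so thresholding the likelihood ratio at `beta` is
#' equivalent to thresholding the cue itself at
#'
#'   x* = (mu_plus + mu_minus) / 2 + sigma^2 log(beta) / (mu_plus - mu_minus).
#'
#' Deciding `+1` iff the cue strictly exceeds `x*` minimises expected cost.
#'
#' @inheritParams lr_criterion
#' @return The threshold `x*`.
#' @seealso [optimal_operating_point()], [expected_cost()]
#' @export
optimal_threshold <- function(eco) {
  stopifnot(inherits(eco, "decision_ecology"))
  beta <- lr_criterion(eco)
  (eco$mu_plus + eco$mu_minus) / 2 +
    eco$sigma^2 * log(beta) / (eco$mu_plus - eco$mu_minus)
}

#' State-wise accuracies at a given threshold
#'
#' A decision-maker who votes `+1` iff the cue exceeds `x` attains
#' `a_plus = 1 - pnorm((x - mu_plus) / sigma)` (true positive rate) and
#' `a_minus = pnorm((x - mu_minus) / sigma)` (true negative rate). The event
#' cue == x has measure zero for a continuous cue; the strict-inequality
#' convention is fixed for determinism.
#'
#' @inheritParams lr_criterion
#' @param x Cue threshold(s); vectorised.
#' @return For scalar `x`, an [operating_point()]; for vector `x`, a
#'   data.frame with columns `threshold`, `a_plus`, `a_minus`.
#' @export
rates_at_threshold <- function(eco, x) {
  stopifnot(inherits(eco, "decision_ecology"), is.numeric(x))
  a_plus <- stats::pnorm(x, mean = eco$mu_plus, sd = eco$sigma,
                         lower.tail = FALSE)
  a_minus <- stats::pnorm(x, mean = eco$mu_minus, sd = eco$sigma)
  if (length(x) == 1L) {
    operating_point(a_plus = a_plus, a_minus = a_minus, threshold = x)
  } else {
    data.frame(threshold = x, a_plus = a_plus, a_minus = a_minus)
  }
}

#' Signal-detection-optimal operating point
#'
#' Composes [optimal_threshold()] and [rates_at_threshold()]: the returned
#' `(a_plus, a_minus)` pair minimises expected cost over all cue thresholds,
#' and lies on the ROC curve of the ecology. Every optimal point lies above
#' the chance diagonal (`a_plus > 1 - a_minus`), since the two cue
#' distributions are distinct.
#'
#' @inheritParams lr_criterion
#' @return An [operating_point()].
#' @examples
#' eco <- decision_ecology(0, 1, 1, p = 0.9, c_fp = 4, c_fn = 1)
#' optimal_operating_point(eco)  # a+ ~ 0.905, a- ~ 0.378
#' @export
optimal_operating_point <- function(eco) {
  rates_at_threshold(eco, optimal_threshold(eco))
}

#' ROC curve of a decision ecology
#'
#' Sweeps the cue threshold linearly over
#' `[mu_minus - 6 sigma, mu_plus + 6 sigma]` and records the resulting
#' (FPR, TPR) pairs. The sweep range reaches within about 1e-9 of the
#' limiting points (0, 0) and (1, 1), which are appended exactly. Rows are
#' ordered by increasing FPR (decreasing threshold).
#'
#' @inheritParams lr_criterion
#' @param n_points Number of thresholds in the sweep (at least 2).
#' @return A data.frame with columns `threshold`, `fpr`, `tpr`, ordered by
#'   increasing `fpr`; the limiting rows carry infinite thresholds.
#' @export
roc_curve <- function(eco, n_points = 512L) {
  stopifnot(inherits(eco, "decision_ecology"),
            is.numeric(n_points), length(n_points) == 1L, n_points >= 2)
  lo <- eco$mu_minus - 6 * eco$sigma
  hi <- eco$mu_plus + 6 * eco$sigma
  x <- seq(hi, lo, length.out = as.integer(n_points))  # FPR increasing
  sweep <- rates_at_threshold(eco, x)
  out <- data.frame(threshold = c(Inf, sweep$threshold, -Inf),
                    fpr = c(0, 1 - sweep$a_minus, 1),
                    tpr = c(0, sweep$a_plus, 1))
  rownames(out) <- NULL
  out
}

#' Expected individual accuracy
#'
#' The single-number accuracy that Condorcet-style reasoning attributes to a
#' decision-maker is the prior-weighted average of the state-wise
#' accuracies:
#'
#'   a = p a_plus + (1 - p) a_minus.
#'
#' When `a_plus == a_minus` the prior drops out — the implicit assumption of
#' the classic jury theorem.
#'
#' @param p Prior probability of state `+`, in \[0, 1\].
#' @param point An [operating_point()].
#' @return The expected accuracy, a probability.
#' @export
expected_accuracy <- function(p, point) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  point <- as_operating_point(point)
  p * point$a_plus + (1 - p) * point$a_minus
}

#' Expected decision cost at an operating point
#'
#' Averages the four outcome costs over states and conditional outcome
#' probabilities:
#'
#'   E\[cost\] = p \[a+ c_tp + (1 - a+) c_fn\] +
#'            (1 - p) \[a- c_tn + (1 - a-) c_fp\].
#'
#' Used as the objective that [optimal_threshold()] minimises; exposed so
#' the optimality can be checked directly (e.g. against a threshold grid).
#'
#' @inheritParams lr_criterion
#' @param point An [operating_point()], or a data.frame with columns
#'   `a_plus` and `a_minus` (e.g. from a vectorised [rates_at_threshold()]).
#' @return Expected cost (scalar or vector matching the rows of `point`).
#' @export
expected_cost <- function(eco, point) {
  stopifnot(inherits(eco, "decision_ecology"))
  if (is.data.frame(point)) {
    a_plus <- point$a_plus; a_minus <- point$a_minus
  } else {
    point <- as_operating_point(point)
    a_plus <- point$a_plus; a_minus <- point$a_minus
  }
  eco$p * (a_plus * eco$c_tp + (1 - a_plus) * eco$c_fn) +
    (1 - eco$p) * (a_minus * eco$c_tn + (1 - a_minus) * eco$c_fp)
}
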