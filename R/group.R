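#' Define a group quorum rule
#'
#' A group of `n` conditionally independent voters chooses action `+1` iff
#' the number of `+1` votes strictly exceeds `q * n`. When `q * n` is an
#' integer an exact tie is possible; `tie_policy` fixes its resolution:
#' `"coin_flip"` (default) decides uniformly at random (counted as half the
#' tie probability mass in exact computation), `"choose_minus"` falls back
#' to action `-1`. With `q = 1/2` and odd `n` this convention reproduces
#' the textbook simple-majority rule with no ties.
#'
#' @param n Group size (positive integer).
#' @param q Quorum fraction in `[0, 1)`. `q = 1/2` is simple majority;
#'   `q < 1/2` sub-majority; `q > 1/2` super-majority.
#' @param tie_policy `"coin_flip"` or `"choose_minus"`.
#' @return An object of class `group_rule`.
#' @export
group_rule <- function(n, q = 0.5, tie_policy = c("coin_flip", "choose_minus")) {
  stopifnot(is.numeric(n), length(n) == 1L, is.numeric(q), length(q) == 1L)
  if (n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (q < 0 || q >= 1) stop("`q` must lie in [0, 1)", call. = FALSE)
  tie_policy <- match.arg(tie_policy)
  structure(list(n = as.integer(n), q = q, tie_policy = tie_policy),
            class = "group_rule")
}

#' @export
print.group_rule <- function(x, ...) {
  cat(sprintf("Group rule: n = %d, quorum q = %g (%s), ties: %s\n",
              x$n, x$q,
              if (x$q < 0.5) "sub-majority" else if (x$q > 0.5)
                "super-majority" else "simple majority",
              x$tie_policy))
  invisible(x)
}

# shared tolerance for detecting an integer quorum count q * n
.tie_tol <- 1e-9

#' Probability that a group chooses the positive action
#'
#' Each voter independently votes `+1` with probability `vote_plus_prob`;
#' the group chooses `+1` iff the `+1`-vote count `K ~ Binomial(n,
#' vote_plus_prob)` strictly exceeds `q * n`, plus half the probability of
#' an exact tie under the `"coin_flip"` policy.
#'
#' @param vote_plus_prob Per-voter probability of a `+1` vote (vectorised).
#' @param rule A [group_rule()].
#' @return Probability (or vector of probabilities) that the group chooses
#'   `+1`.
#' @export
p_choose_plus <- function(vote_plus_prob, rule) {
  stopifnot(inherits(rule, "group_rule"),
            is.numeric(vote_plus_prob),
            all(vote_plus_prob >= 0 & vote_plus_prob <= 1))
  thr <- rule$q * rule$n
  k <- floor(thr + .tie_tol)
  out <- stats::pbinom(k, rule$n, vote_plus_prob, lower.tail = FALSE)
  if (abs(thr - round(thr)) < .tie_tol && rule$tie_policy == "coin_flip") {
    out <- out + 0.5 * stats::dbinom(round(thr), rule$n, vote_plus_prob)
  }
  out
}

group_accuracy_result <- function(accuracy, acc_plus, acc_minus, p, method,
                                  n, q, n_reps = NA_integer_,
                                  std_error = NA_real_, seed = NA_integer_,
                                  point = NULL) {
  if (is.finite(acc_plus) && is.finite(acc_minus) &&
      abs(accuracy - (p * acc_plus + (1 - p) * acc_minus)) > 1e-9) {
    stop("internal error: accuracy does not decompose over states",
         call. = FALSE)
  }
  structure(
    list(accuracy = accuracy, acc_plus = acc_plus, acc_minus = acc_minus,
         p = p, method = method, n = n, q = q, n_reps = n_reps,
         std_error = std_error, seed = seed, point = point),
    class = "group_accuracy"
  )
}

#' @export
print.group_accuracy <- function(x, ...) {
  cat(sprintf("Group accuracy (%s): %.6g\n", x$method, x$accuracy))
  cat(sprintf("  P(correct | +) = %.6g, P(correct | -) = %.6g, prior p = %g\n",
              x$acc_plus, x$acc_minus, x$p))
  cat(sprintf("  n = %s, q = %g", format(x$n), x$q))
  if (!is.na(x$n_reps)) {
    cat(sprintf(", %d replicates (SE %.3g, seed %s)",
                x$n_reps, x$std_error, format(x$seed)))
  }
  cat("\n")
  invisible(x)
}

#' Exact group accuracy under a quorum rule
#'
#' Computes group accuracy from binomial tails, with no simulation error.
#' In state `+` each voter votes `+1` with probability `a_plus`, so the
#' group is correct with probability `P(K > q n)`; in state `-` each voter
#' votes `+1` with probability `1 - a_minus`, so the group is correct with
#' the complementary probability. Overall accuracy weights the two by the
#' prior.
#'
#' @param point An [operating_point()].
#' @param p Prior probability of state `+`, strictly in (0, 1).
#' @param rule A [group_rule()].
#' @return A `group_accuracy` object (`method = "exact"`), with fields
#'   `accuracy`, `acc_plus`, `acc_minus`.
#' @examples
#' pt <- optimal_operating_point(
#'   decision_ecology(0, 1, 1, p = 0.9, c_fp = 4, c_fn = 1))
#' group_accuracy_exact(pt, p = 0.9, group_rule(1001, q = 0.5))  # ~ 0.9
#' group_accuracy_exact(pt, p = 0.9, group_rule(1001, q = 0.7))  # ~ 1
#' @export
group_accuracy_exact <- function(point, p, rule) {
  point <- as_operating_point(point)
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p < 1,
            inherits(rule, "group_rule"))
  acc_plus <- p_choose_plus(point$a_plus, rule)
  acc_minus <- 1 - p_choose_plus(1 - point$a_minus, rule)
  group_accuracy_result(
    accuracy = p * acc_plus + (1 - p) * acc_minus,
    acc_plus = acc_plus, acc_minus = acc_minus, p = p,
    method = "exact", n = rule$n, q = rule$q, point = point
  )
}

#' Monte Carlo group accuracy under a quorum rule
#'
#' Each replicate draws the true state (Bernoulli `p`), draws the `+1`-vote
#' count from the state-conditional binomial, applies the quorum rule
#' (random tie-break under `"coin_flip"`), and scores the group decision
#' against the state. Per-state accuracies are replicate means; the overall
#' accuracy is their prior-weighted combination, so it decomposes over
#' states exactly as the exact computation does. The standard error is the
#' binomial SE of the raw replicate mean. Identical seeds give identical
#' results.
#'
#' Votes are drawn directly from the per-state correctness probabilities
#' rather than from cue values; the two are equivalent by construction
#' (see [simulate_votes_from_cues()] for the cue-level cross-check path).
#'
#' @inheritParams group_accuracy_exact
#' @param n_reps Number of replicate group decisions (>= 1).
#' @param seed Integer seed for the replicate RNG stream.
#' @return A `group_accuracy` object (`method = "simulated"`) with
#'   `std_error`, `n_reps` and `seed` recorded.
#' @export
group_accuracy_sim <- function(point, p, rule, n_reps = 10000L, seed) {
  point <- as_operating_point(point)
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p < 1,
            inherits(rule, "group_rule"),
            is.numeric(n_reps), length(n_reps) == 1L, n_reps >= 1)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` must be supplied as a single integer for reproducibility",
         call. = FALSE)
  }
  n_reps <- as.integer(n_reps)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  state_plus <- stats::rbinom(n_reps, 1L, p) == 1L
  v <- ifelse(state_plus, point$a_plus, 1 - point$a_minus)
  k <- stats::rbinom(n_reps, rule$n, v)
  thr <- rule$q * rule$n
  choose_plus <- k > thr + .tie_tol
  if (abs(thr - round(thr)) < .tie_tol) {
    tie <- k == round(thr)
    if (rule$tie_policy == "coin_flip" && any(tie)) {
      choose_plus[tie] <- stats::rbinom(sum(tie), 1L, 0.5) == 1L
    }
  }
  correct <- choose_plus == state_plus

  acc_plus <- if (any(state_plus)) mean(correct[state_plus]) else NA_real_
  acc_minus <- if (any(!state_plus)) mean(correct[!state_plus]) else NA_real_
  accuracy <- if (is.na(acc_plus) || is.na(acc_minus)) {
    mean(correct)
  } else {
    p * acc_plus + (1 - p) * acc_minus
  }
  raw <- mean(correct)
  group_accuracy_result(
    accuracy = accuracy, acc_plus = acc_plus, acc_minus = acc_minus, p = p,
    method = "simulated", n = rule$n, q = rule$q, n_reps = n_reps,
    std_error = sqrt(raw * (1 - raw) / n_reps), seed = as.integer(seed),
    point = point
  )
}

#' Cue-level vote simulation (cross-check path)
#'
#' Draws raw cue values from the state-conditional Gaussians and thresholds
#' them at `x`, rather than drawing vote correctness directly. Equivalent in
#' distribution to the vote-level path used by [group_accuracy_sim()];
#' retained as an independent route for consistency checks.
#'
#' @param eco A [decision_ecology()].
#' @param x Cue threshold (vote `+1` iff cue > `x`).
#' @param state_plus Logical: the true state.
#' @param n Number of voters.
#' @return Integer count of `+1` votes.
#' @keywords internal
#' @export
simulate_votes_from_cues <- function(eco, x, state_plus, n) {
  stopifnot(inherits(eco, "decision_ecology"))
  mu <- if (state_plus) eco$mu_plus else eco$mu_minus
  sum(stats::rnorm(n, mean = mu, sd = eco$sigma) > x)
}

#' Classic Condorcet majority accuracy
#'
#' The single-error-type jury model: every voter is correct with the same
#' probability `a` regardless of state, and the group decides by simple
#' majority (`q = 1/2`). Equals [group_accuracy_exact()] with
#' `a_plus = a_minus = a` — the prior drops out.
#'
#' @param a Individual accuracy in `[0, 1]`.
#' @param n Group size.
#' @param tie_policy Tie resolution for even `n` (see [group_rule()]).
#' @return Probability that the majority vote is correct.
#' @examples
#' majority_accuracy_condorcet(0.6, 3)  # 0.648
#' @export
majority_accuracy_condorcet <- function(a, n,
                                        tie_policy = c("coin_flip",
                                                       "choose_minus")) {
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0, a <= 1)
  tie_policy <- match.arg(tie_policy)
  p_choose_plus(a, group_rule(n, q = 0.5, tie_policy = tie_policy))
}

#' Large-group limiting accuracy under a quorum rule
#'
#' As group size grows the vote fraction concentrates (law of large
#' numbers) on `a_plus` in state `+` and on `1 - a_minus` in state `-`, so
#' the group decision in each state becomes deterministic: correct in state
#' `+` iff `a_plus > q`, correct in state `-` iff `1 - a_minus < q`. The
#' limit is the prior-weighted sum of those indicators. For `q` strictly
#' inside the quorum interval `(1 - a_minus, a_plus)` the limit is 1; for
#' simple majority it is 1 when both state-wise accuracies exceed 1/2, and
#' `p` or `1 - p` in the mixed cases.
#'
#' `q` exactly equal to `a_plus` or `1 - a_minus` is rejected: the
#' concentration argument is uninformative there.
#'
#' @inheritParams group_accuracy_exact
#' @param q Quorum fraction.
#' @return The limiting accuracy, with attribute `per_state` — a named
#'   logical vector saying whether the group is asymptotically correct in
#'   each state.
#' @export
asymptotic_group_accuracy <- function(point, p, q) {
  point <- as_operating_point(point)
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1,
            is.numeric(q), length(q) == 1L)
  if (abs(q - point$a_plus) < .boundary_tol ||
      abs(q - (1 - point$a_minus)) < .boundary_tol) {
    stop("undefined limit: `q` coincides with a state-wise vote fraction ",
         "(a_plus or 1 - a_minus); the large-group vote share does not ",
         "separate from the quorum", call. = FALSE)
  }
  ok_plus <- point$a_plus > q
  ok_minus <- (1 - point$a_minus) < q
  structure(p * ok_plus + (1 - p) * ok_minus,
            per_state = c(plus = ok_plus, minus = ok_minus))
}

#' Optimal quorum interval
#'
#' Any quorum strictly between the false positive rate and the true
#' positive rate, `1 - a_minus < q < a_plus`, drives group accuracy to 1 as
#' group size grows: the vote share concentrates above `q` in state `+` and
#' below `q` in state `-`. The interval is non-empty exactly when the
#' operating point lies above the chance diagonal.
#'
#' @param point An [operating_point()] with `a_plus > 1 - a_minus`.
#' @return Named numeric `c(lower, upper)` — the open interval endpoints.
#' @examples
#' quorum_bounds(operating_point(0.9051, 0.3779))  # (0.6221, 0.9051)
#' @export
quorum_bounds <- function(point) {
  point <- as_operating_point(point)
  if (point$a_plus <= 1 - point$a_minus) {
    stop("operating point is on or below the chance diagonal ",
         "(a_plus <= 1 - a_minus): no quorum can drive group accuracy to ",
         "1. Such decisions should be inverted by the modeller.",
         call. = FALSE)
  }
  c(lower = 1 - point$a_minus, upper = point$a_plus)
}

#' Recommend a quorum for an operating point
#'
#' Returns the arithmetic midpoint of the optimal quorum interval together
#' with a label relating it to simple majority: `"sub_majority"` when the
#' whole interval lies below 1/2, `"super_majority"` when wholly above, and
#' `"majority_compatible"` when 1/2 lies inside the interval (simple
#' majority already drives accuracy to 1). Per-group-size optimisation of
#' the quorum is deliberately not attempted — any interior quorum achieves
#' the same large-group limit.
#'
#' @inheritParams quorum_bounds
#' @return A list with elements `q` (recommended quorum), `label`, and
#'   `bounds`.
#' @examples
#' recommend_quorum(operating_point(0.9051, 0.3779))  # super-majority
#' recommend_quorum(operating_point(0.1694, 0.9748))  # sub-majority
#' @export
recommend_quorum <- function(point) {
  b <- quorum_bounds(point)
  label <- if (b[["upper"]] <= 0.5) {
    "sub_majority"
  } else if (b[["lower"]] >= 0.5) {
    "super_majority"
  } else {
    "majority_compatible"
  }
  list(q = unname((b[["lower"]] + b[["upper"]]) / 2),
       label = label, bounds = b)
}
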