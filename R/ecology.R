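#' Define a decision ecology
#'
#' A decision ecology bundles everything that defines one binary decision
#' scenario: the two state-conditional Gaussian cue distributions, the prior
#' probability of the positive state, and a 2x2 cost structure over decision
#' outcomes. The world is in state `+` (e.g. predator present, disease
#' present) with probability `p` and in state `-` otherwise; a decision-maker
#' observes a scalar cue drawn from N(`mu_plus`, `sigma^2`) in state `+` and
#' from N(`mu_minus`, `sigma^2`) in state `-`, and must choose action `+1`
#' or `-1`.
#'
#' Costs are minimised (lower is better); a payoff matrix must be negated by
#' the caller. Errors must be strictly costlier than the correct outcome in
#' the same state (`c_fn > c_tp`, `c_fp > c_tn`), otherwise the
#' likelihood-ratio criterion is degenerate.
#'
#' `mu_plus <= mu_minus` is rejected rather than silently inverted: a cue
#' that is lower in state `+` means the states are mislabelled, and
#' relabelling is the modeller's decision, not the library's.
#'
#' @param mu_minus Mean of the cue distribution in state `-`.
#' @param mu_plus Mean of the cue distribution in state `+`; must exceed
#'   `mu_minus`.
#' @param sigma Common standard deviation of the two cue distributions
#'   (positive).
#' @param p Prior probability of state `+`, strictly inside (0, 1).
#' @param c_tp,c_tn Costs of a true positive / true negative.
#' @param c_fp,c_fn Costs of a false positive / false negative.
#'
#' @return An object of class `decision_ecology`.
#'
#' @examples
#' # the reference scenario behind the published error-region maps:
#' eco <- decision_ecology(mu_minus = 0, mu_plus = 1, sigma = 1,
#'                         p = 0.9, c_tp = 0, c_tn = 0, c_fp = 4, c_fn = 1)
#' optimal_operating_point(eco)
#' @export
decision_ecology <- function(mu_minus, mu_plus, sigma, p,
                             c_tp = 0, c_tn = 0, c_fp = 1, c_fn = 1) {
  for (nm in c("mu_minus", "mu_plus", "sigma", "p",
               "c_tp", "c_tn", "c_fp", "c_fn")) {
    v <- get(nm, inherits = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (mu_plus <= mu_minus) {
    stop("`mu_plus` must exceed `mu_minus`: the cue must be larger, on ",
         "average, in state +. If your cue is lower in state +, relabel ",
         "the states (swap + and -) rather than inverting decisions.",
         call. = FALSE)
  }
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (p <= 0 || p >= 1) {
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (c_fn <= c_tp) {
    stop("degenerate costs: `c_fn` must exceed `c_tp` (a miss must be ",
         "strictly costlier than a hit)", call. = FALSE)
  }
  if (c_fp <= c_tn) {
    stop("degenerate costs: `c_fp` must exceed `c_tn` (a false alarm must ",
         "be strictly costlier than a correct rejection)", call. = FALSE)
  }
  structure(
    list(mu_minus = mu_minus, mu_plus = mu_plus, sigma = sigma, p = p,
         c_tp = c_tp, c_tn = c_tn, c_fp = c_fp, c_fn = c_fn),
    class = "decision_ecology"
  )
}

#' @export
print.decision_ecology <- function(x, ...) {
  cat("Decision ecology\n")
  cat(sprintf("  cue:   N(%g, %g^2) in state -,  N(%g, %g^2) in state +\n",
              x$mu_minus, x$sigma, x$mu_plus, x$sigma))
  cat(sprintf("  prior: P(state +) = %g\n", x$p))
  cat(sprintf("  costs: TP=%g TN=%g FP=%g FN=%g (lower is better)\n",
              x$c_tp, x$c_tn, x$c_fp, x$c_fn))
  invisible(x)
}

#' Construct an individual operating point
#'
#' An operating point records a decision threshold (possibly `NA` when the
#' point is specified directly in ROC space) and the two state-wise
#' accuracies it induces: `a_plus`, the true positive rate, and `a_minus`,
#' the true negative rate. The false positive rate is `1 - a_minus`.
#'
#' @param a_plus Probability of a correct vote in state `+` (TPR).
#' @param a_minus Probability of a correct vote in state `-` (TNR).
#' @param threshold Cue criterion that produced the point, or `NA`.
#' @return An object of class `operating_point`.
#' @examples
#' operating_point(a_plus = 0.9051, a_minus = 0.3779)
#' @export
operating_point <- function(a_plus, a_minus, threshold = NA_real_) {
  stopifnot(is.numeric(a_plus), length(a_plus) == 1L,
            is.numeric(a_minus), length(a_minus) == 1L)
  if (a_plus < 0 || a_plus > 1 || a_minus < 0 || a_minus > 1) {
    stop("`a_plus` and `a_minus` must be probabilities in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(threshold = as.numeric(threshold),
         a_plus = as.numeric(a_plus), a_minus = as.numeric(a_minus)),
    class = "operating_point"
  )
}

#' @export
print.operating_point <- function(x, ...) {
  cat("Operating point\n")
  if (!is.na(x$threshold)) {
    cat(sprintf("  threshold x* = %.6g\n", x$threshold))
  }
  cat(sprintf("  a+ (TPR) = %.6g\n", x$a_plus))
  cat(sprintf("  a- (TNR) = %.6g   (FPR = %.6g)\n",
              x$a_minus, 1 - x$a_minus))
  invisible(x)
}

as_operating_point <- function(x) {
  if (inherits(x, "operating_point")) return(x)
  stop("expected an `operating_point`; construct one with ",
       "operating_point() or optimal_operating_point()", call. = FALSE)
}
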