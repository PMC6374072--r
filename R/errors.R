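# tolerance below which a defining inequality is treated as an equality
.boundary_tol <- 1e-12

#' Classic Condorcet prediction from a single accuracy
#'
#' Under the single-error-type jury model, majority-group accuracy is
#' predicted to converge to 1 when individual accuracy exceeds 1/2 and to 0
#' when it falls below; exactly 1/2 (within tolerance) is indeterminate.
#'
#' @param a Expected individual accuracy in `[0, 1]`.
#' @param tol Equality tolerance.
#' @return `"to_one"`, `"to_zero"`, or `"indeterminate"`.
#' @export
condorcet_prediction <- function(a, tol = .boundary_tol) {
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0, a <= 1)
  if (abs(a - 0.5) < tol) "indeterminate" else if (a > 0.5) "to_one" else "to_zero"
}

# Direct evaluation of the error-type conditions as prior-probability
# bounds, the algebraic route (independent of the constructive
# limit-vs-accuracy comparison used by the classifier):
#   mixed sign pattern required throughout (a+ and a- on opposite sides
#   of 1/2, above the chance diagonal);
#   Ia:  expected accuracy a > 1/2, i.e. p (a+ - a-) + a- > 1/2;
#   Ib:  Ia and the majority limit falls below a, i.e.
#        p < a- / (1 - a+ + a-)        when a+ > 1/2 > a-,
#        p > (1 - a-) / (1 + a+ - a-)  when a+ < 1/2 < a-;
#   II:  expected accuracy a < 1/2, i.e.
#        p < (1/2 - a-) / (a+ - a-)    when a+ > 1/2 > a-,
#        p > (1/2 - a-) / (a+ - a-)    when a+ < 1/2 < a-.
#' Error-type conditions as explicit prior bounds
#'
#' Evaluates, for each `(a_plus, a_minus, p)` triple, whether the
#' conditions defining the three Condorcet predictive errors hold, using
#' the closed-form prior-probability bounds rather than comparing computed
#' limits. Vectorised; used as an independent cross-check of
#' [classify_scenario()].
#'
#' @param a_plus,a_minus State-wise accuracies (vectorised).
#' @param p Prior probability of state `+` (vectorised).
#' @return A data.frame of logicals with columns `ia`, `ib`, `ii`
#'   (`ib` implies `ia`; all `FALSE` outside the mixed-sign regions).
#' @export
condorcet_error_conditions <- function(a_plus, a_minus, p) {
  n <- max(length(a_plus), length(a_minus), length(p))
  a_plus <- rep_len(a_plus, n); a_minus <- rep_len(a_minus, n)
  p <- rep_len(p, n)
  above <- a_plus > 1 - a_minus
  hi_lo <- above & a_plus > 0.5 & a_minus < 0.5
  lo_hi <- above & a_plus < 0.5 & a_minus > 0.5
  mixed <- hi_lo | lo_hi
  a <- p * a_plus + (1 - p) * a_minus
  ia <- mixed & a > 0.5
  ib <- ia & ((hi_lo & p < a_minus / (1 - a_plus + a_minus)) |
              (lo_hi & p > (1 - a_minus) / (1 + a_plus - a_minus)))
  ii <- mixed & ((hi_lo & p < (0.5 - a_minus) / (a_plus - a_minus)) |
                 (lo_hi & p > (0.5 - a_minus) / (a_plus - a_minus)))
  data.frame(ia = ia, ib = ib, ii = ii)
}

# Vectorised constructive classifier; returns a character vector over the
# levels NONE / ERROR_IA / ERROR_IB / ERROR_II / BOUNDARY / BELOW_CHANCE.
.classify_vec <- function(a_plus, a_minus, p, tol = .boundary_tol) {
  n <- max(length(a_plus), length(a_minus), length(p))
  a_plus <- rep_len(a_plus, n); a_minus <- rep_len(a_minus, n)
  p <- rep_len(p, n)
  a <- p * a_plus + (1 - p) * a_minus
  limit <- p * (a_plus > 0.5) + (1 - p) * (1 - a_minus < 0.5)

  out <- character(n)
  boundary <- abs(a_plus - (1 - a_minus)) < tol |
    abs(a_plus - 0.5) < tol | abs(a_minus - 0.5) < tol
  below <- !boundary & a_plus < 1 - a_minus
  both_good <- !boundary & !below & a_plus > 0.5 & a_minus > 0.5
  mixed <- !boundary & !below & !both_good
  # within the mixed-sign region two more comparisons can sit on an edge
  boundary <- boundary | (mixed & (abs(a - 0.5) < tol | abs(limit - a) < tol))
  mixed <- mixed & out == "" & !boundary

  out[boundary] <- "BOUNDARY"
  out[below] <- "BELOW_CHANCE"
  out[both_good] <- "NONE"
  out[mixed & a < 0.5] <- "ERROR_II"
  out[mixed & a > 0.5 & limit < a] <- "ERROR_IB"
  out[mixed & out == ""] <- "ERROR_IA"
  out
}

#' Classify a decision scenario by Condorcet predictive error
#'
#' Determines which, if any, of the three predictive errors Condorcet-style
#' majority reasoning makes for a group of voters at the given operating
#' point:
#'
#' * `NONE` — both state-wise accuracies exceed 1/2; simple majority drives
#'   group accuracy to 1 and the classic prediction is correct.
#' * `ERROR_IA` — expected individual accuracy exceeds 1/2, so convergence
#'   to 1 is predicted, but the majority limit is `p` or `1 - p` instead
#'   (still at or above individual accuracy).
#' * `ERROR_IB` — as Ia, and the limit additionally falls below expected
#'   individual accuracy: majority groups are worse than individuals.
#' * `ERROR_II` — expected individual accuracy is below 1/2, so convergence
#'   to 0 is predicted, but the limit is positive (`p` or `1 - p`).
#' * `BELOW_CHANCE` — the point lies below the chance diagonal; decisions
#'   should be inverted and no error type applies.
#' * `BOUNDARY` — a defining inequality is an equality within `tol`
#'   (a measure-zero set).
#'
#' The reported class is the most specific: `ERROR_IB` cells also satisfy
#' the Ia conditions. The complementary refinement of `ERROR_II` ("groups
#' predicted to collapse but actually better than individuals") is
#' algebraically impossible; see [no_error_iib_search()].
#'
#' @param point An [operating_point()].
#' @param p Prior probability of state `+`.
#' @param tol Equality tolerance for boundary detection.
#' @return A list with `class` (string as above), `prediction`
#'   ([condorcet_prediction()] of the expected accuracy), `actual_limit`
#'   (large-group majority accuracy, `NA` for boundary cases),
#'   `expected_accuracy`, and the inputs.
#' @examples
#' classify_scenario(operating_point(0.9051, 0.3779), p = 0.9)  # ERROR_IA
#' classify_scenario(operating_point(0.1694, 0.9748), p = 0.7)  # ERROR_II
#' @export
classify_scenario <- function(point, p, tol = .boundary_tol) {
  point <- as_operating_point(point)
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  cls <- .classify_vec(point$a_plus, point$a_minus, p, tol = tol)
  a <- expected_accuracy(p, point)
  limit <- if (cls %in% c("BOUNDARY")) {
    NA_real_
  } else {
    as.numeric(asymptotic_group_accuracy(point, p, q = 0.5))
  }
  list(class = cls,
       prediction = condorcet_prediction(a, tol = tol),
       actual_limit = limit,
       expected_accuracy = a,
       point = point, p = p)
}

#' Search for the impossible "Error IIb"
#'
#' If majority-group accuracy is predicted to collapse to 0 (expected
#' individual accuracy below 1/2), can the group limit nevertheless exceed
#' individual accuracy? Algebra says no; this routine searches for a
#' counterexample by sampling `(a_plus, a_minus, p)` uniformly above the
#' chance diagonal and returning every sample where the Error II conditions
#' hold *and* the majority limit exceeds expected accuracy. The contract is
#' that the returned set is empty.
#'
#' @param n_samples Number of random triples to test.
#' @param seed RNG seed.
#' @return A data.frame of counterexamples (columns `a_plus`, `a_minus`,
#'   `p`, `limit`, `expected_accuracy`), expected to have zero rows.
#' @export
no_error_iib_search <- function(n_samples, seed = 1L) {
  stopifnot(is.numeric(n_samples), length(n_samples) == 1L, n_samples >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n_samples <- as.integer(n_samples)
  a_plus <- stats::runif(n_samples)
  a_minus <- stats::runif(n_samples)
  # reflect points below the chance diagonal onto the achievable half
  flip <- a_plus < 1 - a_minus
  tmp <- a_plus[flip]
  a_plus[flip] <- 1 - a_minus[flip]
  a_minus[flip] <- 1 - tmp
  p <- stats::runif(n_samples)

  a <- p * a_plus + (1 - p) * a_minus
  limit <- p * (a_plus > 0.5) + (1 - p) * (1 - a_minus < 0.5)
  mixed <- (a_plus > 0.5 & a_minus < 0.5) | (a_plus < 0.5 & a_minus > 0.5)
  err_ii <- mixed & a < 0.5
  hit <- err_ii & limit > a
  data.frame(a_plus = a_plus[hit], a_minus = a_minus[hit], p = p[hit],
             limit = limit[hit], expected_accuracy = a[hit])
}

#' Map Condorcet error regions over prior and cost ratio
#'
#' For each cell of a (prior probability, cost-ratio) grid, builds the
#' decision ecology with `c_fp = ratio` and `c_fn = 1` (correct outcomes
#' cost 0 by default), computes the signal-detection-optimal operating
#' point, classifies the scenario, and records whether the requested error
#' type applies. Because each point is optimal, no cell can be below the
#' chance diagonal.
#'
#' The default grids cover priors linearly on (0.005, 0.995) and cost
#' ratios log-spaced on `[1e-2, 1e2]`; ratios above 1 mean a false positive
#' is costlier than a false negative.
#'
#' @param template Ecology parameters shared by all cells: a list with
#'   elements `mu_minus`, `mu_plus`, `sigma` and optionally `c_tp`, `c_tn`,
#'   `c_fn` (defaults 0, 0, 1).
#' @param p_grid Strictly increasing priors in (0, 1).
#' @param ratio_grid Strictly increasing positive cost ratios
#'   (`c_fp / c_fn`).
#' @param which Which error type to mark: `"ia"` (Ia conditions, including
#'   the Ib refinement), `"ib"`, `"ii"`, or `"any"` (at least one error —
#'   also the set where simple majority voting is suboptimal).
#' @return An object of class `error_region_map`: a list with the grids,
#'   `which`, the `template`, and `cells`, a long-format data.frame with
#'   columns `p`, `ratio`, `a_plus`, `a_minus`, `error_class`, `marked`.
#' @examples
#' m <- region_map(p_grid = seq(0.1, 0.9, by = 0.2),
#'                 ratio_grid = c(0.25, 1, 4), which = "any")
#' subset(m$cells, marked)
#' @export
region_map <- function(template = list(mu_minus = 0, mu_plus = 1, sigma = 1),
                       p_grid = seq(0.005, 0.995, length.out = 201),
                       ratio_grid = 10^seq(-2, 2, length.out = 201),
                       which = c("any", "ia", "ib", "ii")) {
  which <- match.arg(which)
  stopifnot(length(p_grid) >= 1, length(ratio_grid) >= 1,
            all(diff(p_grid) > 0), all(diff(ratio_grid) > 0),
            all(p_grid > 0 & p_grid < 1), all(ratio_grid > 0))
  tpl <- utils::modifyList(list(c_tp = 0, c_tn = 0, c_fn = 1), template)
  for (nm in c("mu_minus", "mu_plus", "sigma")) {
    if (is.null(tpl[[nm]])) stop("template must supply `", nm, "`",
                                 call. = FALSE)
  }
  if (tpl$mu_plus <= tpl$mu_minus || tpl$sigma <= 0) {
    stop("template must satisfy mu_plus > mu_minus and sigma > 0",
         call. = FALSE)
  }

  grid <- expand.grid(p = p_grid, ratio = ratio_grid,
                      KEEP.OUT.ATTRS = FALSE)
  beta <- (1 - grid$p) * (grid$ratio - tpl$c_tn) /
    (grid$p * (tpl$c_fn - tpl$c_tp))
  x_star <- (tpl$mu_plus + tpl$mu_minus) / 2 +
    tpl$sigma^2 * log(beta) / (tpl$mu_plus - tpl$mu_minus)
  a_plus <- stats::pnorm(x_star, tpl$mu_plus, tpl$sigma, lower.tail = FALSE)
  a_minus <- stats::pnorm(x_star, tpl$mu_minus, tpl$sigma)
  cls <- .classify_vec(a_plus, a_minus, grid$p)
  marked <- switch(which,
    ia = cls %in% c("ERROR_IA", "ERROR_IB"),
    ib = cls == "ERROR_IB",
    ii = cls == "ERROR_II",
    any = cls %in% c("ERROR_IA", "ERROR_IB", "ERROR_II")
  )
  cells <- data.frame(p = grid$p, ratio = grid$ratio,
                      a_plus = a_plus, a_minus = a_minus,
                      error_class = cls, marked = marked)
  structure(list(p_grid = p_grid, ratio_grid = ratio_grid, which = which,
                 template = tpl, cells = cells),
            class = "error_region_map")
}

#' @export
print.error_region_map <- function(x, ...) {
  cat(sprintf("Error region map (`%s`): %d x %d cells, %d marked (%.1f%%)\n",
              x$which, length(x$p_grid), length(x$ratio_grid),
              sum(x$cells$marked), 100 * mean(x$cells$marked)))
  cat(sprintf("  priors %g..%g, cost ratios %g..%g\n",
              min(x$p_grid), max(x$p_grid),
              min(x$ratio_grid), max(x$ratio_grid)))
  print(table(x$cells$error_class))
  invisible(x)
}
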