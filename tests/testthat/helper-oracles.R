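# Independent oracles used to cross-check the implementation. These are
# deliberately written from raw arithmetic (pnorm tails, explicit vote-vector
# enumeration) and never call the code paths they validate.

# Dense-grid minimiser of expected decision cost over cue thresholds.
oracle_grid_threshold <- function(mu_minus, mu_plus, sigma, p,
                                  c_tp, c_tn, c_fp, c_fn,
                                  n_grid = 1e4,
                                  lo = mu_minus - 6 * sigma,
                                  hi = mu_plus + 6 * sigma) {
  x <- seq(lo, hi, length.out = n_grid)
  a_plus <- pnorm(x, mu_plus, sigma, lower.tail = FALSE)
  a_minus <- pnorm(x, mu_minus, sigma)
  cost <- p * (a_plus * c_tp + (1 - a_plus) * c_fn) +
    (1 - p) * (a_minus * c_tn + (1 - a_minus) * c_fp)
  list(threshold = x[which.min(cost)], cost = min(cost), grid_costs = cost,
       grid = x)
}

# Brute-force probability that the group chooses +, enumerating all 2^n
# vote vectors (feasible for n <= ~14).
oracle_enum_choose_plus <- function(v, n, q, tie_policy = "coin_flip") {
  total <- 0
  thr <- q * n
  for (i in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(i))[seq_len(n)]
    k <- sum(bits)
    prob <- prod(ifelse(bits == 1L, v, 1 - v))
    if (k > thr + 1e-9) {
      total <- total + prob
    } else if (abs(thr - round(thr)) < 1e-9 && k == round(thr) &&
               tie_policy == "coin_flip") {
      total <- total + 0.5 * prob
    }
  }
  total
}

# Random valid decision ecology (errors strictly costlier than correct
# outcomes, distinct cue means).
random_ecology <- function() {
  mu_minus <- runif(1, -2, 2)
  c_tp <- runif(1, -1, 1)
  c_tn <- runif(1, -1, 1)
  decision_ecology(
    mu_minus = mu_minus,
    mu_plus = mu_minus + runif(1, 0.2, 3),
    sigma = runif(1, 0.3, 2),
    p = runif(1, 0.05, 0.95),
    c_tp = c_tp,
    c_tn = c_tn,
    c_fp = c_tn + runif(1, 0.1, 5),
    c_fn = c_tp + runif(1, 0.1, 5)
  )
}
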