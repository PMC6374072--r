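# Reference ecologies used throughout: the published illustrative scenarios
# with mu- = 0, mu+ = sigma = 1, c_tp = c_tn = 0, c_fn = 1.
eco_cfp4_p09 <- decision_ecology(0, 1, 1, p = 0.9, c_fp = 4, c_fn = 1)
eco_cfp1_p07 <- decision_ecology(0, 1, 1, p = 0.7, c_fp = 1, c_fn = 1)
eco_cfp10_p07 <- decision_ecology(0, 1, 1, p = 0.7, c_fp = 10, c_fn = 1)

test_that("likelihood-ratio criterion matches the cost/prior weighting", {
  expect_equal(lr_criterion(decision_ecology(0, 1, 1, p = 0.5)), 1)
  expect_equal(lr_criterion(eco_cfp4_p09), 4 / 9)
  expect_equal(lr_criterion(eco_cfp10_p07), 3 / 0.7)
  # beta = 1 whenever p = 1/2 and the two error penalties are equal
  expect_equal(lr_criterion(decision_ecology(-1, 2, 0.5, p = 0.5,
                                             c_tp = -2, c_tn = 1,
                                             c_fp = 4, c_fn = 1)), 1)
})

test_that("closed-form optimal threshold agrees with dense grid-search cost minimisation", {
  expect_equal(optimal_threshold(decision_ecology(0, 1, 1, p = 0.5)), 0.5)
  # frozen values: 0.5 + log(4/9) and 0.5 + log(30/7)
  expect_equal(optimal_threshold(eco_cfp4_p09), -0.31093022, tolerance = 1e-7)
  expect_equal(optimal_threshold(eco_cfp10_p07), 1.95528722, tolerance = 1e-7)

  for (eco in list(eco_cfp4_p09, eco_cfp1_p07, eco_cfp10_p07)) {
    oracle <- oracle_grid_threshold(eco$mu_minus, eco$mu_plus, eco$sigma,
                                    eco$p, eco$c_tp, eco$c_tn, eco$c_fp,
                                    eco$c_fn, n_grid = 1e6, lo = -6, hi = 7)
    expect_equal(optimal_threshold(eco), oracle$threshold, tolerance = 1e-4)
  }
})

test_that("state-wise accuracies are the Gaussian tail probabilities", {
  eco <- decision_ecology(0, 1, 1, p = 0.5)
  # ROC endpoints
  far_left <- rates_at_threshold(eco, -50)
  far_right <- rates_at_threshold(eco, 50)
  expect_equal(c(far_left$a_plus, far_left$a_minus), c(1, 0))
  expect_equal(c(far_right$a_plus, far_right$a_minus), c(0, 1))
  # symmetric midpoint: both accuracies equal Phi(1/2)
  mid <- rates_at_threshold(eco, 0.5)
  expect_equal(mid$a_plus, mid$a_minus)
  expect_equal(mid$a_plus, 0.69146246, tolerance = 1e-8)
  # published Error Ia scenario
  pt <- rates_at_threshold(eco, -0.31093022)
  expect_equal(pt$a_plus, 0.90505933, tolerance = 1e-7)
  expect_equal(pt$a_minus, 0.37792684, tolerance = 1e-7)
  # vectorised form returns one row per threshold
  sweep <- rates_at_threshold(eco, c(-1, 0, 1))
  expect_s3_class(sweep, "data.frame")
  expect_equal(nrow(sweep), 3L)
})

test_that("optimal operating points match frozen oracle values", {
  pt_a <- optimal_operating_point(eco_cfp4_p09)
  expect_equal(pt_a$a_plus, 0.90505933, tolerance = 1e-7)
  expect_equal(pt_a$a_minus, 0.37792684, tolerance = 1e-7)

  pt_e <- optimal_operating_point(eco_cfp10_p07)
  expect_equal(pt_e$a_plus, 0.16971623, tolerance = 1e-7)
  expect_equal(pt_e$a_minus, 0.97472541, tolerance = 1e-7)

  # symmetric scenario sits on the equal-accuracy diagonal
  pt_sym <- optimal_operating_point(decision_ecology(0, 1, 1, p = 0.5))
  expect_equal(pt_sym$a_plus, pt_sym$a_minus)
})

test_that("cost minimisation holds across random ecologies (grid oracle)", {
  set.seed(42)
  for (i in 1:200) {
    eco <- random_ecology()
    opt_cost <- expected_cost(eco, optimal_operating_point(eco))
    oracle <- oracle_grid_threshold(eco$mu_minus, eco$mu_plus, eco$sigma,
                                    eco$p, eco$c_tp, eco$c_tn, eco$c_fp,
                                    eco$c_fn, n_grid = 1e4)
    expect_true(all(opt_cost <= oracle$grid_costs + 1e-9))
  }
})

test_that("equal priors with equal error penalties force equal state-wise accuracies", {
  set.seed(99)
  for (i in 1:50) {
    c_tp <- runif(1, -1, 1); c_tn <- runif(1, -1, 1)
    delta <- runif(1, 0.1, 5)
    eco <- decision_ecology(runif(1, -2, 0), runif(1, 0.5, 3),
                            runif(1, 0.3, 2), p = 0.5,
                            c_tp = c_tp, c_tn = c_tn,
                            c_fp = c_tn + delta, c_fn = c_tp + delta)
    pt <- optimal_operating_point(eco)
    expect_lt(abs(pt$a_plus - pt$a_minus), 1e-10)
  }
})

test_that("optimal points lie above the chance diagonal and respond monotonically", {
  set.seed(7)
  for (i in 1:50) {
    eco <- random_ecology()
    pt <- optimal_operating_point(eco)
    # TPR > FPR, compared as upper tails so extreme thresholds stay exact
    fpr <- pnorm(pt$threshold, eco$mu_minus, eco$sigma, lower.tail = FALSE)
    if (fpr > 1e-12) {
      expect_gt(pt$a_plus, fpr)
    } else {
      expect_gte(pt$a_plus, fpr)
    }
  }
  # costlier false positives shift the criterion up, never down
  base <- function(c_fp) decision_ecology(0, 1, 1, p = 0.6, c_fp = c_fp)
  thr <- vapply(c(0.5, 1, 2, 4, 8), function(cf) optimal_threshold(base(cf)),
                numeric(1))
  expect_true(all(diff(thr) >= 0))
  # a likelier positive state shifts it down, never up
  thr_p <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(p)
    optimal_threshold(decision_ecology(0, 1, 1, p = p, c_fp = 2)),
    numeric(1))
  expect_true(all(diff(thr_p) <= 0))
})

test_that("ROC curve is a proper monotone concave sweep", {
  eco <- decision_ecology(0, 1, 1, p = 0.5)
  roc <- roc_curve(eco, n_points = 256)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(roc$tpr >= roc$fpr))
  # finite-threshold rows: FPR strictly decreasing in threshold
  inner <- roc[is.finite(roc$threshold), ]
  expect_true(all(diff(inner$threshold) < 0))
  expect_true(all(diff(inner$fpr) > 0))
  # concavity: secant slopes non-increasing in FPR
  d <- diff(inner$tpr) / diff(inner$fpr)
  expect_true(all(diff(d) <= 1e-9))
  expect_error(roc_curve(eco, n_points = 1))
})

test_that("expected accuracy is the prior-weighted mix of state-wise accuracies", {
  pt <- operating_point(0.9051, 0.3779)
  expect_equal(expected_accuracy(1, pt), pt$a_plus)
  expect_equal(expected_accuracy(0, pt), pt$a_minus)
  # equal accuracies make the prior irrelevant
  flat <- operating_point(0.73, 0.73)
  for (p in c(0.1, 0.4, 0.9)) expect_equal(expected_accuracy(p, flat), 0.73)
  pt_a <- optimal_operating_point(eco_cfp4_p09)
  expect_equal(expected_accuracy(0.9, pt_a), 0.85234608, tolerance = 1e-7)
})

test_that("expected cost evaluates the outcome-weighted objective", {
  eco0 <- decision_ecology(0, 1, 1, p = 0.3, c_tp = 0, c_tn = 0,
                           c_fp = 1e-12, c_fn = 1e-12)
  expect_equal(expected_cost(eco0, operating_point(0.5, 0.5)), 1e-12 * 0.5,
               tolerance = 1e-6)
  eco <- eco_cfp4_p09
  expect_equal(expected_cost(eco, operating_point(1, 1)),
               eco$p * eco$c_tp + (1 - eco$p) * eco$c_tn)
  # the optimum beats every threshold on a dense grid
  oracle <- oracle_grid_threshold(0, 1, 1, 0.9, 0, 0, 4, 1, n_grid = 1e5)
  expect_true(all(expected_cost(eco, optimal_operating_point(eco)) <=
                    oracle$grid_costs + 1e-12))
})
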