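test_that("pooled SD matches the closed form and rejects bad input", {
  expect_equal(pooled_sd(3, 2, 3, 2), 2)
  expect_equal(pooled_sd(2, 1, 2, 1), 1)
  expect_equal(pooled_sd(10, 1, 20, 2), sqrt((9 * 1 + 19 * 4) / 28),
               tolerance = 1e-12)
  expect_equal(round(pooled_sd(10, 1, 20, 2), 4), 1.7423)
  expect_error(pooled_sd(1, 1, 5, 1), class = "escimap_invalid_argument")
  expect_error(pooled_sd(5, 0, 5, 1), class = "escimap_invalid_argument")
  expect_error(pooled_sd(5, -1, 5, 1), class = "escimap_invalid_argument")
})

test_that("d_p from t agrees across generic and convenience scales", {
  expect_equal(dp_from_t(0, 0.37), 0)
  expect_equal(dp_from_t(2, scale_two_sample(50, 50)), 0.4)
  expect_equal(dp_from_t(3, scale_one_sample(36)), 0.5)
  # generic form with the canonical scales reproduces the convenience forms
  for (t in c(-2.5, 0.3, 4)) {
    expect_equal(dp_from_t(t, scale_two_sample(12, 19)),
                 t * sqrt(1 / 12 + 1 / 19))
    expect_equal(dp_from_t(t, scale_one_sample(25)), t * sqrt(1 / 25))
  }
  expect_error(dp_from_t(Inf, 0.2), class = "escimap_invalid_argument")
  expect_error(dp_from_t(1, 0), class = "escimap_invalid_argument")
})

test_that("d_p via t equals the pooled-SD route on raw two-group data", {
  set.seed(11)
  for (i in 1:5) {
    x1 <- rnorm(14)
    x2 <- rnorm(23, mean = 0.4)
    sp <- pooled_sd(14, sd(x1), 23, sd(x2))
    d_direct <- (mean(x2) - mean(x1)) / sp
    tt <- t.test(x2, x1, var.equal = TRUE)$statistic
    expect_equal(dp_from_t(unname(tt), scale_two_sample(14, 23)), d_direct,
                 tolerance = 1e-10)
  }
})

test_that("bias-correction factor J behaves as documented", {
  expect_equal(correction_factor_j(10), 1 - 3 / 39)
  expect_equal(round(correction_factor_j(10), 6), 0.923077)
  expect_equal(round(correction_factor_j(2), 6), 0.571429)
  expect_lt(abs(correction_factor_j(1e6) - 1), 1e-5)
  dofs <- c(2, 5, 10, 50, 500)
  expect_true(all(diff(vapply(dofs, correction_factor_j, 0)) > 0))
  expect_true(all(vapply(dofs, correction_factor_j, 0) > 0 &
                  vapply(dofs, correction_factor_j, 0) < 1))
  # exact gamma form agrees closely with the approximation
  for (dof in c(5, 20, 100)) {
    expect_equal(correction_factor_j(dof, exact = TRUE),
                 correction_factor_j(dof), tolerance = 5e-3)
  }
  expect_error(correction_factor_j(0), class = "escimap_invalid_argument")
})

test_that("Hedges' g shrinks d_p by exactly J and preserves sign", {
  expect_equal(hedges_g(0, 10), 0)
  expect_equal(round(hedges_g(1, 10), 6), 0.923077)
  expect_equal(round(hedges_g(-0.5, 2), 6), -0.285714)
  for (d in c(-2, -0.1, 0.7, 3)) {
    for (dof in c(2, 10, 60)) {
      g <- hedges_g(d, dof)
      expect_lt(abs(g), abs(d))
      expect_equal(sign(g), sign(d))
      expect_equal(g / d, correction_factor_j(dof))
    }
  }
})

test_that("approximate SE of g matches its closed form", {
  expect_equal(se_g_approx(0, 2, 2), 1)
  expect_equal(se_g_approx(0.5, 50, 50), sqrt(100 / 2500 + 0.25 / 196))
  expect_equal(round(se_g_approx(0.5, 50, 50), 4), 0.2032)
  for (n in c(5, 20, 80)) expect_equal(se_g_approx(0, n, n), sqrt(2 / n))
  expect_error(se_g_approx(0.5, 1, 10), class = "escimap_invalid_argument")
})

test_that("noncentrality CI is symmetric for t = 0 and satisfies its defining property", {
  ci <- ncp_ci(0, dof = 30, confidence = 0.90)
  expect_equal(ci$delta_lower, -ci$delta_upper, tolerance = 1e-8)
  ci <- ncp_ci(2, dof = 40, confidence = 0.90)
  expect_equal(suppressWarnings(pt(2, 40, ncp = ci$delta_lower)), 0.95,
               tolerance = 1e-6)
  expect_equal(suppressWarnings(pt(2, 40, ncp = ci$delta_upper)), 0.05,
               tolerance = 1e-6)
  expect_true(ci$delta_lower <= 2 && 2 <= ci$delta_upper)
})

test_that("noncentrality CI matches the brute-force bisection oracle", {
  for (t in c(-3, 0, 1.5, 3)) {
    for (dof in c(5, 60)) {
      for (conf in c(0.90, 0.95)) {
        ci <- ncp_ci(t, dof, conf)
        oracle <- oracle_ncp_interval(t, dof, conf)
        expect_equal(ci$delta_lower, unname(oracle["lower"]), tolerance = 1e-4)
        expect_equal(ci$delta_upper, unname(oracle["upper"]), tolerance = 1e-4)
      }
    }
  }
})

test_that("noncentrality limits are strictly increasing in t and CIs nest", {
  ts <- seq(-2, 4, by = 0.5)
  for (dof in c(10, 98)) {
    lows <- vapply(ts, function(t) ncp_ci(t, dof, 0.90)$delta_lower, 0)
    ups <- vapply(ts, function(t) ncp_ci(t, dof, 0.90)$delta_upper, 0)
    expect_true(all(diff(lows) > 0))
    expect_true(all(diff(ups) > 0))
  }
  for (t in c(-1, 0.5, 3)) {
    narrow <- ncp_ci(t, 40, 0.90)
    wide <- ncp_ci(t, 40, 0.999)
    expect_lt(wide$delta_lower, narrow$delta_lower)
    expect_gt(wide$delta_upper, narrow$delta_upper)
  }
})

test_that("effect-size CI composes the noncentrality CI with the contrast scale", {
  sc <- scale_two_sample(50, 50)
  est <- ci_g(3, dof = 98, scale = sc, confidence = 0.90)
  ncp <- ncp_ci(3, 98, 0.90)
  expect_equal(est$ci_lower, ncp$delta_lower * sc)
  expect_equal(est$ci_upper, ncp$delta_upper * sc)
  expect_equal(est$d_p, 3 * sc)
  expect_equal(est$g, 3 * sc * correction_factor_j(98))
  # one-sample design with n = 25: limits are noncentrality limits * 0.2
  for (t in c(-1, 0, 2.4)) {
    est1 <- ci_g(t, dof = 24, scale = scale_one_sample(25))
    ncp1 <- ncp_ci(t, 24, 0.90)
    expect_equal(est1$ci_lower, ncp1$delta_lower * 0.2)
    expect_equal(est1$ci_upper, ncp1$delta_upper * 0.2)
  }
  # symmetric interval about 0 for t = 0
  est0 <- ci_g(0, dof = 30, scale = 0.2, confidence = 0.90)
  expect_equal(est0$ci_lower, -est0$ci_upper, tolerance = 1e-8)
  # CI limits are not bias-corrected: the point estimate is shrunk by J,
  # the limits are pure noncentrality limits times the scale
  expect_lt(est$g, est$d_p)
  expect_equal(est$ci_upper / ncp$delta_upper, sc)
})

test_that("CI lower bound above zero corresponds exactly to one-sided significance", {
  for (t in c(1.5, 2.2, 3.1, 4)) {
    for (dof in c(20, 65, 200)) {
      for (alpha in c(0.05, 0.01, 0.001)) {
        est <- ci_g(t, dof, scale = 0.2, confidence = 1 - 2 * alpha)
        p_one <- 1 - pt(t, dof)
        expect_equal(est$ci_lower > 0, p_one < alpha,
                     info = sprintf("t=%g dof=%d alpha=%g", t, dof, alpha))
      }
    }
  }
})

test_that("exact CI achieves nominal coverage for the noncentral-t pivot", {
  # two-sample design n = 50 per group, true standardized effect 0.5:
  # t is exactly noncentral t with ncp = delta / scale
  n_rep <- 10000
  sc <- scale_two_sample(50, 50)
  set.seed(202)
  tvals <- rt(n_rep, df = 98, ncp = 0.5 / sc)
  covered <- vapply(tvals, function(t) {
    ci <- ncp_ci(t, 98, 0.90)
    ci$delta_lower * sc <= 0.5 && 0.5 <= ci$delta_upper * sc
  }, NA)
  p_hat <- mean(covered)
  mc_se <- sqrt(0.9 * 0.1 / n_rep)
  expect_lt(abs(p_hat - 0.90), 3 * mc_se)
})

test_that("inferiority and equivalence use the documented boundary conventions", {
  est <- function(lo, up) structure(list(ci_lower = lo, ci_upper = up,
                                         confidence = 0.9),
                                    class = "effect_size_estimate")
  expect_true(inferiority_test(est(0.1, 0.4), 0.5))
  expect_false(inferiority_test(est(0.1, 0.6), 0.5))
  expect_false(inferiority_test(est(0.1, 0.5), 0.5))  # touching the bound
  expect_true(equivalence_test(est(-0.1, 0.1), -0.3, 0.3))
  expect_false(equivalence_test(est(-0.4, 0.1), -0.3, 0.3))
  expect_false(equivalence_test(est(-0.3, 0.1), -0.3, 0.3))  # not strict
  expect_error(equivalence_test(est(0, 0.1), 0.3, -0.3),
               class = "escimap_invalid_argument")
  expect_error(inferiority_test(list(ci_lower = 1, ci_upper = 0), 0.5),
               class = "escimap_invalid_argument")
})
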