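#' Pooled standard deviation of two groups
#'
#' Combines two within-group standard deviations into the pooled estimate
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2) / (n_1+n_2-2)}}, the
#' denominator of the standardized mean difference \eqn{d_p}.
#'
#' @param n1,n2 Group sizes (integers, at least 2 each).
#' @param s1,s2 Within-group standard deviations (positive).
#' @return The pooled standard deviation, a positive scalar.
#' @examples
#' pooled_sd(10, 1, 20, 2)
#' @export
pooled_sd <- function(n1, s1, n2, s2) {
  n1 <- check_count(n1, "n1", min = 2L)
  n2 <- check_count(n2, "n2", min = 2L)
  check_scalar_number(s1, "s1")
  check_scalar_number(s2, "s2")
  if (s1 <= 0 || s2 <= 0) abort_invalid("standard deviations must be positive")
  sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
}

#' Contrast standard-error scale for canonical designs
#'
#' The factor converting a t statistic into a standardized effect size:
#' `sqrt(1/n1 + 1/n2)` for a two-sample comparison, `sqrt(1/n)` for a
#' one-sample test. Both are special cases of the general GLM scale
#' `sqrt(c'(X'X)^-c)` computed by [contrast_variance_scale()].
#'
#' @param n,n1,n2 Group sizes (at least 2).
#' @return A positive scalar scale.
#' @seealso [contrast_variance_scale()]
#' @export
scale_two_sample <- function(n1, n2) {
  n1 <- check_count(n1, "n1", min = 2L)
  n2 <- check_count(n2, "n2", min = 2L)
  sqrt(1 / n1 + 1 / n2)
}

#' @rdname scale_two_sample
#' @export
scale_one_sample <- function(n) {
  n <- check_count(n, "n", min = 2L)
  sqrt(1 / n)
}

#' Standardized effect size from a t statistic
#'
#' Converts a t statistic into the (uncorrected) standardized effect size
#' \eqn{d_p = t \cdot \mathrm{scale}}, where the scale is
#' `sqrt(c'(X'X)^-c)` for the contrast that produced t. For the canonical
#' designs this reduces to `t * sqrt(1/n1 + 1/n2)` (two-sample) and
#' `t * sqrt(1/n)` (one-sample).
#'
#' @param t A single finite t statistic.
#' @param scale The contrast standard-error scale (positive), e.g. from
#'   [scale_two_sample()], [scale_one_sample()] or [contrast_variance_scale()].
#' @return The standardized effect size d_p.
#' @export
dp_from_t <- function(t, scale) {
  check_scalar_number(t, "t")
  check_scalar_number(scale, "scale")
  if (scale <= 0) abort_invalid("`scale` must be positive")
  t * scale
}

#' Small-sample bias-correction factor J
#'
#' The standardized mean difference d_p overestimates the population effect
#' in small samples. Hedges' correction factor shrinks it towards zero:
#' the default is the widely used approximation `J = 1 - 3/(4*dof - 1)`;
#' `exact = TRUE` evaluates the exact gamma-function form
#' \eqn{J = \Gamma(\nu/2) / (\sqrt{\nu/2}\,\Gamma((\nu-1)/2))} (computed on
#' the log scale for numerical stability).
#'
#' @param dof Degrees of freedom used to estimate the standard deviation
#'   (positive integer).
#' @param exact Use the exact gamma form instead of the approximation.
#' @return J, a value in (0, 1), increasing in `dof` with limit 1.
#' @examples
#' correction_factor_j(10)
#' correction_factor_j(10, exact = TRUE)
#' @export
correction_factor_j <- function(dof, exact = FALSE) {
  dof <- check_count(dof, "dof", min = 1L)
  if (exact) {
    if (dof == 1L) abort_invalid("exact J requires dof >= 2")
    exp(lgamma(dof / 2) - lgamma((dof - 1) / 2)) / sqrt(dof / 2)
  } else {
    1 - 3 / (4 * dof - 1)
  }
}

#' Hedges' g: bias-corrected standardized effect size
#'
#' @param d_p Uncorrected standardized effect size (e.g. from [dp_from_t()]).
#' @param dof Degrees of freedom of the variance estimate.
#' @param exact Passed to [correction_factor_j()].
#' @return g = d_p * J(dof). Smaller in magnitude than d_p, same sign.
#' @export
hedges_g <- function(d_p, dof, exact = FALSE) {
  check_scalar_number(d_p, "d_p")
  d_p * correction_factor_j(dof, exact = exact)
}

#' Approximate standard error of Hedges' g (two-sample design)
#'
#' Normal-approximation standard error
#' \eqn{se_g = \sqrt{(n_1+n_2)/(n_1 n_2) + g^2 / (2(n_1+n_2-2))}}.
#' This is offered only as a fast approximate alternative (interval
#' `g +/- z * se_g`); the package's standard confidence intervals use the
#' exact noncentral-t inversion of [ci_g()], which is what all map-level
#' functions call.
#'
#' @param g Hedges' g.
#' @param n1,n2 Group sizes (at least 2).
#' @return The approximate standard error (positive scalar).
#' @seealso [ci_g()] for the exact interval.
#' @export
se_g_approx <- function(g, n1, n2) {
  check_scalar_number(g, "g")
  n1 <- check_count(n1, "n1", min = 2L)
  n2 <- check_count(n2, "n2", min = 2L)
  sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2 - 2)))
}

# Root-finding on the noncentrality parameter: find delta such that
# pt(t, dof, ncp = delta) == target. The CDF is strictly decreasing in delta,
# so the bracket [t - k*sqrt(dof), t + k*sqrt(dof)] is expanded (k doubled)
# until the target is straddled.
solve_ncp <- function(t, dof, target, tol = 1e-6) {
  f <- function(delta) suppressWarnings(stats::pt(t, dof, ncp = delta)) - target
  k <- 1
  lo <- t - k * sqrt(dof)
  hi <- t + k * sqrt(dof)
  for (i in 1:60) {
    flo <- f(lo)
    fhi <- f(hi)
    if (flo >= 0 && fhi <= 0) break
    k <- 2 * k
    lo <- t - k * sqrt(dof)
    hi <- t + k * sqrt(dof)
    if (i == 60L) {
      abort_numerical("failed to bracket the noncentrality root for t = ", t,
                      ", dof = ", dof, ", target = ", target,
                      " after 60 bracket expansions")
    }
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  if (abs(f(root)) > tol) {
    abort_numerical("noncentrality root residual ", abs(f(root)),
                    " exceeds tolerance ", tol, " (t = ", t, ", dof = ", dof, ")")
  }
  root
}

#' Confidence interval for the noncentrality parameter of the t distribution
#'
#' Given an observed t statistic, treats t as the natural estimate of the
#' noncentrality parameter Delta of the noncentral t distribution and inverts
#' the CDF to obtain an exact two-sided confidence interval:
#' `delta_lower` solves `F(t; dof, Delta) = 1 - alpha/2` and `delta_upper`
#' solves `F(t; dof, Delta) = alpha/2`, with `alpha = 1 - confidence`.
#' Because the standardized effect size is a monotone function of Delta,
#' these limits map directly onto effect-size confidence limits (see
#' [ci_g()]).
#'
#' @param t Observed t statistic (finite scalar).
#' @param dof Degrees of freedom (positive integer).
#' @param confidence Two-sided confidence level in (0, 1); default 0.90, the
#'   level conventionally used for equivalence testing.
#' @param tol Maximum allowed CDF residual at the returned roots.
#' @return An object of class `ncp_interval`: a list with `delta_lower`,
#'   `delta_upper` and `confidence`. Always `delta_lower <= t <= delta_upper`.
#' @examples
#' ncp_ci(3, dof = 60, confidence = 0.95)
#' @export
ncp_ci <- function(t, dof, confidence = 0.90, tol = 1e-6) {
  check_scalar_number(t, "t")
  dof <- check_count(dof, "dof", min = 1L)
  confidence <- check_fraction(confidence, "confidence")
  alpha <- 1 - confidence
  out <- list(
    delta_lower = solve_ncp(t, dof, 1 - alpha / 2, tol = tol),
    delta_upper = solve_ncp(t, dof, alpha / 2, tol = tol),
    confidence = confidence
  )
  class(out) <- "ncp_interval"
  out
}

#' @export
print.ncp_interval <- function(x, ...) {
  cat(sprintf("Noncentrality parameter %g%% CI: [%.4f, %.4f]\n",
              100 * x$confidence, x$delta_lower, x$delta_upper))
  invisible(x)
}

#' Hedges' g with its exact noncentral-t confidence interval
#'
#' The full scalar pipeline: d_p = t * scale, g = d_p * J(dof), and the
#' confidence limits obtained by scaling the noncentrality-parameter limits
#' of [ncp_ci()] by the same contrast scale. The limits are deliberately
#' *not* bias-corrected: the noncentral t distribution at the correct
#' degrees of freedom already yields a valid interval, and multiplying the
#' limits by J would break the correspondence between the interval excluding
#' zero and the t test being significant.
#'
#' @inheritParams ncp_ci
#' @param scale Contrast standard-error scale `sqrt(c'(X'X)^-c)` (positive);
#'   see [scale_two_sample()], [scale_one_sample()],
#'   [contrast_variance_scale()].
#' @param exact Use the exact gamma form of the correction factor J.
#' @return An object of class `effect_size_estimate`: a list with fields
#'   `d_p`, `g`, `ci_lower`, `ci_upper`, `confidence`, `dof`, `scale`.
#' @examples
#' # two-sample design, 50 subjects per group
#' ci_g(t = 3, dof = 98, scale = scale_two_sample(50, 50))
#' @export
ci_g <- function(t, dof, scale, confidence = 0.90, tol = 1e-6, exact = FALSE) {
  check_scalar_number(scale, "scale")
  if (scale <= 0) abort_invalid("`scale` must be positive")
  ncp <- ncp_ci(t, dof, confidence, tol = tol)
  d_p <- dp_from_t(t, scale)
  out <- list(
    d_p = d_p,
    g = hedges_g(d_p, dof, exact = exact),
    ci_lower = ncp$delta_lower * scale,
    ci_upper = ncp$delta_upper * scale,
    confidence = confidence,
    dof = as.integer(dof),
    scale = scale
  )
  class(out) <- "effect_size_estimate"
  out
}

#' @export
print.effect_size_estimate <- function(x, ...) {
  cat(sprintf("Hedges' g = %.4f (d_p = %.4f), %g%% CI [%.4f, %.4f], dof = %d\n",
              x$g, x$d_p, 100 * x$confidence, x$ci_lower, x$ci_upper, x$dof))
  invisible(x)
}

# Rank and row-space tooling shared by contrast_variance_scale and glm_dof.
design_svd <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X) || any(!is.finite(X))) {
    abort_invalid("design matrix must be numeric and finite")
  }
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  list(X = X, d = sv$d[keep], v = sv$v[, keep, drop = FALSE],
       rank = sum(keep))
}

#' GLM contrast variance scale sqrt(c'(X'X)^-c)
#'
#' The factor that converts a GLM contrast t statistic into a standardized
#' effect size. Computed from the singular value decomposition of the design
#' matrix with tolerance-based rank determination, so rank-deficient designs
#' (e.g. two group indicators plus an intercept) are handled through the
#' pseudoinverse. For an all-ones one-sample design with contrast 1 this is
#' `sqrt(1/n)`; for two group-indicator columns with contrast (1, -1) it is
#' `sqrt(1/n1 + 1/n2)`. Mean-centered covariates orthogonal to the contrast
#' columns leave the value unchanged.
#'
#' @param X Design matrix, rows = observations.
#' @param contrast Contrast vector, length = `ncol(X)`, not all zero, and
#'   estimable (inside the row space of X).
#' @return The positive scalar `sqrt(c'(X'X)^-c)`.
#' @examples
#' contrast_variance_scale(matrix(1, 25, 1), 1)              # sqrt(1/25)
#' X <- cbind(rep(1:0, c(32, 35)), rep(0:1, c(32, 35)))
#' contrast_variance_scale(X, c(1, -1))                      # sqrt(1/32+1/35)
#' @export
contrast_variance_scale <- function(X, contrast) {
  s <- design_svd(X)
  contrast <- as.numeric(contrast)
  if (length(contrast) != ncol(s$X)) {
    abort_invalid("contrast length ", length(contrast),
                  " does not match the ", ncol(s$X), " design columns")
  }
  if (all(contrast == 0)) abort_invalid("contrast must not be all zero")
  proj <- s$v %*% crossprod(s$v, contrast)
  if (sqrt(sum((contrast - proj)^2)) > 1e-8 * sqrt(sum(contrast^2))) {
    abort_invalid("contrast is not estimable: it lies outside the row space ",
                  "of the design matrix")
  }
  sqrt(sum((crossprod(s$v, contrast) / s$d)^2))
}

#' Residual degrees of freedom of a GLM design
#'
#' `N - rank(X)` with tolerance-based rank: `n - 1` for a one-sample design,
#' `n1 + n2 - 2` for a two-sample design, decreased by one for each
#' linearly independent covariate column added.
#'
#' @inheritParams contrast_variance_scale
#' @return A positive integer.
#' @export
glm_dof <- function(X) {
  s <- design_svd(X)
  dof <- nrow(s$X) - s$rank
  if (dof <= 0) {
    abort_invalid("design has no residual degrees of freedom (N = ",
                  nrow(s$X), ", rank = ", s$rank, ")")
  }
  as.integer(dof)
}

#' Inferiority test against a single bound
#'
#' Declares the effect statistically smaller than `bound` when the upper
#' confidence limit lies strictly below it. An upper limit equal to or
#' exceeding the bound counts as *not* inferior (the interval "includes or
#' exceeds" the reference), the same boundary convention used by
#' [undecidability_map()].
#'
#' @param estimate An `effect_size_estimate` from [ci_g()] (or any list with
#'   `ci_lower`/`ci_upper`).
#' @param bound Reference effect size.
#' @return `TRUE` if the effect is established as smaller than `bound`.
#' @export
inferiority_test <- function(estimate, bound) {
  check_scalar_number(bound, "bound")
  check_estimate(estimate)
  estimate$ci_upper < bound
}

#' Equivalence test against symmetric or asymmetric bounds
#'
#' Equivalence in the two-one-sided-tests sense: established when the whole
#' confidence interval lies strictly inside `(lower_bound, upper_bound)`.
#' A confidence limit exactly on a bound does not establish equivalence.
#'
#' @inheritParams inferiority_test
#' @param lower_bound,upper_bound Equivalence bounds, `lower_bound <
#'   upper_bound`.
#' @return `TRUE` if equivalence is established.
#' @export
equivalence_test <- function(estimate, lower_bound, upper_bound) {
  check_scalar_number(lower_bound, "lower_bound")
  check_scalar_number(upper_bound, "upper_bound")
  if (lower_bound >= upper_bound) {
    abort_invalid("`lower_bound` must be strictly below `upper_bound`")
  }
  check_estimate(estimate)
  lower_bound < estimate$ci_lower && estimate$ci_upper < upper_bound
}

check_estimate <- function(estimate) {
  if (!is.list(estimate) || is.null(estimate$ci_lower) ||
      is.null(estimate$ci_upper) ||
      !is.finite(estimate$ci_lower) || !is.finite(estimate$ci_upper) ||
      estimate$ci_lower > estimate$ci_upper) {
    abort_invalid("`estimate` must carry a valid confidence interval")
  }
  invisible(estimate)
}
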