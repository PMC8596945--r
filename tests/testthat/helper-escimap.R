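# Shared fixtures and independent oracles, built in code at test time.

# Independent brute-force bisection oracle for the noncentrality-parameter
# confidence limit: solves pt(t, dof, ncp = delta) == target by plain
# bisection on a wide fixed bracket, no uniroot involved.
oracle_ncp_bisect <- function(t, dof, target, lo = -1e3, hi = 1e3,
                              iters = 80L) {
  f <- function(delta) suppressWarnings(stats::pt(t, dof, ncp = delta)) - target
  stopifnot(f(lo) > 0, f(hi) < 0)  # CDF decreasing in delta
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

oracle_ncp_interval <- function(t, dof, confidence) {
  alpha <- 1 - confidence
  c(lower = oracle_ncp_bisect(t, dof, 1 - alpha / 2),
    upper = oracle_ncp_bisect(t, dof, alpha / 2))
}

# Small deterministic t map on a given grid.
make_tmap <- function(shape = c(4, 4, 2), seed = 42, affine = diag(4)) {
  set.seed(seed)
  stat_map(array(rnorm(prod(shape)), dim = shape), affine = affine)
}

# Two-sample indicator design (group B minus group A).
make_two_sample_design <- function(n1, n2) {
  X <- cbind(rep(c(1, 0), c(n1, n2)), rep(c(0, 1), c(n1, n2)))
  design_spec(X, c(-1, 1))
}

skip_if_no_nifti <- function() {
  testthat::skip_if_not_installed("RNifti")
}
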