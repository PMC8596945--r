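# Synthetic two-group voxel data with known localized standardized effects.
# The generator emulates a single-slice two-condition comparison: per-subject
# volumes are spatially smoothed Gaussian noise, variance-renormalized so the
# per-voxel marginal SD equals noise_sd exactly, with a deterministic mean
# shift of delta * noise_sd added to group B inside hard-edged disk regions.
# The realized standardized mean difference at an effect voxel therefore
# equals the declared d in expectation.

#' Default effect layout for the demonstration slice
#'
#' Three circular effects (standardized sizes d = 0.28, 0.50, 0.50, labelled
#' I, II, III) placed along the midline row of the slice.
#'
#' @param shape Slice shape (2-element integer vector).
#' @return A list of effects, each a list with `center`, `radius`, `d` and
#'   `label`.
#' @export
default_effects <- function(shape = c(96, 96)) {
  mid <- round(shape[2] / 2)
  qx <- round(shape[1] * c(0.25, 0.50, 0.75))
  # radius scales with the grid but never lets neighbouring disks touch
  r <- max(1L, min(round(min(shape) / 16), floor((shape[1] * 0.25 - 1) / 2)))
  list(
    list(center = c(qx[1], mid), radius = r, d = 0.28, label = "I"),
    list(center = c(qx[2], mid), radius = r, d = 0.50, label = "II"),
    list(center = c(qx[3], mid), radius = r, d = 0.50, label = "III")
  )
}

effect_region <- function(shape, center, radius) {
  nd <- length(shape)
  center <- as.numeric(center)
  if (length(center) != nd) {
    abort_invalid("effect center must have ", nd, " coordinates")
  }
  if (any(center < 1) || any(center > shape)) {
    abort_invalid("effect center (", paste(center, collapse = ", "),
                  ") lies outside the grid")
  }
  grids <- lapply(seq_len(nd), function(a) seq_len(shape[a]) - center[a])
  dist2 <- array(0, dim = shape)
  for (a in seq_len(nd)) {
    shp <- rep(1L, nd); shp[a] <- shape[a]
    dist2 <- dist2 + array(rep(grids[[a]]^2,
                               each = prod(shape[seq_len(a - 1)])),
                           dim = shape)
  }
  dist2 <= radius^2
}

gaussian_kernel_matrix <- function(n, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d <- outer(seq_len(n), seq_len(n), `-`)
  K <- exp(-d^2 / (2 * sigma^2))
  K / rowSums(K)
}

# Smooth along one axis of an array by a kernel matrix; subject dimension is
# just another (unsmoothed) axis.
smooth_axis <- function(x, K, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[axis])
  m <- K %*% m
  xp <- array(m, dim = d[perm])
  aperm(xp, order(perm))
}

#' Simulate a two-group voxel study with known standardized effects
#'
#' Generates per-subject volumes for two groups on one grid. Each volume is
#' white Gaussian noise, smoothed with an isotropic Gaussian kernel and then
#' renormalized voxel-by-voxel so the marginal SD equals `noise_sd` exactly
#' (the renormalization map is computed analytically from the kernel, so the
#' declared standardized effects are realized exactly in expectation, edges
#' included). Group B additionally receives a deterministic mean shift of
#' `d * noise_sd` inside each effect region (a hard-edged disk/sphere).
#' Regeneration from the same seed and parameters is bit-identical.
#'
#' @param shape Grid shape: 2 (slice) or 3 (volume) positive integers.
#' @param effects List of effects, each with `center` (voxel coordinates),
#'   `radius` (voxels) and `d` (standardized effect size); see
#'   [default_effects()]. Regions must not overlap. `list()` for a null
#'   study.
#' @param n_per_group Subjects per group (>= 2).
#' @param noise_sd Per-voxel marginal noise SD (default 1).
#' @param smoothing_fwhm Gaussian smoothing FWHM in voxels (default 2); 0
#'   disables smoothing.
#' @param seed Integer seed governing all randomness of the study.
#' @return An object of class `simulated_study`: arrays `group_a`, `group_b`
#'   with dimensions `c(shape, 1, n_per_group)` for slices (subject last),
#'   `truth_map` (the true per-voxel standardized effect delta), `affine`,
#'   and the generating parameters.
#' @export
simulate_study <- function(shape = c(96, 96), effects = default_effects(shape),
                           n_per_group = 50, noise_sd = 1, smoothing_fwhm = 2,
                           seed = 1) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L) || any(shape < 1L)) {
    abort_invalid("`shape` must be 2 or 3 positive integers")
  }
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2L)
  check_scalar_number(noise_sd, "noise_sd")
  if (noise_sd <= 0) abort_invalid("`noise_sd` must be positive")
  check_scalar_number(smoothing_fwhm, "smoothing_fwhm")
  if (smoothing_fwhm < 0) abort_invalid("`smoothing_fwhm` must be >= 0")
  seed <- check_count(seed, "seed", min = 0L)

  truth <- array(0, dim = shape)
  occupied <- array(FALSE, dim = shape)
  for (e in effects) {
    reg <- effect_region(shape, e$center, e$radius)
    if (any(reg & occupied)) {
      abort_invalid("effect regions overlap; the ground truth would be ambiguous")
    }
    occupied <- occupied | reg
    truth[reg] <- e$d
  }

  kernels <- NULL
  if (smoothing_fwhm > 0) {
    kernels <- lapply(shape, function(n) {
      if (n > 1L) gaussian_kernel_matrix(n, smoothing_fwhm) else NULL
    })
    # Per-voxel SD of separably smoothed unit-variance noise:
    # sqrt of the tensor product of rowSums(K^2) over the smoothed axes.
    sd_factors <- lapply(seq_along(shape), function(a) {
      if (is.null(kernels[[a]])) rep(1, shape[a]) else sqrt(rowSums(kernels[[a]]^2))
    })
    sd_map <- Reduce(function(acc, a) {
      sweep_dims <- rep(1L, length(shape)); sweep_dims[a] <- shape[a]
      acc * array(rep(sd_factors[[a]], each = prod(shape[seq_len(a - 1)])),
                  dim = shape)
    }, seq_along(shape), array(1, dim = shape))
  }

  set.seed(seed)
  gen_group <- function() {
    stack <- array(stats::rnorm(prod(shape) * n_per_group, sd = noise_sd),
                   dim = c(shape, n_per_group))
    if (!is.null(kernels)) {
      for (a in seq_along(shape)) {
        if (!is.null(kernels[[a]])) stack <- smooth_axis(stack, kernels[[a]], a)
      }
      stack <- stack / array(sd_map, dim = dim(stack))
    }
    stack
  }
  group_a <- gen_group()
  group_b <- gen_group()
  group_b <- group_b + array(truth * noise_sd, dim = dim(group_b))

  to4d <- function(x) {
    if (length(shape) == 2L) {
      array(x, dim = c(shape, 1L, n_per_group))
    } else x
  }
  truth3 <- if (length(shape) == 2L) array(truth, dim = c(shape, 1L)) else truth

  structure(list(group_a = to4d(group_a), group_b = to4d(group_b),
                 truth_map = truth3, affine = diag(4),
                 n_per_group = n_per_group, seed = seed,
                 noise_sd = noise_sd, smoothing_fwhm = smoothing_fwhm,
                 shape = shape, effects = effects),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated_study: %s grid, %d subjects/group, %d effect(s), seed %d\n",
              paste(x$shape, collapse = " x "), x$n_per_group,
              length(x$effects), x$seed))
  invisible(x)
}

#' Voxel-wise two-sample t map of a simulated study
#'
#' Pooled-variance two-sample t statistic at every voxel, contrasting group B
#' minus group A, with `n1 + n2 - 2` degrees of freedom. Voxels with zero
#' pooled variance (degenerate data) become `NA`.
#'
#' @param study A [simulate_study()] result.
#' @return A [stat_map()] of t statistics (use [study_design()] for the
#'   matching design).
#' @export
two_sample_tmap <- function(study) {
  stopifnot(inherits(study, "simulated_study"))
  d4 <- dim(study$group_a)
  n <- d4[length(d4)]
  nvox <- prod(d4[-length(d4)])
  A <- matrix(study$group_a, nrow = nvox)
  B <- matrix(study$group_b, nrow = nvox)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n - 1)
  v2 <- rowSums((B - m2)^2) / (n - 1)
  sp2 <- ((n - 1) * v1 + (n - 1) * v2) / (2 * n - 2)
  tvals <- (m2 - m1) / sqrt(sp2 * (2 / n))
  tvals[sp2 <= 0] <- NA_real_
  stat_map(array(tvals, dim = d4[-length(d4)]), affine = study$affine)
}

#' Design specification matching a simulated two-group study
#'
#' Two group-indicator columns with contrast (-1, 1), i.e. group B minus
#' group A: dof = `2n - 2`, scale = `sqrt(2/n)`.
#'
#' @param study A [simulate_study()] result.
#' @return A [design_spec()].
#' @export
study_design <- function(study) {
  stopifnot(inherits(study, "simulated_study"))
  n <- study$n_per_group
  X <- cbind(a = rep(c(1, 0), c(n, n)), b = rep(c(0, 1), c(n, n)))
  design_spec(X, c(-1, 1))
}

#' Run the three-effect demonstration experiment
#'
#' Simulates the default three-effect slice (effects I, II, III with d =
#' 0.28, 0.50, 0.50), computes the two-sample t map, effect-size/CI bundles
#' at 90% and 99.9%, the one-sided p < .001 significance map, and an
#' undecidability map against the peak effect size within the detected
#' significant cluster (falling back to the in-slice maximum when nothing is
#' significant). Returns the maps plus a machine-readable summary at the
#' three effect-center voxels.
#'
#' @param n_per_group Subjects per group (the demonstration contrasts 500,
#'   where all three effects are recoverable, with 50, where they are not).
#' @param seed Simulation seed.
#' @param shape Slice shape.
#' @param alpha Uncorrected significance level for the threshold map.
#' @return A list with `study`, `tmap`, `design`, `es90`, `es999`,
#'   `sig_map`, `undecidability`, `reference` and `summary`. `summary` is a
#'   plain list (JSON-ready): per effect the center voxel, true d, estimated
#'   g, both CIs, the significance call, and the counts of significant and
#'   of nonsignificant-but-undecidable voxels inside the effect region.
#' @export
demo_experiment <- function(n_per_group = 500, seed = 1, shape = c(96, 96),
                            alpha = 0.001) {
  effects <- default_effects(shape)
  study <- simulate_study(shape = shape, effects = effects,
                          n_per_group = n_per_group, seed = seed)
  design <- study_design(study)
  tmap <- two_sample_tmap(study)
  es90 <- es_map_from_tmap(tmap, design, confidence = 0.90)
  es999 <- es_map_from_tmap(tmap, design, confidence = 0.999)
  sig <- threshold_tmap(tmap, design, alpha = alpha, sided = "one")
  # reference: the peak (maximum) g within the detected significant cluster;
  # when nothing is significant, the in-slice maximum
  sig_mask <- !is.na(sig$values) & sig$values == 1
  ref_mask <- if (any(sig_mask)) sig_mask else es90$mask
  ref <- cluster_reference(es90, ref_mask, kind = "percentile", percentile = 1)
  und <- undecidability_map(es90, ref$value, exclude_mask = FALSE)

  per_effect <- lapply(effects, function(e) {
    center <- c(e$center, 1L)[1:3]
    reg <- effect_region(shape, e$center, e$radius)
    reg3 <- array(reg, dim = dim(es90$g_map))
    sig_in <- sig$values[reg3] == 1
    und_in <- und$values[reg3] == 1
    list(
      label = e$label,
      center_voxel = as.integer(center),
      true_d = e$d,
      g = es90$g_map[matrix(center, 1)],
      ci90 = c(es90$ci_lower_map[matrix(center, 1)],
               es90$ci_upper_map[matrix(center, 1)]),
      ci999 = c(es999$ci_lower_map[matrix(center, 1)],
                es999$ci_upper_map[matrix(center, 1)]),
      significant = unname(sig$values[matrix(center, 1)] == 1),
      n_voxels = sum(reg),
      n_significant = sum(sig_in, na.rm = TRUE),
      n_undecidable_nonsig = sum(und_in & !sig_in, na.rm = TRUE)
    )
  })
  names(per_effect) <- vapply(effects, `[[`, "", "label")

  list(study = study, tmap = tmap, design = design, es90 = es90,
       es999 = es999, sig_map = sig, undecidability = und, reference = ref,
       summary = list(
         n_per_group = n_per_group, seed = seed, shape = as.integer(shape),
         dof = design$dof, scale = design$scale, alpha = alpha,
         reference_g_max = ref$value, effects = per_effect
       ))
}
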