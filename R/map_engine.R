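#' Construct a statistic map
#'
#' A `stat_map` bundles a 3-D array of voxel values with a 4x4 voxel-to-world
#' affine and a logical analysis mask on the same grid. Out-of-mask voxels are
#' stored as `NA` and stay `NA` through every downstream operation. A 2-D
#' slice is promoted to a 3-D array with a singleton third dimension.
#'
#' @param values Numeric 2-D or 3-D array.
#' @param affine 4x4 voxel-to-world transform (NIfTI convention: world
#'   coordinates of voxel index `i` are `affine %*% c(i - 1, 1)`).
#' @param mask Logical array on the same grid, or `NULL` to mask in all
#'   finite non-zero... see Details.
#' @details When `mask` is `NULL` the mask is all finite voxels (a value of
#'   zero is a legitimate statistic, so zeros are kept in-mask; masks read
#'   from file via [read_stat_map()] treat non-zero as in-mask).
#' @return An object of class `stat_map` with fields `values`, `affine`,
#'   `mask`.
#' @export
stat_map <- function(values, affine = diag(4), mask = NULL) {
  if (is.logical(values)) storage.mode(values) <- "double"
  if (!is.array(values) && is.numeric(values)) values <- as.array(values)
  nd <- length(dim(values))
  if (nd == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) {
    abort_dimension("`values` must be a 2-D or 3-D array, got ", nd,
                    " dimensions")
  }
  affine <- as_affine(affine)
  if (is.null(mask)) {
    mask <- is.finite(values)
  } else {
    if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
    if (!identical(dim(mask), dim(values))) {
      abort_dimension("mask grid ", paste(dim(mask), collapse = "x"),
                      " does not match map grid ",
                      paste(dim(values), collapse = "x"))
    }
    mask <- array(as.logical(mask) & is.finite(values), dim = dim(values))
  }
  if (!any(mask)) abort_invalid("mask contains no in-mask voxels")
  values[!mask] <- NA_real_
  structure(list(values = values, affine = affine, mask = mask),
            class = "stat_map")
}

as_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || anyNA(affine)) {
    abort_invalid("`affine` must be a 4x4 numeric matrix")
  }
  storage.mode(affine) <- "double"
  affine
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map: %s grid, %d in-mask voxels\n",
              paste(dim(x$values), collapse = " x "), sum(x$mask)))
  invisible(x)
}

#' Read a 3-D statistic volume from NIfTI
#'
#' @param path Path to a 3-D NIfTI volume (`.nii` or `.nii.gz`).
#' @param mask_path Optional NIfTI mask on the same grid; non-zero voxels are
#'   in-mask. Without a mask, all finite non-zero voxels are in-mask (zero is
#'   the background fill SPM and similar tools write outside the analysis
#'   mask).
#' @return A [stat_map()].
#' @export
read_stat_map <- function(path, mask_path = NULL) {
  img <- RNifti::readNifti(path)
  dims <- dim(img)
  if (length(dims) == 4L && dims[4] > 1L) {
    abort_dimension("`", path, "` is a 4-D volume (", paste(dims, collapse = "x"),
                    "); statistic maps must be 3-D")
  }
  if (length(dims) == 4L) dims <- dims[1:3]
  if (length(dims) > 4L || length(dims) < 2L) {
    abort_dimension("unsupported image dimensionality: ",
                    paste(dim(img), collapse = "x"))
  }
  values <- array(as.numeric(img), dim = dims)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  if (is.null(mask_path)) {
    mask <- is.finite(values) & values != 0
  } else {
    mimg <- RNifti::readNifti(mask_path)
    mdims <- dim(mimg)
    if (length(mdims) == 4L && mdims[4] == 1L) mdims <- mdims[1:3]
    if (!identical(as.integer(mdims), as.integer(dims))) {
      abort_dimension("mask grid ", paste(dim(mimg), collapse = "x"),
                      " does not match map grid ", paste(dims, collapse = "x"))
    }
    maff <- unclass(RNifti::xform(mimg))
    if (max(abs(maff - affine)) > 1e-4) {
      abort_dimension("mask affine does not match map affine")
    }
    mask <- array(as.numeric(mimg) != 0, dim = dims) & is.finite(values)
  }
  stat_map(values, affine = affine, mask = mask)
}

#' Write a statistic map (or any array on a grid) to NIfTI
#'
#' @param x A [stat_map()], or a numeric array (then `affine` is taken from
#'   the `affine` argument).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param affine Used when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(x, path, affine = diag(4)) {
  if (inherits(x, "stat_map")) {
    values <- x$values
    affine <- x$affine
  } else {
    values <- x
    if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
    affine <- as_affine(affine)
  }
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Group-level design specification
#'
#' Couples a design matrix and contrast vector with the two derived
#' quantities every effect-size computation needs: the residual degrees of
#' freedom `N - rank(X)` and the contrast variance scale `sqrt(c'(X'X)^-c)`.
#'
#' @param X Design matrix (rows = subjects/observations).
#' @param contrast Contrast vector of length `ncol(X)`.
#' @return An object of class `design_spec` with fields `X`, `contrast`,
#'   `n`, `rank`, `dof`, `scale`.
#' @export
design_spec <- function(X, contrast) {
  if (!is.matrix(X)) X <- as.matrix(X)
  contrast <- as.numeric(contrast)
  out <- list(
    X = X,
    contrast = contrast,
    n = nrow(X),
    rank = design_svd(X)$rank,
    dof = glm_dof(X),
    scale = contrast_variance_scale(X, contrast)
  )
  class(out) <- "design_spec"
  out
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("design_spec: N = %d, rank = %d, dof = %d, scale = %.6f\n",
              x$n, x$rank, x$dof, x$scale))
  invisible(x)
}

#' Read a group-level design matrix from delimited text
#'
#' Accepts whitespace- or comma-delimited text, one row per observation,
#' with an optional single header line (detected when any field of the first
#' line is non-numeric). Ragged rows are an error. Native binary formats of
#' analysis suites are not read; export the design matrix to text first.
#'
#' @param matrix_path Path to the text file.
#' @param contrast Contrast vector, or a comma-separated string such as
#'   `"1,-1"`.
#' @param quiet Suppress the informational message describing the design.
#' @return A [design_spec()].
#' @export
read_design <- function(matrix_path, contrast, quiet = FALSE) {
  lines <- readLines(matrix_path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) abort_invalid("design file `", matrix_path, "` is empty")
  split_row <- function(l) {
    if (grepl(",", l, fixed = TRUE)) trimws(strsplit(l, ",", fixed = TRUE)[[1]])
    else strsplit(l, "[[:space:]]+")[[1]]
  }
  rows <- lapply(lines, split_row)
  first_numeric <- !anyNA(suppressWarnings(as.numeric(rows[[1]])))
  if (!first_numeric) rows <- rows[-1]
  if (length(rows) == 0L) abort_invalid("design file has a header but no data rows")
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    abort_invalid("ragged design file: row widths ",
                  paste(unique(widths), collapse = ", "))
  }
  X <- suppressWarnings(matrix(as.numeric(unlist(rows)), nrow = length(rows),
                               byrow = TRUE))
  if (anyNA(X)) abort_invalid("design file contains non-numeric entries")
  spec <- design_spec(X, parse_contrast(contrast))
  if (!quiet) {
    message(sprintf("design: N = %d, rank = %d, dof = %d, scale = %.6f",
                    spec$n, spec$rank, spec$dof, spec$scale))
  }
  spec
}

parse_contrast <- function(contrast) {
  if (is.character(contrast)) {
    contrast <- suppressWarnings(as.numeric(strsplit(paste(contrast, collapse = ","),
                                                     ",")[[1]]))
    if (anyNA(contrast)) abort_invalid("could not parse contrast string")
  }
  as.numeric(contrast)
}

#' Voxel-wise Hedges' g and confidence-limit maps from a t map
#'
#' Lifts the scalar pipeline ([dp_from_t()], [hedges_g()], [ci_g()]) to every
#' in-mask voxel of a t-statistic map: g = t * scale * J(dof) and confidence
#' limits = noncentrality limits * scale. Out-of-mask or non-finite voxels
#' propagate as `NA`. The result is deterministic given the inputs; voxel
#' order does not matter.
#'
#' @param tmap A [stat_map()] of t statistics.
#' @param design A [design_spec()] supplying `dof` and `scale`.
#' @param confidence Two-sided confidence level (default 0.90).
#' @param adjust `"none"` (default) or `"bonferroni"`, which divides alpha by
#'   the number of in-mask voxels before building the interval. Off by
#'   default: unadjusted intervals give the *lower bound* of undecidable-area
#'   size and match the usual reporting convention.
#' @param exact Use the exact gamma-form bias correction.
#' @return An object of class `es_map_bundle` with 3-D arrays `g_map`,
#'   `ci_lower_map`, `ci_upper_map`, plus `mask`, `affine`, `confidence`
#'   (the effective level after adjustment), `dof` and `scale`.
#' @export
es_map_from_tmap <- function(tmap, design, confidence = 0.90,
                             adjust = c("none", "bonferroni"), exact = FALSE) {
  stopifnot(inherits(tmap, "stat_map"))
  adjust <- match.arg(adjust)
  dof <- design$dof
  scale <- design$scale
  if (is.null(dof) || is.null(scale)) {
    abort_invalid("`design` must provide `dof` and `scale`")
  }
  confidence <- check_fraction(confidence, "confidence")
  mask <- tmap$mask & is.finite(tmap$values)
  if (adjust == "bonferroni") {
    m <- sum(mask)
    confidence <- 1 - (1 - confidence) / m
  }
  tvals <- tmap$values[mask]
  J <- correction_factor_j(dof, exact = exact)
  shape <- dim(tmap$values)
  g_map <- ci_lo <- ci_up <- array(NA_real_, dim = shape)
  g_map[mask] <- tvals * scale * J
  lims <- ncp_limits_vec(tvals, dof, confidence)
  ci_lo[mask] <- lims$lower * scale
  ci_up[mask] <- lims$upper * scale
  structure(list(g_map = g_map, ci_lower_map = ci_lo, ci_upper_map = ci_up,
                 mask = mask, affine = tmap$affine, confidence = confidence,
                 dof = as.integer(dof), scale = scale),
            class = "es_map_bundle")
}

# Vectorized noncentrality limits. Duplicate t values (common in thresholded
# or integer-quantized maps) are solved once.
ncp_limits_vec <- function(tvals, dof, confidence) {
  ut <- unique(tvals)
  alpha <- 1 - confidence
  lo <- vapply(ut, solve_ncp, numeric(1), dof = dof, target = 1 - alpha / 2)
  up <- vapply(ut, solve_ncp, numeric(1), dof = dof, target = alpha / 2)
  idx <- match(tvals, ut)
  list(lower = lo[idx], upper = up[idx])
}

#' @export
print.es_map_bundle <- function(x, ...) {
  cat(sprintf(paste0("es_map_bundle: %s grid, %d in-mask voxels, ",
                     "%g%% CI, dof = %d, scale = %.4f\n"),
              paste(dim(x$g_map), collapse = " x "), sum(x$mask),
              100 * x$confidence, x$dof, x$scale))
  invisible(x)
}

#' Reference effect size from a cluster (median or percentile voxel)
#'
#' Selects the voxel inside `cluster_mask` whose g value sits at the
#' requested order statistic and returns that voxel's actual value — the
#' reference is always a real voxel, by the nearest-rank convention
#' `rank = ceiling(p * n)` (so the median of an even-sized cluster is the
#' lower of the two middle values). Ties are resolved to the first voxel in
#' array order.
#'
#' @param es An [es_map_from_tmap()] bundle.
#' @param cluster_mask A [stat_map()] (non-zero = in cluster) or logical
#'   array on the same grid.
#' @param kind `"median"` or `"percentile"`.
#' @param percentile Fraction in (0, 1], required when `kind =
#'   "percentile"`.
#' @return An object of class `cluster_reference`: `statistic_kind`,
#'   `percentile`, `value` (the reference g), `source_voxel` (1-based voxel
#'   index triple) and `cluster_mask` (logical array, kept so downstream
#'   procedures can exclude the cluster).
#' @export
cluster_reference <- function(es, cluster_mask, kind = c("median", "percentile"),
                              percentile = NULL) {
  stopifnot(inherits(es, "es_map_bundle"))
  kind <- match.arg(kind)
  cl <- coerce_mask(cluster_mask, dim(es$g_map), es$affine)
  sel <- cl & es$mask & is.finite(es$g_map)
  n <- sum(sel)
  if (n == 0L) abort_invalid("cluster mask contains no in-mask voxels")
  p <- if (kind == "median") 0.5 else {
    if (is.null(percentile)) abort_invalid("`percentile` is required")
    check_scalar_number(percentile, "percentile")
    if (percentile <= 0 || percentile > 1) {
      abort_invalid("`percentile` must lie in (0, 1]")
    }
    percentile
  }
  rank <- max(1L, min(n, as.integer(ceiling(p * n))))
  idx_lin <- which(sel)
  ord <- order(es$g_map[idx_lin])
  chosen <- idx_lin[ord[rank]]
  structure(list(statistic_kind = kind,
                 percentile = if (kind == "percentile") p else NULL,
                 value = es$g_map[chosen],
                 source_voxel = as.integer(arrayInd(chosen, dim(es$g_map))),
                 cluster_mask = cl),
            class = "cluster_reference")
}

#' @export
print.cluster_reference <- function(x, ...) {
  cat(sprintf("cluster_reference: %s%s g = %.4f at voxel (%s)\n",
              x$statistic_kind,
              if (!is.null(x$percentile)) sprintf(" (p = %g)", x$percentile) else "",
              x$value, paste(x$source_voxel, collapse = ", ")))
  invisible(x)
}

coerce_mask <- function(mask, shape, affine = NULL) {
  if (inherits(mask, "stat_map")) {
    if (!is.null(affine) && max(abs(mask$affine - affine)) > 1e-4) {
      abort_dimension("mask affine does not match the map affine")
    }
    m <- is.finite(mask$values) & mask$values != 0 & mask$mask
  } else {
    m <- mask
    if (length(dim(m)) == 2L) dim(m) <- c(dim(m), 1L)
    m <- array(as.logical(m), dim = dim(m))
    m[is.na(m)] <- FALSE
  }
  if (!identical(dim(m), as.integer(shape)) &&
      !identical(as.integer(dim(m)), as.integer(shape))) {
    abort_dimension("mask grid ", paste(dim(m), collapse = "x"),
                    " does not match map grid ", paste(shape, collapse = "x"))
  }
  m
}

#' Threshold a t map at an uncorrected alpha level
#'
#' Binary map of voxels whose t statistic strictly exceeds the central-t
#' critical value at the design's degrees of freedom. One-sided by default,
#' matching the usual directional fMRI contrast convention; two-sided
#' thresholds `|t|`. Family-wise-error-corrected cluster masks are inputs to
#' this package, not computed here.
#'
#' @param tmap A [stat_map()] of t statistics.
#' @param design A [design_spec()] (only `dof` is used).
#' @param alpha Uncorrected significance level, default 0.001.
#' @param sided `"one"` (default) or `"two"`.
#' @return A binary [stat_map()] (1 = suprathreshold, 0 = not, `NA` out of
#'   mask).
#' @export
threshold_tmap <- function(tmap, design, alpha = 0.001, sided = c("one", "two")) {
  stopifnot(inherits(tmap, "stat_map"))
  sided <- match.arg(sided)
  check_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha > 1) abort_invalid("`alpha` must lie in (0, 1]")
  dof <- design$dof
  vals <- tmap$values
  out <- array(NA_real_, dim = dim(vals))
  if (sided == "one") {
    crit <- stats::qt(1 - alpha, dof)
    out[tmap$mask] <- as.numeric(vals[tmap$mask] > crit)
  } else {
    crit <- stats::qt(1 - alpha / 2, dof)
    out[tmap$mask] <- as.numeric(abs(vals[tmap$mask]) > crit)
  }
  stat_map(out, affine = tmap$affine, mask = tmap$mask)
}
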