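# The three confidence-interval-based inference procedures built on top of
# es_map_bundle: undecidability maps, voxel-wise replication maps, and
# lateralization tests against a mirrored cluster reference.

binary_result_map <- function(values, affine, label,
                              extra = list()) {
  structure(c(list(values = values, affine = affine, label = label), extra),
            class = "binary_result_map")
}

#' @export
print.binary_result_map <- function(x, ...) {
  n_eval <- sum(!is.na(x$values))
  cat(sprintf("binary_result_map (%s): %d/%d evaluated voxels positive\n",
              x$label, sum(x$values == 1, na.rm = TRUE), n_eval))
  invisible(x)
}

#' Map of undecidability
#'
#' Flags every voxel whose effect-size confidence interval *includes or
#' exceeds* a reference effect from a detected cluster: voxel is positive iff
#' `ci_upper >= reference`. Such voxels cannot be declared inferior to the
#' detected effect — they are statistically undecidable, even where the
#' statistic map itself shows nothing significant. The complement of this
#' call is exactly [inferiority_test()] at the same level.
#'
#' @param es An [es_map_from_tmap()] bundle.
#' @param reference A [cluster_reference()] or a bare numeric reference
#'   effect size.
#' @param exclude_mask Voxels to force to 0 in the output (logical array or
#'   [stat_map()]). Defaults to the reference's own cluster when `reference`
#'   is a [cluster_reference()] — those voxels are already "decided" — and to
#'   nothing otherwise. Pass `FALSE` to disable exclusion entirely.
#' @return A `binary_result_map` labelled `"undecidable"`: 1 = undecidable,
#'   0 = inferior to the reference (or excluded), `NA` = out of mask.
#' @export
undecidability_map <- function(es, reference, exclude_mask = NULL) {
  stopifnot(inherits(es, "es_map_bundle"))
  ref_value <- if (inherits(reference, "cluster_reference")) reference$value
               else reference
  check_scalar_number(ref_value, "reference")
  if (is.null(exclude_mask) && inherits(reference, "cluster_reference")) {
    exclude_mask <- reference$cluster_mask
  }
  if (isFALSE(exclude_mask)) exclude_mask <- NULL
  out <- array(NA_real_, dim = dim(es$g_map))
  out[es$mask] <- as.numeric(es$ci_upper_map[es$mask] >= ref_value)
  if (!is.null(exclude_mask)) {
    excl <- coerce_mask(exclude_mask, dim(es$g_map), es$affine)
    out[excl & es$mask] <- 0
  }
  binary_result_map(out, es$affine, "undecidable",
                    extra = list(reference_value = ref_value))
}

#' Voxel-wise replication map
#'
#' Tests, voxel by voxel, whether the effect size estimated in a reference
#' sample falls inside the replication sample's effect-size confidence
#' interval (closed interval: a reference value exactly on a limit counts as
#' replicated). Following the directional convention of fMRI contrasts, only
#' voxels with reference g > 0 are evaluated; the rest are coded `NA`.
#'
#' @param reference An [es_map_from_tmap()] bundle from the reference sample,
#'   or a bare numeric array of reference g values on the same grid.
#' @param replication An [es_map_from_tmap()] bundle from the replication
#'   sample.
#' @return A `binary_result_map` labelled `"replicated"` with three states:
#'   1 = reference effect inside the replication CI, 0 = outside, `NA` = not
#'   evaluated (reference g <= 0, or either voxel out of mask).
#' @export
replication_map <- function(reference, replication) {
  stopifnot(inherits(replication, "es_map_bundle"))
  if (inherits(reference, "es_map_bundle")) {
    if (max(abs(reference$affine - replication$affine)) > 1e-4) {
      abort_dimension("reference and replication affines do not match")
    }
    ref_g <- reference$g_map
  } else if (inherits(reference, "stat_map")) {
    ref_g <- reference$values
  } else {
    ref_g <- reference
    if (length(dim(ref_g)) == 2L) dim(ref_g) <- c(dim(ref_g), 1L)
  }
  if (!identical(as.integer(dim(ref_g)), as.integer(dim(replication$g_map)))) {
    abort_dimension("reference grid ", paste(dim(ref_g), collapse = "x"),
                    " does not match replication grid ",
                    paste(dim(replication$g_map), collapse = "x"))
  }
  eval_mask <- replication$mask & is.finite(ref_g) & ref_g > 0
  out <- array(NA_real_, dim = dim(replication$g_map))
  out[eval_mask] <- as.numeric(
    ref_g[eval_mask] >= replication$ci_lower_map[eval_mask] &
    ref_g[eval_mask] <= replication$ci_upper_map[eval_mask]
  )
  binary_result_map(out, replication$affine, "replicated")
}

#' Mirror a mask across the midline of one voxel axis
#'
#' Index reflection `i -> n + 1 - i` along the chosen axis. Applying it twice
#' returns the original mask. Assumes the grid itself is midline-symmetric
#' along that axis (standard for template-space fMRI grids).
#'
#' @param mask Logical (or 0/1 numeric) 3-D array.
#' @param axis Voxel axis to flip (1, 2 or 3).
#' @return The mirrored array, same type and shape.
#' @export
mirror_mask <- function(mask, axis) {
  axis <- check_count(axis, "axis")
  d <- dim(mask)
  if (is.null(d)) abort_invalid("`mask` must be an array")
  if (length(d) == 2L) { dim(mask) <- c(d, 1L); d <- dim(mask) }
  if (axis > length(d)) abort_invalid("`axis` exceeds mask dimensionality")
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- d[axis]:1
  do.call(`[`, c(list(mask), idx, list(drop = FALSE)))
}

# Left-right voxel axis: the voxel axis whose direction cosine dominates the
# world x (left-right) direction.
infer_lr_axis <- function(affine) {
  which.max(abs(affine[1, 1:3]))
}

#' Lateralization test against a mirrored cluster reference
#'
#' Tests whether effects comparable to a detected unilateral cluster exist
#' contralaterally. The reference is the voxel at the given percentile
#' (nearest-rank; default the 75th percentile) of g within the cluster. The
#' cluster mask is mirrored across the brain midline and every voxel of the
#' mirrored region whose CI upper limit includes or exceeds the reference is
#' flagged. An empty (all-zero) result supports lateralization of the
#' effect; any flagged voxel speaks against it.
#'
#' @param es An [es_map_from_tmap()] bundle.
#' @param cluster_mask The detected cluster ([stat_map()] or logical array);
#'   must lie entirely within one hemisphere.
#' @param percentile Nearest-rank percentile for the reference (default
#'   0.75).
#' @param mirror_axis Voxel axis to mirror across; `NULL` (default) infers
#'   the left-right axis from the affine's dominant world-x direction.
#' @return A `binary_result_map` labelled `"not_inferior"`, evaluated only
#'   inside the mirrored region (1 = contralateral voxel not inferior to the
#'   reference, 0 = inferior, `NA` = outside the mirrored region or out of
#'   mask). Carries the `reference` and the `mirrored_mask` used.
#' @export
lateralization_test <- function(es, cluster_mask, percentile = 0.75,
                                mirror_axis = NULL) {
  stopifnot(inherits(es, "es_map_bundle"))
  cl <- coerce_mask(cluster_mask, dim(es$g_map), es$affine)
  axis <- if (is.null(mirror_axis)) infer_lr_axis(es$affine)
          else check_count(mirror_axis, "mirror_axis")
  n_axis <- dim(cl)[axis]
  coords <- arrayInd(which(cl), dim(cl))[, axis]
  mid <- (n_axis + 1) / 2
  if (length(coords) && (any(coords == mid) ||
                         (any(coords < mid) && any(coords > mid)))) {
    abort_invalid("cluster straddles the midline of axis ", axis,
                  "; lateralization against its mirror is undefined")
  }
  ref <- cluster_reference(es, cl, kind = "percentile", percentile = percentile)
  mirrored <- mirror_mask(cl, axis)
  out <- array(NA_real_, dim = dim(es$g_map))
  sel <- mirrored & es$mask
  out[sel] <- as.numeric(es$ci_upper_map[sel] >= ref$value)
  binary_result_map(out, es$affine, "not_inferior",
                    extra = list(reference = ref, mirrored_mask = mirrored,
                                 mirror_axis = axis))
}
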