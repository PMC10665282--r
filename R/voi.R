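#' Volume-of-interest masks
#'
#' A `voi_mask` is a logical voxel grid aligned to a [count_image], with
#' the delineation method and the achieved volume attached.
#'
#' @name voi_mask
#' @keywords internal
NULL

new_voi_mask <- function(mask, image, method, threshold = NA_real_) {
  stopifnot(identical(dim(mask), dim(image$counts)))
  structure(
    list(mask = mask, method = method,
         achieved_volume = sum(mask) * image$voxel_size^3 / 1000,
         threshold = threshold, voxel_size = image$voxel_size),
    class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s: %d voxels, %.3g mL\n",
              x$method, sum(x$mask), x$achieved_volume))
  invisible(x)
}

#' Counts inside a VOI
#'
#' @param image A [count_image].
#' @param voi A [voi_mask] (or a logical array of matching shape).
#' @return Total counts inside the mask.
#' @export
voi_counts <- function(image, voi) {
  mask <- if (inherits(voi, "voi_mask")) voi$mask else voi
  stopifnot(identical(dim(mask), dim(image$counts)))
  sum(image$counts[mask])
}

#' Volume-matched threshold VOI
#'
#' Finds the count threshold whose superlevel set matches a target volume,
#' the delineation most sites use to match a cylinder's physical active
#' volume. The threshold is located by bisection over the sorted unique
#' counts; voxels on the threshold plateau are then admitted in order of
#' descending count and, among equals, ascending linear voxel index, so the
#' mask always contains exactly `round(target_volume / voxel_volume)`
#' voxels.
#'
#' @param image A [count_image].
#' @param target_volume Target volume in mL (at least one voxel volume).
#' @param region Optional logical array restricting the search (e.g. a
#'   crop around one cylinder when several sources share the image).
#' @return A [voi_mask] with `method = "threshold_matched"`.
#' @export
threshold_matched_voi <- function(image, target_volume, region = NULL) {
  stopifnot(inherits(image, "count_image"), target_volume > 0)
  vox_mL <- image$voxel_size^3 / 1000
  k <- as.integer(round(target_volume / vox_mL))
  if (k < 1L)
    stop("empty-mask error: target_volume is smaller than one voxel")
  counts <- image$counts
  idx <- if (is.null(region)) seq_along(counts) else which(region)
  if (k > length(idx))
    stop("target_volume exceeds the searchable field of view")
  vals <- counts[idx]
  if (all(vals == 0))
    stop("degenerate-image error: all counts are zero in the search region")
  # bisection over sorted unique counts for the largest T with
  # #{v >= T} >= k
  u <- sort(unique(vals))
  lo <- 1L; hi <- length(u)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (sum(vals >= u[mid]) >= k) lo <- mid else hi <- mid - 1L
  }
  T <- u[lo]
  above <- idx[vals > T]
  ties <- sort(idx[vals == T])  # ascending linear index among equals
  sel <- c(above, ties[seq_len(k - length(above))])
  mask <- array(FALSE, dim = dim(counts))
  mask[sel] <- TRUE
  new_voi_mask(mask, image, "threshold_matched", threshold = T)
}

#' Nominal-geometry VOI
#'
#' Marks the voxels whose centres lie inside the nominal cylinder placed at
#' a given baseplate position, the delineation used by sites that draw
#' VOIs from the known cylinder dimensions rather than by thresholding.
#'
#' @param image A [count_image].
#' @param cylinder A [cylinder_spec()].
#' @param position Length-2 numeric, (x, y) centre offset in mm.
#' @param z_base Axial coordinate of the cylinder base (mm; default 0, the
#'   baseplate plane).
#' @return A [voi_mask] with `method = "nominal_geometry"`.
#' @export
nominal_geometry_voi <- function(image, cylinder, position = c(0, 0),
                                 z_base = 0) {
  stopifnot(inherits(image, "count_image"), inherits(cylinder, "cylinder_spec"))
  r <- cylinder$diameter / 2
  if (position[1] - r < min(image$xs) - image$voxel_size / 2 ||
      position[1] + r > max(image$xs) + image$voxel_size / 2 ||
      position[2] - r < min(image$ys) - image$voxel_size / 2 ||
      position[2] + r > max(image$ys) + image$voxel_size / 2)
    stop("layout error: cylinder footprint outside the image grid")
  inplane <- outer((image$xs - position[1])^2, (image$ys - position[2])^2,
                   `+`) <= r^2
  inz <- image$zs >= z_base & image$zs <= z_base + cylinder$height
  mask <- array(FALSE, dim = dim(image$counts))
  mask[, , inz] <- inplane
  if (!any(mask))
    stop("empty-mask error: cylinder smaller than one voxel at this grid")
  new_voi_mask(mask, image, "nominal_geometry")
}

# Morphological dilation of a logical 3D array by a Euclidean ball, via an
# FFT convolution with the ball indicator (exact for binary input).
dilate_mask <- function(mask, radius_vox) {
  if (radius_vox <= 0) return(mask)
  d <- dim(mask)
  R <- ceiling(radius_vox)
  P <- d + 2L * R
  off <- seq(-R, R)
  ball <- outer(outer(off^2, off^2, `+`), off^2, `+`) <= radius_vox^2 + 1e-9
  km <- array(0, dim = P)
  wrap <- (off %% P[1]) + 1L  # P > 2R, so indices are distinct
  wy <- (off %% P[2]) + 1L
  wz <- (off %% P[3]) + 1L
  km[wrap, wy, wz] <- ball + 0
  mp <- array(0, dim = P)
  mp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask + 0
  conv <- Re(stats::fft(stats::fft(mp) * stats::fft(km), inverse = TRUE)) /
    prod(P)
  conv[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] > 0.5
}

#' Enlarged VOI
#'
#' Dilates a base region by a Euclidean ball of radius `margin`, clipped at
#' the grid bounds. Used for the uniform-phantom calibration-factor
#' measurement, where the VOI must be enlarged beyond the phantom wall to
#' recapture counts lost to partial-volume spill-out.
#'
#' @param image A [count_image].
#' @param base A [voi_mask] or logical array: the region to enlarge.
#' @param margin Dilation radius in mm (>= 0). The package default for
#'   calibration measurements is twice the PSF FWHM.
#' @return A [voi_mask] with `method = "enlarged"`; `margin = 0` returns
#'   the base region unchanged. Masks are nested in `margin`.
#' @export
enlarged_voi <- function(image, base, margin) {
  stopifnot(inherits(image, "count_image"), margin >= 0)
  mask <- if (inherits(base, "voi_mask")) base$mask else base
  stopifnot(identical(dim(mask), dim(image$counts)))
  out <- dilate_mask(mask, margin / image$voxel_size)
  new_voi_mask(out, image, "enlarged")
}
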