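#' Convert a Gaussian FWHM to a standard deviation
#'
#' @param fwhm Full width at half maximum.
#' @return `fwhm / (2 * sqrt(2 * log(2)))`.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Normalized 1D Gaussian kernel sampled at voxel centres, truncated at 4 sigma.
gaussian_kernel1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# Band matrix that applies kernel k (odd length) along a dimension of size n
# with zero padding at the boundaries (counts blurred off the grid are lost).
kernel_matrix <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- k[o + r + 1L]
  }
  K
}

# Separable convolution of a 3D array with a 1D kernel along dimension d.
blur_along <- function(A, K, d) {
  dd <- dim(A)
  perm <- c(d, setdiff(1:3, d))
  Ap <- aperm(A, perm)
  M <- matrix(Ap, nrow = dd[d])
  Ap <- array(K %*% M, dim = dd[perm])
  aperm(Ap, order(perm))
}

#' Blur a 3D volume with an isotropic Gaussian point-spread function
#'
#' Separable convolution with a normalized, 4-sigma-truncated Gaussian
#' kernel sampled at voxel centres; boundaries are zero-padded, so counts
#' blurred off the grid are lost (pad the grid by at least 3 sigma when
#' conservation matters).
#'
#' @param A 3D numeric array.
#' @param fwhm PSF full width at half maximum, in mm.
#' @param voxel_size Isotropic voxel size in mm.
#' @return The blurred array. `fwhm = 0` returns `A` unchanged.
#' @export
blur_gaussian3d <- function(A, fwhm, voxel_size) {
  if (fwhm == 0) return(A)
  stopifnot(fwhm > 0, voxel_size > 0)
  k <- gaussian_kernel1d(fwhm_to_sigma(fwhm) / voxel_size)
  for (d in 1:3) A <- blur_along(A, kernel_matrix(dim(A)[d], k), d)
  A
}

# Supersampled in-plane occupancy of a disc of radius r centred at (cx, cy),
# evaluated for voxel centres xs x ys. Returns a length(xs) x length(ys)
# matrix of fractions in [0, 1].
disc_occupancy <- function(xs, ys, cx, cy, r, voxel_size, supersample) {
  occ <- matrix(0, length(xs), length(ys))
  off <- ((seq_len(supersample) - 0.5) / supersample - 0.5) * voxel_size
  for (ox in off) for (oy in off) {
    occ <- occ + (outer((xs + ox - cx)^2, (ys + oy - cy)^2, `+`) <= r^2)
  }
  occ / supersample^2
}

#' Voxelize a phantom layout into an activity-concentration volume
#'
#' Rasterises each cylinder onto an isotropic voxel grid. The per-voxel
#' concentration is the cylinder's mean concentration (activity divided by
#' the analytic volume pi*(d/2)^2*h) times the fractional voxel occupancy.
#' Occupancy factorises for the z-aligned cylinders: the axial overlap is
#' computed analytically and the in-plane disc occupancy by supersampling.
#'
#' The grid is centred on the phantom axis; world coordinates are taken at
#' voxel centres, with the baseplate plane at z = 0 and cylinders extending
#' to z = height.
#'
#' @param layout A [phantom_layout()] (validated against `cylinders`).
#' @param cylinders Named list of [cylinder_spec()].
#' @param voxel_size Isotropic voxel size in mm (default 4.42, a 128 matrix
#'   over a typical SPECT field of view).
#' @param supersample In-plane subsamples per voxel edge (>= 1); 4 keeps
#'   the activity integral within 0.2% of truth.
#' @param padding Grid padding beyond the Jaszczak radius / cylinder
#'   heights, in mm (default 30, i.e. > 3 sigma of a 20 mm FWHM PSF).
#' @param activities_MBq Optional named vector overriding the cylinders'
#'   tabulated activities (MBq at scan time).
#'
#' @return An object of class `activity_volume` with elements `conc`
#'   (3D array, MBq/mL), `voxel_size`, coordinate vectors `xs`, `ys`, `zs`
#'   (mm, voxel centres), `activities_MBq`, `layout`, `cylinders`.
#' @export
voxelize_layout <- function(layout, cylinders, voxel_size = 4.42,
                            supersample = 4L, padding = 30,
                            activities_MBq = NULL) {
  stopifnot(voxel_size > 0, supersample >= 1)
  validate_phantom_layout(layout, cylinders)
  pos <- layout$positions
  R <- layout$jaszczak_diameter / 2
  hmax <- if (nrow(pos)) max(vapply(pos$id, function(id) cylinders[[id]]$height, 0)) else 0
  nx <- ceiling((2 * R + 2 * padding) / voxel_size)
  if (nx %% 2L == 0L) nx <- nx + 1L  # centre a voxel column on the axis
  nz <- max(1L, ceiling((hmax + 2 * padding) / voxel_size))
  xs <- (seq_len(nx) - (nx + 1) / 2) * voxel_size
  zs <- -padding + (seq_len(nz) - 0.5) * voxel_size
  conc <- array(0, dim = c(nx, nx, nz))
  acts <- numeric(0)
  for (i in seq_len(nrow(pos))) {
    cyl <- cylinders[[pos$id[i]]]
    A_MBq <- if (!is.null(activities_MBq)) {
      unname(activities_MBq[[pos$id[i]]])
    } else {
      if (is.na(cyl$activity_kBq))
        stop("cylinder ", cyl$id, " has no activity; supply activities_MBq")
      cyl$activity_kBq / 1000
    }
    r <- cyl$diameter / 2
    # an underfilled cylinder (active volume < nominal) is modelled as a
    # lower fill height at the same concentration
    h_eff <- min(cyl$height, 1000 * cyl$active_volume / (pi * r^2))
    c0 <- A_MBq / (pi * r^2 * h_eff / 1000)  # MBq/mL
    # axial fractional overlap of each voxel with [0, fill height]
    zfrac <- pmax(0, pmin(zs + voxel_size / 2, h_eff) -
                     pmax(zs - voxel_size / 2, 0)) / voxel_size
    ix <- which(abs(xs - pos$x[i]) <= r + voxel_size)
    iy <- which(abs(xs - pos$y[i]) <= r + voxel_size)
    iz <- which(zfrac > 0)
    occ <- disc_occupancy(xs[ix], xs[iy], pos$x[i], pos$y[i], r,
                          voxel_size, as.integer(supersample))
    conc[ix, iy, iz] <- conc[ix, iy, iz] +
      c0 * outer(occ, zfrac[iz])
    acts[cyl$id] <- A_MBq
  }
  if (layout$water_background_activity_MBq > 0) {
    # uniform concentration in the water volume of the Jaszczak cylinder
    occJ <- disc_occupancy(xs, xs, 0, 0, R, voxel_size, as.integer(supersample))
    zJ <- pmax(0, pmin(zs + voxel_size / 2, layout$jaszczak_height) -
                  pmax(zs - voxel_size / 2, 0)) / voxel_size
    cw <- layout$water_background_activity_MBq /
      (pi * R^2 * layout$jaszczak_height / 1000)
    conc <- conc + array(cw * outer(as.vector(occJ), zJ), dim = dim(conc))
  }
  structure(
    list(conc = conc, voxel_size = voxel_size,
         xs = xs, ys = xs, zs = zs,
         activities_MBq = acts, layout = layout, cylinders = cylinders),
    class = "activity_volume")
}

#' @export
print.activity_volume <- function(x, ...) {
  cat(sprintf("<activity_volume> %s voxels @ %g mm, total activity %.4g MBq\n",
              paste(dim(x$conc), collapse = " x "), x$voxel_size,
              sum(x$activities_MBq)))
  invisible(x)
}

#' Imaging system model
#'
#' Collapses the acquisition/reconstruction chain of a SPECT/CT setup into
#' four effective parameters acting on reconstructed, attenuation- and
#' scatter-corrected images: an overall sensitivity, an isotropic Gaussian
#' point-spread function, a multiplicative residual scatter/septal
#' penetration bias, and an additive background rate.
#'
#' @param sensitivity_per_emission Counts per second per MBq per unit
#'   emission probability. The implied true image calibration factor for a
#'   nuclide with emission probability p is
#'   `sensitivity_per_emission * p * scatter_bias` cps/MBq.
#' @param psf_fwhm Reconstructed resolution, FWHM in mm (default 20, a
#'   worst-case clinical value for I-131 with high-energy collimation).
#' @param scatter_bias Dimensionless multiplicative residual on recovered
#'   counts (1 = perfect correction; > 1 emulates residual septal
#'   penetration left by triple-energy-window correction).
#' @param background_offset_rate Additive cps per voxel.
#' @return An object of class `system_model`.
#' @export
system_model <- function(sensitivity_per_emission, psf_fwhm = 20,
                         scatter_bias = 1, background_offset_rate = 0) {
  stopifnot(sensitivity_per_emission > 0, psf_fwhm >= 0, scatter_bias > 0,
            background_offset_rate >= 0)
  structure(list(sensitivity_per_emission = sensitivity_per_emission,
                 psf_fwhm = psf_fwhm, scatter_bias = scatter_bias,
                 background_offset_rate = background_offset_rate),
            class = "system_model")
}

#' True image calibration factor implied by a system model
#'
#' @param system A [system_model()].
#' @param nuclide A [radionuclide_spec()].
#' @return `sensitivity_per_emission * emission_probability * scatter_bias`
#'   in cps/MBq.
#' @export
true_icf <- function(system, nuclide) {
  system$sensitivity_per_emission * nuclide$emission_probability *
    system$scatter_bias
}

#' Expected-count image for an activity volume
#'
#' The Poisson mean image: `lambda_v = T * S * p * bias *
#' blur(conc)_v * voxel_volume + T * background_offset_rate`.
#'
#' @inheritParams simulate_count_image
#' @return 3D array of expected counts.
#' @export
expected_counts <- function(activity_volume, system, nuclide, duration_s) {
  stopifnot(inherits(activity_volume, "activity_volume"),
            inherits(system, "system_model"),
            inherits(nuclide, "radionuclide_spec"),
            duration_s > 0)
  vox_mL <- activity_volume$voxel_size^3 / 1000
  blurred <- blur_gaussian3d(activity_volume$conc, system$psf_fwhm,
                             activity_volume$voxel_size)
  lam <- duration_s * true_icf(system, nuclide) * blurred * vox_mL +
    duration_s * system$background_offset_rate
  if (any(!is.finite(lam)))
    stop("simulation error: non-finite expected counts")
  lam
}

#' Simulate a reconstructed SPECT count image
#'
#' Draws Poisson counts around the expected-count image of
#' [expected_counts()]. With a fixed `seed` the output is reproducible
#' bit-for-bit; the global random-number state is left untouched.
#'
#' @param activity_volume An [voxelize_layout()] result (MBq/mL at scan
#'   time).
#' @param system A [system_model()].
#' @param nuclide A [radionuclide_spec()].
#' @param duration_s Acquisition duration in seconds.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param noise `"poisson"` (default) or `"none"`, which returns the
#'   expected-count image itself (non-integer).
#'
#' @return An object of class `count_image`: `counts` (3D array),
#'   `voxel_size` (mm), `duration_s`, `nuclide`, and a `truth` sidecar
#'   recording the true activities at scan time, the implied true
#'   calibration factor in cps/MBq, the layout, and the seed.
#' @export
simulate_count_image <- function(activity_volume, system, nuclide, duration_s,
                                 seed = NULL, noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  lam <- expected_counts(activity_volume, system, nuclide, duration_s)
  if (noise == "poisson") {
    counts <- with_seed(seed, stats::rpois(length(lam), lam))
    counts <- array(counts, dim = dim(lam))
  } else {
    counts <- lam
  }
  structure(
    list(counts = counts, voxel_size = activity_volume$voxel_size,
         xs = activity_volume$xs, ys = activity_volume$ys,
         zs = activity_volume$zs,
         duration_s = duration_s, nuclide = nuclide,
         truth = list(activities_MBq = activity_volume$activities_MBq,
                      icf_true = true_icf(system, nuclide),
                      layout = activity_volume$layout,
                      system = system, seed = seed)),
    class = "count_image")
}

#' @export
print.count_image <- function(x, ...) {
  cat(sprintf("<count_image> %s voxels @ %g mm, %s, T = %g s, %.4g counts\n",
              paste(dim(x$counts), collapse = " x "), x$voxel_size,
              x$nuclide$name, x$duration_s, sum(x$counts)))
  invisible(x)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Fraction of blurred counts spilling out of a cylinder
#'
#' For a uniformly active cylinder imaged with an isotropic Gaussian PSF,
#' the fraction of counts that end up outside the physical cylinder
#' boundary. Because both the cylinder indicator and the Gaussian
#' factorise, the retained fraction is the product of an axial factor
#' (closed-form, via the Gaussian CDF) and an in-plane disc factor
#' (computed on a supersampled 2D grid).
#'
#' @param cylinder A [cylinder_spec()].
#' @param psf_fwhm PSF full width at half maximum in mm.
#' @param voxel_size Grid step (mm) for the in-plane computation; must not
#'   exceed the cylinder diameter.
#' @return Spill-out fraction in [0, 1); 0 when `psf_fwhm = 0`.
#' @export
#' @examples
#' spillout_fraction(cylinder_spec("C1", 7.5, 38), psf_fwhm = 20)
spillout_fraction <- function(cylinder, psf_fwhm, voxel_size = 1) {
  stopifnot(inherits(cylinder, "cylinder_spec"), psf_fwhm >= 0)
  if (voxel_size > cylinder$diameter)
    stop("resolution error: voxel_size exceeds the cylinder diameter")
  if (psf_fwhm == 0) return(0)
  sig <- fwhm_to_sigma(psf_fwhm)
  h <- cylinder$height
  # axial retained fraction: (1/h) * int_0^h [Phi(z/s) - Phi((z-h)/s)] dz
  ax <- stats::integrate(function(z) stats::pnorm(z / sig) -
                           stats::pnorm((z - h) / sig),
                         0, h, rel.tol = 1e-9)$value / h
  # in-plane retained fraction on a fine 2D grid
  r <- cylinder$diameter / 2
  half <- r + 4 * sig + voxel_size
  n <- ceiling(2 * half / voxel_size)
  xs <- (seq_len(n) - (n + 1) / 2) * voxel_size
  occ <- disc_occupancy(xs, xs, 0, 0, r, voxel_size, 4L)
  k <- gaussian_kernel1d(sig / voxel_size)
  K <- kernel_matrix(n, k)
  blurred <- K %*% occ %*% t(K)
  radial <- sum(blurred * occ) / sum(occ)
  1 - ax * radial
}
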