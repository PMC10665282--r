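# Baseplate placement optimisation.
#
# The phantom design question is where to mount the cylinders so that,
# after blurring by the reconstructed PSF, their count distributions
# interfere as little as possible with each other and with the phantom
# wall. All cylinders share the same height and sit on the baseplate, so
# the problem is two-dimensional: each source contributes a radially
# symmetric blurred in-plane count density.

# Radial profile (unit total mass, per mm^2) of a Gaussian-blurred disc.
# Returns a function of radius, 0 beyond its support.
blurred_disc_profile <- function(radius, sigma, step = 1) {
  half <- radius + 4 * sigma + step
  n <- ceiling(2 * half / step)
  if (n %% 2L == 0L) n <- n + 1L  # odd: a grid point sits at the centre
  xs <- (seq_len(n) - (n + 1) / 2) * step
  occ <- disc_occupancy(xs, xs, 0, 0, radius, step, 4L)
  if (sigma > 0) {
    K <- kernel_matrix(n, gaussian_kernel1d(sigma / step))
    occ <- K %*% occ %*% t(K)
  }
  dens <- occ / (sum(occ) * step^2)
  mid <- (n + 1L) %/% 2L
  prof_r <- xs[mid:n]
  prof_v <- dens[mid:n, mid]
  support <- max(prof_r)
  function(r) {
    out <- stats::approx(prof_r, prof_v, xout = pmin(r, support),
                         rule = 2)$y
    out[r > support] <- 0
    out
  }
}

# Tabulate f over a grid and return a fast linear interpolant.
tabulate_fun <- function(xs, ys) {
  function(x) stats::approx(xs, ys, xout = x, rule = 2)$y
}

#' Placement objective for a cylinder layout
#'
#' The objective minimised by [optimize_placement()]: the sum over cylinder
#' pairs of the integrated product of their blurred in-plane count
#' densities (unit mass each, so the term is a density overlap in mm^-2),
#' plus `boundary_weight` times the total blurred mass spilling beyond the
#' Jaszczak wall. Overlapping or out-of-bounds layouts return `Inf`.
#'
#' @param layout A [phantom_layout()].
#' @param cylinders Named list of [cylinder_spec()].
#' @param psf_fwhm PSF full width at half maximum in mm.
#' @param boundary_weight Weight (mm^-2) of the wall-spill term.
#' @return Scalar objective value.
#' @export
placement_objective <- function(layout, cylinders, psf_fwhm = 20,
                                boundary_weight = 1e-4) {
  ok <- tryCatch({validate_phantom_layout(layout, cylinders); TRUE},
                 error = function(e) FALSE)
  if (!ok) return(Inf)
  tabs <- placement_tables(layout$positions$id, cylinders, layout,
                           psf_fwhm, boundary_weight)
  eval_placement(as.matrix(layout$positions[, c("x", "y")]), tabs)
}

# Precompute pairwise-overlap and wall-spill interpolants for a cylinder
# id set. Grid step 2 mm for the density integrals.
placement_tables <- function(ids, cylinders, layout, psf_fwhm,
                             boundary_weight, step = 2) {
  sigma <- fwhm_to_sigma(psf_fwhm)
  R <- layout$jaszczak_diameter / 2
  n <- length(ids)
  profs <- lapply(ids, function(id)
    blurred_disc_profile(cylinders[[id]]$diameter / 2, sigma, step = step))
  supp <- vapply(ids, function(id)
    cylinders[[id]]$diameter / 2 + 4 * sigma + step, 0)
  # grids for numeric 2D integrals, one per cylinder (covers its support)
  grids <- lapply(supp, function(s) {
    m <- ceiling(s / step)
    g <- seq(-m, m) * step
    list(x = rep(g, times = length(g)), y = rep(g, each = length(g)))
  })
  dgrid <- seq(0, 2 * R + step, by = step)
  overlap <- vector("list", n)
  for (i in seq_len(n)) {
    overlap[[i]] <- vector("list", n)
    bi <- profs[[i]](sqrt(grids[[i]]$x^2 + grids[[i]]$y^2))
    for (j in seq_len(n)) {
      if (j == i) next
      vals <- vapply(dgrid, function(d) {
        bj <- profs[[j]](sqrt((grids[[i]]$x - d)^2 + grids[[i]]$y^2))
        sum(bi * bj) * step^2
      }, 0)
      overlap[[i]][[j]] <- tabulate_fun(dgrid, vals)
    }
  }
  rgrid <- seq(0, R, by = step)
  spill <- lapply(seq_len(n), function(i) {
    bi <- profs[[i]](sqrt(grids[[i]]$x^2 + grids[[i]]$y^2))
    vals <- vapply(rgrid, function(r) {
      outside <- sqrt((grids[[i]]$x + r)^2 + grids[[i]]$y^2) > R
      sum(bi[outside]) * step^2
    }, 0)
    tabulate_fun(rgrid, vals)
  })
  radii <- vapply(ids, function(id) cylinders[[id]]$diameter / 2, 0)
  list(overlap = overlap, spill = spill, radii = radii,
       rmax = R - layout$wall_margin - radii,
       boundary_weight = boundary_weight, n = n)
}

# Objective for a position matrix (n x 2) given precomputed tables.
eval_placement <- function(P, tabs) {
  n <- tabs$n
  obj <- 0
  for (i in seq_len(n)) {
    ri <- sqrt(sum(P[i, ]^2))
    if (ri > tabs$rmax[i] + 1e-9) return(Inf)
    obj <- obj + tabs$boundary_weight * tabs$spill[[i]](ri)
    if (i < n) for (j in (i + 1L):n) {
      d <- sqrt(sum((P[i, ] - P[j, ])^2))
      if (d < tabs$radii[i] + tabs$radii[j] - 1e-9) return(Inf)
      obj <- obj + tabs$overlap[[i]][[j]](d)
    }
  }
  obj
}

#' Optimise the placement of cylinders on the baseplate
#'
#' Deterministic coordinate descent on a polar position grid: cylinders
#' are initialised at equally spaced angles and mid radius, then each in
#' turn is moved to the grid position minimising the full
#' [placement_objective()] (pairwise blurred-density overlap plus wall
#' spill), until no move improves it. Objective ties (the overlap terms
#' plateau near zero once the blurred densities separate) are broken
#' towards the largest nearest-neighbour separation, then the smaller
#' radius and angle.
#'
#' @param cylinders Named list of [cylinder_spec()] to place.
#' @param jaszczak_diameter,jaszczak_height,wall_margin Envelope, mm.
#' @param psf_fwhm PSF full width at half maximum in mm.
#' @param radius_step,angle_step Search grid resolution (mm and degrees).
#' @param boundary_weight Weight of the wall-spill term (mm^-2).
#' @param max_sweeps Maximum coordinate-descent sweeps.
#' @return A feasible [phantom_layout()]; the attained objective value is
#'   attached as attribute `"objective"`.
#' @export
optimize_placement <- function(cylinders,
                               jaszczak_diameter = 216,
                               jaszczak_height = 186,
                               wall_margin = 5,
                               psf_fwhm = 20,
                               radius_step = 1, angle_step = 5,
                               boundary_weight = 1e-4,
                               max_sweeps = 25L) {
  ids <- names(cylinders)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("cylinders must be a named list")
  n <- length(ids)
  env <- phantom_layout(data.frame(id = ids, x = 0, y = 0),
                        jaszczak_diameter = jaszczak_diameter,
                        jaszczak_height = jaszczak_height,
                        wall_margin = wall_margin)
  tabs <- placement_tables(ids, cylinders, env, psf_fwhm, boundary_weight)
  if (any(tabs$rmax < 0))
    stop("layout error: a cylinder does not fit inside the envelope")
  if (n == 1L) {
    # pure wall-spill problem; the symmetric optimum is the centre, but
    # run the 1D search anyway so a non-monotone spill table would show
    rs <- seq(0, tabs$rmax[1], by = radius_step)
    best <- rs[which.min(tabs$spill[[1]](rs))]
    lay <- phantom_layout(data.frame(id = ids, x = best, y = 0),
                          jaszczak_diameter, jaszczak_height, wall_margin)
    attr(lay, "objective") <- boundary_weight * tabs$spill[[1]](best)
    return(lay)
  }
  ang0 <- (seq_len(n) - 1L) * 360 / n
  P <- cbind(tabs$rmax * cospi(ang0 / 180) / 2, tabs$rmax * sinpi(ang0 / 180) / 2)
  angles <- seq(0, 360 - angle_step, by = angle_step)
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      rs <- seq(0, tabs$rmax[i], by = radius_step)
      cand <- cbind(rep(rs, times = length(angles)),
                    rep(angles, each = length(rs)))
      others <- setdiff(seq_len(n), i)
      cx <- cand[, 1] * cospi(cand[, 2] / 180)
      cy <- cand[, 1] * sinpi(cand[, 2] / 180)
      score <- tabs$boundary_weight * tabs$spill[[i]](cand[, 1])
      feasible <- rep(TRUE, nrow(cand))
      for (j in others) {
        d <- sqrt((cx - P[j, 1])^2 + (cy - P[j, 2])^2)
        feasible <- feasible & d >= tabs$radii[i] + tabs$radii[j] - 1e-9
        score <- score + tabs$overlap[[i]][[j]](d)
      }
      score[!feasible] <- Inf
      smin <- min(score)
      if (!is.finite(smin))
        stop("layout error: no feasible position for cylinder ", ids[i])
      # the objective can plateau at (near) zero once the blurred
      # densities separate; break ties toward the largest
      # nearest-neighbour distance, then the smallest radius and angle
      near <- which(score <= smin + abs(smin) * 1e-9 + 1e-15)
      if (length(near) > 1L) {
        dmin <- rep(Inf, length(near))
        for (j in others)
          dmin <- pmin(dmin, sqrt((cx[near] - P[j, 1])^2 +
                                  (cy[near] - P[j, 2])^2))
        k <- near[which.max(dmin)]
      } else {
        k <- near
      }
      newP <- c(cx[k], cy[k])
      if (sqrt(sum((newP - P[i, ])^2)) > 1e-9) {
        P[i, ] <- newP
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  lay <- phantom_layout(data.frame(id = ids, x = P[, 1], y = P[, 2]),
                        jaszczak_diameter, jaszczak_height, wall_margin)
  validate_phantom_layout(lay, cylinders)
  attr(lay, "objective") <- eval_placement(P, tabs)
  lay
}
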