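#' Cylindrical source specification
#'
#' Describes one of the cylindrical phantom inserts: its nominal geometry
#' and, optionally, its assayed activity and active volume. Heights and
#' diameters are in mm, volumes in mL, activities in kBq. Uncertainties are
#' standard (k = 1) uncertainties.
#'
#' The nominal volume is computed as `pi * (diameter/2)^2 * height`; if a
#' `nominal_volume` is supplied it must agree with the geometric value
#' within 0.5%.
#'
#' @param id Short label, e.g. `"C1"`.
#' @param diameter,height Inner dimensions in mm.
#' @param nominal_volume Optional nominal volume in mL (cross-checked).
#' @param activity_kBq Activity at `reference_time` in kBq (`NA` if unknown).
#' @param activity_u_kBq Standard uncertainty of `activity_kBq` in kBq.
#' @param active_volume Active (filled) volume in mL; defaults to the
#'   nominal volume.
#' @param active_volume_u Standard uncertainty of `active_volume` in mL.
#' @param reference_time Assay reference time (`POSIXct`), or `NULL`.
#'
#' @return An object of class `cylinder_spec`.
#' @export
#' @examples
#' cylinder_spec("C4", diameter = 60, height = 38, activity_kBq = 10304 / 1)
cylinder_spec <- function(id, diameter, height, nominal_volume = NULL,
                          activity_kBq = NA_real_, activity_u_kBq = 0,
                          active_volume = NULL, active_volume_u = 0,
                          reference_time = NULL) {
  stopifnot(diameter > 0, height > 0)
  geom_volume <- pi * (diameter / 2)^2 * height / 1000  # mL
  if (is.null(nominal_volume)) {
    nominal_volume <- geom_volume
  } else if (abs(nominal_volume - geom_volume) > 0.005 * geom_volume) {
    stop(sprintf("nominal_volume %.4g mL disagrees with pi*(d/2)^2*h = %.4g mL by more than 0.5%%",
                 nominal_volume, geom_volume))
  }
  if (is.null(active_volume)) active_volume <- nominal_volume
  stopifnot(nominal_volume > 0, active_volume > 0,
            activity_u_kBq >= 0, active_volume_u >= 0)
  if (!is.na(activity_kBq) && activity_kBq <= 0)
    stop("activity_kBq must be positive when given")
  structure(
    list(id = id, diameter = diameter, height = height,
         nominal_volume = nominal_volume,
         activity_kBq = activity_kBq, activity_u_kBq = activity_u_kBq,
         active_volume = active_volume, active_volume_u = active_volume_u,
         reference_time = reference_time),
    class = "cylinder_spec")
}

#' @export
print.cylinder_spec <- function(x, ...) {
  cat(sprintf("<cylinder_spec> %s: %g x %g mm (%.3g mL), A = %.4g +/- %.2g kBq\n",
              x$id, x$diameter, x$height, x$nominal_volume,
              x$activity_kBq, x$activity_u_kBq))
  invisible(x)
}

#' Solid Ba-133 source sets
#'
#' The two traceable sets of four solid Ba-133 cylinders produced for the
#' multi-centre comparison, one fixed in silicone rubber at a national
#' metrology institute ("CMI" set) and one in epoxy resin ("CEA" set).
#' Activities are referenced to 2018-12-15 12:00 UTC; the published
#' expanded (k = 2) uncertainties are converted to standard uncertainties.
#'
#' @param set `"CMI"` or `"CEA"`.
#' @return A named list of four [cylinder_spec()] objects (C1-C4).
#' @export
#' @examples
#' ba133_source_set("CMI")$C4$activity_kBq  # 10304
ba133_source_set <- function(set = c("CMI", "CEA")) {
  set <- match.arg(set)
  ref <- as.POSIXct("2018-12-15 12:00:00", tz = "UTC")
  d <- c(C1 = 7.5, C2 = 15, C3 = 30, C4 = 60)
  tab <- switch(set,
    CMI = list(A  = c(155.8, 649, 2583, 10304),
               Au = c(3.4, 14, 57, 227) / 2,
               V  = c(1.62, 6.76, 26.9, 107.3),
               Vu = c(0.02, 0.07, 0.3, 1.2) / 2),
    CEA = list(A  = c(333.5, 1343, 5150, 20350),
               Au = c(8.7, 35, 130, 530) / 2,
               V  = c(1.66, 6.67, 25.6, 101.1),
               Vu = c(0.03, 0.13, 0.5, 2.0) / 2))
  out <- lapply(seq_along(d), function(i)
    cylinder_spec(names(d)[i], diameter = d[[i]], height = 38,
                  activity_kBq = tab$A[i], activity_u_kBq = tab$Au[i],
                  active_volume = tab$V[i], active_volume_u = tab$Vu[i],
                  reference_time = ref))
  names(out) <- names(d)
  out
}

#' Activity dispensed into a cylinder from a stock solution
#'
#' The liquid-filled cylinders are loaded by injecting a stock solution of
#' known activity concentration; the cylinder activity is the product of
#' concentration and active volume, with relative uncertainties combined in
#' quadrature.
#'
#' @param concentration_MBq_mL Activity concentration in MBq/mL.
#' @param active_volume_mL Active volume in mL.
#' @param concentration_u_rel,active_volume_u_rel Relative standard
#'   uncertainties of the two factors.
#'
#' @return A list with `activity_MBq` and `u_rel` (relative standard
#'   uncertainty of the product).
#' @export
#' @examples
#' cylinder_activity_from_stock(0.18, 107.4)$activity_MBq  # ~19 MBq
cylinder_activity_from_stock <- function(concentration_MBq_mL, active_volume_mL,
                                         concentration_u_rel = 0,
                                         active_volume_u_rel = 0) {
  stopifnot(concentration_MBq_mL > 0, active_volume_mL > 0,
            concentration_u_rel >= 0, active_volume_u_rel >= 0)
  list(activity_MBq = concentration_MBq_mL * active_volume_mL,
       u_rel = sqrt(concentration_u_rel^2 + active_volume_u_rel^2))
}

#' Liquid I-131 cylinder set
#'
#' Builds the set of four fillable cylinders (same geometry as the solid
#' sources) loaded from an I-131 stock solution of the given activity
#' concentration at scan time.
#'
#' @param concentration_MBq_mL Stock activity concentration (MBq/mL) at the
#'   reference time; the study median was 0.18 MBq/mL.
#' @param concentration_u_rel Relative standard uncertainty of the
#'   concentration.
#' @param reference_time Assay reference time, or `NULL`.
#' @return A named list of four [cylinder_spec()] objects.
#' @export
i131_cylinder_set <- function(concentration_MBq_mL = 0.18,
                              concentration_u_rel = 0,
                              reference_time = NULL) {
  d <- c(C1 = 7.5, C2 = 15, C3 = 30, C4 = 60)
  out <- lapply(names(d), function(id) {
    geom <- cylinder_spec(id, diameter = d[[id]], height = 38)
    act <- cylinder_activity_from_stock(concentration_MBq_mL,
                                        geom$nominal_volume,
                                        concentration_u_rel)
    cylinder_spec(id, diameter = d[[id]], height = 38,
                  activity_kBq = act$activity_MBq * 1000,
                  activity_u_kBq = act$activity_MBq * act$u_rel * 1000,
                  reference_time = reference_time)
  })
  names(out) <- names(d)
  out
}

#' Phantom layout
#'
#' Positions of the cylindrical sources on the mounting baseplate inside a
#' water-filled Jaszczak cylinder. Coordinates are mm offsets of each
#' cylinder axis from the phantom axis, in the baseplate plane; cylinders
#' stand on the baseplate (z = 0) and extend upwards.
#'
#' @param positions `data.frame` with columns `id`, `x`, `y` (mm).
#' @param jaszczak_diameter,jaszczak_height Fillable dimensions in mm.
#' @param wall_margin Clearance (mm) that every cylinder footprint must
#'   keep from the Jaszczak wall.
#' @param water_background_activity_MBq Activity dissolved in the
#'   background water (0 for the calibration measurements).
#' @return An object of class `phantom_layout`.
#' @export
phantom_layout <- function(positions,
                           jaszczak_diameter = 216, jaszczak_height = 186,
                           wall_margin = 5, water_background_activity_MBq = 0) {
  positions <- as.data.frame(positions)
  stopifnot(all(c("id", "x", "y") %in% names(positions)),
            jaszczak_diameter > 0, jaszczak_height > 0, wall_margin >= 0,
            water_background_activity_MBq >= 0)
  if (anyDuplicated(positions$id))
    stop("duplicate cylinder id in layout")
  structure(
    list(positions = positions,
         jaszczak_diameter = jaszczak_diameter,
         jaszczak_height = jaszczak_height,
         wall_margin = wall_margin,
         water_background_activity_MBq = water_background_activity_MBq),
    class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("<phantom_layout> Jaszczak %g x %g mm, %d source(s)\n",
              x$jaszczak_diameter, x$jaszczak_height, nrow(x$positions)))
  print(x$positions, row.names = FALSE)
  invisible(x)
}

#' Validate a phantom layout against a cylinder set
#'
#' Checks the layout invariants: every cylinder footprint lies fully inside
#' the Jaszczak radius minus the wall margin, and no two cylinder
#' footprints overlap. Errors describe the first violation found.
#'
#' @param layout A [phantom_layout()].
#' @param cylinders Named list of [cylinder_spec()] covering every id in
#'   the layout.
#' @return `layout`, invisibly, if valid.
#' @export
validate_phantom_layout <- function(layout, cylinders) {
  stopifnot(inherits(layout, "phantom_layout"))
  pos <- layout$positions
  if (nrow(pos) == 0L) return(invisible(layout))
  missing <- setdiff(pos$id, names(cylinders))
  if (length(missing))
    stop("layout error: no cylinder_spec for id(s) ", paste(missing, collapse = ", "))
  R <- layout$jaszczak_diameter / 2 - layout$wall_margin
  r <- vapply(pos$id, function(id) cylinders[[id]]$diameter / 2, 0)
  rad <- sqrt(pos$x^2 + pos$y^2)
  bad <- which(rad + r > R + 1e-9)
  if (length(bad))
    stop(sprintf("layout error: cylinder %s extends beyond the Jaszczak radius (%.1f + %.1f > %.1f mm)",
                 pos$id[bad[1]], rad[bad[1]], r[bad[1]], R))
  if (nrow(pos) > 1L) {
    for (i in seq_len(nrow(pos) - 1L)) for (j in (i + 1L):nrow(pos)) {
      dij <- sqrt((pos$x[i] - pos$x[j])^2 + (pos$y[i] - pos$y[j])^2)
      if (dij < r[i] + r[j] - 1e-9)
        stop(sprintf("layout error: cylinders %s and %s overlap (centre distance %.1f < %.1f mm)",
                     pos$id[i], pos$id[j], dij, r[i] + r[j]))
    }
  }
  invisible(layout)
}
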