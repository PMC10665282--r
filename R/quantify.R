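#' Radionuclide-calibrator activity measurement with uncertainty budget
#'
#' Holds an assayed activity and the relative standard-uncertainty
#' components of the measurement. The calibration-setting,
#' reproducibility, linearity, background-correction, decay-correction and
#' statistical components are treated as normally distributed; the
#' weighing component is given as the half-width of a rectangular
#' distribution and converted to a standard uncertainty by dividing by
#' sqrt(3).
#'
#' @param activity_MBq Assayed activity in MBq (> 0).
#' @param u_calibration,u_reproducibility,u_linearity,u_background,u_decay,u_statistical
#'   Relative standard uncertainties (fractions), normal.
#' @param u_weighing_halfwidth Relative half-width (fraction) of the
#'   rectangular weighing component.
#' @return An object of class `activity_measurement`.
#' @export
activity_measurement <- function(activity_MBq,
                                 u_calibration = 0, u_reproducibility = 0,
                                 u_linearity = 0, u_background = 0,
                                 u_decay = 0, u_statistical = 0,
                                 u_weighing_halfwidth = 0) {
  comps <- c(calibration = u_calibration, reproducibility = u_reproducibility,
             linearity = u_linearity, background = u_background,
             decay = u_decay, statistical = u_statistical,
             weighing_halfwidth = u_weighing_halfwidth)
  stopifnot(activity_MBq > 0, all(comps >= 0))
  structure(list(activity_MBq = activity_MBq, components = comps),
            class = "activity_measurement")
}

#' Combined relative standard uncertainty of an activity measurement
#'
#' Quadrature of the normal components plus the rectangular weighing
#' half-width divided by sqrt(3).
#'
#' @param measurement An [activity_measurement()], or a bare named vector
#'   of components in the same layout.
#' @return Relative combined standard uncertainty (fraction).
#' @export
activity_uncertainty <- function(measurement) {
  comps <- if (inherits(measurement, "activity_measurement"))
    measurement$components else measurement
  normals <- comps[setdiff(names(comps), "weighing_halfwidth")]
  rect <- if ("weighing_halfwidth" %in% names(comps))
    comps[["weighing_halfwidth"]] else 0
  sqrt(sum(normals^2) + rect^2 / 3)
}

#' Image calibration factor and pseudo image calibration factor
#'
#' The calibration factor is the measured count rate per unit activity:
#' `value = counts / (duration * activity)` in cps/MBq. Measured on a
#' large uniform phantom with an enlarged VOI it is the image calibration
#' factor (ICF); measured on a small cylinder with a volume-matched VOI it
#' is a pseudo-ICF, reduced by partial-volume spill-out.
#'
#' The combined standard uncertainty follows the study's budget:
#' `u_rel = sqrt(1/C + (u_T/T)^2 + u_A_rel^2)`, where the count term is the
#' Poisson assumption on reconstructed counts, `u_T` is the scan-duration
#' uncertainty (1 s by convention), and `u_A_rel` is the relative combined
#' standard uncertainty of the activity (see [activity_uncertainty()]).
#'
#' @param counts Total counts in the VOI (>= 0).
#' @param duration_s Acquisition duration in seconds (> 0).
#' @param activity_MBq Activity at scan start in MBq (> 0), decay-corrected
#'   by the caller (see [decay_correct()]).
#' @param activity_u_rel Relative standard uncertainty of the activity, or
#'   an [activity_measurement()] from which it is computed.
#' @param u_T_s Scan-duration standard uncertainty in seconds.
#' @param kind `"pseudo_ICF"` or `"ICF"`.
#' @param cylinder Optional cylinder id label, used for pairing checks.
#' @return An object of class `icf_result` with elements `value`, `u`
#'   (combined standard uncertainty, cps/MBq), `u_rel`, `counts`,
#'   `duration_s`, `activity_MBq`, `kind`, `cylinder`, and a `components`
#'   breakdown of the relative variance.
#' @export
#' @examples
#' icf(72000, 1800, 1.0)  # 40 cps/MBq
icf <- function(counts, duration_s, activity_MBq, activity_u_rel = 0,
                u_T_s = 1, kind = c("pseudo_ICF", "ICF"), cylinder = NULL) {
  kind <- match.arg(kind)
  if (duration_s <= 0 || activity_MBq <= 0)
    stop("division error: duration and activity must be positive")
  stopifnot(counts >= 0)
  if (inherits(activity_u_rel, "activity_measurement"))
    activity_u_rel <- activity_uncertainty(activity_u_rel)
  value <- counts / (duration_s * activity_MBq)
  comps <- c(counts = if (counts > 0) 1 / counts else 0,
             time = (u_T_s / duration_s)^2,
             activity = activity_u_rel^2)
  u_rel <- sqrt(sum(comps))
  structure(
    list(value = value, u = value * u_rel, u_rel = u_rel,
         counts = counts, duration_s = duration_s,
         activity_MBq = activity_MBq, kind = kind, cylinder = cylinder,
         components = comps),
    class = "icf_result")
}

#' @export
print.icf_result <- function(x, ...) {
  cat(sprintf("<icf_result> %s%s = %.4g +/- %.3g cps/MBq (k=1; C=%.4g, T=%g s, A=%.4g MBq)\n",
              x$kind, if (!is.null(x$cylinder)) paste0("[", x$cylinder, "]") else "",
              x$value, x$u, x$counts, x$duration_s, x$activity_MBq))
  invisible(x)
}

#' Combined standard uncertainty of a calibration factor
#'
#' Standalone form of the budget used inside [icf()]:
#' `u_rel = sqrt(1/C + (u_T/T)^2 + sum(normal^2) + halfwidth^2/3)`.
#'
#' @param counts Counts in the VOI (> 0).
#' @param duration_s Scan duration in s.
#' @param activity_components An [activity_measurement()] or named
#'   component vector (see [activity_uncertainty()]).
#' @param u_T_s Scan-duration standard uncertainty in seconds.
#' @return Relative combined standard uncertainty (fraction).
#' @export
icf_uncertainty <- function(counts, duration_s, activity_components = NULL,
                            u_T_s = 1) {
  if (counts <= 0) stop("budget error: counts must be positive")
  ua <- if (is.null(activity_components)) 0 else
    activity_uncertainty(activity_components)
  sqrt(1 / counts + (u_T_s / duration_s)^2 + ua^2)
}

#' Combine the two solid-source measurements of one cylinder
#'
#' The two independently produced source sets give two pseudo-ICF
#' measurements per cylinder and setup. They are combined as the
#' arithmetic mean; its uncertainty adds, in quadrature, the propagated
#' uncertainty of the average and an allowance for the deviation between
#' the two measurements, treated as a uniform distribution over their
#' range: `u = sqrt((u_a^2 + u_b^2)/4 + (a - b)^2/12)`.
#'
#' @param a,b The two measurements: [icf()] results, or bare numerics
#'   (then give `u_a`, `u_b`).
#' @param u_a,u_b Standard uncertainties when `a`, `b` are numeric.
#' @return An object of class `dual_source_combination` with `mean`, `u`,
#'   and the inputs.
#' @export
#' @examples
#' combine_dual_source(40, 44, u_a = 0, u_b = 0)  # mean 42, u = 4/sqrt(12)
combine_dual_source <- function(a, b, u_a = NULL, u_b = NULL) {
  cyl <- NULL
  if (inherits(a, "icf_result") && inherits(b, "icf_result")) {
    if (!is.null(a$cylinder) && !is.null(b$cylinder) &&
        !identical(a$cylinder, b$cylinder))
      stop("pairing error: measurements are for different cylinders (",
           a$cylinder, " vs ", b$cylinder, ")")
    cyl <- a$cylinder
    u_a <- a$u; u_b <- b$u
    a <- a$value; b <- b$value
  }
  stopifnot(is.numeric(a), is.numeric(b),
            !is.null(u_a), !is.null(u_b), u_a >= 0, u_b >= 0)
  structure(
    list(mean = (a + b) / 2,
         u = sqrt((u_a^2 + u_b^2) / 4 + (a - b)^2 / 12),
         inputs = list(a = a, u_a = u_a, b = b, u_b = u_b),
         cylinder = cyl),
    class = "dual_source_combination")
}

#' @export
print.dual_source_combination <- function(x, ...) {
  cat(sprintf("<dual_source_combination>%s mean = %.4g +/- %.3g cps/MBq (k=1)\n",
              if (!is.null(x$cylinder)) paste0(" [", x$cylinder, "]") else "",
              x$mean, x$u))
  invisible(x)
}

#' Expand a standard uncertainty
#'
#' @param u Standard (k = 1) uncertainty.
#' @param k Coverage factor (default 2, ~95% coverage, the convention used
#'   for the tabulated source activities).
#' @return `k * u`.
#' @export
expand_uncertainty <- function(u, k = 2) k * u
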