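#' Radionuclide specification
#'
#' Bundles the decay and photopeak emission data needed to turn an activity
#' into an expected photopeak count rate: the half-life, the photopeak
#' energy, and the gamma emission probability with its standard uncertainty.
#'
#' @param name Radionuclide label, e.g. `"Ba-133"`.
#' @param half_life_s Half-life in seconds. Must be positive.
#' @param photopeak_keV Photopeak energy in keV (informational).
#' @param emission_probability Probability that a decay emits the photopeak
#'   gamma, as a fraction in (0, 1].
#' @param emission_probability_u Standard uncertainty of
#'   `emission_probability` (same scale), non-negative.
#'
#' @return An object of class `radionuclide_spec`.
#' @seealso [ba133()], [i131()], [decay_correct()]
#' @export
#' @examples
#' radionuclide_spec("Sn-113", 115.1 * 86400, 391.7, 0.6497, 0.0017)
radionuclide_spec <- function(name, half_life_s, photopeak_keV,
                              emission_probability,
                              emission_probability_u = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(half_life_s) || half_life_s <= 0)
    stop("half_life_s must be a positive, finite number of seconds")
  if (!is.finite(emission_probability) ||
      emission_probability <= 0 || emission_probability > 1)
    stop("emission_probability must lie in (0, 1]")
  if (!is.finite(emission_probability_u) || emission_probability_u < 0)
    stop("emission_probability_u must be non-negative")
  structure(
    list(name = name,
         half_life_s = half_life_s,
         photopeak_keV = photopeak_keV,
         emission_probability = emission_probability,
         emission_probability_u = emission_probability_u),
    class = "radionuclide_spec")
}

#' @export
print.radionuclide_spec <- function(x, ...) {
  cat(sprintf("<radionuclide_spec> %s: T1/2 = %.4g d, %g keV, p = %.4f +/- %.4f\n",
              x$name, x$half_life_s / 86400, x$photopeak_keV,
              x$emission_probability, x$emission_probability_u))
  invisible(x)
}

#' Built-in radionuclides
#'
#' `ba133()` returns the Ba-133 specification used for the solid surrogate
#' sources (356 keV photopeak, emission probability 0.6205 +/- 0.0019,
#' half-life 10.5 y). `i131()` returns the I-131 specification (364.5 keV
#' photopeak, emission probability 0.812 +/- 0.005, half-life 8.0252 d,
#' the standard evaluated value).
#'
#' @return A [radionuclide_spec()].
#' @export
ba133 <- function() {
  radionuclide_spec("Ba-133", 10.5 * 365.25 * 86400, 356.0, 0.6205, 0.0019)
}

#' @rdname ba133
#' @export
i131 <- function() {
  radionuclide_spec("I-131", 8.0252 * 86400, 364.5, 0.812, 0.005)
}

#' Decay-correct an activity
#'
#' Applies exponential decay `A(t) = A0 * 2^(-dt / T1/2)` to translate an
#' activity from its assay time to another time (typically the start of the
#' SPECT acquisition). Negative elapsed times back-correct.
#'
#' @param activity Activity at the assay time (any unit; the unit is
#'   preserved).
#' @param half_life_s Half-life in seconds, or a [radionuclide_spec()].
#' @param elapsed_s Elapsed time in seconds from assay to target time. May
#'   be negative. Alternatively supply `from`/`to`.
#' @param from,to `POSIXct` (or anything `difftime`-compatible) assay and
#'   target times, used when `elapsed_s` is `NULL`.
#'
#' @return The decay-corrected activity.
#' @export
#' @examples
#' decay_correct(10304, ba133(), elapsed_s = 365.25 * 86400)  # one year
decay_correct <- function(activity, half_life_s, elapsed_s = NULL,
                          from = NULL, to = NULL) {
  if (inherits(half_life_s, "radionuclide_spec"))
    half_life_s <- half_life_s$half_life_s
  stopifnot(half_life_s > 0)
  if (is.null(elapsed_s)) {
    if (is.null(from) || is.null(to))
      stop("supply either elapsed_s or both from and to")
    elapsed_s <- as.numeric(difftime(to, from, units = "secs"))
  }
  if (any(!is.finite(elapsed_s)))
    stop("elapsed time is not finite")
  activity * 2^(-elapsed_s / half_life_s)
}
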