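#' Lattice spacing conversion: d10 vs surface-to-surface spacing
#'
#' Internally the models work with the surface-to-surface thick-to-thin
#' filament spacing (ssLS), the radial distance a bound cross-bridge tip must
#' span. X-ray diffraction studies report the d10 Bragg spacing, the distance
#' between (1,0) lattice planes of thick-filament centres of mass. In the
#' hexagonal vertebrate filament lattice the thick-to-thin centre distance is
#' (2/3) d10, so the two measures are related by
#' \deqn{ssLS = \frac{2}{3} d_{10} - c,}
#' where the correction factor \eqn{c} absorbs the filament radii. \eqn{c} is
#' not taken from crystallographic radii: it is calibrated so that at the
#' rest spacing (d10 = 34 nm by default) the post-power-stroke cross-bridge
#' at its unstrained axial offset generates neither compressive nor tensile
#' radial force, which ties the model's internal geometry to the
#' experimental axis.
#'
#' `d10_from_ssls()` and `ssls_from_d10()` are mutually inverse on the
#' physical window; spacings outside the studied 30-38 nm d10 window warn
#' but compute.
#'
#' @param d10,ssls Spacings in nm.
#' @param correction Correction factor in nm, from [correction_factor()] or
#'   a [lattice_calibration()].
#' @return Converted spacing in nm.
#' @export
ssls_from_d10 <- function(d10, correction) {
  warn_window(d10)
  ssls <- (2 / 3) * d10 - correction
  if (any(ssls <= 0))
    stop("conversion yields non-positive surface-to-surface spacing",
         call. = FALSE)
  ssls
}

#' @rdname ssls_from_d10
#' @export
d10_from_ssls <- function(ssls, correction) {
  if (any(ssls <= 0))
    stop("surface-to-surface spacing must be positive", call. = FALSE)
  d10 <- 1.5 * (ssls + correction)
  warn_window(d10)
  d10
}

warn_window <- function(d10, window = c(30, 38)) {
  if (any(d10 < window[1] | d10 > window[2]))
    warning("d10 spacing outside the studied 30-38 nm window; ",
            "values are extrapolated", call. = FALSE)
  invisible(d10)
}

#' Calibrate the filament-radius correction factor
#'
#' Finds the surface-to-surface spacing at which the post-power-stroke
#' cross-bridge, held at its unstrained axial offset, exerts zero radial
#' force (by root-finding the radial reaction force over ssLS in (0, 60) nm)
#' and returns the offset mapping that spacing to `rest_d10`:
#' `correction = (2/3) rest_d10 - ssls0`.
#'
#' @param xb A [crossbridge()] with a post-power-stroke rest geometry
#'   (default: the 4sXB with shipped parameters).
#' @param rest_d10 Rest lattice spacing in nm (default 34).
#' @return Correction factor in nm.
#' @examples
#' correction_factor(crossbridge("4sXB")) # ~6.90 nm
#' @export
correction_factor <- function(xb = crossbridge("4sXB"), rest_d10 = 34) {
  if (xb$name == "1sXB")
    stop("the 1sXB has no radial geometry to calibrate", call. = FALSE)
  x0 <- tip_rest(xb, 3)[1]
  frad <- function(y) reaction_force(xb, 3, tip_position(x0, y))[["radial"]]
  lo <- 1; hi <- 59.99
  if (frad(lo) * frad(hi) > 0)
    stop("calibration error: no zero-radial-force spacing in (0, 60) nm",
         call. = FALSE)
  ssls0 <- stats::uniroot(frad, c(lo, hi), tol = 1e-10)$root
  (2 / 3) * rest_d10 - ssls0
}

#' Lattice calibration object
#'
#' Bundles the correction factor with its rest spacing so downstream
#' functions can convert d10 to the internal spacing without recalibrating.
#'
#' @inheritParams correction_factor
#' @return List of class `"xb_lattice"` with `correction`, `rest_d10`,
#'   `rest_ssls` and the calibrated model name.
#' @export
lattice_calibration <- function(xb = crossbridge("4sXB"), rest_d10 = 34) {
  corr <- correction_factor(xb, rest_d10)
  structure(list(correction = corr, rest_d10 = rest_d10,
                 rest_ssls = (2 / 3) * rest_d10 - corr, model = xb$name),
            class = "xb_lattice")
}

#' @export
print.xb_lattice <- function(x, ...) {
  cat(sprintf(
    "<xb_lattice> correction %.4f nm (rest d10 %.3g nm <-> ssLS %.4f nm; %s)\n",
    x$correction, x$rest_d10, x$rest_ssls, x$model))
  invisible(x)
}

as_correction <- function(cal) {
  if (inherits(cal, "xb_lattice")) cal$correction
  else if (is.numeric(cal) && length(cal) == 1L) cal
  else stop("expected a lattice_calibration() or a numeric correction factor",
            call. = FALSE)
}

#' Tip position of a binding site
#'
#' A binding site at axial offset `axial` on a thin filament at lattice
#' spacing `d10` sits at radial separation `ssls_from_d10(d10, correction)`.
#'
#' @param axial Axial offset, nm.
#' @param d10 Lattice spacing, nm.
#' @param cal A [lattice_calibration()] (or numeric correction factor).
#' @return A [tip_position()].
#' @export
site_tip <- function(axial, d10, cal = lattice_calibration()) {
  tip_position(axial, ssls_from_d10(d10, as_correction(cal)))
}
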