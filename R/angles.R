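#' Normalize a gantry angle to [0, 360)
#'
#' Angles follow the IEC 61217 convention: 0 degrees is a beam entering from
#' the patient's anterior, 90 degrees from the patient's left, with angles
#' increasing toward the patient's left. All gantry arithmetic in the package
#' is carried out modulo 360 and reported in `[0, 360)`.
#'
#' @param degrees Numeric vector of angles in degrees (any real values).
#' @return Numeric vector of the same length, reduced to `[0, 360)`.
#' @examples
#' normalize_angle(c(-8, 360, 365, 190.5))
#' @export
normalize_angle <- function(degrees) {
  stopifnot(is.numeric(degrees), all(is.finite(degrees)))
  out <- degrees %% 360
  # guard against 360 - eps rounding artefacts from the modulo
  out[abs(out - 360) < 1e-9] <- 0
  out
}

#' Gantry rotation sign for "lateral" offsets by target laterality
#'
#' Resolves the anatomical directions "medially" / "laterally" into a signed
#' gantry rotation. For a left-sided target the gantry sweeps toward larger
#' IEC angles (over the patient's left hemithorax), so lateral offsets are
#' added; for a right-sided target they are subtracted.
#'
#' @param laterality `"LEFT"` or `"RIGHT"` (case-insensitive).
#' @return `+1` for `"LEFT"`, `-1` for `"RIGHT"`.
#' @examples
#' lateral_sign("LEFT")
#' lateral_sign("right")
#' @export
lateral_sign <- function(laterality) {
  side <- match.arg(toupper(laterality), c("LEFT", "RIGHT"))
  if (side == "LEFT") 1L else -1L
}

#' Smallest absolute angular separation between two gantry angles
#'
#' @param a,b Angles in degrees.
#' @return Separation in `[0, 180]` degrees.
#' @keywords internal
angle_separation <- function(a, b) {
  d <- abs(normalize_angle(a) - normalize_angle(b)) %% 360
  pmin(d, 360 - d)
}

#' Unit direction from isocenter toward the radiation source
#'
#' Patient coordinates are LPS (x toward patient's left, y posterior,
#' z superior), so an anterior source (gantry 0) lies along `-y` and a source
#' at the patient's left (gantry 90) along `+x`.
#'
#' @param gantry_deg Gantry angle, degrees, IEC 61217.
#' @return Length-3 unit vector.
#' @keywords internal
source_direction <- function(gantry_deg) {
  th <- gantry_deg * pi / 180
  c(sin(th), -cos(th), 0)
}
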