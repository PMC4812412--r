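# Back-of-envelope hydraulics: pressure-driven flow through the thin blood
# channel (parallel-plate Poiseuille law) and extracorporeal priming volume.

#' Define a rectangular flow channel
#'
#' @param width_cm Channel extent perpendicular to the flow, cm.
#' @param height_um Channel height (plate gap), micrometers.
#' @param length_cm Channel extent along the flow, cm.
#' @param viscosity_mPa_s Fluid dynamic viscosity, mPa*s. Default 1.0
#'   (water-like); whole blood is nearer 3.
#' @return Object of class `rect_channel` (SI fields `w`, `h`, `Lf`, `mu`).
#'   Warns when the aspect ratio `w/h < 10`, where the parallel-plate
#'   formula loses accuracy.
#' @export
rect_channel <- function(width_cm, height_um, length_cm, viscosity_mPa_s = 1.0) {
  check_positive(width_cm, "width_cm")
  check_positive(height_um, "height_um")
  check_positive(length_cm, "length_cm")
  check_positive(viscosity_mPa_s, "viscosity_mPa_s")
  w <- width_cm * 1e-2
  h <- height_um * 1e-6
  if (w / h < 10)
    warning("aspect ratio w/h < 10: parallel-plate approximation is inaccurate")
  structure(list(w = w, h = h, Lf = length_cm * 1e-2,
                 mu = viscosity_mPa_s * 1e-3), class = "rect_channel")
}

#' Pressure-driven flow through a thin rectangular channel
#'
#' Parallel-plate Poiseuille law `Q = w * h^3 * dP / (12 * mu * L)`;
#' linear in the pressure drop and in `1/mu`, cubic in the gap.
#'
#' @param channel A [rect_channel()].
#' @param delta_p_Pa Applied pressure drop, Pa (>= 0).
#' @return Volumetric flow rate in L/min.
#' @examples
#' ch <- rect_channel(width_cm = 30, height_um = 50, length_cm = 0.3)
#' flow_from_pressure(ch, 14000)   # ~0.87 L/min
#' @export
flow_from_pressure <- function(channel, delta_p_Pa) {
  stopifnot(inherits(channel, "rect_channel"))
  if (!is.numeric(delta_p_Pa) || any(delta_p_Pa < 0))
    stop_invalid("`delta_p_Pa` must be >= 0")
  Q <- channel$w * channel$h^3 * delta_p_Pa / (12 * channel$mu * channel$Lf)
  m3s_to_L_per_min(Q)
}

#' Hydraulic resistance of a thin rectangular channel
#'
#' `R = dP / Q = 12 * mu * L / (w * h^3)`, in Pa/(m^3/s).
#'
#' @param channel A [rect_channel()].
#' @return Resistance in Pa*s/m^3.
#' @export
hydraulic_resistance <- function(channel) {
  stopifnot(inherits(channel, "rect_channel"))
  12 * channel$mu * channel$Lf / (channel$w * channel$h^3)
}

#' Extracorporeal priming volume
#'
#' Blood volume held inside the device: active membrane area times channel
#' height.
#'
#' @param area_cm2 Active membrane area, cm^2.
#' @param height_um Channel height, micrometers.
#' @return Priming volume in microliters.
#' @examples
#' priming_volume(9, 50)   # 45 uL
#' @export
priming_volume <- function(area_cm2, height_um) {
  if (any(area_cm2 < 0) || any(height_um < 0))
    stop_invalid("`area_cm2` and `height_um` must be >= 0")
  (area_cm2 * 1e-4) * (height_um * 1e-6) * 1e9   # m^3 -> uL
}
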