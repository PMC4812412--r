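#' @keywords internal
"_PACKAGE"

# Unit conventions
# ----------------
# All internal fields are SI: m, m^2, m^3/s, m^2/s, mol/s, mol/m^3.
# Constructors accept the mixed units practitioners use for these devices
# (cm^2/s diffusivities, nm radii, mmol/h generation rates, mM concentrations,
# um channel heights, cm^2 membrane areas, L/min blood flows); argument names
# carry the unit as a suffix.  1 mM == 1 mol/m^3, so concentrations need no
# conversion factor.

L_PER_MIN <- 1e-3 / 60      # m^3/s per L/min
L_PER_H   <- 1e-3 / 3600    # m^3/s per L/h
MMOL_PER_H <- 1e-3 / 3600   # mol/s per mmol/h

m3s_to_L_per_h   <- function(q) q / L_PER_H
m3s_to_L_per_min <- function(q) q / L_PER_MIN

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("nanodialyzer_invalid_argument", "error")))
}

stop_infeasible <- function(msg) {
  stop(errorCondition(msg, class = c("nanodialyzer_infeasible_design", "error")))
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid(sprintf("`%s` must be a single positive finite number", what))
  invisible(x)
}

#' Define a plasma solute
#'
#' Bundles the transport and kinetic properties of a blood solute: its free
#' diffusion coefficient, hydrodynamic (Stokes) radius, and optionally the
#' endogenous generation rate and the healthy physiological plasma
#' concentration used by the adequacy model.
#'
#' @param name Solute name.
#' @param D0_cm2_s Free diffusion coefficient in plasma/water, cm^2/s.
#' @param radius_nm Hydrodynamic radius, nm.
#' @param generation_mmol_h Endogenous generation rate, mmol/h (optional).
#' @param conc_mM Healthy physiological plasma concentration, mM (optional).
#' @param target_L_per_h Target clearance-volume product, L/h (optional;
#'   when absent it is derived as generation rate / physiological
#'   concentration).
#' @return An object of class `solute` with SI fields `D0` (m^2/s), `rs` (m),
#'   `G` (mol/s or `NA`), `C` (mol/m^3 or `NA`), `target` (m^3/s or `NA`).
#' @examples
#' urea <- solute("urea", D0_cm2_s = 1.38e-5, radius_nm = 0.26,
#'                conc_mM = 4.6, target_L_per_h = 2.3)
#' @export
solute <- function(name, D0_cm2_s, radius_nm,
                   generation_mmol_h = NA_real_, conc_mM = NA_real_,
                   target_L_per_h = NA_real_) {
  check_positive(D0_cm2_s, "D0_cm2_s")
  check_positive(radius_nm, "radius_nm")
  if (!is.na(generation_mmol_h) && generation_mmol_h < 0)
    stop_invalid("`generation_mmol_h` must be >= 0 when supplied")
  if (!is.na(conc_mM) && conc_mM <= 0)
    stop_invalid("`conc_mM` must be > 0 when supplied")
  structure(list(
    name = as.character(name),
    D0 = D0_cm2_s * 1e-4,
    rs = radius_nm * 1e-9,
    G = if (is.na(generation_mmol_h)) NA_real_ else generation_mmol_h * MMOL_PER_H,
    C = if (is.na(conc_mM)) NA_real_ else conc_mM,  # mM == mol/m^3
    target = if (is.na(target_L_per_h)) NA_real_ else target_L_per_h * L_PER_H
  ), class = "solute")
}

#' @export
print.solute <- function(x, ...) {
  cat(sprintf("<solute> %s\n  D0 = %.3g cm^2/s, rs = %.3g nm\n",
              x$name, x$D0 * 1e4, x$rs * 1e9))
  if (!is.na(x$G)) cat(sprintf("  generation = %.3g mmol/h\n", x$G / MMOL_PER_H))
  if (!is.na(x$C)) cat(sprintf("  physiological concentration = %.3g mM\n", x$C))
  if (!is.na(x$target)) cat(sprintf("  target clearance = %.3g L/h\n", m3s_to_L_per_h(x$target)))
  invisible(x)
}

#' Define a nanoporous membrane
#'
#' Physical description of an ultrathin nanoporous membrane: thickness,
#' mean pore diameter and porosity (open-area fraction). The pore-size
#' distribution is collapsed to a single mean diameter.
#'
#' @param thickness_nm Membrane thickness, nm.
#' @param pore_nm Mean pore diameter, nm.
#' @param porosity Open-area fraction in (0, 1]. Default 0.03, within the
#'   reported porosity range of porous nanocrystalline silicon membranes.
#' @return Object of class `membrane` with SI fields `d` (m),
#'   `pore_diameter` (m), `porosity`.
#' @examples
#' membrane(thickness_nm = 50, pore_nm = 23)
#' @export
membrane <- function(thickness_nm = 50, pore_nm, porosity = 0.03) {
  check_positive(thickness_nm, "thickness_nm")
  check_positive(pore_nm, "pore_nm")
  check_positive(porosity, "porosity")
  if (porosity > 1) stop_invalid("`porosity` must lie in (0, 1]")
  structure(list(
    d = thickness_nm * 1e-9,
    pore_diameter = pore_nm * 1e-9,
    porosity = porosity
  ), class = "membrane")
}

#' @export
print.membrane <- function(x, ...) {
  cat(sprintf("<membrane> d = %g nm, pore diameter = %g nm, porosity = %g\n",
              x$d * 1e9, x$pore_diameter * 1e9, x$porosity))
  invisible(x)
}

#' Define a dialyzer flow-channel design
#'
#' Geometry and flow condition of the blood channel: channel height (the
#' wall-to-membrane distance), active membrane area, optionally the membrane
#' length along the flow and the channel width, the fraction of the channel
#' width covered by active membrane, and either the volumetric blood flow
#' rate or the mean flow velocity (the other is derived when the
#' cross-section is known).
#'
#' @param channel_height_um Wall-to-membrane distance a, micrometers.
#' @param membrane_area_cm2 Active membrane area A, cm^2.
#' @param flow_L_min Volumetric blood flow rate, L/min (optional).
#' @param velocity_mm_s Mean flow velocity, mm/s (optional).
#' @param membrane_length_mm Membrane extent along the flow direction, mm
#'   (optional; enables the length/velocity residence-time path).
#' @param channel_width_mm Blood-channel width, mm (optional; converts
#'   between flow rate and velocity).
#' @param coverage Fraction of the channel width overlain by active
#'   membrane, in (0, 1]. Applied multiplicatively to fractional clearance.
#' @return Object of class `dialyzer_design` with SI fields `a`, `A`, `L`,
#'   `W`, `Q`, `v`, `coverage` (`NA` where not derivable).
#' @examples
#' dialyzer_design(channel_height_um = 50, membrane_area_cm2 = 9,
#'                 flow_L_min = 0.85)
#' @export
dialyzer_design <- function(channel_height_um, membrane_area_cm2,
                            flow_L_min = NA_real_, velocity_mm_s = NA_real_,
                            membrane_length_mm = NA_real_,
                            channel_width_mm = NA_real_,
                            coverage = 1) {
  check_positive(channel_height_um, "channel_height_um")
  check_positive(membrane_area_cm2, "membrane_area_cm2")
  check_positive(coverage, "coverage")
  if (coverage > 1) stop_invalid("`coverage` must lie in (0, 1]")
  if (is.na(flow_L_min) && is.na(velocity_mm_s))
    stop_invalid("one of `flow_L_min` or `velocity_mm_s` must be given")

  a <- channel_height_um * 1e-6
  A <- membrane_area_cm2 * 1e-4
  W <- if (is.na(channel_width_mm)) NA_real_ else channel_width_mm * 1e-3
  L <- if (is.na(membrane_length_mm)) NA_real_ else membrane_length_mm * 1e-3
  Q <- if (is.na(flow_L_min)) NA_real_ else flow_L_min * L_PER_MIN
  v <- if (is.na(velocity_mm_s)) NA_real_ else velocity_mm_s * 1e-3
  if (!is.na(Q) && Q <= 0) stop_invalid("`flow_L_min` must be > 0")
  if (!is.na(v) && v <= 0) stop_invalid("`velocity_mm_s` must be > 0")
  # derive the missing flow descriptor where the cross-section is known
  if (is.na(v) && !is.na(W)) v <- Q / (W * a)
  if (is.na(Q) && !is.na(W)) Q <- v * W * a
  structure(list(a = a, A = A, L = L, W = W, Q = Q, v = v,
                 coverage = coverage), class = "dialyzer_design")
}

#' @export
print.dialyzer_design <- function(x, ...) {
  cat(sprintf("<dialyzer design> a = %g um, A = %g cm^2, coverage = %g\n",
              x$a * 1e6, x$A * 1e4, x$coverage))
  if (!is.na(x$Q)) cat(sprintf("  blood flow = %.4g L/min\n", m3s_to_L_per_min(x$Q)))
  if (!is.na(x$v)) cat(sprintf("  mean velocity = %.4g mm/s\n", x$v * 1e3))
  if (!is.na(x$L)) cat(sprintf("  membrane length (flow dir.) = %g mm\n", x$L * 1e3))
  cat(sprintf("  residence time = %.4g s\n", residence_time(x)))
  invisible(x)
}
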