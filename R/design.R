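# Three-step design selection
# ---------------------------
# For a fixed active membrane area the design space (channel height a,
# blood flow Q, pore diameter) is reduced lexicographically:
#   1. at each a, fix urea clearance at its target, which pins Q
#      (pore size is irrelevant for urea: beta is tiny);
#   2. given Q(a), fix albumin clearance at its target, which pins the pore
#      diameter through the membrane-resistance (Robin) model;
#   3. evaluate the middle-molecule (beta2-microglobulin) clearance along
#      the resulting one-parameter family and maximise it over a, subject
#      to an optional practicality floor on a.

FLOW_BRACKET_L_MIN <- c(1e-3, 100)   # search bracket for Q, L/min
PORE_BRACKET_MAX_NM <- 200           # upper pore-diameter bracket, nm

#' Blood flow satisfying the urea clearance target
#'
#' Solves `Q * f_urea(Q; a, A) = target` for the volumetric blood flow by
#' bracketed root finding.  The membrane is ignored (urea's `beta` is always
#' tiny) so the perfect-sink series is used.  `Q*f` grows like `sqrt(Q)` in
#' the short-residence regime, so the root is unique.
#'
#' @param channel_height_um Channel height a, micrometers.
#' @param area_cm2 Active membrane area, cm^2.
#' @param urea Urea [solute()] (only `D0` is used).
#' @param target_L_per_h Target urea clearance, L/h.
#' @param flow_bracket_L_min Search bracket for Q, L/min.
#' @return Blood flow in L/min.
#' @examples
#' u <- solute("urea", 1.38e-5, 0.26)
#' urea_isoline(50, 9, u, 2.3)    # ~0.77 L/min
#' @export
urea_isoline <- function(channel_height_um, area_cm2, urea, target_L_per_h,
                         flow_bracket_L_min = FLOW_BRACKET_L_MIN) {
  stopifnot(inherits(urea, "solute"))
  check_positive(channel_height_um, "channel_height_um")
  check_positive(area_cm2, "area_cm2")
  if (target_L_per_h == 0) return(0)
  check_positive(target_L_per_h, "target_L_per_h")
  g <- function(Q_L_min) {
    d <- dialyzer_design(channel_height_um, area_cm2, flow_L_min = Q_L_min)
    cr <- fractional_clearance(d, urea, membrane = NULL, model = "sink")
    m3s_to_L_per_h(d$Q) * cr$fractional_clearance - target_L_per_h
  }
  lo <- g(flow_bracket_L_min[1]); hi <- g(flow_bracket_L_min[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    stop_infeasible(sprintf(
      "urea target %.3g L/h unreachable for a = %g um within Q in [%g, %g] L/min",
      target_L_per_h, channel_height_um,
      flow_bracket_L_min[1], flow_bracket_L_min[2]))
  stats::uniroot(g, flow_bracket_L_min, tol = 1e-10)$root
}

#' Pore diameter satisfying the albumin clearance target
#'
#' Given the blood flow pinned by the urea constraint, solves
#' `Q * f_albumin(pore) = target` for the mean pore diameter using the
#' membrane-resistance model with hindered-pore diffusivity.  Albumin
#' clearance increases monotonically with pore size on the bracket
#' `(2*rs_albumin, 200 nm]`, so the root is unique when it exists.
#'
#' @param channel_height_um Channel height a, micrometers.
#' @param flow_L_min Blood flow, L/min (from [urea_isoline()]).
#' @param area_cm2 Active membrane area, cm^2.
#' @param albumin Albumin [solute()].
#' @param membrane_template A [membrane()] providing thickness and porosity
#'   (its pore diameter is the unknown).
#' @param target_L_per_h Target albumin clearance, L/h.
#' @param hindrance_model Hindrance model used for `Dm`.
#' @return Pore diameter in nm.
#' @export
albumin_isocurve <- function(channel_height_um, flow_L_min, area_cm2,
                             albumin, membrane_template = membrane(pore_nm = 20),
                             target_L_per_h, hindrance_model = "renkin") {
  stopifnot(inherits(albumin, "solute"), inherits(membrane_template, "membrane"))
  check_positive(flow_L_min, "flow_L_min")
  check_positive(target_L_per_h, "target_L_per_h")
  d <- dialyzer_design(channel_height_um, area_cm2, flow_L_min = flow_L_min)
  Q_L_h <- m3s_to_L_per_h(d$Q)
  g <- function(pore_nm) {
    m <- membrane(thickness_nm = membrane_template$d * 1e9, pore_nm = pore_nm,
                  porosity = membrane_template$porosity)
    # the Robin series is the general solution, exact for every beta > 0;
    # forcing it avoids the discontinuity of the beta-switch rule, which
    # would otherwise leave the root equation without a zero crossing when
    # the solution falls near the switch
    cr <- fractional_clearance(d, albumin, m, model = "robin",
                               hindrance_model = hindrance_model)
    Q_L_h * cr$fractional_clearance - target_L_per_h
  }
  lo_nm <- 2 * albumin$rs * 1e9 * (1 + 1e-6)
  lo <- g(lo_nm); hi <- g(PORE_BRACKET_MAX_NM)
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    stop_infeasible(sprintf(
      "albumin target %.3g L/h unreachable for a = %g um on pore bracket (%.3g, %g] nm",
      target_L_per_h, channel_height_um, lo_nm, PORE_BRACKET_MAX_NM))
  stats::uniroot(g, c(lo_nm, PORE_BRACKET_MAX_NM), tol = 1e-9)$root
}

#' Select a dialyzer design
#'
#' Runs the three-step selection over a grid of channel heights: urea
#' isoline pins the flow, albumin isocurve pins the pore size, and the
#' middle-molecule clearance-volume product is evaluated along the
#' resulting family.  Returns the whole curve, its argmax, and (when a
#' practicality floor `min_height_um` is supplied) the recommended
#' compromise: the best height at or above the floor.
#'
#' @param area_cm2 Active membrane area, cm^2.
#' @param solutes Named list with elements `urea`, `albumin`, `beta2m`
#'   ([solute()] objects).
#' @param targets Named numeric vector/list with urea and albumin target
#'   clearances in L/h (e.g. `c(urea = 2.3, albumin = 0.015)`).
#' @param heights_um Grid of channel heights, micrometers. Default 40
#'   log-spaced points over 10-500 um.
#' @param membrane_template [membrane()] supplying thickness and porosity.
#' @param min_height_um Optional practicality floor on the channel height.
#' @param hindrance_model Hindrance model name.
#' @return List of class `design_selection`: `curve` (data.frame with
#'   `height_um`, `flow_L_min`, `pore_nm`, `beta2m_L_per_h`, `feasible`,
#'   `note`), `argmax` and `recommended` (rows of `curve`), and
#'   `hindrance_model`.
#' @export
select_design <- function(area_cm2, solutes, targets,
                          heights_um = exp(seq(log(10), log(500), length.out = 40)),
                          membrane_template = membrane(pore_nm = 20),
                          min_height_um = NULL,
                          hindrance_model = "renkin") {
  stopifnot(all(c("urea", "albumin", "beta2m") %in% names(solutes)))
  targets <- as.list(targets)
  stopifnot(all(c("urea", "albumin") %in% names(targets)))
  rows <- lapply(heights_um, function(a_um) {
    res <- tryCatch({
      Q <- urea_isoline(a_um, area_cm2, solutes$urea, targets$urea)
      pore <- albumin_isocurve(a_um, Q, area_cm2, solutes$albumin,
                               membrane_template, targets$albumin,
                               hindrance_model = hindrance_model)
      d <- dialyzer_design(a_um, area_cm2, flow_L_min = Q)
      m <- membrane(thickness_nm = membrane_template$d * 1e9, pore_nm = pore,
                    porosity = membrane_template$porosity)
      cr <- fractional_clearance(d, solutes$beta2m, m,
                                 hindrance_model = hindrance_model)
      data.frame(height_um = a_um, flow_L_min = Q, pore_nm = pore,
                 beta2m_L_per_h = m3s_to_L_per_h(d$Q) * cr$fractional_clearance,
                 feasible = TRUE, note = "", stringsAsFactors = FALSE)
    }, nanodialyzer_infeasible_design = function(e) {
      data.frame(height_um = a_um, flow_L_min = NA_real_, pore_nm = NA_real_,
                 beta2m_L_per_h = NA_real_, feasible = FALSE,
                 note = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  curve <- do.call(rbind, rows)
  feas <- curve[curve$feasible, , drop = FALSE]
  if (nrow(feas) == 0) {
    stop_infeasible(paste("no feasible design on the height grid:",
                          paste(unique(curve$note), collapse = "; ")))
  }
  argmax <- feas[which.max(feas$beta2m_L_per_h), , drop = FALSE]
  ok <- feas
  if (!is.null(min_height_um)) {
    ok <- feas[feas$height_um >= min_height_um, , drop = FALSE]
    if (nrow(ok) == 0)
      stop_infeasible("no feasible design at or above the practicality floor")
  }
  # practicality tie-break: the middle-molecule clearance saturates once the
  # membrane dominates the resistance, so among heights within 1% of the
  # constrained maximum pick the smallest (lowest blood flow on the urea
  # isoline)
  best <- max(ok$beta2m_L_per_h)
  near <- ok[ok$beta2m_L_per_h >= 0.99 * best, , drop = FALSE]
  recommended <- near[which.min(near$height_um), , drop = FALSE]
  structure(list(curve = curve, argmax = argmax, recommended = recommended,
                 area_cm2 = area_cm2, hindrance_model = hindrance_model),
            class = "design_selection")
}

#' @export
print.design_selection <- function(x, ...) {
  r <- x$recommended
  cat(sprintf(
    "<design selection> A = %g cm^2 (%d feasible heights, hindrance = %s)\n",
    x$area_cm2, sum(x$curve$feasible), x$hindrance_model))
  cat(sprintf(
    "  recommended: a = %.3g um, Q = %.3g L/min, pore = %.3g nm, beta2m clearance = %.3g L/h\n",
    r$height_um, r$flow_L_min, r$pore_nm, r$beta2m_L_per_h))
  if (!identical(r$height_um, x$argmax$height_um))
    cat(sprintf("  (global argmax at a = %.3g um: %.3g L/h)\n",
                x$argmax$height_um, x$argmax$beta2m_L_per_h))
  invisible(x)
}

#' Membrane-coverage correction
#'
#' Scales an ideal-geometry fractional clearance by the fraction of the
#' blood-channel width actually overlain by active membrane.
#'
#' @param f Fractional clearance in `[0, 1]`.
#' @param coverage Coverage fraction in `[0, 1]`.
#' @return `coverage * f`.
#' @export
coverage_correction <- function(f, coverage) {
  if (any(f < 0 | f > 1)) stop_invalid("`f` must lie in [0, 1]")
  if (any(coverage < 0 | coverage > 1)) stop_invalid("`coverage` must lie in [0, 1]")
  coverage * f
}
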