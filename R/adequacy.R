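# Dialysis adequacy under continuous treatment
# --------------------------------------------
# During continuous dialysis the plasma concentration of a toxin settles
# where endogenous generation balances removal:
#   G = Q * C * f,
# with G the generation rate, Q the blood flow through the dialyzer, C the
# steady-state plasma concentration and f the single-pass fractional
# clearance.  The clearance-volume product Q*f plays the role of a renal
# clearance; the treatment is adequate for a solute when Q*f reaches
# G / C_physiological.

#' Target clearance-volume product for a solute
#'
#' The clearance `Q*f` needed to hold the solute at its healthy
#' physiological plasma level: generation rate divided by physiological
#' concentration. When kinetics are incomplete but the solute carries a
#' stored target (e.g. urea, whose generation rate is bundled only as the
#' ratio), the stored target is returned.
#'
#' @param solute A [solute()] with generation rate and physiological
#'   concentration (or a stored target).
#' @return Target clearance in L/h.
#' @examples
#' creat <- solute("creatinine", 1.0e-5, 0.33,
#'                 generation_mmol_h = 0.58, conc_mM = 0.11)
#' required_clearance(creat)   # ~5.3 L/h
#' @export
required_clearance <- function(solute) {
  stopifnot(inherits(solute, "solute"))
  if (!is.na(solute$G) && !is.na(solute$C)) {
    if (solute$G == 0) return(0)
    return(m3s_to_L_per_h(solute$G / solute$C))
  }
  if (!is.na(solute$target)) return(m3s_to_L_per_h(solute$target))
  stop_invalid(sprintf(
    "solute '%s' lacks generation rate + physiological concentration (or a stored target)",
    solute$name))
}

#' Steady-state plasma concentration during continuous treatment
#'
#' `C_ss = G / (Q * f)`.  A solute that is not cleared at all (`f = 0`)
#' has no steady state: the function then returns an explicit
#' `no_steady_state` marker object rather than a number.
#'
#' @param solute A [solute()] with a generation rate (or physiological
#'   concentration plus stored target, from which G is implied).
#' @param flow_L_min Blood flow through the dialyzer, L/min.
#' @param f Single-pass fractional clearance in `[0, 1]`.
#' @return Steady-state concentration in mM, or a `no_steady_state` object
#'   when `f = 0`.
#' @export
steady_state_concentration <- function(solute, flow_L_min, f) {
  stopifnot(inherits(solute, "solute"))
  check_positive(flow_L_min, "flow_L_min")
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1)
    stop_invalid("`f` must lie in [0, 1]")
  if (f == 0) return(no_steady_state(solute$name))
  G <- solute_generation(solute)
  Q <- flow_L_min * L_PER_MIN
  G / (Q * f)   # mol/m^3 == mM
}

# generation rate in mol/s, implied from target * C when not stored directly
solute_generation <- function(solute) {
  if (!is.na(solute$G)) return(solute$G)
  if (!is.na(solute$target) && !is.na(solute$C)) return(solute$target * solute$C)
  stop_invalid(sprintf("solute '%s' has no generation rate", solute$name))
}

#' @rdname steady_state_concentration
#' @param name Solute name carried by the marker.
#' @export
no_steady_state <- function(name = NA_character_) {
  structure(list(solute = name), class = "no_steady_state")
}

#' @export
print.no_steady_state <- function(x, ...) {
  cat(sprintf("<no steady state> '%s' accumulates without bound (f = 0)\n",
              x$solute))
  invisible(x)
}

#' Adequacy table for a design
#'
#' For each solute: membrane resistance `beta`, the series model selected by
#' the switch rule, single-pass fractional clearance, the clearance-volume
#' product `Q*f`, the target clearance, and the steady-state plasma
#' concentration during continuous treatment.
#'
#' @param design A [dialyzer_design()] (must carry a flow rate).
#' @param membrane A [membrane()], or `NULL` for an ideal membrane.
#' @param solutes List of [solute()] objects.
#' @param hindrance_model Hindrance model used for `beta`.
#' @param digits Significant digits for the printed summary (full precision
#'   is kept in the returned data frame).
#' @return `data.frame` with one row per solute (input order): `solute`,
#'   `beta`, `model`, `f`, `achieved_L_per_h`, `target_L_per_h`,
#'   `steady_state_mM`, `physiological_mM`, `accumulates`.
#' @export
adequacy_table <- function(design, membrane = NULL, solutes,
                           hindrance_model = "renkin", digits = 2) {
  stopifnot(inherits(design, "dialyzer_design"))
  if (inherits(solutes, "solute")) solutes <- list(solutes)
  if (is.na(design$Q)) stop_invalid("design must carry a volumetric flow rate")
  Q_L_h <- m3s_to_L_per_h(design$Q)
  rows <- lapply(solutes, function(s) {
    cr <- fractional_clearance(design, s, membrane,
                               hindrance_model = hindrance_model)
    f <- cr$fractional_clearance
    achieved <- Q_L_h * f
    target <- tryCatch(required_clearance(s), error = function(e) NA_real_)
    css <- if (f > 0) {
      tryCatch(steady_state_concentration(s, m3s_to_L_per_min(design$Q), f),
               error = function(e) NA_real_)
    } else NA_real_
    data.frame(solute = s$name, beta = cr$beta, model = cr$model_used,
               f = f, achieved_L_per_h = achieved, target_L_per_h = target,
               steady_state_mM = if (is.numeric(css)) css else NA_real_,
               physiological_mM = s$C, accumulates = (f == 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "digits") <- digits
  class(out) <- c("adequacy_table", "data.frame")
  out
}

#' @export
print.adequacy_table <- function(x, ...) {
  digits <- attr(x, "digits")
  if (is.null(digits)) digits <- 2
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
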