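# Dimensionless 1-D transport model of the blood channel
# -------------------------------------------------------
# The blood channel is bounded by an impermeable wall (xbar = 0) and the
# nanomembrane (xbar = 1).  Under plug flow with negligible axial diffusion
# the cross-channel concentration obeys the dimensionless diffusion equation
#   dc/dtbar = d2c/dxbar2,  tbar = t * D0 / a^2,
# with no flux at the wall, uniform initial concentration 1, and either a
# perfect-sink condition c(1) = 0 or, when the membrane itself resists
# diffusion, the Robin condition c(1) + beta * dc/dx(1) = 0 where
#   beta = (d / Dm) / (a / D0)
# is the ratio of membrane to channel diffusive resistance.

MAX_SERIES_TERMS <- 100000L
SERIES_RTOL <- 1e-14
SHORT_TIME_TBAR <- 1e-6     # below this, use the half-space closed form
BETA_SWITCH_DEFAULT <- 0.2  # sink model selected when beta < this

#' Sink-model eigenvalues
#'
#' Eigenvalues of the perfect-sink (Dirichlet) diffusion problem,
#' `lambda_n = pi * (n - 1/2)`.
#'
#' @param n_terms Number of eigenvalues.
#' @return Numeric vector of length `n_terms`, strictly increasing with
#'   spacing `pi`.
#' @export
dirichlet_eigenvalues <- function(n_terms) {
  if (!is.numeric(n_terms) || length(n_terms) != 1L || n_terms < 1)
    stop_invalid("`n_terms` must be a positive count")
  pi * (seq_len(as.integer(n_terms)) - 0.5)
}

#' Membrane-resistance (Robin) eigenvalues
#'
#' The `n_terms` smallest positive roots `z_n` of the transcendental
#' eigencondition `tan(z) = 1 / (beta * z)`.  One root lies in each interval
#' `((n-1)*pi, (n-1)*pi + pi/2)`; roots are located by bracketed root
#' finding on the singularity-free form `beta*z*sin(z) - cos(z) = 0` and
#' polished by Newton steps.  As `beta -> 0` the roots approach the sink
#' eigenvalues `pi*(n - 1/2)`.
#'
#' @param beta Dimensionless membrane resistance, > 0. Use
#'   [dirichlet_eigenvalues()] for the sink limit `beta = 0`.
#' @param n_terms Number of roots.
#' @return Ascending numeric vector of roots.
#' @examples
#' robin_eigenvalues(1, 3)   # z1 ~ 0.86033
#' @export
robin_eigenvalues <- function(beta, n_terms) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop_invalid("`beta` must be > 0 (sink limit handled by dirichlet_eigenvalues)")
  if (!is.numeric(n_terms) || length(n_terms) != 1L || n_terms < 1)
    stop_invalid("`n_terms` must be a positive count")
  n_terms <- as.integer(n_terms)
  g <- function(z) beta * z * sin(z) - cos(z)
  z <- vapply(seq_len(n_terms), function(k) {
    lo <- (k - 1) * pi
    hi <- lo + pi / 2
    # asymptotic shortcuts when the root sits within rounding of a bracket
    # end: large beta pushes roots onto (k-1)*pi (z ~ lo + 1/(beta*lo)),
    # small beta pushes them onto the sink eigenvalue (z ~ hi - beta*hi)
    if (k >= 2 && 1 / (beta * lo) < 1e-11) return(lo + 1 / (beta * lo))
    if (beta * hi < 1e-11) return(hi - beta * hi)
    r <- stats::uniroot(g, c(lo + 1e-13, hi - 1e-13), tol = 1e-14,
                        check.conv = FALSE)$root
    # Newton polish on the same singularity-free form
    for (i in 1:3) {
      fz <- beta * r * sin(r) - cos(r)
      dfz <- beta * sin(r) + beta * r * cos(r) + sin(r)
      step <- fz / dfz
      if (!is.finite(step)) break
      r2 <- r - step
      if (r2 > lo && r2 < hi) r <- r2
    }
    r
  }, numeric(1))
  z
}

#' Series coefficients of the membrane-resistance model
#'
#' `C_n = 2*sin(z_n) / (z_n + sin(z_n)*cos(z_n))` for Robin eigenvalues
#' `z_n`.
#'
#' @param eigenvalues Positive, ascending eigenvalues (from
#'   [robin_eigenvalues()]).
#' @return Numeric vector of coefficients.
#' @export
robin_coefficients <- function(eigenvalues) {
  if (!is.numeric(eigenvalues) || length(eigenvalues) < 1L ||
      any(!is.finite(eigenvalues)) || any(eigenvalues <= 0))
    stop_invalid("`eigenvalues` must be positive numbers")
  if (is.unsorted(eigenvalues, strictly = TRUE))
    stop_invalid("`eigenvalues` must be strictly ascending")
  2 * sin(eigenvalues) / (eigenvalues + sin(eigenvalues) * cos(eigenvalues))
}

# number of series terms needed so the smallest retained factor
# exp(-lambda_n^2 tbar) is below double-precision noise
series_terms_needed <- function(tbar) {
  if (tbar <= 0) return(MAX_SERIES_TERMS)
  n <- ceiling(sqrt(42 / tbar) / pi + 0.5)
  as.integer(min(max(n, 8L), MAX_SERIES_TERMS))
}

#' Pointwise dimensionless concentration
#'
#' Evaluates the series solution for the dimensionless concentration
#' `cbar(xbar, tbar)` in the blood channel, using the perfect-sink series
#' when `beta` is below the model-switch threshold (or when forced) and the
#' membrane-resistance (Robin) series otherwise.
#'
#' @param xbar Dimensionless position(s) in `[0, 1]` (0 = wall,
#'   1 = membrane).
#' @param tbar Dimensionless time `t*D0/a^2`, >= 0.
#' @param beta Dimensionless membrane resistance, >= 0.
#' @param model `"auto"` (default, sink iff `beta < beta_switch`), `"sink"`
#'   or `"robin"`.
#' @param n_terms Number of series terms; default adapts to `tbar`.
#' @param beta_switch Model-switch threshold on `beta` (default 0.2).
#' @return Numeric vector of concentrations, same length as `xbar`.
#' @export
concentration_profile <- function(xbar, tbar, beta = 0,
                                  model = c("auto", "sink", "robin"),
                                  n_terms = NULL,
                                  beta_switch = BETA_SWITCH_DEFAULT) {
  model <- match.arg(model)
  if (any(xbar < 0 | xbar > 1)) stop_invalid("`xbar` must lie in [0, 1]")
  if (!is.numeric(tbar) || length(tbar) != 1L || tbar < 0)
    stop_invalid("`tbar` must be a single number >= 0")
  model <- resolve_model(model, beta, beta_switch)
  if (is.null(n_terms)) n_terms <- max(series_terms_needed(tbar), 2000L)
  if (model == "sink") {
    lam <- dirichlet_eigenvalues(n_terms)
    n <- seq_len(n_terms)
    coef <- (2 / pi) * (-1)^(n + 1) / (n - 0.5)
  } else {
    lam <- robin_eigenvalues(beta, min(n_terms, 5000L))
    coef <- robin_coefficients(lam)
  }
  decay <- exp(-lam^2 * tbar)
  out <- as.numeric(cos(outer(xbar, lam)) %*% (coef * decay))
  if (tbar > 0) pmin(pmax(out, 0), 1) else out
}

resolve_model <- function(model, beta, beta_switch) {
  if (model != "auto") return(model)
  if (beta < beta_switch) "sink" else "robin"
}

#' Cross-channel mean concentration
#'
#' The fraction of the initial solute content remaining in the channel at
#' dimensionless time `tbar`: the average of `cbar` over `xbar`.  Sink
#' model: `2 * sum(exp(-lambda_n^2 tbar) / lambda_n^2)`; Robin model:
#' `sum(C_n * sin(z_n)/z_n * exp(-z_n^2 tbar))`.  For very small `tbar`
#' (`< 1e-6`) the series converges slowly and the half-space closed form is
#' used instead (`1 - 2*sqrt(tbar/pi)` at `beta = 0`; its surface-resistance
#' generalisation via the scaled complementary error function otherwise).
#'
#' @inheritParams concentration_profile
#' @return Mean concentration in `[0, 1]`, monotone non-increasing in
#'   `tbar` and non-decreasing in `beta`.
#' @examples
#' mean_concentration(0.1)          # ~0.6433
#' @export
mean_concentration <- function(tbar, beta = 0,
                               model = c("auto", "sink", "robin"),
                               n_terms = NULL,
                               beta_switch = BETA_SWITCH_DEFAULT) {
  model <- match.arg(model)
  if (!is.numeric(tbar) || length(tbar) != 1L || !is.finite(tbar) || tbar < 0)
    stop_invalid("`tbar` must be a single finite number >= 0")
  if (beta < 0) stop_invalid("`beta` must be >= 0")
  if (tbar == 0) return(1)
  model <- resolve_model(model, beta, beta_switch)
  beta_eff <- if (model == "sink") 0 else beta
  if (tbar < SHORT_TIME_TBAR) return(max(1 - halfspace_removed(tbar, beta_eff), 0))
  if (model == "sink") {
    N <- if (is.null(n_terms)) series_terms_needed(tbar) else as.integer(n_terms)
    lam <- dirichlet_eigenvalues(N)
    terms <- 2 * exp(-lam^2 * tbar) / lam^2
  } else {
    N <- if (is.null(n_terms)) min(series_terms_needed(tbar), 20000L) else as.integer(n_terms)
    z <- robin_eigenvalues(beta, N)
    Cn <- robin_coefficients(z)
    terms <- Cn * sin(z) / z * exp(-z^2 * tbar)
  }
  # adaptive truncation: drop the negligible tail
  csum <- cumsum(terms)
  keep <- which(abs(terms) >= SERIES_RTOL * abs(csum))
  val <- if (length(keep)) csum[max(keep)] else csum[length(csum)]
  min(max(val, 0), 1)
}

# Fraction of a unit-depth channel's content removed through the membrane
# face in the half-space (short-time) limit, with surface resistance beta:
#   M(tbar) = beta * (erfcx(sqrt(tbar)/beta) - 1) + 2*sqrt(tbar/pi),
# reducing to 2*sqrt(tbar/pi) at beta = 0.
halfspace_removed <- function(tbar, beta) {
  if (beta <= 0) return(2 * sqrt(tbar / pi))
  u <- sqrt(tbar) / beta
  beta * (pracma::erfcx(u) - 1) + 2 * sqrt(tbar / pi)
}

#' Dimensionless membrane resistance
#'
#' `beta = (d / Dm) / (a / D0)`: the membrane's diffusive resistance
#' (thickness over effective in-pore diffusivity) relative to the
#' channel's (height over free diffusivity).  The effective diffusivity
#' `Dm` defaults to the hindered-pore estimate from
#' [effective_membrane_diffusivity()].
#'
#' @param membrane A [membrane()].
#' @param solute A [solute()].
#' @param channel_height_um Channel height a, micrometers.
#' @param Dm_cm2_s Effective in-membrane diffusivity, cm^2/s; computed from
#'   the hindrance model when `NULL`.
#' @param hindrance_model Hindrance model name, see [hindrance_factor()].
#' @return `beta` (dimensionless); `Inf` when the solute is sterically
#'   excluded from the pores (`Dm = 0`), which callers must treat as an
#'   impermeable wall (`f = 0`).
#' @export
membrane_resistance_beta <- function(membrane, solute, channel_height_um,
                                     Dm_cm2_s = NULL,
                                     hindrance_model = "renkin") {
  stopifnot(inherits(membrane, "membrane"), inherits(solute, "solute"))
  check_positive(channel_height_um, "channel_height_um")
  a <- channel_height_um * 1e-6
  Dm <- if (is.null(Dm_cm2_s)) {
    effective_membrane_diffusivity(solute, membrane, model = hindrance_model)
  } else {
    if (Dm_cm2_s < 0) stop_invalid("`Dm_cm2_s` must be >= 0")
    Dm_cm2_s * 1e-4
  }
  if (Dm == 0) return(Inf)
  (membrane$d / Dm) / (a / solute$D0)
}

#' Blood residence time under the active membrane
#'
#' Time a fluid element spends in the active region: membrane length along
#' the flow divided by the mean velocity, `t = L / v`.  When only the
#' membrane area, channel height and volumetric flow are known (a
#' full-coverage design), the equivalent form `t = A * a / Q` is used; the
#' two paths agree because `Q = v * W * a` and `A = L * W`.
#'
#' @param design A [dialyzer_design()].
#' @return Residence time in seconds.
#' @export
residence_time <- function(design) {
  stopifnot(inherits(design, "dialyzer_design"))
  if (!is.na(design$L) && !is.na(design$v)) return(design$L / design$v)
  if (!is.na(design$Q)) return(design$A * design$a / design$Q)
  stop_invalid("design must carry either membrane length + velocity or flow rate")
}

#' Single-pass fractional clearance
#'
#' Fraction of a solute removed from the blood in one pass through the
#' dialyzer: `f = coverage * (1 - mean_concentration(tbar, beta))`, with
#' `tbar = residence_time * D0 / a^2` and `beta` from the membrane and
#' hindrance model.  The perfect-sink series is used when
#' `beta < beta_switch` (default 0.2) and the membrane-resistance series
#' otherwise, unless `model` forces one.
#'
#' @param design A [dialyzer_design()].
#' @param solute A [solute()].
#' @param membrane A [membrane()], or `NULL` for an ideal non-resisting
#'   membrane (`beta = 0`).
#' @param model `"auto"`, `"sink"` or `"robin"`.
#' @param hindrance_model Hindrance model name for `Dm`.
#' @param beta_switch Model-switch threshold (default 0.2).
#' @return Object of class `clearance_result`: list with
#'   `fractional_clearance`, `tbar`, `beta`, `model_used`, `terms_used`,
#'   `residence_time_s`.
#' @examples
#' d <- dialyzer_design(50, 9, flow_L_min = 0.85)
#' u <- solute("urea", 1.38e-5, 0.26)
#' fractional_clearance(d, u)
#' @export
fractional_clearance <- function(design, solute, membrane = NULL,
                                 model = c("auto", "sink", "robin"),
                                 hindrance_model = "renkin",
                                 beta_switch = BETA_SWITCH_DEFAULT) {
  model <- match.arg(model)
  stopifnot(inherits(design, "dialyzer_design"), inherits(solute, "solute"))
  t_res <- residence_time(design)
  tbar <- t_res * solute$D0 / design$a^2
  beta <- if (is.null(membrane)) 0 else
    membrane_resistance_beta(membrane, solute, design$a * 1e6,
                             hindrance_model = hindrance_model)
  if (is.infinite(beta)) {
    res <- list(fractional_clearance = 0, tbar = tbar, beta = Inf,
                model_used = "excluded", terms_used = 0L,
                residence_time_s = t_res)
    class(res) <- "clearance_result"
    return(res)
  }
  model_used <- resolve_model(model, beta, beta_switch)
  cavg <- mean_concentration(tbar, beta, model = model_used,
                             beta_switch = beta_switch)
  f <- design$coverage * (1 - cavg)
  res <- list(fractional_clearance = min(max(f, 0), 1),
              tbar = tbar, beta = beta, model_used = model_used,
              terms_used = series_terms_needed(tbar),
              residence_time_s = t_res)
  class(res) <- "clearance_result"
  res
}

#' @export
print.clearance_result <- function(x, ...) {
  cat(sprintf(
    "<clearance> f = %.4g  (tbar = %.4g, beta = %.4g, model = %s, t = %.4g s)\n",
    x$fractional_clearance, x$tbar, x$beta, x$model_used, x$residence_time_s))
  invisible(x)
}
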