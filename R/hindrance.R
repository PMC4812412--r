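# Hindered pore diffusion
# -----------------------
# A solute of hydrodynamic radius rs diffusing through a cylindrical pore of
# radius rp is slowed by steric partitioning at the pore mouth and
# hydrodynamic drag inside the pore.  Both effects are functions of
# lambda = rs / rp only.  The effective in-membrane diffusivity is
#   Dm = D0 * H(lambda) * porosity,
# where H is the hindrance factor of the chosen model.  Models live in a
# registry so alternative formulations can be compared; the classical
# Renkin expression is the default.

hindrance_registry <- new.env(parent = emptyenv())

register_hindrance_model <- function(name, fn) {
  assign(name, fn, envir = hindrance_registry)
  invisible(name)
}

#' Available hindrance models
#' @return Character vector of registered model names.
#' @export
hindrance_models <- function() sort(ls(hindrance_registry))

# Renkin (1954): partition (1-lambda)^2 times the drag polynomial.
register_hindrance_model("renkin", function(lambda) {
  (1 - lambda)^2 *
    (1 - 2.104 * lambda + 2.09 * lambda^3 - 0.95 * lambda^5)
})

# Dechadilok & Deen (2006) centreline approximation.  Their polynomial is
# the full diffusive hindrance factor H = partition * in-pore drag; it must
# not be multiplied by (1-lambda)^2 again.
register_hindrance_model("centerline", function(lambda) {
  H <- 1 + (9 / 8) * lambda * log(lambda) - 1.56034 * lambda +
    0.528155 * lambda^2 + 1.91521 * lambda^3 - 2.81903 * lambda^4 +
    0.270788 * lambda^5 + 1.10115 * lambda^6 - 0.435933 * lambda^7
  H[lambda == 0] <- 1
  H
})

#' Pore hindrance factor
#'
#' Ratio of in-pore to free diffusivity for a solute-to-pore size ratio
#' `lambda = rs / rp`, including steric partitioning. Returns 0 for
#' `lambda >= 1` (steric exclusion) and 1 at `lambda = 0`; results are
#' clamped to `[0, 1]`.
#'
#' @param lambda_ratio Solute radius over pore radius, >= 0 (vectorised).
#' @param model `"renkin"` (default) or `"centerline"`; see
#'   [hindrance_models()].
#' @return Hindrance factor(s) in `[0, 1]`.
#' @examples
#' hindrance_factor(0.2)               # ~0.3812
#' hindrance_factor(c(0, 0.5, 1.2))    # 1, partial, 0
#' @export
hindrance_factor <- function(lambda_ratio, model = "renkin") {
  if (any(!is.finite(lambda_ratio)) || any(lambda_ratio < 0))
    stop_invalid("`lambda_ratio` must be finite and >= 0")
  if (!is.character(model) || length(model) != 1L ||
      !exists(model, envir = hindrance_registry))
    stop_invalid(sprintf("unknown hindrance model; available: %s",
                         paste(hindrance_models(), collapse = ", ")))
  fn <- get(model, envir = hindrance_registry)
  out <- numeric(length(lambda_ratio))
  inside <- lambda_ratio < 1
  out[inside] <- pmin(pmax(fn(lambda_ratio[inside]), 0), 1)
  out
}

#' Effective in-membrane diffusivity
#'
#' `Dm = D0 * H(lambda) * porosity` with `lambda = rs / (pore diameter/2)`:
#' the hindered-pore estimate of the diffusivity entering the membrane
#' resistance `beta`.
#'
#' @param solute A [solute()].
#' @param membrane A [membrane()].
#' @param model Hindrance model name.
#' @return Effective diffusivity in m^2/s; 0 when the solute is excluded
#'   (`rs >=` pore radius).
#' @export
effective_membrane_diffusivity <- function(solute, membrane, model = "renkin") {
  stopifnot(inherits(solute, "solute"), inherits(membrane, "membrane"))
  lambda <- solute$rs / (membrane$pore_diameter / 2)
  solute$D0 * hindrance_factor(lambda, model = model) * membrane$porosity
}
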