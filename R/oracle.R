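# Finite-difference cross-checks for the analytical series
# --------------------------------------------------------
# Two solvers: a 1-D transient Crank-Nicolson integrator of the
# dimensionless channel-diffusion problem (the independent oracle for the
# eigenfunction series), and a 2-D steady advection-diffusion march of the
# full channel that relaxes the plug-flow assumption.  Both use the same
# coordinate convention as the analytical model: xbar (or ybar) = 0 at the
# impermeable wall, = 1 at the membrane.

# second-difference operator with wall (no-flux) and membrane (Robin or
# Dirichlet) boundaries, as a sparse tridiagonal matrix acting on the
# unknown nodes.  For beta = 0 the membrane node is eliminated (c = 0).
diffusion_operator_1d <- function(nodes, beta) {
  h <- 1 / (nodes - 1)
  m <- if (beta == 0) nodes - 1L else nodes  # unknowns
  main <- rep(-2, m); lower <- rep(1, m - 1); upper <- rep(1, m - 1)
  upper[1] <- 2                       # mirror ghost at the wall
  if (beta == 0) {
    # last unknown is node m (x = 1 - h); membrane neighbour is fixed 0
  } else {
    main[m] <- -2 * (1 + h / beta)    # Robin ghost: c_{M+1} = c_{M-1} - 2h c_M / beta
    lower[m - 1] <- 2
  }
  Matrix::bandSparse(m, m, k = c(-1, 0, 1),
                     diagonals = list(lower, main, upper)) / h^2
}

trapz_uniform <- function(y, h) h * (sum(y) - (y[1] + y[length(y)]) / 2)

full_profile <- function(u, beta) if (beta == 0) c(u, 0) else u

#' 1-D transient diffusion oracle (Crank-Nicolson)
#'
#' Integrates `dc/dtbar = d2c/dxbar2` on `[0, 1]` with no flux at the wall
#' and a perfect-sink (`beta = 0`) or Robin membrane condition
#' `c + beta*dc/dx = 0`, from the uniform initial state `c = 1`.
#' Crank-Nicolson stepping (second order, unconditionally stable) with a
#' few damped implicit-Euler start-up steps to suppress the ringing excited
#' by the incompatible sink initial condition, and geometric time-step
#' growth capped at `1e-3` once the transient has smoothed.
#'
#' @param tbar_end Final dimensionless time, > 0.
#' @param beta Dimensionless membrane resistance, >= 0.
#' @param nodes Spatial nodes (default 2001).
#' @param dt0 Initial time step (default 1e-5).
#' @param checkpoints Optional ascending times in `(0, tbar_end]` at which
#'   the mean concentration is recorded.
#' @return List: `xbar`, `profile` (concentration at `tbar_end`), `mean`,
#'   `checkpoints` (data.frame `tbar`, `mean`), `nodes`, `dt0`.
#' @examples
#' solve_diffusion_1d(0.1, beta = 0, nodes = 401)$mean   # ~0.6433
#' @export
solve_diffusion_1d <- function(tbar_end, beta = 0, nodes = 2001, dt0 = 1e-5,
                               checkpoints = NULL) {
  check_positive(tbar_end, "tbar_end")
  if (beta < 0) stop_invalid("`beta` must be >= 0")
  if (nodes < 3) stop_invalid("`nodes` must be >= 3")
  check_positive(dt0, "dt0")
  if (!is.null(checkpoints)) {
    checkpoints <- sort(unique(checkpoints))
    if (any(checkpoints <= 0 | checkpoints > tbar_end * (1 + 1e-12)))
      stop_invalid("`checkpoints` must lie in (0, tbar_end]")
  }
  h <- 1 / (nodes - 1)
  A <- diffusion_operator_1d(nodes, beta)
  m <- nrow(A)
  u <- rep(1, m)
  if (beta == 0) u[m] <- 1  # node at x = 1 - h; membrane value fixed at 0
  Ident <- Matrix::Diagonal(m)

  mean_of <- function(u) trapz_uniform(full_profile(u, beta), h)

  t_now <- 0
  cp_out <- numeric(0); cp_t <- numeric(0)
  pending <- checkpoints
  # implicit-Euler start-up (Rannacher damping), then Crank-Nicolson with
  # dt growing geometrically: dt <- min(dt_cap, max(dt0, t/50)), refactoring
  # only when dt changes.
  startup_left <- if (beta == 0) 4L else 0L
  dt <- min(dt0, tbar_end / 4)
  fact <- NULL; fact_dt <- NA; fact_theta <- NA
  get_fact <- function(dt, theta) {
    Matrix::lu(Ident - theta * dt * A)
  }
  while (t_now < tbar_end * (1 - 1e-14)) {
    theta <- if (startup_left > 0L) 1 else 0.5
    dt_target <- if (startup_left > 0L) dt else
      min(1e-3, max(dt0, t_now / 50), tbar_end - t_now)
    # land exactly on the next checkpoint
    if (length(pending)) dt_target <- min(dt_target, pending[1] - t_now)
    if (is.null(fact) || abs(dt_target - fact_dt) > 1e-16 || theta != fact_theta) {
      fact <- get_fact(dt_target, theta)
      fact_dt <- dt_target; fact_theta <- theta
    }
    rhs <- if (theta == 1) u else as.numeric(u + 0.5 * dt_target * (A %*% u))
    u <- as.numeric(Matrix::solve(fact, rhs))
    t_now <- t_now + dt_target
    if (startup_left > 0L) startup_left <- startup_left - 1L
    if (length(pending) && t_now >= pending[1] * (1 - 1e-12)) {
      cp_out <- c(cp_out, mean_of(u)); cp_t <- c(cp_t, pending[1])
      pending <- pending[-1]
    }
  }
  list(xbar = seq(0, 1, length.out = nodes),
       profile = full_profile(u, beta),
       mean = mean_of(u),
       checkpoints = data.frame(tbar = cp_t, mean = cp_out),
       nodes = nodes, dt0 = dt0)
}

#' 2-D steady advection-diffusion channel solver
#'
#' Marches the steady transport equation
#' `v(ybar) * dc/dz = D * d2c/dy2` down the channel (axial diffusion
#' neglected, the analytical model's assumption) with a plug or parabolic
#' (Poiseuille) velocity profile, uniform inlet concentration, no flux at
#' the wall and a sink or Robin condition at the membrane.  In dimensionless
#' form the axial coordinate plays the role of `tbar`, so with a plug
#' profile the problem reduces exactly to the 1-D model; the parabolic
#' profile quantifies the error of the plug-flow assumption.  Fractional
#' clearance is evaluated from the flow-weighted (mixing-cup) outlet mean
#' and scaled by the design's coverage fraction.
#'
#' @param design A [dialyzer_design()].
#' @param solute A [solute()].
#' @param membrane A [membrane()] or `NULL` (ideal sink).
#' @param profile `"plug"` or `"parabolic"`.
#' @param ny Transverse nodes (default 401).
#' @param nz Axial steps (default 1500).
#' @param hindrance_model Hindrance model for `beta`.
#' @return List of class `channel2d_result`: `f`, `outlet_mean` (mixing
#'   cup), `beta`, `tbar_end`, `profile`, `mass_balance_error` (relative
#'   inlet-vs-outlet+membrane flux mismatch), `outlet_profile` (data.frame
#'   `ybar`, `c`).
#' @export
solve_channel_2d <- function(design, solute, membrane = NULL,
                             profile = c("plug", "parabolic"),
                             ny = 401, nz = 1500,
                             hindrance_model = "renkin") {
  profile <- match.arg(profile)
  stopifnot(inherits(design, "dialyzer_design"), inherits(solute, "solute"))
  if (ny < 5 || nz < 10) stop_invalid("grid too coarse: need ny >= 5, nz >= 10")
  t_res <- residence_time(design)
  tbar_end <- t_res * solute$D0 / design$a^2
  beta <- if (is.null(membrane)) 0 else
    membrane_resistance_beta(membrane, solute, design$a * 1e6,
                             hindrance_model = hindrance_model)
  if (is.infinite(beta)) {
    out <- list(f = 0, outlet_mean = 1, beta = Inf, tbar_end = tbar_end,
                profile = profile, mass_balance_error = 0,
                outlet_profile = NULL)
    class(out) <- "channel2d_result"
    return(out)
  }
  h <- 1 / (ny - 1)
  ybar <- seq(0, 1, length.out = ny)
  w_full <- if (profile == "plug") rep(1, ny) else pmax(6 * ybar * (1 - ybar), 1e-3)
  A <- diffusion_operator_1d(ny, beta)
  m <- nrow(A)
  w <- w_full[seq_len(m)]
  W <- Matrix::Diagonal(m, w)
  dz <- tbar_end / nz
  lhs <- Matrix::lu(W - (dz / 2) * A)
  rhs_op <- W + (dz / 2) * A
  u <- rep(1, m)
  mem_flux <- function(u) {
    cfull <- full_profile(u, beta)
    M <- length(cfull)
    -(3 * cfull[M] - 4 * cfull[M - 1] + cfull[M - 2]) / (2 * h)
  }
  flux_acc <- 0
  fl_prev <- mem_flux(u)
  for (k in seq_len(nz)) {
    u <- as.numeric(Matrix::solve(lhs, rhs_op %*% u))
    fl <- mem_flux(u)
    flux_acc <- flux_acc + dz * (fl_prev + fl) / 2
    fl_prev <- fl
  }
  cfull <- full_profile(u, beta)
  inlet <- trapz_uniform(w_full, h)
  outlet <- trapz_uniform(w_full * cfull, h)
  mixing_cup <- outlet / inlet
  f <- design$coverage * (1 - mixing_cup)
  out <- list(f = min(max(f, 0), 1), outlet_mean = mixing_cup, beta = beta,
              tbar_end = tbar_end, profile = profile,
              mass_balance_error = ((inlet - outlet) - flux_acc) / inlet,
              outlet_profile = data.frame(ybar = ybar, c = cfull))
  class(out) <- "channel2d_result"
  out
}

#' @export
print.channel2d_result <- function(x, ...) {
  cat(sprintf(
    "<2-D channel> %s flow: f = %.4g (outlet mean %.4g, beta = %.3g, tbar = %.4g)\n",
    x$profile, x$f, x$outlet_mean, x$beta, x$tbar_end))
  cat(sprintf("  mass-balance error = %.2e\n", x$mass_balance_error))
  invisible(x)
}
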