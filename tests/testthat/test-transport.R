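test_that("sink eigenvalues follow the half-odd-integer ladder", {
  lam <- dirichlet_eigenvalues(5)
  expect_equal(lam[1], pi / 2)
  expect_equal(lam[3], 5 * pi / 2)
  expect_equal(diff(lam), rep(pi, 4))
  expect_error(dirichlet_eigenvalues(0), class = "nanodialyzer_invalid_argument")
})

test_that("Robin eigenvalues solve tan(z) = 1/(beta z) in every bracket", {
  # first root at beta = 1 against the independent bisection oracle
  expect_equal(robin_eigenvalues(1, 1), bisect_z1(1), tolerance = 1e-11)
  expect_equal(robin_eigenvalues(1, 1), 0.860333589019, tolerance = 1e-9)

  # residuals on the eigencondition, moderate resistances
  for (b in c(0.1, 1, 10)) {
    z <- robin_eigenvalues(b, 50)
    expect_true(all(diff(z) > 0))
    expect_true(all(z > (seq_len(50) - 1) * pi & z < (seq_len(50) - 0.5) * pi))
    expect_lt(max(abs(z * tan(z) - 1 / b)), 1e-10)
  }

  # sink limit: beta -> 0 recovers pi*(n - 1/2)
  z <- robin_eigenvalues(1e-10, 6)
  expect_equal(z, dirichlet_eigenvalues(6), tolerance = 1e-4)

  # high-resistance limit: z1 ~ beta^(-1/2)
  expect_equal(robin_eigenvalues(1e4, 1), 1e-2, tolerance = 1e-2)

  expect_error(robin_eigenvalues(0, 3), class = "nanodialyzer_invalid_argument")
  expect_error(robin_eigenvalues(-1, 3), class = "nanodialyzer_invalid_argument")
})

test_that("Robin series coefficients match the Fourier-projection oracle", {
  # closed sink-limit value: z = pi/2 gives 4/pi
  expect_equal(robin_coefficients(pi / 2), 4 / pi)

  # independent oracle: Cn is the Fourier coefficient of 1 in the cos(zn x)
  # basis, int_0^1 cos / int_0^1 cos^2, evaluated by quadrature
  z <- robin_eigenvalues(1, 4)
  oracle <- vapply(z, function(zz) {
    stats::integrate(function(x) cos(zz * x), 0, 1, rel.tol = 1e-12)$value /
      stats::integrate(function(x) cos(zz * x)^2, 0, 1, rel.tol = 1e-12)$value
  }, numeric(1))
  expect_equal(robin_coefficients(z), oracle, tolerance = 1e-9)
  expect_equal(robin_coefficients(z[1]), 1.11913201, tolerance = 1e-7)

  # completeness: the series reproduces the uniform initial state
  z100 <- robin_eigenvalues(1, 400)
  Cn <- robin_coefficients(z100)
  expect_equal(sum(Cn * sin(z100) / z100), 1, tolerance = 1e-4)

  expect_error(robin_coefficients(c(-1, 2)), class = "nanodialyzer_invalid_argument")
  expect_error(robin_coefficients(c(2, 1)), class = "nanodialyzer_invalid_argument")
})

test_that("concentration profile honours boundary conditions and decay", {
  # sink boundary: zero at the membrane for t > 0
  expect_equal(concentration_profile(1, 0.5, model = "sink"), 0, tolerance = 1e-12)
  # everything decays away eventually
  expect_lt(concentration_profile(0.3, 50), 1e-12)
  # profile decreases from wall to membrane (sink)
  prof <- concentration_profile(seq(0, 1, 0.1), 0.1)
  expect_true(all(diff(prof) <= 1e-12))
  expect_error(concentration_profile(0.5, -1), class = "nanodialyzer_invalid_argument")
  expect_error(concentration_profile(1.5, 1), class = "nanodialyzer_invalid_argument")
})

test_that("mean concentration matches frozen oracle values and asymptotes", {
  expect_equal(mean_concentration(0), 1)
  # series identity at t = 0+: 2 * sum(1/lambda^2) = 1
  lam <- dirichlet_eigenvalues(1e5)
  expect_equal(2 * sum(1 / lam^2), 1, tolerance = 1e-5)
  # frozen value computed with the Crank-Nicolson oracle (2001 nodes)
  expect_equal(mean_concentration(0.1), 0.643176, tolerance = 1e-4)
  # single-mode asymptote for large t
  for (tb in c(1, 2, 4))
    expect_equal(mean_concentration(tb), (8 / pi^2) * exp(-pi^2 * tb / 4),
                 tolerance = 1e-3)
})

test_that("mean concentration is monotone in time and in membrane resistance", {
  tgrid <- 10^seq(-4, 1, length.out = 12)
  for (b in c(0, 0.05, 0.5, 5)) {
    vals <- vapply(tgrid, mean_concentration, numeric(1), beta = b)
    expect_true(all(diff(vals) <= 1e-12), info = paste("beta =", b))
  }
  bgrid <- c(0, 1e-3, 1e-2, 0.1, 0.5, 1, 5, 20)
  for (tb in c(1e-3, 0.05, 0.5)) {
    vals <- vapply(bgrid, function(b)
      mean_concentration(tb, b, model = if (b == 0) "sink" else "robin"),
      numeric(1))
    expect_true(all(diff(vals) >= -1e-12), info = paste("tbar =", tb))
  }
})

test_that("Robin series converges continuously to the sink series", {
  for (tb in c(1e-4, 1e-3, 1e-2, 0.1, 1, 10)) {
    f_sink <- 1 - mean_concentration(tb, 0, model = "sink")
    f_robin <- 1 - mean_concentration(tb, 1e-8, model = "robin")
    expect_lt(abs(f_robin - f_sink), 1e-6)
  }
})

test_that("short-time clearance follows the half-space square-root law", {
  for (tb in c(1e-6, 1e-5, 1e-4, 1e-3)) {
    f <- 1 - mean_concentration(tb, 0)
    expect_equal(f, 2 * sqrt(tb / pi), tolerance = 1e-2)
  }
})

test_that("membrane resistance number is the resistance ratio", {
  m <- membrane(thickness_nm = 50, pore_nm = 100, porosity = 1)
  s <- solute("tiny", 1e-5, 1e-3)   # lambda ~ 0: Dm ~ D0
  b <- membrane_resistance_beta(m, s, channel_height_um = 50)
  expect_equal(b, 1e-3, tolerance = 1e-4)
  # halving Dm doubles beta
  b1 <- membrane_resistance_beta(m, s, 50, Dm_cm2_s = 1e-5)
  b2 <- membrane_resistance_beta(m, s, 50, Dm_cm2_s = 0.5e-5)
  expect_equal(b2 / b1, 2)
  # steric exclusion signals infinite resistance
  s_big <- solute("huge", 1e-6, 60)
  expect_identical(membrane_resistance_beta(m, s_big, 50), Inf)
  # urea at the proof-of-principle design: sink regime
  bu <- membrane_resistance_beta(membrane(pore_nm = 23), urea_ref(), 50)
  expect_lt(bu, 0.2)
})

test_that("residence time agrees between the length/velocity and area/flow paths", {
  # benchtop geometry: L = 2 mm at 0.2 mm/s -> 10 s
  bench <- fixture_experimental_device(0.3)$design
  expect_equal(residence_time(bench), 10)
  # miniature design: t = A*a/Q
  t_mini <- residence_time(proto_design())
  expect_equal(t_mini, 9e-4 * 50e-6 / (0.85e-3 / 60), tolerance = 1e-12)
  expect_equal(t_mini, 3.18e-3, tolerance = 1e-2)
  # both paths agree on a self-consistent full-coverage design
  d2 <- dialyzer_design(100, 0.02, flow_L_min = 0.2 * 1e-6 * 60,
                        membrane_length_mm = 2, channel_width_mm = 1)
  expect_equal(residence_time(d2), d2$L / d2$v)
  expect_equal(residence_time(d2), d2$A * d2$a / d2$Q, tolerance = 1e-12)
  # doubling the flow halves the residence time
  expect_equal(residence_time(proto_design(1.7)), t_mini / 2)
})

test_that("fractional clearance combines residence, resistance and coverage", {
  # short-residence sink limit at the benchtop geometry (ideal coverage)
  d <- dialyzer_design(300, 0.014, velocity_mm_s = 0.2,
                       membrane_length_mm = 2, channel_width_mm = 1)
  s <- solute("dye", 1.6e-6, 0.5)
  cr <- fractional_clearance(d, s)
  expect_equal(cr$model_used, "sink")
  expect_equal(cr$fractional_clearance, 0.150, tolerance = 5e-3)

  # coverage scales multiplicatively
  d70 <- dialyzer_design(300, 0.014, velocity_mm_s = 0.2,
                         membrane_length_mm = 2, channel_width_mm = 1,
                         coverage = 0.7)
  expect_equal(fractional_clearance(d70, s)$fractional_clearance,
               0.7 * cr$fractional_clearance, tolerance = 1e-12)

  # excluded solute: impermeable wall
  m <- membrane(pore_nm = 5)
  big <- solute("big", 6e-7, 10)
  cr0 <- fractional_clearance(d, big, m)
  expect_identical(cr0$fractional_clearance, 0)
  expect_identical(cr0$model_used, "excluded")

  # model switch rule: beta above threshold selects the Robin series
  mid <- solute("mid", 1.3e-6, 1.6)
  m_small <- membrane(pore_nm = 4.5, porosity = 0.03)
  cr_r <- fractional_clearance(d, mid, m_small)
  expect_gt(cr_r$beta, 0.2)
  expect_equal(cr_r$model_used, "robin")
})

test_that("coverage correction is plain multiplication with range checks", {
  expect_equal(coverage_correction(0.5, 0.7), 0.35)
  expect_equal(coverage_correction(0.42, 1), 0.42)
  expect_error(coverage_correction(1.2, 0.5), class = "nanodialyzer_invalid_argument")
  expect_error(coverage_correction(0.5, -0.1), class = "nanodialyzer_invalid_argument")
})
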