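test_that("urea isoline recovers the blood flow pinned by the urea target", {
  u <- urea_ref()
  Q <- urea_isoline(50, 9, u, 2.3)
  # published design flow 0.85 L/min, within 15%
  expect_equal(Q, 0.85, tolerance = 0.15)
  # the solve closes: Q*f equals the target to root-solver precision
  d <- dialyzer_design(50, 9, flow_L_min = Q)
  f <- fractional_clearance(d, u)$fractional_clearance
  expect_equal(Q * 60 * f, 2.3, tolerance = 1e-6)
  # thinner channel clears faster, needs less flow
  expect_lt(urea_isoline(25, 9, u, 2.3), Q)
  # vanishing target, vanishing flow
  expect_equal(urea_isoline(50, 9, u, 0), 0)
  # unreachable target signals infeasibility
  expect_error(urea_isoline(50, 9, u, 1e6),
               class = "nanodialyzer_infeasible_design")
})

test_that("urea isoline is invariant to channel aspect ratio at fixed A, a, Q", {
  u <- urea_ref()
  # same A = 9 cm^2 and flow, three different length/width splits
  f <- vapply(c(1, 3, 10), function(width_cm) {
    L_mm <- 9 / width_cm * 10
    d <- dialyzer_design(50, 9, flow_L_min = 0.85,
                         membrane_length_mm = L_mm,
                         channel_width_mm = width_cm * 10)
    fractional_clearance(d, u)$fractional_clearance
  }, numeric(1))
  expect_equal(f[2], f[1], tolerance = 1e-10)
  expect_equal(f[3], f[1], tolerance = 1e-10)
})

test_that("albumin isocurve recovers a pore size in the expected range", {
  lib <- solute_lib()
  Q <- urea_isoline(50, 9, lib$urea, 2.3)
  pore <- albumin_isocurve(50, Q, 9, lib$albumin, membrane(pore_nm = 20),
                           target_L_per_h = required_clearance(lib$albumin))
  expect_gt(pore, 15); expect_lt(pore, 35)
  # the solve closes on the albumin target (Robin model, as solved)
  d <- dialyzer_design(50, 9, flow_L_min = Q)
  m <- membrane(pore_nm = pore)
  f <- fractional_clearance(d, lib$albumin, m, model = "robin")$fractional_clearance
  expect_equal(Q * 60 * f, required_clearance(lib$albumin), tolerance = 1e-6)
  # albumin clearance is strictly monotone in pore size on the bracket
  fs <- vapply(c(9, 12, 20, 50, 150), function(p) {
    fractional_clearance(d, lib$albumin, membrane(pore_nm = p),
                         model = "robin")$fractional_clearance
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
  # exclusion limit: pore barely above 2*rs clears a negligible fraction
  # of the albumin target
  expect_lt(fs[1] * Q * 60, required_clearance(lib$albumin) / 10)
  # unreachable target: infeasible signal
  expect_error(albumin_isocurve(50, Q, 9, lib$albumin, membrane(pore_nm = 20),
                                target_L_per_h = 100),
               class = "nanodialyzer_infeasible_design")
})

test_that("three-step selection returns a closed-loop-consistent design", {
  lib <- solute_lib()
  sel <- select_design(
    area_cm2 = 9,
    solutes = list(urea = lib$urea, albumin = lib$albumin,
                   beta2m = lib[["beta2-microglobulin"]]),
    targets = c(urea = 2.3, albumin = required_clearance(lib$albumin)),
    heights_um = c(20, 30, 40, 50, 70, 100, 140),
    min_height_um = 50)
  curve <- sel$curve
  # well-posed: one finite row per height
  expect_equal(nrow(curve), 7)
  expect_true(all(is.finite(curve$beta2m_L_per_h[curve$feasible])))
  expect_true(all(curve$feasible))
  # the recommendation respects the practicality floor
  r <- sel$recommended
  expect_gte(r$height_um, 50)
  # published design region: tens of um and ~0.8-0.9 L/min
  expect_gt(r$height_um, 20); expect_lt(r$height_um, 100)
  expect_equal(r$flow_L_min, 0.85, tolerance = 0.15)
  # closed loop: feeding the candidate back reproduces both targets
  d <- dialyzer_design(r$height_um, 9, flow_L_min = r$flow_L_min)
  m <- membrane(pore_nm = r$pore_nm)
  fu <- fractional_clearance(d, lib$urea)$fractional_clearance
  fa <- fractional_clearance(d, lib$albumin, m, model = "robin")$fractional_clearance
  expect_equal(r$flow_L_min * 60 * fu, 2.3, tolerance = 1e-6)
  expect_equal(r$flow_L_min * 60 * fa, required_clearance(lib$albumin),
               tolerance = 1e-6)
  # infeasible grids raise the dedicated signal
  expect_error(
    select_design(9, list(urea = lib$urea, albumin = lib$albumin,
                          beta2m = lib[["beta2-microglobulin"]]),
                  targets = c(urea = 1e6, albumin = 0.015),
                  heights_um = c(30, 50)),
    class = "nanodialyzer_infeasible_design")
})

test_that("unconstrained pore size never reduces middle-molecule clearance", {
  # with the albumin constraint removed, beta2m clearance is non-decreasing
  # in pore size at each height (brute force over a small grid)
  b2m <- solute_lib()[["beta2-microglobulin"]]
  for (a_um in c(30, 80)) {
    d <- dialyzer_design(a_um, 9, flow_L_min = 0.85)
    f <- vapply(c(5, 10, 20, 40, 80), function(p)
      fractional_clearance(d, b2m, membrane(pore_nm = p))$fractional_clearance,
      numeric(1))
    expect_true(all(diff(f) >= -1e-12), info = paste("a =", a_um))
  }
})
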