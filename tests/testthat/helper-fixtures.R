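# shared fixtures: the miniature proof-of-principle design, the bundled
# solute kinetics, and small independent oracles

proto_design <- function(flow_L_min = 0.85) {
  dialyzer_design(channel_height_um = 50, membrane_area_cm2 = 9,
                  flow_L_min = flow_L_min)
}

solute_lib <- function() load_solute_library()

urea_ref <- function() solute("urea", 1.38e-5, 0.26, conc_mM = 4.6,
                              target_L_per_h = 2.3)

# independent bisection oracle for the first Robin eigenvalue:
# root of z*tan(z) = 1/beta on (0, pi/2), to ~1e-12
bisect_z1 <- function(beta) {
  f <- function(z) z * tan(z) - 1 / beta
  lo <- 1e-9; hi <- pi / 2 - 1e-9
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
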