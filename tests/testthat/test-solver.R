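test_that("vessel compliance matches the Lame displacement slope", {
  v <- build_vessel()
  # u(a)/p from the field solution, 1e-10 relative (checked at build, re-checked here)
  u <- lame_solution(1, 2.5, v$wall, 780, 0, r_mm = 1)$u_mm * 1e-3
  expect_equal(v$C_law_m_per_Pa, u / 780, tolerance = 1e-10)
  # doubling E halves the compliance; the rigid limit kills it
  v2 <- build_vessel(wall = wall_elasticity(2 * 28.6e3, 0.45))
  expect_equal(v2$C_law_m_per_Pa, v$C_law_m_per_Pa / 2, tolerance = 1e-12)
  vr <- build_vessel(wall = wall_elasticity(28.6e9, 0.45))
  expect_lt(vr$C_law_m_per_Pa / v$C_law_m_per_Pa, 1e-5)
  expect_error(build_vessel(a_mm = 3, b_mm = 2.5),
               class = "tebv_geometry_error")
})

test_that("tube law is the invertible linearised Lame closure", {
  v <- build_vessel()
  A0 <- pi * 1^2
  expect_equal(tube_law(A0, v), 0) # reference state
  # 780 Pa opens the lumen by the Lame displacement
  A780 <- area_from_pressure(780, v)
  expect_equal(sqrt(A780 / pi) - 1, 0.047831, tolerance = 1e-4)
  # inverse consistency and monotonicity
  p <- seq(-200, 900, by = 50)
  expect_equal(tube_law(area_from_pressure(p, v), v), p, tolerance = 1e-9)
  A <- seq(2.5, 4, length.out = 30)
  expect_true(all(diff(tube_law(A, v)) > 0))
  expect_error(tube_law(-1, v), class = "tebv_state_error")
})

test_that("wall friction reduces to Poiseuille for a Newtonian fluid", {
  mu <- 5e-3 # Pa s
  newt <- newtonian_fluid(5)
  A <- pi * 1^2 # mm^2, D = 2 mm
  V <- 2.65 # mm/s
  Q <- V * A * 60 # mm/s * mm^2 = mm^3/s -> uL/min
  tau <- wall_friction(Q, A, newt)
  expect_equal(tau, 8 * mu * (V * 1e-3) / 2e-3, tolerance = 1e-6)
  # no flow, no stress; odd in Q
  expect_equal(wall_friction(0, A, newt), 0)
  expect_equal(wall_friction(-Q, A, newt), -tau, tolerance = 1e-10)
})

test_that("wall friction matches the hand-evaluated power-law value", {
  # V = 2.65 mm/s, D = 2 mm, K = 11.885 cP, n = -0.2188:
  # gamma_w = 1.07002 * 10.6 = 11.3422 1/s, tau_w = 0.011885 * 11.3422^0.7812
  fl <- default_fluid()
  A <- pi * 1^2
  Q <- 2.65 * A * 60 # mm/s * mm^2 = mm^3/s -> uL/min
  expect_equal(wall_friction(Q, A, fl), 0.07924, tolerance = 2e-4)
})

test_that("reconstructed profile has the exact section mean and no slip", {
  fl <- default_fluid()
  A <- pi * 1.05^2
  Q <- 500
  prof <- reconstruct_profile(Q, A, fl, r_frac = seq(0, 1, length.out = 201))
  V <- 500 * (1e-9 / 60) / (A * 1e-6) * 1e3 # mm/s
  expect_equal(prof$u_mm_s[nrow(prof)], 0) # u(R) = 0
  # quadrature of u over the cross section returns Q (fine trapezoid rule)
  z <- seq(0, 1, length.out = 20001)
  u <- reconstruct_profile(Q, A, fl, r_frac = z)$u_mm_s
  f <- 2 * z * u
  Vbar <- sum((f[-1] + f[-length(f)]) / 2) * (z[2] - z[1])
  expect_equal(Vbar, V, tolerance = 1e-6)
  # Newtonian centreline velocity is 2V
  profN <- reconstruct_profile(Q, A, newtonian_fluid(), r_frac = c(0, 1))
  expect_equal(profN$u_mm_s[1], 2 * V, tolerance = 1e-10)
})

test_that("profile wall gradient reproduces the wall-friction closure", {
  fl <- default_fluid()
  A <- pi * 1^2
  Q <- 500
  h <- 1e-6
  prof <- reconstruct_profile(Q, A, fl, r_frac = c(1 - h, 1))
  R_m <- sqrt(A / pi) * 1e-3
  gamma_wall <- (prof$u_mm_s[1] - prof$u_mm_s[2]) * 1e-3 / (h * R_m) # 1/s
  tau_from_profile <- apparent_viscosity(fl, gamma_wall) * gamma_wall
  expect_equal(tau_from_profile, wall_friction(Q, A, fl), tolerance = 0.01)
})

test_that("momentum correction integrates the profile (4/3 when parabolic)", {
  expect_equal(momentum_correction(1), 4 / 3, tolerance = 1e-9)
  # flatter shear-thinning profiles have smaller alpha
  expect_lt(momentum_correction(0.7812), 4 / 3)
  expect_gt(momentum_correction(0.7812), 1)
})

test_that("steady rigid-tube flow reproduces the analytic power-law pressure drop", {
  # rigid limit (E x 1e6), constant inlet velocity and outlet pressure
  vr <- build_vessel(wall = wall_elasticity(28.6e3 * 1e6, 0.45))
  fl <- default_fluid()
  sim <- run_simulation(vr, fl,
                        inlet = inlet_waveform(2.65, PI = 0),
                        outlet = outlet_pressure_waveform(710, 710),
                        settings = fast_settings())
  nt <- length(sim$t_s)
  # flow is uniform in x at steady state
  expect_lt(max(abs(sim$Q_uL_min[, nt] - mean(sim$Q_uL_min[, nt]))) /
              mean(sim$Q_uL_min[, nt]), 1e-6)
  # diameter stays at the unloaded 2 mm in the rigid limit
  expect_equal(sim$monitor$d_mm, rep(2, nt), tolerance = 1e-5)
  # axial pressure drop between first and last cell centres: dp/dx = 4 tau_w / D
  N <- length(sim$x_mm)
  dp_sim <- sim$p_Pa[1, nt] - sim$p_Pa[N, nt]
  tau <- wall_friction(sim$Q_uL_min[1, nt], sim$A_mm2[1, nt], fl)
  D_m <- 2 * sqrt(sim$A_mm2[1, nt] / pi) * 1e-3
  L_m <- (sim$x_mm[N] - sim$x_mm[1]) * 1e-3
  expect_equal(dp_sim, 4 * L_m / D_m * tau, tolerance = 0.01)
})

test_that("zero inflow relaxes to the hydrostatic Lame state", {
  v <- build_vessel()
  fl <- default_fluid()
  sim <- run_simulation(v, fl,
                        inlet = inlet_waveform(0, PI = 0),
                        outlet = outlet_pressure_waveform(700, 700),
                        settings = fast_settings())
  nt <- length(sim$t_s)
  A_expected <- area_from_pressure(700, v)
  expect_equal(sim$A_mm2[, nt], rep(A_expected, length(sim$x_mm)),
               tolerance = 1e-6)
  expect_lt(max(abs(sim$Q_uL_min[, nt])), 1e-6)
})

test_that("the periodic pulsatile solution conserves mass and closes the cycle", {
  sim <- run_simulation(build_vessel(), default_fluid(),
                        settings = fast_settings())
  expect_lt(sim$mass_error_rel, 1e-3) # < 0.1% over a cycle
  nt <- nrow(sim$monitor)
  expect_equal(sim$monitor$d_mm[1], sim$monitor$d_mm[nt], tolerance = 1e-4)
  expect_true(all(sim$A_mm2 > 0))
  # cycle-mean inlet velocity is the prescribed 2.65 mm/s by construction
  Vin <- sim$Q_inlet_uL_min * (1e-9 / 60) / (sim$A_mm2[1, ] * 1e-6) * 1e3
  expect_equal(mean((Vin[-1] + Vin[-nt]) / 2), 2.65, tolerance = 2e-3)
  # laminar regime
  expect_lt(sim$reynolds, 100)
})

test_that("diameter amplitude scales linearly with pressure amplitude", {
  v <- build_vessel(); fl <- default_fluid()
  amp <- function(p_min, p_max) {
    sim <- run_simulation(v, fl,
                          outlet = outlet_pressure_waveform(p_min, p_max),
                          settings = fast_settings())
    diff(range(sim$monitor$d_mm))
  }
  a_full <- amp(640, 780) # 140 Pa swing
  a_half <- amp(675, 745) # 70 Pa swing
  expect_equal(a_full / a_half, 2, tolerance = 0.05)
})

test_that("pressure-inlet mode drives flow down the prescribed gradient", {
  v <- build_vessel(); fl <- default_fluid()
  sim <- run_simulation(
    v, fl,
    inlet = inlet_waveform(2.65), # period/bookkeeping only
    outlet = outlet_pressure_waveform(700, 700),
    settings = fast_settings(),
    inlet_mode = "pressure",
    inlet_pressure = outlet_pressure_waveform(702, 702))
  nt <- length(sim$t_s)
  expect_gt(sim$Q_uL_min[1, nt], 0) # flows from high to low pressure
  expect_lt(sim$mass_error_rel, 1e-3)
  # inlet-face pressure (extrapolated from the first cells) near the prescription
  p_in <- sim$p_Pa[1, nt] + (sim$p_Pa[1, nt] - sim$p_Pa[2, nt]) / 2
  expect_equal(p_in, 702, tolerance = 0.01)
})

test_that("mesh refinement stops once the expansion waveform is grid-independent", {
  v <- build_vessel(); fl <- default_fluid()
  base <- solver_settings(n_nodes = 9, dt_s = 0.02)
  ref <- refine_until_converged(v, fl, settings = base)
  expect_true(ref$converged)
  expect_lte(max(ref$trace$refinement), 10)
  expect_lt(utils::tail(ref$trace$l2_change, 1), 0.02)
  expect_true(all(diff(ref$trace$n_nodes) > 0))
  # an already-refined solution is confirmed by a single refinement
  again <- refine_until_converged(v, fl, settings = ref$result$settings)
  expect_equal(max(again$trace$refinement), 1)
  # tightening the tolerance never accepts a coarser grid
  tight <- refine_until_converged(v, fl, settings = base, tol = 0.005)
  expect_gte(utils::tail(tight$trace$n_nodes, 1),
             utils::tail(ref$trace$n_nodes, 1))
})

test_that("post-processing yields Lame-consistent wall stress and WSS series", {
  sim <- run_simulation(build_vessel(), default_fluid(),
                        settings = fast_settings())
  post <- postprocess(sim)
  # inner hoop stress exceeds outer, both tensile under internal pressure
  expect_true(all(post$wall$sigma_tt_inner_Pa > post$wall$sigma_tt_outer_Pa))
  expect_true(all(post$wall$sigma_tt_outer_Pa > 0))
  # max principal stress is the inner hoop stress
  expect_equal(post$wall$max_principal_stress_Pa, post$wall$sigma_tt_inner_Pa)
  # WSS is positive throughout for this non-reversing flow
  expect_true(all(post$wss$wss_Pa > 0))
  expect_gt(post$summary$Q_mean_uL_min, 0)
  # zero transmural pressure would give zero wall stress
  ls0 <- lame_solution(1, 2.5, sim$vessel$wall, 0, 0)
  expect_true(all(abs(ls0$sigma_tt_Pa) == 0))
})
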