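test_that("stress-stretch reduction implements lambda = L/L0, sigma = F/(D h)", {
  recs <- tibble::tibble(
    sample_id = "s1",
    force_N = c(0, 0.01, 0.02),
    length_mm = c(10, 11, 12))
  dims <- tibble::tibble(sample_id = "s1", L0_mm = 10, width_mm = 2,
                         thickness_mm = 1)
  out <- compute_stress_strain(recs, dims)
  # zero-force baseline maps to (lambda, sigma) = (1, 0)
  expect_equal(out$stretch[1], 1)
  expect_equal(out$stress_Pa[1], 0)
  # hand value: 0.02 N over 2 mm x 1 mm = 10 kPa
  expect_equal(out$stress_Pa[3], 10e3)
  expect_equal(out$stretch, recs$length_mm / 10)
  expect_equal(nrow(out), nrow(recs))

  # linearity: doubling F doubles sigma; doubling D and h quarters sigma
  out2 <- compute_stress_strain(dplyr::mutate(recs, force_N = 2 * force_N), dims)
  expect_equal(out2$stress_Pa, 2 * out$stress_Pa)
  dims4 <- dplyr::mutate(dims, width_mm = 2 * width_mm,
                         thickness_mm = 2 * thickness_mm)
  out4 <- compute_stress_strain(recs, dims4)
  expect_equal(out4$stress_Pa, out$stress_Pa / 4)
})

test_that("per-location thickness readings are averaged before use", {
  recs <- tibble::tibble(sample_id = "s1", force_N = c(0, 0.01, 0.02),
                         length_mm = c(10, 11, 12))
  dims <- tibble::tibble(sample_id = "s1", L0_mm = 10, width_mm = 2,
                         thickness_mm = c(0.8, 1.2, 0.9, 1.1))
  out <- compute_stress_strain(recs, dims)
  expect_equal(out$stress_Pa[3], 0.02 / (2e-3 * 1e-3))
})

test_that("stress-stretch reduction validates its inputs", {
  recs <- tibble::tibble(sample_id = "s1", force_N = c(0, 0.01, 0.02),
                         length_mm = c(10, 11, 12))
  dims <- tibble::tibble(sample_id = "s1", L0_mm = 10, width_mm = 2,
                         thickness_mm = 1)
  expect_error(compute_stress_strain(recs, dplyr::mutate(dims, L0_mm = -1)),
               class = "tebv_dimension_error")
  expect_error(compute_stress_strain(recs[1:2, ], dims),
               class = "tebv_shape_error")
  expect_error(
    compute_stress_strain(dplyr::mutate(recs, sample_id = "other"), dims),
    class = "tebv_shape_error")
  expect_error(compute_stress_strain(recs[, -2], dims),
               class = "tebv_validation_error")
})

test_that("Hookean fit recovers a noise-free linear law exactly", {
  # sigma = 10 * lambda kPa through the origin of the stretch axis
  curve <- tibble::tibble(stretch = seq(1, 1.3, length.out = 10),
                          stress_Pa = 10e3 * seq(1, 1.3, length.out = 10))
  fit <- fit_hookean(curve, "stretch_linear")
  expect_equal(fit$E_kPa, 10, tolerance = 1e-12)
  expect_equal(fit$rss_kPa2, 0, tolerance = 1e-16)
})

test_that("stretch_linear and strain_linear are affine reparameterisations", {
  curve <- linear_curve(28.6, n = 25)
  f1 <- fit_hookean(curve, "stretch_linear")
  f2 <- fit_hookean(curve, "strain_linear")
  # same slope, same residuals; intercepts differ by E
  expect_equal(f1$E_kPa, f2$E_kPa, tolerance = 1e-10)
  expect_equal(f1$rss_kPa2, f2$rss_kPa2, tolerance = 1e-12)
  expect_equal(f1$intercept_kPa, f2$intercept_kPa - f2$E_kPa,
               tolerance = 1e-8)
})

test_that("Hookean fit rejects degenerate designs", {
  flat <- tibble::tibble(stretch = rep(1.1, 5), stress_Pa = 1:5)
  expect_error(fit_hookean(flat), class = "tebv_degenerate_fit_error")
  expect_error(fit_hookean(linear_curve(10, n = 2)),
               class = "tebv_shape_error")
})

test_that("modulus recovery error shrinks roughly as 1/sqrt(n)", {
  recover <- function(n, seed) {
    set.seed(seed)
    strain <- seq(0.01, 0.3, length.out = n)
    curve <- tibble::tibble(
      stretch = 1 + strain * (1 + rnorm(n, 0, 0.05)),
      stress_Pa = 28.6e3 * strain)
    fit_hookean(curve, "strain_linear")$E_kPa - 28.6
  }
  err_small <- sd(vapply(1:40, function(s) recover(25, s), numeric(1)))
  err_large <- sd(vapply(1:40, function(s) recover(400, s), numeric(1)))
  expect_lt(err_large, err_small / 2) # expect ~1/4, allow slack
})

test_that("modulus summary reproduces closed forms and printed study values", {
  s <- summarize_moduli(c(26.5, 29.2, 30.6, 28.1))
  expect_equal(s$mean_E_3sf, 28.6)
  expect_equal(s$sd_E_3sf, 1.73)

  expect_equal(summarize_moduli(c(5, 5, 5))$sd_E_kPa, 0)
  a <- 3.2; b <- 7.9
  s2 <- summarize_moduli(c(a, b))
  expect_equal(s2$mean_E_kPa, (a + b) / 2)
  expect_equal(s2$sd_E_kPa, abs(a - b) / sqrt(2))
})

test_that("modulus summary is permutation-invariant and translation-equivariant", {
  x <- c(26.5, 29.2, 30.6, 28.1)
  s <- summarize_moduli(x)
  sp <- summarize_moduli(rev(x))
  expect_equal(s$mean_E_kPa, sp$mean_E_kPa)
  expect_equal(s$sd_E_kPa, sp$sd_E_kPa)
  st <- summarize_moduli(x + 5)
  expect_equal(st$mean_E_kPa, s$mean_E_kPa + 5)
  expect_equal(st$sd_E_kPa, s$sd_E_kPa)
  expect_error(summarize_moduli(28.6),
               class = "tebv_insufficient_samples_error")
})

test_that("Lame solution satisfies the traction boundary conditions exactly", {
  wall <- wall_elasticity(28.6e3, 0.45)
  for (pp in list(c(780, 0), c(500, 200), c(0, 0))) {
    ls <- lame_solution(1, 2.5, wall, pp[1], pp[2])
    expect_equal(ls$sigma_rr_Pa[1], -pp[1], tolerance = 1e-10)
    expect_equal(ls$sigma_rr_Pa[nrow(ls)], -pp[2], tolerance = 1e-10)
  }
  # unloaded state is identically zero
  ls0 <- lame_solution(1, 2.5, wall, 0, 0)
  expect_true(all(ls0$sigma_rr_Pa == 0 & ls0$sigma_tt_Pa == 0 & ls0$u_mm == 0))
})

test_that("Lame field satisfies radial equilibrium at second order", {
  wall <- wall_elasticity(28.6e3, 0.45)
  resid <- function(n) {
    ls <- lame_solution(1, 2.5, wall, 780, 0,
                        r_mm = seq(1, 2.5, length.out = n))
    r <- ls$r_mm
    i <- 2:(n - 1)
    dsig <- (ls$sigma_rr_Pa[i + 1] - ls$sigma_rr_Pa[i - 1]) / (r[i + 1] - r[i - 1])
    max(abs(dsig + (ls$sigma_rr_Pa[i] - ls$sigma_tt_Pa[i]) / r[i]))
  }
  r1 <- resid(51); r2 <- resid(101)
  expect_lt(r2, r1) # converging
  expect_gt(r1 / r2, 3) # ~4 for a second-order stencil
})

test_that("Lame hoop stress approaches the thin-wall estimate", {
  wall <- wall_elasticity(28.6e3, 0.45)
  ls <- lame_solution(10, 10.5, wall, 1000, 0, r_mm = 10)
  thin <- 1000 * 10 / 0.5 # p a / t = 20 kPa
  expect_equal(ls$sigma_tt_Pa[1], thin, tolerance = 0.03)
})

test_that("Lame displacement matches the independently evaluated closed form", {
  # a = 1 mm, b = 2.5 mm, E = 28.6 kPa, nu = 0.45, p_in = 780 Pa, plane strain
  wall <- wall_elasticity(28.6e3, 0.45)
  u_a <- lame_solution(1, 2.5, wall, 780, 0, r_mm = 1)$u_mm
  expect_equal(u_a, 0.047831, tolerance = 1e-4)
})

test_that("Lame solution is linear in pressure and inverse in modulus", {
  w1 <- wall_elasticity(28.6e3, 0.45)
  w2 <- wall_elasticity(2 * 28.6e3, 0.45)
  l1 <- lame_solution(1, 2.5, w1, 780, 0)
  l2 <- lame_solution(1, 2.5, w1, 2 * 780, 0)
  l3 <- lame_solution(1, 2.5, w2, 780, 0)
  expect_equal(l2$sigma_tt_Pa, 2 * l1$sigma_tt_Pa)
  expect_equal(l2$u_mm, 2 * l1$u_mm)
  expect_equal(l3$u_mm, l1$u_mm / 2)
  expect_equal(l3$sigma_tt_Pa, l1$sigma_tt_Pa) # stress is E-independent
})

test_that("Lame hoop stress decreases outward and stays positive under internal pressure", {
  wall <- wall_elasticity(28.6e3, 0.45)
  ls <- lame_solution(1, 2.5, wall, 780, 0)
  expect_gt(ls$sigma_tt_Pa[1], ls$sigma_tt_Pa[nrow(ls)])
  expect_gt(ls$sigma_tt_Pa[nrow(ls)], 0)
})

test_that("geometry and material validation fails loudly", {
  wall <- wall_elasticity(28.6e3, 0.45)
  expect_error(lame_solution(2.5, 1, wall, 100), class = "tebv_geometry_error")
  expect_error(wall_elasticity(-5, 0.45), class = "tebv_dimension_error")
  expect_error(wall_elasticity(1e3, 0.5), class = "tebv_material_error")
})
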