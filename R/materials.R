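#' Reduce uniaxial tensile records to stress-stretch curves
#'
#' Converts force/length records from a force-controlled uniaxial tensile test
#' of a dog-bone hydrogel specimen into engineering stress and stretch:
#' stretch \eqn{\lambda = L / L_0} and stress \eqn{\sigma = F / (D h)}, where
#' \eqn{D} and \eqn{h} are the specimen width and thickness. When several
#' thickness (or width) measurements are recorded per sample they are
#' averaged before use.
#'
#' @param data Tensile records: a data frame with columns `sample_id`,
#'   `force_N` and `length_mm` (a `time_s` column is carried through if
#'   present).
#' @param dimensions Specimen dimensions: a data frame with columns
#'   `sample_id`, `L0_mm`, `width_mm`, `thickness_mm`; multiple rows per
#'   sample are averaged.
#' @return A tibble with columns `sample_id`, `stretch` (dimensionless) and
#'   `stress_Pa`, one row per input record.
#' @examples
#' recs <- tibble::tibble(sample_id = "s1", force_N = c(0, 0.01, 0.02),
#'                        length_mm = c(10, 11, 12))
#' dims <- tibble::tibble(sample_id = "s1", L0_mm = 10,
#'                        width_mm = 2, thickness_mm = 1)
#' compute_stress_strain(recs, dims)
#' @export
compute_stress_strain <- function(data, dimensions) {
  require_columns(data, c("sample_id", "force_N", "length_mm"),
                  "tensile data")
  require_columns(dimensions, c("sample_id", "L0_mm", "width_mm", "thickness_mm"),
                  "dimensions table")
  dims <- dimensions |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(L0_mm = mean(.data$L0_mm),
                     width_mm = mean(.data$width_mm),
                     thickness_mm = mean(.data$thickness_mm),
                     .groups = "drop")
  if (any(dims$L0_mm <= 0) || any(dims$width_mm <= 0) || any(dims$thickness_mm <= 0)) {
    stopf("tebv_dimension_error",
          "specimen dimensions L0, width and thickness must all be > 0")
  }
  missing <- setdiff(unique(data$sample_id), dims$sample_id)
  if (length(missing) > 0) {
    stopf("tebv_shape_error", "no dimensions recorded for sample(s): %s",
          paste(missing, collapse = ", "))
  }
  counts <- dplyr::count(data, .data$sample_id)
  if (any(counts$n < 3)) {
    stopf("tebv_shape_error",
          "each tensile record needs at least 3 points")
  }
  if (any(!is.finite(data$force_N)) || any(data$force_N < 0)) {
    stopf("tebv_validation_error", "force_N must be finite and non-negative")
  }
  data |>
    dplyr::inner_join(dims, by = "sample_id") |>
    dplyr::mutate(
      stretch = .data$length_mm / .data$L0_mm,
      # mm^2 -> m^2 for stress in Pa
      stress_Pa = .data$force_N / (.data$width_mm * .data$thickness_mm * MM^2)
    ) |>
    dplyr::select(dplyr::any_of(c("sample_id", "time_s")),
                  "stretch", "stress_Pa")
}

#' Fit the linear Hookean wall model to stress-stretch data
#'
#' Ordinary least squares of stress on stretch. Two parameterisations are
#' offered: `"stretch_linear"` regresses \eqn{\sigma} on \eqn{\lambda}
#' (the form \eqn{\sigma = E\lambda}, literal Hookean fit used for this class
#' of hydrogel vessel), `"strain_linear"` regresses on the engineering strain
#' \eqn{\lambda - 1}. With an intercept, both forms are affine
#' reparameterisations: they return identical fitted values and the same
#' slope `E`; they differ only in the reported intercept.
#'
#' @param curve Output of [compute_stress_strain()]: a data frame with
#'   `stretch` and `stress_Pa` (optionally `sample_id` for grouped fits).
#' @param model_form `"stretch_linear"` (default) or `"strain_linear"`.
#' @param fit_intercept Include an intercept (default `TRUE`).
#' @return A tibble of class `hookean_fit`, one row per sample, with columns
#'   `sample_id`, `E_kPa` (slope), `intercept_kPa`, `rss_kPa2`, `model_form`,
#'   `n`.
#' @export
fit_hookean <- function(curve,
                        model_form = c("stretch_linear", "strain_linear"),
                        fit_intercept = TRUE) {
  model_form <- match.arg(model_form)
  require_columns(curve, c("stretch", "stress_Pa"), "stress-stretch curve")
  if (!"sample_id" %in% names(curve)) curve$sample_id <- "sample"
  fits <- curve |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) {
        stopf("tebv_shape_error", "need at least 3 points to fit (sample %s)",
              key$sample_id)
      }
      x <- if (model_form == "stretch_linear") d$stretch else d$stretch - 1
      if (diff(range(x)) < .Machine$double.eps * 10) {
        stopf("tebv_degenerate_fit_error",
              "stretch values are constant; Hookean fit is rank-deficient")
      }
      y <- d$stress_Pa / 1e3 # kPa
      fit <- if (fit_intercept) stats::lm(y ~ x) else stats::lm(y ~ x - 1)
      co <- stats::coef(fit)
      tibble(
        E_kPa = unname(co[["x"]]),
        intercept_kPa = if (fit_intercept) unname(co[["(Intercept)"]]) else 0,
        rss_kPa2 = sum(stats::residuals(fit)^2),
        model_form = model_form,
        n = nrow(d)
      )
    }) |>
    dplyr::ungroup()
  structure(fits, class = c("hookean_fit", class(fits)))
}

#' @method tidy hookean_fit
#' @export
tidy.hookean_fit <- function(x, ...) as_tibble(x)

#' @method glance hookean_fit
#' @export
glance.hookean_fit <- function(x, ...) {
  tibble(n_samples = nrow(x), mean_E_kPa = mean(x$E_kPa),
         sd_E_kPa = if (nrow(x) >= 2) stats::sd(x$E_kPa) else NA_real_,
         model_form = x$model_form[1])
}

#' Summarise Young's moduli across tensile samples
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of
#' per-sample moduli, reported to 3 significant figures alongside the exact
#' values.
#'
#' @param E_kPa Numeric vector of per-sample moduli in kPa (length >= 2), or
#'   a `hookean_fit` object.
#' @return A list of class `modulus_summary` with `per_sample_E_kPa`,
#'   `mean_E_kPa`, `sd_E_kPa` (exact) and `mean_E_3sf`, `sd_E_3sf`.
#' @examples
#' summarize_moduli(c(26.5, 29.2, 30.6, 28.1))
#' @export
summarize_moduli <- function(E_kPa) {
  if (inherits(E_kPa, "hookean_fit")) E_kPa <- E_kPa$E_kPa
  if (!is.numeric(E_kPa) || length(E_kPa) < 2) {
    stopf("tebv_insufficient_samples_error",
          "modulus summary needs at least 2 samples (got %d)", length(E_kPa))
  }
  out <- list(
    per_sample_E_kPa = E_kPa,
    mean_E_kPa = mean(E_kPa),
    sd_E_kPa = stats::sd(E_kPa),
    mean_E_3sf = signif(mean(E_kPa), 3),
    sd_E_3sf = signif(stats::sd(E_kPa), 3)
  )
  structure(out, class = "modulus_summary")
}

#' @export
print.modulus_summary <- function(x, ...) {
  cat(sprintf("Wall modulus over %d samples: E = %g (+/- %g) kPa\n",
              length(x$per_sample_E_kPa), x$mean_E_3sf, x$sd_E_3sf))
  invisible(x)
}

#' @method tidy modulus_summary
#' @export
tidy.modulus_summary <- function(x, ...) {
  tibble(sample = seq_along(x$per_sample_E_kPa), E_kPa = x$per_sample_E_kPa)
}

#' @method glance modulus_summary
#' @export
glance.modulus_summary <- function(x, ...) {
  tibble(n = length(x$per_sample_E_kPa),
         mean_E_kPa = x$mean_E_kPa, sd_E_kPa = x$sd_E_kPa)
}

#' Wall elasticity descriptor
#'
#' Linear-elastic description of the vessel wall: Young's modulus, Poisson
#' ratio and the 2D elasticity regime used for the thick-walled-cylinder
#' solution. A long vessel held at both ends by sutures is closest to plane
#' strain; plane stress is offered for short unconstrained rings.
#'
#' @param E_Pa Young's modulus in Pa.
#' @param nu Poisson ratio, in `[0, 0.5)`. Default 0.45 (nearly
#'   incompressible hydrogel).
#' @param regime `"plane_strain"` (default) or `"plane_stress"`.
#' @export
wall_elasticity <- function(E_Pa, nu = 0.45,
                            regime = c("plane_strain", "plane_stress")) {
  regime <- match.arg(regime)
  check_number(E_Pa, "E_Pa", positive = TRUE)
  check_number(nu, "nu", nonneg = TRUE)
  if (nu >= 0.5) {
    stopf("tebv_material_error", "Poisson ratio must be < 0.5 (got %g)", nu)
  }
  structure(list(E_Pa = E_Pa, nu = nu, regime = regime),
            class = "wall_elasticity")
}

#' Lame solution for a pressurised thick-walled elastic cylinder
#'
#' Closed-form static stress and displacement field of a linear-elastic
#' cylinder with inner radius `a`, outer radius `b`, internal pressure
#' `p_in` and external pressure `p_out`:
#' \deqn{\sigma_{rr}(r) = \frac{p_{in}a^2 - p_{out}b^2}{b^2-a^2}
#'       - \frac{(p_{in}-p_{out})a^2 b^2}{(b^2-a^2) r^2}}
#' \deqn{\sigma_{\theta\theta}(r) = \frac{p_{in}a^2 - p_{out}b^2}{b^2-a^2}
#'       + \frac{(p_{in}-p_{out})a^2 b^2}{(b^2-a^2) r^2}}
#' with the plane-strain radial displacement
#' \deqn{u(r) = \frac{1+\nu}{E}\left[(1-2\nu)\frac{(p_{in}a^2-p_{out}b^2)r}
#'       {b^2-a^2} + \frac{(p_{in}-p_{out})a^2b^2}{(b^2-a^2)r}\right].}
#' This is the structural closure used as the tube law of the perfusion
#' solver and as the wall-stress post-processing kernel.
#'
#' @param a_mm,b_mm Inner and outer radius in mm (`0 < a < b`).
#' @param wall A [wall_elasticity()] object.
#' @param p_in_Pa,p_out_Pa Inner and outer surface pressure in Pa.
#' @param r_mm Radial evaluation grid in mm (default 50 points across the
#'   wall).
#' @return A tibble with columns `r_mm`, `sigma_rr_Pa`, `sigma_tt_Pa`,
#'   `u_mm`, `eps_rr`, `eps_tt`.
#' @export
lame_solution <- function(a_mm, b_mm, wall, p_in_Pa, p_out_Pa = 0,
                          r_mm = seq(a_mm, b_mm, length.out = 50)) {
  check_number(a_mm, "a_mm", positive = TRUE)
  check_number(b_mm, "b_mm", positive = TRUE)
  if (a_mm >= b_mm) {
    stopf("tebv_geometry_error",
          "inner radius must be smaller than outer radius (a=%g, b=%g mm)",
          a_mm, b_mm)
  }
  stopifnot(inherits(wall, "wall_elasticity"))
  a <- a_mm * MM; b <- b_mm * MM; r <- r_mm * MM
  if (any(r < a - 1e-12) || any(r > b + 1e-12)) {
    stopf("tebv_geometry_error", "radial grid must lie within [a, b]")
  }
  E <- wall$E_Pa; nu <- wall$nu
  A2 <- a^2; B2 <- b^2
  den <- B2 - A2
  c1 <- (p_in_Pa * A2 - p_out_Pa * B2) / den          # uniform part [Pa]
  c2 <- (p_in_Pa - p_out_Pa) * A2 * B2 / den          # 1/r^2 part [Pa m^2]
  sig_rr <- c1 - c2 / r^2
  sig_tt <- c1 + c2 / r^2
  if (wall$regime == "plane_strain") {
    u <- ((1 + nu) / E) * ((1 - 2 * nu) * c1 * r + c2 / r)
  } else {
    u <- (1 / E) * ((1 - nu) * c1 * r + (1 + nu) * c2 / r)
  }
  eps_tt <- u / r
  eps_rr <- if (wall$regime == "plane_strain") {
    ((1 + nu) / E) * ((1 - 2 * nu) * c1 - c2 / r^2)
  } else {
    (1 / E) * ((1 - nu) * c1 - (1 + nu) * c2 / r^2)
  }
  tibble(r_mm = r / MM,
         sigma_rr_Pa = sig_rr, sigma_tt_Pa = sig_tt,
         u_mm = u / MM, eps_rr = eps_rr, eps_tt = eps_tt)
}

#' Radial wall compliance of the Lame solution
#'
#' Slope of inner-radius displacement with respect to internal pressure,
#' `u(a)/p_in` at zero external pressure, in m/Pa. For plane strain this is
#' \deqn{C = \frac{a(1+\nu)\,[(1-2\nu)a^2 + b^2]}{E\,(b^2 - a^2)}.}
#' This constant closes the one-dimensional flow model as its tube law.
#'
#' @inheritParams lame_solution
#' @return Compliance in m/Pa.
#' @export
lame_compliance <- function(a_mm, b_mm, wall) {
  a <- a_mm * MM; b <- b_mm * MM
  E <- wall$E_Pa; nu <- wall$nu
  if (wall$regime == "plane_strain") {
    a * (1 + nu) * ((1 - 2 * nu) * a^2 + b^2) / (E * (b^2 - a^2))
  } else {
    a * ((1 - nu) * a^2 + (1 + nu) * b^2) / (E * (b^2 - a^2))
  }
}
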