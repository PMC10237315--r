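#' Power-law (shear-thinning) fluid descriptor
#'
#' Apparent-viscosity law \eqn{\mu(\dot\gamma) = K \dot\gamma^{\,n}} with `K`
#' in centipoise at \eqn{\dot\gamma = 1\,s^{-1}} and dimensionless exponent
#' `n` (`n < 0` for shear thinning). The equivalent stress form is
#' \eqn{\tau = K \dot\gamma^{\,m}} with flow-behaviour index `m = n + 1`.
#' Outside the calibrated shear-rate window the viscosity is clamped to its
#' boundary value so that \eqn{\mu} stays bounded as \eqn{\dot\gamma \to 0}.
#'
#' @param K_cP Consistency in cP (> 0).
#' @param n Viscosity exponent; requires `n + 1 > 0`.
#' @param density_kg_m3 Fluid density, default 1000 (aqueous culture media).
#' @param clamp Two-element shear-rate clamp range in 1/s, default
#'   `c(1, 1000)` (the calibrated sweep window).
#' @export
power_law_fluid <- function(K_cP, n, density_kg_m3 = 1000,
                            clamp = c(1, 1000)) {
  check_number(K_cP, "K_cP", positive = TRUE)
  check_number(n, "n")
  if (n + 1 <= 0) {
    stopf("tebv_material_error",
          "flow-behaviour index m = n + 1 must be > 0 (n = %g)", n)
  }
  check_number(density_kg_m3, "density_kg_m3", positive = TRUE)
  if (length(clamp) != 2 || clamp[1] <= 0 || clamp[1] >= clamp[2]) {
    stopf("tebv_validation_error",
          "clamp must be an increasing positive pair of shear rates")
  }
  structure(list(K_cP = K_cP, n = n, m = n + 1,
                 density_kg_m3 = density_kg_m3, clamp = clamp),
            class = "power_law_fluid")
}

#' @export
print.power_law_fluid <- function(x, ...) {
  cat(sprintf(
    "Power-law fluid: K = %g cP, n = %g (m = n + 1 = %g), rho = %g kg/m3\n",
    x$K_cP, x$n, x$m, x$density_kg_m3))
  cat(sprintf("  viscosity clamped to shear rates [%g, %g] 1/s\n",
              x$clamp[1], x$clamp[2]))
  invisible(x)
}

#' Fit the power-law viscosity model to a rheometer sweep
#'
#' Log-log least squares of apparent viscosity on shear rate:
#' \eqn{\log\mu = \log K + n \log\dot\gamma}. If the sweep records shear
#' stress, the apparent viscosity \eqn{\mu = \tau / \dot\gamma} is formed
#' first. The intercept gives `K` (cP), the slope gives `n`.
#'
#' @param sweep Data frame with column `shear_rate_1_per_s` and one of
#'   `shear_stress_Pa` or `viscosity_cP`.
#' @param density_kg_m3 Density carried into the returned fluid object.
#' @param clamp Clamp range for the returned fluid; default the sweep's own
#'   shear-rate range.
#' @return A `power_law_fluid` with extra fields `rss_log` (residual sum of
#'   squares on the log scale) and `fit_n_points`.
#' @export
fit_power_law <- function(sweep, density_kg_m3 = 1000, clamp = NULL) {
  require_columns(sweep, "shear_rate_1_per_s", "rheometry sweep")
  g <- sweep$shear_rate_1_per_s
  if (length(g) < 3) {
    stopf("tebv_shape_error", "rheometry fit needs at least 3 points")
  }
  if (any(!is.finite(g)) || any(g <= 0)) {
    stopf("tebv_domain_error",
          "shear rates must be positive for the log transform")
  }
  if ("viscosity_cP" %in% names(sweep)) {
    mu_cP <- sweep$viscosity_cP
  } else if ("shear_stress_Pa" %in% names(sweep)) {
    mu_cP <- sweep$shear_stress_Pa / g / CP
  } else {
    stopf("tebv_validation_error",
          "rheometry sweep is missing required column(s): shear_stress_Pa or viscosity_cP")
  }
  if (any(!is.finite(mu_cP)) || any(mu_cP <= 0)) {
    stopf("tebv_domain_error",
          "shear stress / viscosity must be positive for the log transform")
  }
  fit <- stats::lm(log(mu_cP) ~ log(g))
  co <- stats::coef(fit)
  if (is.null(clamp)) clamp <- range(g)
  fluid <- power_law_fluid(K_cP = exp(unname(co[1])), n = unname(co[2]),
                           density_kg_m3 = density_kg_m3, clamp = clamp)
  fluid$rss_log <- sum(stats::residuals(fit)^2)
  fluid$fit_n_points <- length(g)
  fluid
}

#' @method tidy power_law_fluid
#' @export
tidy.power_law_fluid <- function(x, ...) {
  tibble(term = c("K_cP", "n"), estimate = c(x$K_cP, x$n))
}

#' @method glance power_law_fluid
#' @export
glance.power_law_fluid <- function(x, ...) {
  tibble(K_cP = x$K_cP, n = x$n, m = x$m,
         rss_log = x$rss_log %||% NA_real_,
         n_points = x$fit_n_points %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apparent viscosity of a power-law fluid
#'
#' Evaluates \eqn{\mu(\dot\gamma) = K\,\mathrm{clamp}(\dot\gamma)^{\,n}} in
#' Pa s. Clamping to the calibrated window makes every non-negative shear
#' rate valid and keeps the law monotone non-increasing (for `n < 0`) and
#' continuous at the window boundaries.
#'
#' @param fluid A [power_law_fluid()].
#' @param shear_rate_1_per_s Shear rate(s) in 1/s, >= 0.
#' @return Viscosity in Pa s, same length as `shear_rate_1_per_s`.
#' @examples
#' media <- power_law_fluid(K_cP = 11.885, n = -0.2188)
#' apparent_viscosity(media, c(1, 10, 1000))
#' @export
apparent_viscosity <- function(fluid, shear_rate_1_per_s) {
  stopifnot(inherits(fluid, "power_law_fluid"))
  g <- pmin(pmax(shear_rate_1_per_s, fluid$clamp[1]), fluid$clamp[2])
  fluid$K_cP * CP * g^fluid$n
}
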