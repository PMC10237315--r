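#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   facet_wrap geom_abline theme_minimal scale_x_log10 scale_y_log10
NULL

#' Plot stress-stretch data with fitted Hookean lines
#'
#' @param object A [fit_hookean()] result (must retain the fitting data via
#'   the `curve` argument).
#' @param curve The stress-stretch tibble the fit was computed from.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hookean_fit
#' @export
autoplot.hookean_fit <- function(object, curve, ...) {
  if (!"sample_id" %in% names(curve)) curve$sample_id <- "sample"
  # express both model forms as lines in (stretch, stress) coordinates
  lines <- tibble(
    sample_id = object$sample_id,
    slope = object$E_kPa,
    icpt = if (object$model_form[1] == "stretch_linear") {
      object$intercept_kPa
    } else {
      object$intercept_kPa - object$E_kPa
    })
  ggplot(curve, aes(x = .data$stretch, y = .data$stress_Pa / 1e3,
                    colour = .data$sample_id)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_abline(data = lines,
                aes(slope = .data$slope, intercept = .data$icpt,
                    colour = .data$sample_id)) +
    labs(x = "stretch λ", y = "stress [kPa]", colour = "sample") +
    theme_minimal()
}

#' Plot a rheometer sweep and the fitted power law
#'
#' @param object A [power_law_fluid()] (typically from [fit_power_law()]).
#' @param sweep Optional sweep tibble to overlay as points.
#' @param ... Unused.
#' @return A ggplot of apparent viscosity vs shear rate on log-log axes.
#' @method autoplot power_law_fluid
#' @export
autoplot.power_law_fluid <- function(object, sweep = NULL, ...) {
  g <- 10^seq(log10(object$clamp[1]), log10(object$clamp[2]),
              length.out = 100)
  fitted <- tibble(shear_rate_1_per_s = g,
                   viscosity_cP = apparent_viscosity(object, g) / CP)
  p <- ggplot(fitted, aes(x = .data$shear_rate_1_per_s,
                          y = .data$viscosity_cP)) +
    geom_line() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "shear rate [1/s]", y = "apparent viscosity [cP]") +
    theme_minimal()
  if (!is.null(sweep)) {
    if ("shear_stress_Pa" %in% names(sweep) && !"viscosity_cP" %in% names(sweep)) {
      sweep$viscosity_cP <- sweep$shear_stress_Pa / sweep$shear_rate_1_per_s / CP
    }
    p <- p + geom_point(data = sweep, size = 1, alpha = 0.7)
  }
  p
}

#' Plot the monitor-section waveforms of a simulation
#'
#' Inner diameter, section-mean velocity, pressure and wall shear stress at
#' the monitor section over the converged cycle.
#'
#' @param object A [run_simulation()] result.
#' @param ... Unused.
#' @return A ggplot faceted by quantity.
#' @method autoplot tebv_sim
#' @export
autoplot.tebv_sim <- function(object, ...) {
  long <- object$monitor |>
    tidyr::pivot_longer(-"t_s", names_to = "quantity", values_to = "value")
  ggplot(long, aes(x = .data$t_s, y = .data$value)) +
    geom_line() +
    facet_wrap(~quantity, scales = "free_y",
               labeller = ggplot2::as_labeller(c(
                 d_mm = "inner diameter [mm]", V_mm_s = "mean velocity [mm/s]",
                 p_Pa = "pressure [Pa]", Q_uL_min = "flow rate [uL/min]",
                 wss_Pa = "wall shear stress [Pa]"))) +
    labs(x = "time in cycle [s]", y = NULL) +
    theme_minimal()
}

#' Plot a simulation-vs-experiment expansion comparison
#'
#' @param object An [expansion_error()] result.
#' @param ... Unused.
#' @return A ggplot of the two expansion waveforms and the per-time error.
#' @method autoplot expansion_error
#' @export
autoplot.expansion_error <- function(object, ...) {
  long <- object$by_time |>
    dplyr::select("t_s", simulated = "dd_sim_mm", measured = "dd_exp_mm") |>
    tidyr::pivot_longer(-"t_s", names_to = "source", values_to = "dd_mm")
  ggplot(long, aes(x = .data$t_s, y = .data$dd_mm, colour = .data$source)) +
    geom_line() +
    labs(x = "time in cycle [s]", y = "diameter expansion [mm]",
         colour = NULL,
         subtitle = sprintf("mean relative error %.1f%%, max %.1f%%",
                            object$mean_error_pct, object$max_error_pct)) +
    theme_minimal()
}
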