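#' Relative error between two diameter expansions
#'
#' The scalar kernel of the diameter comparison: for expansions from
#' baseline \eqn{\Delta d_{sim}} and \eqn{\Delta d_{exp}},
#' \deqn{e = 100\,\frac{|\Delta d_{sim} - \Delta d_{exp}|}{|\Delta d_{exp}|}.}
#'
#' @param dd_sim_mm,dd_exp_mm Simulated and measured diameter expansion(s)
#'   from baseline, in mm.
#' @return Relative error(s) in percent.
#' @examples
#' relative_expansion_error(0.18, 0.14) # 28.6%
#' @export
relative_expansion_error <- function(dd_sim_mm, dd_exp_mm) {
  100 * abs(dd_sim_mm - dd_exp_mm) / abs(dd_exp_mm)
}

#' Time-resolved diameter-waveform comparison
#'
#' Registers a simulated and a measured inner-diameter waveform on a common
#' uniform time grid over one period (linear interpolation, optional phase
#' alignment by circular cross-correlation of the expansion waveforms),
#' forms the expansions \eqn{\Delta d(t) = d(t) - d_0}, and reports the
#' per-time relative error [relative_expansion_error()] wherever the
#' measured expansion is above a floor, together with its unweighted mean
#' and maximum over the period.
#'
#' @param sim,exp Data frames with columns `t_s`, `d_mm`, each spanning at
#'   least one period.
#' @param d0_sim_mm,d0_exp_mm Baseline (zero-pressure) diameters in mm.
#' @param period_s Common period; default the span of `exp$t_s`.
#' @param n_grid Points of the common uniform grid (default 200).
#' @param eps_frac Error floor as a fraction of the peak measured expansion
#'   (default 0.05): instants with `|expansion| < eps_frac * peak` are
#'   excluded from the error statistics to avoid division blow-ups near
#'   zero-crossings.
#' @param align Phase-align by circular cross-correlation (default `TRUE`).
#' @return A list of class `expansion_error` with `by_time` (tibble: `t_s`,
#'   `dd_sim_mm`, `dd_exp_mm`, `rel_error_pct`, `retained`),
#'   `mean_error_pct`, `max_error_pct`, `t_max_error_s`, `lag_s` and
#'   `n_retained`.
#' @export
expansion_error <- function(sim, exp, d0_sim_mm = NULL, d0_exp_mm = NULL,
                            period_s = NULL, n_grid = 200,
                            eps_frac = 0.05, align = TRUE) {
  require_columns(sim, c("t_s", "d_mm"), "simulated waveform")
  require_columns(exp, c("t_s", "d_mm"), "measured waveform")
  d0_sim_mm <- d0_sim_mm %||% attr(sim, "d0_mm") %||%
    stopf("tebv_validation_error", "baseline d0_sim_mm is required")
  d0_exp_mm <- d0_exp_mm %||% attr(exp, "d0_mm") %||%
    stopf("tebv_validation_error", "baseline d0_exp_mm is required")
  if (is.null(period_s)) period_s <- diff(range(exp$t_s))
  if (diff(range(sim$t_s)) < period_s - 1e-9) {
    stopf("tebv_alignment_error",
          "waveforms do not overlap over a common period")
  }
  tg <- seq(0, period_s, length.out = n_grid + 1)[-(n_grid + 1)]
  resample <- function(w) {
    t0 <- (w$t_s - w$t_s[1]) %% period_s
    o <- order(t0)
    t0 <- t0[o]; d <- w$d_mm[o]
    # periodic linear interpolation
    stats::approx(c(t0 - period_s, t0, t0 + period_s), rep(d, 3),
                  xout = tg, rule = 2, ties = mean)$y
  }
  dd_sim <- resample(sim) - d0_sim_mm
  dd_exp <- resample(exp) - d0_exp_mm
  lag_idx <- 0L
  if (align) {
    xc <- vapply(0:(n_grid - 1), function(k) {
      sum(dd_sim * dd_exp[((seq_len(n_grid) - 1 + k) %% n_grid) + 1])
    }, numeric(1))
    lag_idx <- which.max(xc) - 1L
    dd_exp <- dd_exp[((seq_len(n_grid) - 1 + lag_idx) %% n_grid) + 1]
  }
  peak <- max(abs(dd_exp))
  floor_mm <- eps_frac * peak
  retained <- peak > 0 & abs(dd_exp) >= floor_mm
  if (!any(retained)) {
    stopf("tebv_undefined_error",
          "measured expansion never exceeds the error floor; relative error undefined")
  }
  e <- ifelse(retained, relative_expansion_error(dd_sim, dd_exp), NA_real_)
  by_time <- tibble(t_s = tg, dd_sim_mm = dd_sim, dd_exp_mm = dd_exp,
                    rel_error_pct = e, retained = retained)
  imax <- which.max(e)
  structure(list(
    by_time = by_time,
    mean_error_pct = mean(e[retained]),
    max_error_pct = e[imax],
    t_max_error_s = tg[imax],
    lag_s = lag_idx * period_s / n_grid,
    n_retained = sum(retained),
    eps_floor_mm = floor_mm
  ), class = "expansion_error")
}

#' @export
print.expansion_error <- function(x, ...) {
  cat(sprintf(
    "Diameter-expansion comparison: mean error %.3g%%, max %.3g%% at t = %.4g s (%d/%d instants retained)\n",
    x$mean_error_pct, x$max_error_pct, x$t_max_error_s,
    x$n_retained, nrow(x$by_time)))
  invisible(x)
}

#' @method tidy expansion_error
#' @export
tidy.expansion_error <- function(x, ...) x$by_time

#' @method glance expansion_error
#' @export
glance.expansion_error <- function(x, ...) {
  tibble(mean_error_pct = x$mean_error_pct, max_error_pct = x$max_error_pct,
         t_max_error_s = x$t_max_error_s, lag_s = x$lag_s,
         n_retained = x$n_retained)
}

#' Mean velocity of tracked cell clusters
#'
#' Per-cluster axial velocity as the least-squares slope of position against
#' time (robust to frame jitter compared with two-point differencing), then
#' the across-cluster mean and sample standard deviation (n-1 denominator;
#' `NA` and flagged for a single track).
#'
#' @param tracks Data frame with columns `cluster_id`, `t_s`, `x_mm`.
#' @return A list of class `track_velocities` with `per_track` (tibble:
#'   `cluster_id`, `v_mm_s`, `n_points`), `mean_v_mm_s`, `sd_v_mm_s`,
#'   `n_clusters`.
#' @export
track_velocities <- function(tracks) {
  require_columns(tracks, c("cluster_id", "t_s", "x_mm"), "cluster tracks")
  per <- tracks |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$t_s)) < 2) {
        stopf("tebv_degenerate_track_error",
              "cluster %s has fewer than 2 distinct times", key$cluster_id)
      }
      fit <- stats::lm(x_mm ~ t_s, data = d)
      tibble(v_mm_s = unname(stats::coef(fit)[["t_s"]]), n_points = nrow(d))
    }) |>
    dplyr::ungroup()
  n <- nrow(per)
  structure(list(per_track = per,
                 mean_v_mm_s = mean(per$v_mm_s),
                 sd_v_mm_s = if (n >= 2) stats::sd(per$v_mm_s) else NA_real_,
                 n_clusters = n,
                 sd_defined = n >= 2),
            class = "track_velocities")
}

#' @export
print.track_velocities <- function(x, ...) {
  sd_txt <- if (x$sd_defined) sprintf("+/- %.3g", x$sd_v_mm_s) else "sd undefined (n = 1)"
  cat(sprintf("Tracked cluster velocity (n = %d): %.3g mm/s (%s)\n",
              x$n_clusters, x$mean_v_mm_s, sd_txt))
  invisible(x)
}

#' @method tidy track_velocities
#' @export
tidy.track_velocities <- function(x, ...) x$per_track

#' @method glance track_velocities
#' @export
glance.track_velocities <- function(x, ...) {
  tibble(n_clusters = x$n_clusters, mean_v_mm_s = x$mean_v_mm_s,
         sd_v_mm_s = x$sd_v_mm_s)
}

#' Signed relative difference between simulated and tracked mean velocity
#'
#' \eqn{100 (V_{sim} - V_{track}) / V_{track}}: positive when the simulated
#' cross-section-mean velocity exceeds the tracked cell-cluster mean.
#'
#' @param sim_mean_V_mm_s Simulated cycle-mean cross-section velocity, mm/s.
#' @param tracked_mean_V_mm_s Tracked mean cluster velocity, mm/s (> 0).
#' @return Signed relative difference in percent.
#' @examples
#' velocity_comparison(2.52, 2.28) # +10.5%
#' @export
velocity_comparison <- function(sim_mean_V_mm_s, tracked_mean_V_mm_s) {
  if (tracked_mean_V_mm_s <= 0) {
    stopf("tebv_domain_error", "tracked mean velocity must be positive")
  }
  100 * (sim_mean_V_mm_s - tracked_mean_V_mm_s) / tracked_mean_V_mm_s
}

#' Relative error of the simulated cycle-mean flow rate
#'
#' \eqn{100\,|Q_{sim} - Q_{nom}| / Q_{nom}} against the nominal (pump
#' set-point) flow rate. The nominal value is the denominator; the error is
#' invariant to a common unit rescaling of both arguments.
#'
#' @param Q_sim_uL_min Simulated cycle-mean flow rate, uL/min.
#' @param Q_nominal_uL_min Nominal flow rate, uL/min (> 0).
#' @return Relative error in percent.
#' @examples
#' flow_rate_check(474.78, 500) # 5.04%
#' @export
flow_rate_check <- function(Q_sim_uL_min, Q_nominal_uL_min) {
  if (Q_nominal_uL_min <= 0) {
    stopf("tebv_domain_error", "nominal flow rate must be positive")
  }
  100 * abs(Q_sim_uL_min - Q_nominal_uL_min) / Q_nominal_uL_min
}

#' Full simulation-vs-experiment comparison report
#'
#' Combines the diameter-expansion comparison, the flow-rate check and the
#' velocity comparison into one report.
#'
#' @param sim A [run_simulation()] result.
#' @param exp_waveform Measured diameter waveform (`t_s`, `d_mm`).
#' @param tracks Measured cluster tracks (`cluster_id`, `t_s`, `x_mm`).
#' @param d0_exp_mm Measured baseline diameter, mm (default 2.0).
#' @param Q_nominal_uL_min Pump set-point, uL/min (default 500).
#' @param ... Passed to [expansion_error()].
#' @return A list of class `comparison_report`.
#' @export
comparison_report <- function(sim, exp_waveform, tracks,
                              d0_exp_mm = 2.0, Q_nominal_uL_min = 500, ...) {
  stopifnot(inherits(sim, "tebv_sim"))
  g <- glance(sim)
  ee <- expansion_error(sim = sim$monitor[, c("t_s", "d_mm")],
                        exp = exp_waveform,
                        d0_sim_mm = 2 * sim$vessel$a_mm,
                        d0_exp_mm = d0_exp_mm, ...)
  tv <- track_velocities(tracks)
  structure(list(
    expansion = ee,
    tracks = tv,
    Q_sim_uL_min = g$Q_mean_uL_min,
    Q_nominal_uL_min = Q_nominal_uL_min,
    flow_error_pct = flow_rate_check(g$Q_mean_uL_min, Q_nominal_uL_min),
    V_sim_mm_s = g$V_mean_mm_s,
    velocity_diff_pct = velocity_comparison(g$V_mean_mm_s, tv$mean_v_mm_s)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Simulation vs experiment\n")
  print(x$expansion)
  cat(sprintf("  cycle-mean flow %.4g uL/min vs nominal %g uL/min: error %.3g%%\n",
              x$Q_sim_uL_min, x$Q_nominal_uL_min, x$flow_error_pct))
  print(x$tracks)
  cat(sprintf("  simulated mean velocity %.3g mm/s: %+.3g%% vs tracked mean\n",
              x$V_sim_mm_s, x$velocity_diff_pct))
  invisible(x)
}

#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  tibble(
    mean_expansion_error_pct = x$expansion$mean_error_pct,
    max_expansion_error_pct = x$expansion$max_error_pct,
    Q_sim_uL_min = x$Q_sim_uL_min,
    flow_error_pct = x$flow_error_pct,
    V_sim_mm_s = x$V_sim_mm_s,
    tracked_V_mm_s = x$tracks$mean_v_mm_s,
    velocity_diff_pct = x$velocity_diff_pct
  )
}
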