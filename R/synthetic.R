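#' Configuration for the synthetic bench-data generator
#'
#' One seeded configuration drives every generator; each data stream draws
#' from its own substream (a stream-specific offset of the base seed) so a
#' stage can be regenerated independently without disturbing the others.
#' Defaults emulate the study conditions of the perfused-vessel experiment:
#' a force-controlled tensile ramp 0 to 0.02 N at 0.0002 N/s, a 1-1000 1/s
#' rheometer sweep, a 640-780 Pa 1 Hz outlet pressure, and five tracked
#' cell clusters.
#'
#' @param seed Integer base seed.
#' @param tensile List: `E_true_kPa` (28.6), `noise_cv` (0.01, multiplicative
#'   on strain), `n_points` (50), `n_samples` (4), `force_max_N` (0.02),
#'   `force_rate_N_s` (2e-4), `L0_mm` (10), `width_mm` (2),
#'   `thickness_mm` (four per-location readings averaging 1 mm).
#' @param rheometry List: `K_true_cP` (11.885), `n_true` (-0.2188),
#'   `gamma_grid` (25 log-spaced points over 1-1000 1/s), `noise_log_sd`
#'   (0.02), `emit` ("viscosity" or "stress").
#' @param pressure List: `p_min_Pa` (640), `p_max_Pa` (780), `period_s` (1),
#'   `noise_sd_Pa` (5), `rate_Hz` (100).
#' @param experiment List: `frame_rate_Hz` (25), `diameter_noise_sd_mm`
#'   (0.01), `n_clusters` (5), `radial_law` ("uniform_area",
#'   "uniform_radius" or "near_wall"), `track_noise_sd_mm` (0.02),
#'   `n_periods` (1).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         tensile = list(), rheometry = list(),
                         pressure = list(), experiment = list()) {
  merge_defaults <- function(user, def, what) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown) > 0) {
      stopf("tebv_validation_error", "unknown %s option(s): %s",
            what, paste(unknown, collapse = ", "))
    }
    utils::modifyList(def, user)
  }
  cfg <- list(
    seed = as.integer(seed),
    tensile = merge_defaults(tensile, list(
      E_true_kPa = 28.6, noise_cv = 0.01, n_points = 50L, n_samples = 4L,
      force_max_N = 0.02, force_rate_N_s = 2e-4,
      L0_mm = 10, width_mm = 2, thickness_mm = c(0.98, 1.01, 1.0, 1.01)
    ), "tensile"),
    rheometry = merge_defaults(rheometry, list(
      K_true_cP = 11.885, n_true = -0.2188,
      gamma_grid = 10^seq(0, 3, length.out = 25),
      noise_log_sd = 0.02, emit = "viscosity"
    ), "rheometry"),
    pressure = merge_defaults(pressure, list(
      p_min_Pa = 640, p_max_Pa = 780, period_s = 1,
      noise_sd_Pa = 5, rate_Hz = 100
    ), "pressure"),
    experiment = merge_defaults(experiment, list(
      frame_rate_Hz = 25, diameter_noise_sd_mm = 0.01,
      n_clusters = 5L, radial_law = "uniform_area",
      track_noise_sd_mm = 0.02, n_periods = 1
    ), "experiment")
  )
  stopifnot(cfg$tensile$noise_cv >= 0, cfg$rheometry$noise_log_sd >= 0,
            cfg$pressure$noise_sd_Pa >= 0,
            cfg$experiment$diameter_noise_sd_mm >= 0,
            cfg$experiment$track_noise_sd_mm >= 0)
  structure(cfg, class = "synth_config")
}

# per-stream substream seeding; keeps streams independent and reproducible
with_substream <- function(cfg, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((cfg$seed * 1000L + offset) %% .Machine$integer.max)
  force(code)
}

#' Generate synthetic uniaxial tensile records
#'
#' Emulates a force-controlled tensile ramp on dog-bone specimens of a
#' Hookean material with modulus `E_true_kPa`: the force rises linearly at
#' the configured rate, the stress follows from the specimen cross-section,
#' and the length is the inverse of the linear stress-strain law with
#' multiplicative Gaussian noise on the strain
#' (\eqn{\lambda = 1 + (\sigma/E)(1 + \epsilon)}).
#'
#' @param cfg A [synth_config()].
#' @return A list with `data` (tibble: `sample_id`, `time_s`, `force_N`,
#'   `length_mm`) and `dimensions` (tibble: `sample_id`, `L0_mm`,
#'   `width_mm`, `thickness_mm`, one row per thickness reading), the exact
#'   dialect consumed by [compute_stress_strain()].
#' @export
gen_tensile <- function(cfg = synth_config()) {
  tc <- cfg$tensile
  stopifnot(tc$E_true_kPa > 0)
  with_substream(cfg, 1L, {
    E_Pa <- tc$E_true_kPa * 1e3
    area_m2 <- tc$width_mm * mean(tc$thickness_mm) * MM^2
    t_end <- tc$force_max_N / tc$force_rate_N_s
    data <- purrr::map_dfr(seq_len(tc$n_samples), function(s) {
      time_s <- seq(0, t_end, length.out = tc$n_points)
      force_N <- tc$force_rate_N_s * time_s
      sigma <- force_N / area_m2
      strain <- (sigma / E_Pa) * (1 + stats::rnorm(tc$n_points, 0, tc$noise_cv))
      tibble(sample_id = sprintf("tebv_%02d", s), time_s = time_s,
             force_N = force_N, length_mm = tc$L0_mm * (1 + strain))
    })
    dims <- purrr::map_dfr(seq_len(tc$n_samples), function(s) {
      tibble(sample_id = sprintf("tebv_%02d", s), L0_mm = tc$L0_mm,
             width_mm = tc$width_mm, thickness_mm = tc$thickness_mm)
    })
    list(data = data, dimensions = dims)
  })
}

#' Generate a synthetic rheometer sweep
#'
#' Shear-thinning power-law viscosity \eqn{\mu = K\dot\gamma^{\,n}} over the
#' configured shear-rate grid with log-normal noise, emitted either as
#' apparent viscosity (cP) or as shear stress (Pa), the two dialects the
#' rheology fitter accepts.
#'
#' @param cfg A [synth_config()].
#' @return A tibble with `shear_rate_1_per_s` and `viscosity_cP` or
#'   `shear_stress_Pa`.
#' @export
gen_rheometry <- function(cfg = synth_config()) {
  rc <- cfg$rheometry
  stopifnot(rc$K_true_cP > 0, all(rc$gamma_grid > 0))
  with_substream(cfg, 2L, {
    g <- sort(rc$gamma_grid)
    mu_cP <- rc$K_true_cP * g^rc$n_true *
      exp(stats::rnorm(length(g), 0, rc$noise_log_sd))
    if (identical(rc$emit, "stress")) {
      tibble(shear_rate_1_per_s = g, shear_stress_Pa = mu_cP * CP * g)
    } else {
      tibble(shear_rate_1_per_s = g, viscosity_cP = mu_cP)
    }
  })
}

#' Generate synthetic outlet-pressure sensor readings
#'
#' Sinusoidal outlet pressure plus Gaussian sensor noise, sampled at the
#' configured rate over one period.
#'
#' @param cfg A [synth_config()].
#' @return A tibble with `t_s` and `p_Pa`.
#' @export
gen_pressure <- function(cfg = synth_config()) {
  pc <- cfg$pressure
  with_substream(cfg, 3L, {
    w <- outlet_pressure_waveform(pc$p_min_Pa, pc$p_max_Pa, pc$period_s)
    t <- seq(0, pc$period_s, by = 1 / pc$rate_Hz)
    tibble(t_s = t,
           p_Pa = eval_waveform(w, t) + stats::rnorm(length(t), 0, pc$noise_sd_Pa))
  })
}

#' Generate a synthetic perfusion "experiment" from a simulation
#'
#' Emulates the microscope measurements the comparison stage consumes, using
#' a converged simulation as ground truth: the inner-diameter waveform is
#' the simulated monitor-section diameter sampled at the frame rate with
#' Gaussian noise; cell clusters receive radial positions drawn from the
#' configured sampling law and are advected axially at the local
#' [reconstruct_profile()] velocity driven by the simulated section-mean
#' velocity, with Gaussian position noise; pressure readings come from
#' [gen_pressure()].
#'
#' Radial sampling laws: `"uniform_area"` (uniform over the cross-section
#' area; the unbiased law, tracked mean approaches the section-mean
#' velocity), `"uniform_radius"` (uniform in radius; oversamples the fast
#' core, tracked mean biased high, 4V/3 for a parabolic profile),
#' `"near_wall"` (clusters confined to the outer 15% of the radius; tracked
#' mean biased low, the configuration conjectured for the bench
#' measurement).
#'
#' @param sim A [run_simulation()] result.
#' @param cfg A [synth_config()].
#' @return A list with `diameter` (tibble `t_s`, `d_mm`; attribute `d0_mm`),
#'   `tracks` (tibble `cluster_id`, `t_s`, `x_mm`, `r_frac`), `pressure`
#'   (tibble `t_s`, `p_Pa`) and `truth` (list: section-mean velocity series
#'   and cycle mean).
#' @export
gen_experiment <- function(sim, cfg = synth_config()) {
  stopifnot(inherits(sim, "tebv_sim"))
  ec <- cfg$experiment
  mon <- sim$monitor
  Tper <- sim$inlet$period_s
  with_substream(cfg, 4L, {
    # diameter waveform at the frame rate
    t_d <- seq(0, ec$n_periods * Tper, by = 1 / ec$frame_rate_Hz)
    d_true <- stats::approx(mon$t_s, mon$d_mm, xout = t_d %% Tper, ties = mean)$y
    diameter <- tibble(t_s = t_d,
                       d_mm = d_true + stats::rnorm(length(t_d), 0,
                                                    ec$diameter_noise_sd_mm))
    attr(diameter, "d0_mm") <- 2 * sim$vessel$a_mm

    # cluster radial positions
    u01 <- stats::runif(ec$n_clusters)
    r_frac <- switch(ec$radial_law,
      uniform_area = sqrt(u01),
      uniform_radius = u01,
      near_wall = 0.85 + 0.149 * u01,
      stopf("tebv_validation_error", "unknown radial_law '%s'", ec$radial_law))
    shape <- profile_shape(r_frac, sim$fluid$m)

    # advect at the local profile velocity driven by the section mean V(t)
    Vfun <- function(t) stats::approx(mon$t_s, mon$V_mm_s, xout = t %% Tper, ties = mean)$y
    t_f <- seq(0, ec$n_periods * Tper, by = 1 / ec$frame_rate_Hz)
    # cumulative displacement of the section mean by trapezoid integration
    Vt <- Vfun(t_f)
    disp_mean <- c(0, cumsum((Vt[-1] + Vt[-length(Vt)]) / 2 * diff(t_f)))
    tracks <- purrr::map_dfr(seq_len(ec$n_clusters), function(k) {
      tibble(cluster_id = sprintf("c%02d", k), t_s = t_f,
             x_mm = shape[k] * disp_mean +
               stats::rnorm(length(t_f), 0, ec$track_noise_sd_mm),
             r_frac = r_frac[k])
    })

    pressure <- gen_pressure(cfg)
    list(diameter = diameter, tracks = tracks, pressure = pressure,
         truth = list(V_mean_mm_s = mean((mon$V_mm_s[-1] + mon$V_mm_s[-nrow(mon)]) / 2),
                      r_frac = r_frac, profile_shape = shape))
  })
}

#' Write a complete synthetic demo dataset to CSV fixtures
#'
#' Emits every CSV dialect the pipeline consumes: tensile records and
#' dimensions, a rheometer sweep, outlet-pressure readings, and (when a
#' simulation is supplied) a measured diameter waveform and cluster tracks.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [synth_config()].
#' @param sim Optional [run_simulation()] result for the experiment streams.
#' @return Invisibly, a character vector of the files written.
#' @export
write_fixtures <- function(dir, cfg = synth_config(), sim = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tens <- gen_tensile(cfg)
  rheo <- gen_rheometry(cfg)
  pres <- gen_pressure(cfg)
  paths <- c(
    tensile = file.path(dir, "tensile.csv"),
    dimensions = file.path(dir, "tensile_dimensions.csv"),
    rheometry = file.path(dir, "rheometry.csv"),
    pressure = file.path(dir, "outlet_pressure.csv")
  )
  readr::write_csv(tens$data, paths[["tensile"]])
  readr::write_csv(tens$dimensions, paths[["dimensions"]])
  readr::write_csv(rheo, paths[["rheometry"]])
  readr::write_csv(pres, paths[["pressure"]])
  if (!is.null(sim)) {
    expt <- gen_experiment(sim, cfg)
    paths <- c(paths,
               diameter = file.path(dir, "diameter_waveform.csv"),
               tracks = file.path(dir, "cluster_tracks.csv"))
    readr::write_csv(
      dplyr::mutate(expt$diameter, d0_mm = attr(expt$diameter, "d0_mm")),
      paths[["diameter"]])
    readr::write_csv(expt$tracks, paths[["tracks"]])
  }
  invisible(paths)
}
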