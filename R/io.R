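#' Read pipeline input CSV files
#'
#' Readers for the CSV dialects the pipeline consumes. Each validates its
#' required columns and fails with a message naming the missing column.
#'
#' @param path File path.
#' @return A tibble (for `read_waveform_csv()`, with a `d0_mm` attribute
#'   when the file carries a `d0_mm` column).
#' @name tebv_readers
NULL

read_tebv_csv <- function(path, cols, what) {
  if (!file.exists(path)) {
    stopf("tebv_validation_error", "input file not found: %s", path)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, cols, sprintf("%s (%s)", what, path))
  df
}

#' @rdname tebv_readers
#' @export
read_tensile_csv <- function(path) {
  read_tebv_csv(path, c("sample_id", "force_N", "length_mm"), "tensile CSV")
}

#' @rdname tebv_readers
#' @export
read_dimensions_csv <- function(path) {
  read_tebv_csv(path, c("sample_id", "L0_mm", "width_mm", "thickness_mm"),
                "dimensions CSV")
}

#' @rdname tebv_readers
#' @export
read_rheometry_csv <- function(path) {
  df <- read_tebv_csv(path, "shear_rate_1_per_s", "rheometry CSV")
  if (!any(c("shear_stress_Pa", "viscosity_cP") %in% names(df))) {
    stopf("tebv_validation_error",
          "rheometry CSV (%s) is missing required column(s): shear_stress_Pa or viscosity_cP",
          path)
  }
  df
}

#' @rdname tebv_readers
#' @export
read_waveform_csv <- function(path) {
  df <- read_tebv_csv(path, c("t_s", "d_mm"), "diameter waveform CSV")
  if ("d0_mm" %in% names(df)) {
    attr(df, "d0_mm") <- df$d0_mm[1]
  }
  df
}

#' @rdname tebv_readers
#' @export
read_tracks_csv <- function(path) {
  read_tebv_csv(path, c("cluster_id", "t_s", "x_mm"), "cluster tracks CSV")
}

#' Default pipeline configuration
#'
#' Flat configuration with `geometry`, `wall`, `fluid`, `inlet`, `outlet`
#' and `solver` blocks; all defaults are the study conditions of the
#' perfused-vessel experiment. A YAML copy ships at
#' `system.file("extdata", "tebv_defaults.yaml", package = "tebvflow")`.
#'
#' @param path Optional YAML file; values found there override the
#'   built-ins, unknown keys fail with a message naming the key.
#' @return A nested list of class `tebv_config`.
#' @export
pipeline_config <- function(path = NULL) {
  defaults <- list(
    geometry = list(a_mm = 1.0, b_mm = 2.5, length_mm = 20, p_ext_Pa = 0),
    wall = list(E_kPa = 28.6, nu = 0.45, regime = "plane_strain"),
    fluid = list(K_cP = 11.885, n = -0.2188, density_kg_m3 = 1000,
                 clamp = c(1, 1000)),
    inlet = list(U_mean_mm_s = 2.65, period_s = 1, shape = "offset_sinusoid",
                 PI = 1, phase_rad = 0),
    outlet = list(p_min_Pa = 640, p_max_Pa = 780, period_s = 1,
                  phase_rad = 0),
    solver = list(n_nodes = 33, dt_s = 0.01, max_cycles = 40,
                  periodicity_tol = 1e-5, theta = 0.6),
    materials = list(model_form = "stretch_linear", fit_intercept = TRUE),
    comparison = list(Q_nominal_uL_min = 500, d0_exp_mm = 2.0,
                      eps_frac = 0.05)
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (blk in names(user)) {
      if (!blk %in% names(defaults)) {
        stopf("tebv_validation_error", "unknown config block '%s'", blk)
      }
      unknown <- setdiff(names(user[[blk]]), names(defaults[[blk]]))
      if (length(unknown) > 0) {
        stopf("tebv_validation_error", "unknown config key '%s.%s'",
              blk, unknown[1])
      }
      defaults[[blk]] <- utils::modifyList(defaults[[blk]], user[[blk]])
    }
  }
  structure(defaults, class = "tebv_config")
}

config_objects <- function(config) {
  wall <- wall_elasticity(config$wall$E_kPa * 1e3, config$wall$nu,
                          config$wall$regime)
  list(
    vessel = build_vessel(config$geometry$a_mm, config$geometry$b_mm,
                          config$geometry$length_mm, wall,
                          config$geometry$p_ext_Pa),
    fluid = power_law_fluid(config$fluid$K_cP, config$fluid$n,
                            config$fluid$density_kg_m3,
                            unlist(config$fluid$clamp)),
    inlet = inlet_waveform(config$inlet$U_mean_mm_s, config$inlet$period_s,
                           config$inlet$shape, config$inlet$PI,
                           config$inlet$phase_rad),
    outlet = outlet_pressure_waveform(config$outlet$p_min_Pa,
                                      config$outlet$p_max_Pa,
                                      config$outlet$period_s,
                                      config$outlet$phase_rad),
    settings = solver_settings(config$solver$n_nodes, config$solver$dt_s,
                               config$solver$max_cycles,
                               config$solver$periodicity_tol,
                               theta = config$solver$theta)
  )
}

#' Run the full calibration-simulation-comparison pipeline
#'
#' End-to-end orchestration: fit the wall modulus from tensile CSVs, fit
#' the power-law viscosity from a rheometer CSV, simulate pulsatile
#' perfusion with mesh refinement, and compare against the measured
#' diameter waveform and cluster tracks. With `inputs = NULL` a complete
#' synthetic dataset is generated first ([write_fixtures()]), so the
#' pipeline runs out of the box.
#'
#' @param config A [pipeline_config()] or a YAML path.
#' @param inputs Optional named list of CSV paths (`tensile`, `dimensions`,
#'   `rheometry`, `diameter`, `tracks`); `NULL` generates synthetic inputs.
#' @param seed Seed for the synthetic inputs.
#' @param out_dir Optional output directory; when given, the JSON report
#'   and a run manifest are written there.
#' @param refine Run the mesh-refinement harness (default `TRUE`); set
#'   `FALSE` to simulate once at the configured resolution.
#' @param verbose Print progress lines with units.
#' @return A list of class `tebv_pipeline` with `moduli`, `fluid_fit`,
#'   `simulation`, `refinement`, `comparison`, `report` (the JSON-ready
#'   summary list) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL,
                         seed = 1L, out_dir = NULL, refine = TRUE,
                         verbose = FALSE) {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "tebv_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  synthetic <- is.null(inputs)
  if (synthetic) {
    say("[synth] generating synthetic bench data (seed %d)", seed)
    tmp <- file.path(tempdir(), sprintf("tebvflow_fixtures_%d", seed))
    cfg <- synth_config(seed = seed)
    paths <- write_fixtures(tmp, cfg)
    inputs <- as.list(paths)
  }

  say("[materials] reducing tensile records and fitting the Hookean modulus")
  curves <- compute_stress_strain(read_tensile_csv(inputs$tensile),
                                  read_dimensions_csv(inputs$dimensions))
  fits <- fit_hookean(curves, config$materials$model_form,
                      config$materials$fit_intercept)
  moduli <- summarize_moduli(fits)
  say("[materials] E = %g (+/- %g) kPa over %d samples",
      moduli$mean_E_3sf, moduli$sd_E_3sf, nrow(fits))

  say("[rheology] fitting the power-law viscosity model")
  fluid_fit <- fit_power_law(read_rheometry_csv(inputs$rheometry),
                             density_kg_m3 = config$fluid$density_kg_m3)
  say("[rheology] K = %.4g cP, n = %.4g", fluid_fit$K_cP, fluid_fit$n)

  # simulate with the calibrated constants
  cal <- config
  cal$wall$E_kPa <- moduli$mean_E_kPa
  cal$fluid$K_cP <- fluid_fit$K_cP
  cal$fluid$n <- fluid_fit$n
  obj <- config_objects(cal)
  say("[solver] simulating pulsatile perfusion (%s)",
      if (refine) "with mesh refinement" else "single grid")
  refinement <- NULL
  if (refine) {
    refinement <- refine_until_converged(obj$vessel, obj$fluid, obj$inlet,
                                         obj$outlet, obj$settings)
    sim <- refinement$result
  } else {
    sim <- run_simulation(obj$vessel, obj$fluid, obj$inlet, obj$outlet,
                          obj$settings)
  }
  g <- glance(sim)
  say("[solver] cycle-mean flow %.4g uL/min, peak expansion %.4g mm, Re ~ %.2g",
      g$Q_mean_uL_min, g$peak_expansion_mm, sim$reynolds)
  post <- postprocess(sim)

  comparison <- NULL
  if (synthetic) {
    expt <- gen_experiment(sim, synth_config(seed = seed))
    diameter <- expt$diameter
    tracks <- expt$tracks
  } else if (!is.null(inputs$diameter) && !is.null(inputs$tracks)) {
    diameter <- read_waveform_csv(inputs$diameter)
    tracks <- read_tracks_csv(inputs$tracks)
  } else {
    diameter <- NULL
  }
  if (!is.null(diameter)) {
    say("[comparison] comparing simulation against the measured waveforms")
    comparison <- comparison_report(
      sim, diameter, tracks,
      d0_exp_mm = attr(diameter, "d0_mm") %||% config$comparison$d0_exp_mm,
      Q_nominal_uL_min = config$comparison$Q_nominal_uL_min,
      eps_frac = config$comparison$eps_frac)
  }

  report <- list(
    moduli = list(per_sample_E_kPa = moduli$per_sample_E_kPa,
                  mean_E_kPa = moduli$mean_E_kPa, sd_E_kPa = moduli$sd_E_kPa,
                  model_form = config$materials$model_form),
    rheology = list(K_cP = fluid_fit$K_cP, n = fluid_fit$n,
                    m = fluid_fit$m, rss_log = fluid_fit$rss_log,
                    tau_form = "tau = K * gamma^(n+1), K in cP s^n"),
    simulation = c(as.list(g), list(
      alpha = sim$alpha, dt_s = sim$dt_s,
      max_principal_stress_Pa = post$summary$max_principal_stress_Pa,
      wss_mean_Pa = post$summary$wss_mean_Pa)),
    refinement = if (!is.null(refinement)) {
      list(n_refinements = max(refinement$trace$refinement),
           final_n_nodes = utils::tail(refinement$trace$n_nodes, 1),
           final_l2_change = utils::tail(refinement$trace$l2_change, 1))
    },
    comparison = if (!is.null(comparison)) {
      as.list(glance(comparison))
    }
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("tebvflow")),
    r_version = R.version.string,
    seed = seed,
    synthetic_inputs = synthetic,
    config = unclass(config),
    input_digests = vapply(unlist(inputs), function(p) {
      unname(tools::md5sum(p))
    }, character(1)),
    cycles_run = sim$cycles_run
  )
  out <- structure(list(moduli = moduli, fits = fits, fluid_fit = fluid_fit,
                        simulation = sim, postprocess = post,
                        refinement = refinement, comparison = comparison,
                        report = report, manifest = manifest),
                   class = "tebv_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_csv(tidy(sim), file.path(out_dir, "fields.csv"))
  }
  out
}

#' @export
print.tebv_pipeline <- function(x, ...) {
  print(x$moduli)
  cat(sprintf("Fluid: K = %.4g cP, n = %.4g\n", x$fluid_fit$K_cP,
              x$fluid_fit$n))
  print(x$simulation)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
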