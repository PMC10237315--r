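# shared fixtures: study-condition objects and a fast solver configuration
default_vessel <- function(...) build_vessel(...)

default_fluid <- function() power_law_fluid(11.885, -0.2188)

newtonian_fluid <- function(mu_cP = 1) {
  # n = 0: constant viscosity, m = 1
  power_law_fluid(K_cP = mu_cP, n = 0)
}

fast_settings <- function(...) {
  solver_settings(n_nodes = 17, dt_s = 0.01, ...)
}

# noise-free stress-stretch curve on sigma = E * (lambda - 1), sigma in Pa
linear_curve <- function(E_kPa, n = 20, strain_max = 0.3, sample_id = "s1") {
  strain <- seq(0, strain_max, length.out = n)
  tibble::tibble(sample_id = sample_id, stretch = 1 + strain,
                 stress_Pa = E_kPa * 1e3 * strain)
}
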