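#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

# unit conversions (SI internally: Pa, m, s; reporting in kPa, mm, uL/min)
MM <- 1e-3 # m per mm
CP <- 1e-3 # Pa s per cP
UL_MIN <- 1e-9 / 60 # m^3/s per uL/min

q_si_to_ul_min <- function(q) q / UL_MIN
q_ul_min_to_si <- function(q) q * UL_MIN

stopf <- function(class, fmt, ...) {
  abort(sprintf(fmt, ...), class = c(class, "tebvflow_error"))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("tebv_dimension_error", "`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) {
    stopf("tebv_dimension_error", "`%s` must be > 0 (got %g)", name, x)
  }
  if (nonneg && x < 0) {
    stopf("tebv_dimension_error", "`%s` must be >= 0 (got %g)", name, x)
  }
  invisible(x)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stopf("tebv_validation_error", "%s is missing required column(s): %s",
          what, paste(missing, collapse = ", "))
  }
  invisible(df)
}
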