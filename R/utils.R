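# Internal helpers shared across modules.

# Evaluate `code` under a fixed, named RNG (Mersenne-Twister / Inversion),
# restoring the caller's RNG state afterwards so generators never perturb
# the global random stream.
with_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0) {
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Multiplicative lognormal residual error with median 1 (log-sd sigma).
lognormal_noise <- function(n, sigma) {
  if (sigma < 0) stop("noise sd `sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) rep(1, n) else exp(stats::rnorm(n, mean = 0, sd = sigma))
}

# Check a scalar is a single finite number, optionally within (lo, hi].
assert_scalar <- function(x, name, lo = -Inf, hi = Inf, lo_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  bad_lo <- if (lo_open) x <= lo else x < lo
  if (bad_lo || x > hi) {
    stop(sprintf("`%s` = %g is outside the allowed range %s%g, %g]",
                 name, x, if (lo_open) "(" else "[", lo, hi), call. = FALSE)
  }
  invisible(x)
}

#' Convert a per-animal flow or clearance to per-kilogram-per-hour units
#'
#' Physiological flows are often reported per animal per minute (e.g. a
#' hepatic blood flow of 14.5 mL/min for a 250 g rat); pharmacokinetic
#' parameters are conventionally expressed per kilogram body weight per hour.
#'
#' @param x_ml_per_min Flow or clearance in mL/min for the whole animal.
#' @param body_weight_kg Body weight in kg (default 0.25, a standard rat).
#' @return Numeric value in mL/h/kg.
#' @examples
#' flow_per_kg(14.5, 0.25)  # 3480 mL/h/kg hepatic blood flow
#' @export
flow_per_kg <- function(x_ml_per_min, body_weight_kg = 0.25) {
  assert_scalar(x_ml_per_min, "x_ml_per_min", lo = 0)
  assert_scalar(body_weight_kg, "body_weight_kg", lo = 0, lo_open = TRUE)
  x_ml_per_min * 60 / body_weight_kg
}

#' Convert a per-kilogram clearance back to a per-animal value in mL/min
#'
#' @param x_ml_per_h_per_kg Clearance in mL/h/kg.
#' @param body_weight_kg Body weight in kg.
#' @return Numeric value in mL/min for the whole animal.
#' @export
flow_per_animal <- function(x_ml_per_h_per_kg, body_weight_kg = 0.25) {
  x_ml_per_h_per_kg * body_weight_kg / 60
}

# Path to a file shipped under inst/extdata.
ratpbpk_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ratpbpk")
  if (!nzchar(path)) stop("shipped data file not found: ", file, call. = FALSE)
  path
}
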