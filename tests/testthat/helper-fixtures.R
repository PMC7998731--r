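# Shared fixtures and independent oracles for the test suite.

# Standard rat blood-sampling design (IV includes the 5-min sample).
IV_TIMES <- c(0.083, 0.25, 0.5, 1, 3, 7, 10, 24)
PO_TIMES <- c(0.25, 0.5, 1, 3, 7, 10, 24)

# Independent trapezoid oracle (kept separate from the package internals).
oracle_trapz <- function(t, c) sum(diff(t) * (head(c, -1) + tail(c, -1)) / 2)

# Independent brute-force terminal-slope oracle: enumerate every contiguous
# terminal subset of >= 3 points after the peak, pick max adjusted R^2,
# ties (1e-4) to the larger subset.
oracle_lambda_z <- function(times, conc) {
  tmax_idx <- which.max(conc)
  t <- times[seq_along(times) > tmax_idx]
  c <- conc[seq_along(conc) > tmax_idx]
  m <- length(t)
  best <- NULL
  for (k in 3:m) {
    idx <- (m - k + 1):m
    fit <- lm(log(c[idx]) ~ t[idx])
    slope <- unname(coef(fit)[2])
    if (!is.finite(slope) || slope >= 0) next
    r2 <- summary(fit)$r.squared
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj + 1e-4 ||
        (adj >= best$adj - 1e-4 && k > best$k)) {
      best <- list(lambda = -slope, adj = adj, k = k)
    }
  }
  best
}

make_profile <- function(times, conc, route = "iv", dose = 1,
                         subject = "s1", tissue = "plasma") {
  conc_profile(subject, tissue, route, dose, times, conc)
}

# Write a long-format profile CSV for io tests.
write_profile_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

supinoxin_yaml <- function(drop = NULL, extra = list()) {
  cfg <- list(compound = "supinoxin", molecular_weight = 441.465, logP = 2.7,
              pKa = 1.5, compound_type = "monoprotic acid", fu_plasma = 0.0363,
              fu_mic = 0.623)
  cfg[drop] <- NULL
  cfg <- modifyList(cfg, extra)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  path
}
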