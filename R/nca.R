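# Noncompartmental analysis: linear-trapezoid moments, terminal-slope
# estimation, and the derived parameter set (CL, MRT, Vss, F).

# Linear-trapezoid AUC plus the exact first moment of the piecewise-linear
# concentration curve (integrating t*C(t) with C linear on each segment,
# rather than trapezoiding the t*C ordinates, which degrades to zero on
# segments whose endpoints both have t*C = 0).
.trapz_moments <- function(times, conc) {
  n <- length(times)
  t1 <- times[-n]; t2 <- times[-1]
  c1 <- conc[-n]; c2 <- conc[-1]
  dt <- t2 - t1
  auc <- sum(dt * (c1 + c2) / 2)
  aumc <- sum(dt / 6 * (t1 * (2 * c1 + c2) + t2 * (c1 + 2 * c2)))
  list(auc = auc, aumc = aumc)
}

# R-squared without summary.lm (which warns on exact fits).
.r_squared <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum(stats::resid(fit)^2) / ss_tot
}

#' Area under the concentration-time curve by the linear trapezoidal rule
#'
#' Integrates a profile's concentration (AUC) and first-moment (AUMC)
#' ordinates over adjacent non-missing samples. Below-LOQ points (`NA`) are
#' excluded, not imputed. With a numeric `upper` lying between samples the
#' concentration at the cut point is obtained by linear interpolation.
#'
#' @param profile A [conc_profile()].
#' @param upper `"last"` (default) to integrate to the last quantifiable
#'   sample, or a numeric time t* within the sampled range.
#' @return A list with `auc` (ug.h/mL), `aumc` (ug.h^2/mL), `tlast`, `clast`.
#' @examples
#' p <- conc_profile("s1", "plasma", "iv", 1, times = c(0, 1), conc = c(1, 1))
#' auc_trapz(p)$auc  # 1: unit rectangle
#' @export
auc_trapz <- function(profile, upper = "last") {
  stopifnot(inherits(profile, "conc_profile"))
  keep <- !is.na(profile$conc)
  times <- profile$times[keep]
  conc <- profile$conc[keep]
  if (length(times) < 2L) stop("need >= 2 non-missing points", call. = FALSE)
  if (!identical(upper, "last")) {
    tstar <- upper
    assert_scalar(tstar, "upper")
    if (tstar < times[1]) {
      stop("`upper` lies before the first quantifiable sample", call. = FALSE)
    }
    if (tstar > times[length(times)]) {
      stop("`upper` lies beyond the last quantifiable sample", call. = FALSE)
    }
    cstar <- stats::approx(times, conc, xout = tstar)$y
    keep2 <- times < tstar
    times <- c(times[keep2], tstar)
    conc <- c(conc[keep2], cstar)
    if (length(times) < 2L) stop("need >= 2 points below `upper`", call. = FALSE)
  }
  m <- .trapz_moments(times, conc)
  list(auc = m$auc, aumc = m$aumc,
       tlast = times[length(times)], clast = conc[length(conc)])
}

#' Terminal log-linear slope (lambda-z) and half-life
#'
#' Fits ordinary least squares to log-concentration versus time over a
#' terminal point set. Under `selection = "best_fit"` all candidate sets of
#' the last k points strictly after Tmax (k = 3 ... all) are fitted and the
#' one maximizing adjusted R-squared wins; sets within 1e-4 of the best are
#' tied and the tie goes to the larger set. The half-life is `0.693 /
#' lambda_z`, matching the conventional reporting identity. A non-negative
#' terminal slope is a flagged failure (`ok = FALSE`), leaving the
#' extrapolated quantities undefined downstream.
#'
#' @param profile A [conc_profile()].
#' @param selection `"best_fit"` (default) or `"fixed"`.
#' @param n_points Number of terminal points when `selection = "fixed"`.
#' @return A list: `lambda_z` (1/h), `t_half` (h), `adj_r2`, `n_points`,
#'   `intercept` (log scale), `ok`.
#' @export
fit_lambda_z <- function(profile, selection = c("best_fit", "fixed"), n_points = 3L) {
  stopifnot(inherits(profile, "conc_profile"))
  selection <- match.arg(selection)
  keep <- !is.na(profile$conc) & profile$conc > 0
  times <- profile$times[keep]
  conc <- profile$conc[keep]
  tmax_idx <- which.max(conc)
  post <- seq_along(times) > tmax_idx
  if (sum(post) < 3L) {
    stop("need >= 3 positive concentrations after Tmax for lambda-z", call. = FALSE)
  }
  t_post <- times[post]
  c_post <- conc[post]
  m <- length(t_post)
  fit_one <- function(k) {
    idx <- (m - k + 1L):m
    x <- t_post[idx]
    y <- log(c_post[idx])
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    r2 <- .r_squared(fit, y)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    list(slope = slope, adj_r2 = adj, k = k,
         intercept = unname(stats::coef(fit)[1]))
  }
  cand <- if (selection == "fixed") {
    if (n_points < 3L || n_points > m) stop("invalid `n_points`", call. = FALSE)
    list(fit_one(as.integer(n_points)))
  } else {
    lapply(3:m, fit_one)
  }
  cand <- Filter(function(f) is.finite(f$slope) && f$slope < 0, cand)
  if (length(cand) == 0L) {
    return(list(lambda_z = NA_real_, t_half = NA_real_, adj_r2 = NA_real_,
                n_points = NA_integer_, intercept = NA_real_, ok = FALSE))
  }
  best_adj <- max(vapply(cand, `[[`, numeric(1), "adj_r2"))
  tied <- Filter(function(f) f$adj_r2 >= best_adj - 1e-4, cand)
  ks <- vapply(tied, `[[`, numeric(1), "k")
  best <- tied[[which.max(ks)]]
  lambda <- -best$slope
  list(lambda_z = lambda, t_half = 0.693 / lambda, adj_r2 = best$adj_r2,
       n_points = best$k, intercept = best$intercept, ok = TRUE)
}

#' Full noncompartmental parameter set for one profile
#'
#' Computes Cmax/Tmax directly from the samples, AUClast/AUMClast by the
#' linear trapezoidal rule, the infinity extensions
#' `AUCinf = AUClast + Clast/lambda_z` and
#' `AUMCinf = AUMClast + Clast*tlast/lambda_z + Clast/lambda_z^2`
#' (observed Clast, not the regression prediction), and the derived
#' parameters `CL = dose/AUCinf`, `MRT = AUMCinf/AUCinf`, `Vss = MRT * CL`
#' (intravenous only). For an oral profile the absolute bioavailability
#' `F = AUCinf_po/AUCinf_iv * dose_iv/dose_po` is filled in when the paired
#' intravenous exposure is supplied. The first trapezoid starts at the first
#' sample; optional log-linear back-extrapolation of C(0) from the first two
#' samples is available for intravenous bolus profiles.
#'
#' @param profile A [conc_profile()].
#' @param lambda_fit Optional result of [fit_lambda_z()]; computed if `NULL`.
#' @param paired_iv_aucinf Optional paired intravenous AUCinf (ug.h/mL) for F.
#' @param paired_iv_dose Dose (mg/kg) of the paired intravenous arm
#'   (defaults to the profile's own dose).
#' @param back_extrapolate If `TRUE` and the route is `"iv"`, prepend a
#'   log-linearly extrapolated C(0) before integration.
#' @return An object of class `nca_result`.
#' @export
nca_summarize <- function(profile, lambda_fit = NULL, paired_iv_aucinf = NULL,
                          paired_iv_dose = NULL, back_extrapolate = FALSE) {
  stopifnot(inherits(profile, "conc_profile"))
  work <- profile
  if (isTRUE(back_extrapolate) && profile$route == "iv" && profile$times[1] > 0) {
    keep <- !is.na(profile$conc) & profile$conc > 0
    t12 <- profile$times[keep][1:2]
    c12 <- profile$conc[keep][1:2]
    slope <- (log(c12[2]) - log(c12[1])) / (t12[2] - t12[1])
    c0 <- exp(log(c12[1]) - slope * t12[1])
    work <- conc_profile(profile$subject, profile$tissue, profile$route,
                         profile$dose, c(0, profile$times), c(c0, profile$conc),
                         loq = profile$loq)
  }
  if (is.null(lambda_fit)) lambda_fit <- fit_lambda_z(work)
  moments <- auc_trapz(work)
  keep <- !is.na(work$conc)
  cmax <- max(work$conc[keep])
  tmax <- work$times[keep][which.max(work$conc[keep])]
  dose_ug_kg <- work$dose * 1000
  auclast <- moments$auc
  aumclast <- moments$aumc
  if (isTRUE(lambda_fit$ok)) {
    lam <- lambda_fit$lambda_z
    aucinf <- auclast + moments$clast / lam
    aumcinf <- aumclast + moments$clast * moments$tlast / lam +
      moments$clast / lam^2
  } else {
    aucinf <- aumcinf <- NA_real_
  }
  is_iv <- work$route == "iv"
  cl <- if (is_iv && is.finite(aucinf)) dose_ug_kg / aucinf else NA_real_
  mrt <- if (is.finite(aucinf)) aumcinf / aucinf else NA_real_
  vss <- if (is_iv && is.finite(mrt)) mrt * cl else NA_real_
  f <- NA_real_
  if (work$route == "po" && !is.null(paired_iv_aucinf) && is.finite(aucinf)) {
    dose_iv <- if (is.null(paired_iv_dose)) work$dose else paired_iv_dose
    f <- (aucinf / paired_iv_aucinf) * (dose_iv / work$dose)
  }
  structure(
    list(subject = work$subject, tissue = work$tissue, route = work$route,
         dose = work$dose, cmax = cmax, tmax = tmax,
         auclast = auclast, aucinf = aucinf,
         aumclast = aumclast, aumcinf = aumcinf,
         lambda_z = if (lambda_fit$ok) lambda_fit$lambda_z else NA_real_,
         t_half = if (lambda_fit$ok) lambda_fit$t_half else NA_real_,
         lambda_z_points = lambda_fit$n_points,
         lambda_z_adj_r2 = lambda_fit$adj_r2,
         cl = cl, mrt = mrt, vss = vss, f = f),
    class = "nca_result"
  )
}

#' Extract a single parameter from an NCA result
#'
#' Errors when a parameter undefined for the route is requested (e.g. `CL`
#' or `Vss` from an oral profile, `F` from an intravenous one).
#'
#' @param result An `nca_result`.
#' @param param Parameter name, e.g. `"cl"`, `"vss"`, `"aucinf"`, `"f"`.
#' @return The numeric value.
#' @export
nca_param <- function(result, param) {
  stopifnot(inherits(result, "nca_result"))
  param <- tolower(param)
  if (!param %in% names(result)) stop("unknown NCA parameter: ", param, call. = FALSE)
  if (param %in% c("cl", "vss") && result$route != "iv") {
    stop(sprintf("'%s' is undefined for route '%s'", param, result$route),
         call. = FALSE)
  }
  if (param == "f" && result$route != "po") {
    stop("'f' is undefined for an intravenous profile", call. = FALSE)
  }
  result[[param]]
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %s %s | %s %g mg/kg\n",
              x$subject, x$tissue, x$route, x$dose))
  fmt <- function(v) if (is.na(v)) "-" else format(signif(v, 4))
  cat("  Cmax", fmt(x$cmax), "ug/mL | Tmax", fmt(x$tmax), "h\n")
  cat("  AUClast", fmt(x$auclast), "| AUCinf", fmt(x$aucinf), "ug.h/mL\n")
  cat("  T1/2", fmt(x$t_half), "h | MRT", fmt(x$mrt), "h\n")
  if (x$route == "iv") {
    cat("  CL", fmt(x$cl), "mL/h/kg | Vss", fmt(x$vss), "mL/kg\n")
  } else {
    cat("  F", fmt(x$f), "\n")
  }
  invisible(x)
}

#' Mean-profile AUC for destructively sampled tissue data
#'
#' Tissue distribution studies sacrifice a few animals per time point, so no
#' animal contributes a full profile. The per-time mean concentration is
#' computed first and the linear trapezoid is applied to the mean profile.
#'
#' @param samples A data frame with columns `time_h` and `conc_ug_per_mL`
#'   (one row per animal per time point; `NA` concentrations are dropped).
#' @param expected_times Optional vector of design times; an expected time
#'   with no animals is an error naming the gap.
#' @return A list with `auc` (ug.h/mL), `mean_profile` (data frame), `n_per_time`.
#' @export
sparse_tissue_auc <- function(samples, expected_times = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("time_h", "conc_ug_per_mL") %in% names(samples)))
  samples <- samples[!is.na(samples$conc_ug_per_mL), , drop = FALSE]
  if (!is.null(expected_times)) {
    gaps <- setdiff(expected_times, unique(samples$time_h))
    if (length(gaps)) {
      stop("no animals at expected time point(s): ",
           paste(gaps, collapse = ", "), " h", call. = FALSE)
    }
  }
  agg <- stats::aggregate(conc_ug_per_mL ~ time_h, data = samples, FUN = mean)
  agg <- agg[order(agg$time_h), , drop = FALSE]
  n <- stats::aggregate(conc_ug_per_mL ~ time_h, data = samples, FUN = length)
  if (nrow(agg) < 2L) {
    stop("need >= 2 distinct time points for a mean-profile AUC", call. = FALSE)
  }
  m <- .trapz_moments(agg$time_h, agg$conc_ug_per_mL)
  list(auc = m$auc, mean_profile = agg,
       n_per_time = stats::setNames(n$conc_ug_per_mL, n$time_h))
}
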