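# In-vitro assay analysis: transwell permeability, equilibrium-dialysis
# binding, microsomal depletion, IVIVE via the well-stirred liver model,
# CYP inhibition IC50, and drug-drug interaction screening indices.

#' Bidirectional transwell transport assay record
#'
#' @param direction `"a2b"` (apical-to-basolateral) or `"b2a"`.
#' @param c0_uM Initial donor concentration, uM (> 0).
#' @param area_cm2 Insert membrane area, cm^2 (> 0).
#' @param times_min Receiver sampling times, min, strictly increasing.
#' @param receiver_conc_nmol_mL Measured receiver concentrations at each
#'   sampling time, nmol/mL.
#' @param receiver_volume_mL Receiver chamber volume, mL.
#' @param donor_volume_mL Donor chamber volume, mL (for the sink check).
#' @param sample_volume_mL Withdrawn-and-replaced aliquot volume, mL.
#' @param dilution_corrected `TRUE` if the concentrations were already
#'   corrected for sampling-replacement dilution.
#' @return An object of class `transport_assay`.
#' @export
transport_assay <- function(direction = c("a2b", "b2a"), c0_uM, area_cm2,
                            times_min, receiver_conc_nmol_mL,
                            receiver_volume_mL, donor_volume_mL,
                            sample_volume_mL = 0.2,
                            dilution_corrected = FALSE) {
  direction <- match.arg(direction)
  assert_scalar(c0_uM, "c0_uM", lo = 0, lo_open = TRUE)
  assert_scalar(area_cm2, "area_cm2", lo = 0, lo_open = TRUE)
  assert_scalar(receiver_volume_mL, "receiver_volume_mL", lo = 0, lo_open = TRUE)
  assert_scalar(donor_volume_mL, "donor_volume_mL", lo = 0, lo_open = TRUE)
  assert_scalar(sample_volume_mL, "sample_volume_mL", lo = 0)
  stopifnot(length(times_min) == length(receiver_conc_nmol_mL))
  if (any(times_min <= 0) || any(diff(times_min) <= 0)) {
    stop("sampling times must be positive and strictly increasing", call. = FALSE)
  }
  if (any(receiver_conc_nmol_mL < 0)) stop("negative receiver concentration", call. = FALSE)
  structure(
    list(direction = direction, c0_uM = c0_uM, area_cm2 = area_cm2,
         times_min = as.numeric(times_min),
         receiver_conc_nmol_mL = as.numeric(receiver_conc_nmol_mL),
         receiver_volume_mL = receiver_volume_mL,
         donor_volume_mL = donor_volume_mL,
         sample_volume_mL = sample_volume_mL,
         dilution_corrected = isTRUE(dilution_corrected)),
    class = "transport_assay"
  )
}

# Serial-dilution bookkeeping: each withdrawn aliquot of volume v is replaced
# with blank buffer, so the cumulative transported amount at sample i is
# C_i * V_r + sum_{j<i} C_j * v.
dilution_correct_amounts <- function(conc, receiver_volume, sample_volume) {
  removed <- c(0, cumsum(conc * sample_volume)[-length(conc)])
  conc * receiver_volume + removed
}

#' Apparent permeability coefficient from a transwell assay
#'
#' `Papp = (dQ/dt) / (A * C0)`: the transport rate dQ/dt is the least-squares
#' slope (intercept estimated) of the cumulative transported amount versus
#' time, after correcting the measured receiver concentrations for
#' sampling-replacement dilution. The sink condition is checked: if the
#' cumulative transported amount exceeds 10% of the initial donor amount a
#' warning is issued, since the linear-accumulation assumption degrades.
#'
#' @param assay A [transport_assay()].
#' @return A list: `papp_cm_s`, `slope_nmol_min`, `r2`, `sink_ok`, `ok`
#'   (`FALSE` flags a non-positive slope).
#' @export
papp <- function(assay) {
  stopifnot(inherits(assay, "transport_assay"))
  if (length(assay$times_min) < 2L) stop("need >= 2 time points", call. = FALSE)
  q <- if (assay$dilution_corrected) {
    assay$receiver_conc_nmol_mL * assay$receiver_volume_mL
  } else {
    dilution_correct_amounts(assay$receiver_conc_nmol_mL,
                             assay$receiver_volume_mL, assay$sample_volume_mL)
  }
  donor_amount <- assay$c0_uM * assay$donor_volume_mL  # nmol (uM == nmol/mL)
  sink_ok <- max(q) <= 0.1 * donor_amount
  if (!sink_ok) {
    warning("sink condition violated: >10% of donor amount transported",
            call. = FALSE)
  }
  if (all(q == 0)) {
    return(list(papp_cm_s = 0, slope_nmol_min = 0, r2 = 1,
                sink_ok = TRUE, ok = TRUE))
  }
  fit <- stats::lm(q ~ assay$times_min)
  slope <- unname(stats::coef(fit)[2])  # nmol/min
  r2 <- .r_squared(fit, q)
  ok <- is.finite(slope) && slope > 0
  if (!ok) warning("non-positive transport slope; Papp flagged as failed", call. = FALSE)
  papp_val <- slope / 60 / (assay$area_cm2 * assay$c0_uM)  # cm/s (uM = nmol/cm^3)
  list(papp_cm_s = if (ok) papp_val else NA_real_, slope_nmol_min = slope,
       r2 = r2, sink_ok = sink_ok, ok = ok)
}

#' Efflux ratio of basolateral-to-apical over apical-to-basolateral Papp
#'
#' @param papp_b2a Papp in the secretory (b->a) direction, cm/s.
#' @param papp_a2b Papp in the absorptive (a->b) direction, cm/s.
#' @return The dimensionless efflux ratio.
#' @export
efflux_ratio <- function(papp_b2a, papp_a2b) {
  assert_scalar(papp_b2a, "papp_b2a", lo = 0, lo_open = TRUE)
  assert_scalar(papp_a2b, "papp_a2b", lo = 0, lo_open = TRUE)
  papp_b2a / papp_a2b
}

#' Paired buffer/plasma (or buffer/microsome) dialysis time course
#'
#' @param times_h Sampling times, h.
#' @param buffer Buffer-chamber concentrations.
#' @param matrix_conc Matrix (plasma or microsomal mixture) concentrations,
#'   same units as `buffer`.
#' @return An object of class `binding_timecourse`.
#' @export
binding_timecourse <- function(times_h, buffer, matrix_conc) {
  stopifnot(length(times_h) == length(buffer),
            length(buffer) == length(matrix_conc))
  if (any(diff(times_h) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(buffer < 0) || any(matrix_conc < 0)) stop("negative concentration", call. = FALSE)
  structure(list(times_h = as.numeric(times_h), buffer = as.numeric(buffer),
                 matrix_conc = as.numeric(matrix_conc)),
            class = "binding_timecourse")
}

#' Unbound fraction from an equilibrium-dialysis time course
#'
#' The instantaneous unbound fraction is the buffer/matrix concentration
#' ratio; equilibrium is declared at the first time whose ratio changed by
#' less than `equilibrium_tol` (relative) from the preceding sample, and the
#' reported fu is the mean ratio over the equilibrated tail. Percent bound is
#' `(1 - fu) * 100`. If the trajectory never satisfies the tolerance (or the
#' ratio is stuck at zero, as with an unequilibrated device) the result is a
#' flagged failure carrying the full trajectory.
#'
#' @param tc A [binding_timecourse()].
#' @param equilibrium_tol Relative-change tolerance between consecutive
#'   samples (default 0.05).
#' @return A list: `fu`, `percent_bound`, `equilibrium_time_h`, `ratio`
#'   (per-time trajectory), `equilibrated`.
#' @export
fraction_unbound <- function(tc, equilibrium_tol = 0.05) {
  stopifnot(inherits(tc, "binding_timecourse"))
  if (length(tc$times_h) < 2L) stop("need >= 2 time points", call. = FALSE)
  ratio <- tc$buffer / tc$matrix_conc
  eq_idx <- NA_integer_
  for (i in 2:length(ratio)) {
    if (is.finite(ratio[i - 1]) && ratio[i - 1] > 0 &&
        abs(ratio[i] - ratio[i - 1]) / ratio[i - 1] < equilibrium_tol) {
      eq_idx <- i
      break
    }
  }
  if (is.na(eq_idx)) {
    return(list(fu = NA_real_, percent_bound = NA_real_,
                equilibrium_time_h = NA_real_, ratio = ratio,
                equilibrated = FALSE))
  }
  fu <- mean(ratio[eq_idx:length(ratio)])
  list(fu = fu, percent_bound = (1 - fu) * 100,
       equilibrium_time_h = tc$times_h[eq_idx], ratio = ratio,
       equilibrated = TRUE)
}

#' Microsomal substrate-depletion assay record
#'
#' @param times_min Incubation sampling times, min (>= 0).
#' @param remaining_pct Percent of initial substrate remaining at each time.
#' @param c_protein_mg_mL Microsomal protein concentration in the incubation,
#'   mg/mL (default 0.5).
#' @param fu_mic Unbound fraction in the incubation, (0, 1].
#' @param a_protein_mg_kg Scaling factor: liver microsomal protein per kg body
#'   weight, mg/kg (default 1790, rat).
#' @return An object of class `depletion_assay`.
#' @export
depletion_assay <- function(times_min, remaining_pct, c_protein_mg_mL = 0.5,
                            fu_mic = 1, a_protein_mg_kg = 1790) {
  stopifnot(length(times_min) == length(remaining_pct))
  if (any(times_min < 0)) stop("negative incubation time", call. = FALSE)
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  assert_scalar(c_protein_mg_mL, "c_protein_mg_mL", lo = 0, lo_open = TRUE)
  assert_scalar(fu_mic, "fu_mic", lo = 0, hi = 1, lo_open = TRUE)
  assert_scalar(a_protein_mg_kg, "a_protein_mg_kg", lo = 0, lo_open = TRUE)
  structure(list(times_min = as.numeric(times_min),
                 remaining_pct = as.numeric(remaining_pct),
                 c_protein_mg_mL = c_protein_mg_mL, fu_mic = fu_mic,
                 a_protein_mg_kg = a_protein_mg_kg),
            class = "depletion_assay")
}

#' First-order depletion rate constant from a substrate-depletion time course
#'
#' Log-linear regression of the percent remaining against incubation time;
#' `ke` is minus the slope and the in-vitro half-life is `ln 2 / ke`. A
#' non-negative slope is reported as metabolic stability (`ke = 0`,
#' `stable = TRUE`).
#'
#' @param assay A [depletion_assay()].
#' @return A list: `ke_per_min`, `t_half_min`, `stable`, `r2`.
#' @export
depletion_rate <- function(assay) {
  stopifnot(inherits(assay, "depletion_assay"))
  keep <- assay$remaining_pct > 0
  if (sum(keep) < 3L) stop("need >= 3 positive remaining fractions", call. = FALSE)
  x <- assay$times_min[keep]
  y <- log(assay$remaining_pct[keep])
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- .r_squared(fit, y)
  # a slope indistinguishable from zero is metabolic stability, not decay
  if (!is.finite(slope) || slope >= -1e-12) {
    return(list(ke_per_min = 0, t_half_min = Inf, stable = TRUE, r2 = r2))
  }
  ke <- -slope
  list(ke_per_min = ke, t_half_min = log(2) / ke, stable = FALSE, r2 = r2)
}

#' Intrinsic clearance scaled from a microsomal depletion rate constant
#'
#' `CLint = A_protein * ke / (fu_mic * C_protein)`, where `A_protein` is the
#' total liver microsomal protein per kg body weight, `ke` the depletion rate
#' constant, `fu_mic` the unbound fraction in the incubation, and `C_protein`
#' the incubation protein concentration. Valid below the Km of the reaction.
#'
#' @param ke_per_min Depletion rate constant, 1/min (>= 0).
#' @param a_protein_mg_kg Scaling factor, mg protein/kg (default 1790, rat).
#' @param fu_mic Unbound fraction in the incubation (0, 1].
#' @param c_protein_mg_mL Incubation protein concentration, mg/mL.
#' @return A list: `clint_mL_min_kg` and `clint_L_h_kg`.
#' @examples
#' clint(log(2) / 17.1, fu_mic = 0.623)$clint_L_h_kg  # ~14.0
#' @export
clint <- function(ke_per_min, a_protein_mg_kg = 1790, fu_mic = 1,
                  c_protein_mg_mL = 0.5) {
  assert_scalar(ke_per_min, "ke_per_min", lo = 0)
  assert_scalar(a_protein_mg_kg, "a_protein_mg_kg", lo = 0, lo_open = TRUE)
  assert_scalar(fu_mic, "fu_mic", lo = 0, hi = 1, lo_open = TRUE)
  assert_scalar(c_protein_mg_mL, "c_protein_mg_mL", lo = 0, lo_open = TRUE)
  cl_ml_min_kg <- a_protein_mg_kg * ke_per_min / (fu_mic * c_protein_mg_mL)
  list(clint_mL_min_kg = cl_ml_min_kg, clint_L_h_kg = cl_ml_min_kg * 60 / 1000)
}

#' Hepatic clearance by the well-stirred liver model
#'
#' `CLh = Q * CLint * fu / (Q + CLint * fu / R)`, with hepatic blood flow Q,
#' unbound intrinsic clearance scaled by the plasma unbound fraction fu, and
#' blood-to-plasma ratio R. Also returns the hepatic extraction ratio
#' `E = CLh / (Q * R)` and hepatic availability `Fh = 1 - E`. CLh is bounded
#' above by the flow limit `Q * R`.
#'
#' @param q_mL_h_kg Hepatic blood flow, mL/h/kg (> 0); see [flow_per_kg()].
#' @param clint_mL_h_kg Intrinsic clearance, mL/h/kg (>= 0).
#' @param fu_p Plasma unbound fraction (0, 1].
#' @param r_bp Blood-to-plasma concentration ratio (> 0, default 1).
#' @return A list: `clh_mL_h_kg`, `extraction`, `fh`.
#' @export
well_stirred_clh <- function(q_mL_h_kg, clint_mL_h_kg, fu_p, r_bp = 1) {
  assert_scalar(q_mL_h_kg, "q_mL_h_kg", lo = 0, lo_open = TRUE)
  assert_scalar(clint_mL_h_kg, "clint_mL_h_kg", lo = 0)
  assert_scalar(fu_p, "fu_p", lo = 0, hi = 1, lo_open = TRUE)
  assert_scalar(r_bp, "r_bp", lo = 0, lo_open = TRUE)
  clh <- q_mL_h_kg * clint_mL_h_kg * fu_p /
    (q_mL_h_kg + clint_mL_h_kg * fu_p / r_bp)
  e <- clh / (q_mL_h_kg * r_bp)
  list(clh_mL_h_kg = clh, extraction = e, fh = 1 - e)
}

#' Fit an IC50 to a concentration-dependent CYP inhibition curve
#'
#' Least-squares fit of `inhibition% = 100 * c^h / (c^h + IC50^h)`. Because
#' the measurement error of such assays scales with the remaining activity
#' (the fluorescence signal), the residuals are weighted by the inverse
#' squared observed activity `1/(1 - inh/100)^2` (floored at 0.02), i.e.
#' strongly inhibited wells count as the precise observations they are. The
#' Hill slope is fixed at 1 by default or co-estimated with
#' `hill = "fitted"`.
#' When the maximal observed inhibition never reaches 50% the IC50 cannot be
#' located inside the tested range: the result is censored and reported as a
#' lower bound at the highest tested concentration rather than a point
#' estimate.
#'
#' @param concentrations_uM Tested inhibitor concentrations, uM (>= 3 values).
#' @param inhibition_pct Percent inhibition at each concentration.
#' @param hill `"fixed"` (slope 1) or `"fitted"`.
#' @return A list: `ic50_uM` (NA when censored), `hill`, `censored`,
#'   `ic50_lower_bound_uM`, `converged`.
#' @export
ic50_fit <- function(concentrations_uM, inhibition_pct, hill = c("fixed", "fitted")) {
  hill <- match.arg(hill)
  stopifnot(length(concentrations_uM) == length(inhibition_pct))
  if (length(concentrations_uM) < 3L) stop("need >= 3 concentrations", call. = FALSE)
  if (any(concentrations_uM <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (any(inhibition_pct < -10 | inhibition_pct > 110)) {
    stop("inhibition outside the plausible [-10, 110]% window", call. = FALSE)
  }
  if (max(inhibition_pct) < 50) {
    return(list(ic50_uM = NA_real_, hill = NA_real_, censored = TRUE,
                ic50_lower_bound_uM = max(concentrations_uM), converged = TRUE))
  }
  if (any(diff(inhibition_pct[order(concentrations_uM)]) < -15)) {
    warning("grossly non-monotone inhibition data; fit may be unreliable",
            call. = FALSE)
  }
  df <- data.frame(conc = concentrations_uM, inh = inhibition_pct)
  df$w <- 1 / pmax(1 - df$inh / 100, 0.02)^2
  # interpolate the 50% crossing for a starting value
  ord <- order(df$conc)
  start_ic50 <- stats::approx(df$inh[ord], df$conc[ord], xout = 50,
                              ties = "ordered")$y
  if (!is.finite(start_ic50)) start_ic50 <- stats::median(df$conc)
  fit <- if (hill == "fixed") {
    minpack.lm::nlsLM(inh ~ 100 * conc / (conc + ic50), data = df,
                      start = list(ic50 = start_ic50), weights = df$w,
                      lower = c(ic50 = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(inh ~ 100 * conc^h / (conc^h + ic50^h), data = df,
                      start = list(ic50 = start_ic50, h = 1), weights = df$w,
                      lower = c(ic50 = 1e-9, h = 0.1),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  est <- stats::coef(fit)
  list(ic50_uM = unname(est["ic50"]),
       hill = if (hill == "fixed") 1 else unname(est["h"]),
       censored = FALSE, ic50_lower_bound_uM = NA_real_, converged = TRUE)
}

#' Drug-drug interaction screening indices for a CYP inhibitor
#'
#' Systemic index: the maximal unbound plasma concentration
#' `Imax,u = Cmax_total * fu_p` divided by Ki. Gut index: the theoretical
#' maximal gastrointestinal concentration `Igut = (dose / 250 mL) / MW`
#' (in uM) divided by Ki. Flags compare against the conventional screening
#' thresholds of 0.02 (systemic) and 10 (gut).
#'
#' @param cmax_total_uM Total (bound + unbound) maximal plasma concentration, uM.
#' @param fu_p Plasma unbound fraction (0, 1].
#' @param dose_mg Oral dose, mg.
#' @param mw_g_mol Molecular weight, g/mol.
#' @param ki_uM Inhibition constant, uM (commonly taken equal to the IC50
#'   for a screening-level assessment).
#' @return A list: `imax_u_uM`, `igut_uM`, `imax_u_over_ki`, `igut_over_ki`,
#'   `systemic_flag`, `gut_flag`.
#' @export
ddi_indices <- function(cmax_total_uM, fu_p, dose_mg, mw_g_mol, ki_uM) {
  assert_scalar(cmax_total_uM, "cmax_total_uM", lo = 0)
  assert_scalar(fu_p, "fu_p", lo = 0, hi = 1, lo_open = TRUE)
  assert_scalar(dose_mg, "dose_mg", lo = 0)
  assert_scalar(mw_g_mol, "mw_g_mol", lo = 0, lo_open = TRUE)
  assert_scalar(ki_uM, "ki_uM", lo = 0, lo_open = TRUE)
  imax_u <- cmax_total_uM * fu_p
  igut_uM <- dose_mg / mw_g_mol / 0.25 * 1000  # mmol / 0.25 L -> mM -> uM
  list(imax_u_uM = imax_u, igut_uM = igut_uM,
       imax_u_over_ki = imax_u / ki_uM, igut_over_ki = igut_uM / ki_uM,
       systemic_flag = imax_u / ki_uM > 0.02, gut_flag = igut_uM / ki_uM > 10)
}
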