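# Synthetic-data generators. Every input the pipeline consumes can be
# produced here from known ground-truth parameters, so each analysis stage
# is testable by parameter recovery without any external data. All residual
# error is multiplicative lognormal with median 1 (PK concentrations are
# positive and right-skewed); sigma = 0 yields the noise-free model exactly.

# Closed-form disposition models.
.one_cpt_iv <- function(t, dose_ug_kg, cl, v) {
  (dose_ug_kg / v) * exp(-(cl / v) * t)
}

.one_cpt_po <- function(t, dose_ug_kg, cl, v, ka, f) {
  ke <- cl / v
  if (abs(ka - ke) < 1e-12) {
    f * dose_ug_kg / v * ka * t * exp(-ka * t)
  } else {
    f * dose_ug_kg * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
  }
}

#' Generate disposition (concentration-time) profiles from known truth
#'
#' The generating model is either a one-compartment disposition
#' (`truth = list(cl_mL_h_kg=, v_mL_kg=, ka_per_h=, f=)`, the latter two
#' only for oral dosing) or a full PBPK specification
#' (`truth = list(pbpk_spec = <pbpk_model_spec>)`), evaluated on the sampling
#' design and multiplied per point by lognormal noise.
#'
#' @param truth Named list of true parameters (see above).
#' @param times_h Sampling times, h, strictly increasing and positive.
#' @param dose_mg_kg Dose, mg/kg.
#' @param route `"iv"` or `"po"`.
#' @param n_subjects Number of subjects (default 1).
#' @param sigma Lognormal residual log-sd (default 0.15; 0 = noise-free).
#' @param seed RNG seed.
#' @param tissue Tissue label stamped on the profiles (default `"plasma"`).
#' @return A list: `profiles` (list of [conc_profile()]), `truth` (the
#'   generating parameters, noise model and seed).
#' @export
gen_disposition_profiles <- function(truth, times_h, dose_mg_kg,
                                     route = c("iv", "po"), n_subjects = 1L,
                                     sigma = 0.15, seed = 0L,
                                     tissue = "plasma") {
  route <- match.arg(route)
  if (any(times_h <= 0) || any(diff(times_h) <= 0)) {
    stop("sampling times must be positive and strictly increasing", call. = FALSE)
  }
  if (n_subjects < 1L) stop("need n_subjects >= 1", call. = FALSE)
  if (sigma < 0) stop("noise sd `sigma` must be >= 0", call. = FALSE)
  dose_ug_kg <- dose_mg_kg * 1000
  pred <- if (!is.null(truth$pbpk_spec)) {
    spec <- truth$pbpk_spec
    grid_times <- if (times_h[1] > 0) c(0, times_h) else times_h
    sim <- pbpk_simulate(spec, times = grid_times, dose_mg_kg = dose_mg_kg,
                         route = route)
    sim$plasma[match(times_h, sim$time)]
  } else {
    cl <- truth$cl_mL_h_kg; v <- truth$v_mL_kg
    if (is.null(cl) || is.null(v)) {
      stop("one-compartment truth needs `cl_mL_h_kg` and `v_mL_kg`", call. = FALSE)
    }
    if (route == "iv") {
      .one_cpt_iv(times_h, dose_ug_kg, cl, v)
    } else {
      if (is.null(truth$ka_per_h) || is.null(truth$f)) {
        stop("oral one-compartment truth needs `ka_per_h` and `f`", call. = FALSE)
      }
      .one_cpt_po(times_h, dose_ug_kg, cl, v, truth$ka_per_h, truth$f)
    }
  }
  profiles <- with_rng(seed, {
    lapply(seq_len(n_subjects), function(i) {
      conc <- pred * lognormal_noise(length(pred), sigma)
      conc_profile(subject = sprintf("sim%03d", i), tissue = tissue,
                   route = route, dose = dose_mg_kg,
                   times = times_h, conc = conc)
    })
  })
  list(profiles = profiles,
       truth = c(truth, list(noise = "lognormal", sigma = sigma, seed = seed)))
}

#' Generate a microsomal substrate-depletion time course
#'
#' `remaining(t) = 100 * exp(-ke * t)`, times noise.
#'
#' @param ke_per_min True first-order depletion rate constant, 1/min (>= 0).
#' @param times_min Sampling times, min (default the 5/15/30/60 min design).
#' @param sigma Lognormal residual log-sd (default 0).
#' @param seed RNG seed.
#' @param ... Assay constants passed to [depletion_assay()]
#'   (`c_protein_mg_mL`, `fu_mic`, `a_protein_mg_kg`).
#' @return A [depletion_assay()].
#' @export
gen_depletion_assay <- function(ke_per_min, times_min = c(5, 15, 30, 60),
                                sigma = 0, seed = 0L, ...) {
  assert_scalar(ke_per_min, "ke_per_min", lo = 0)
  if (any(times_min < 0)) stop("negative incubation time", call. = FALSE)
  remaining <- with_rng(seed, {
    100 * exp(-ke_per_min * times_min) * lognormal_noise(length(times_min), sigma)
  })
  depletion_assay(times_min = times_min, remaining_pct = remaining, ...)
}

#' Generate a bidirectional transwell transport assay
#'
#' The true cumulative transported amount is the sink-condition line
#' `Q(t) = Papp * A * C0 * t`; the generated record is the *measured*
#' receiver concentration series, i.e. the sampling-replacement dilution
#' (each withdrawn aliquot replaced with blank buffer) is applied to the
#' truth, so [papp()] must undo it. Warns when the generated transport
#' exceeds 10% of the donor amount (sink assumption broken by construction).
#'
#' @param papp_cm_s Named numeric of true permeabilities, e.g.
#'   `c(a2b = 18.5e-6, b2a = 22.6e-6)` (cm/s); a single unnamed value
#'   generates `a2b` only.
#' @param c0_uM Donor concentration, uM.
#' @param area_cm2 Membrane area, cm^2.
#' @param receiver_volume_mL,donor_volume_mL,sample_volume_mL Chamber
#'   geometry, mL.
#' @param times_min Sampling times, min.
#' @param sigma Lognormal residual log-sd on the cumulative amounts.
#' @param seed RNG seed.
#' @return A named list of [transport_assay()] objects, one per direction.
#' @export
gen_transport_assay <- function(papp_cm_s, c0_uM = 1, area_cm2 = 1.12,
                                receiver_volume_mL = 1.5,
                                donor_volume_mL = 0.5,
                                sample_volume_mL = 0.2,
                                times_min = c(30, 60, 90, 120),
                                sigma = 0, seed = 0L) {
  if (is.null(names(papp_cm_s))) names(papp_cm_s) <- "a2b"
  if (any(papp_cm_s < 0)) stop("negative permeability", call. = FALSE)
  with_rng(seed, {
    out <- lapply(names(papp_cm_s), function(dir) {
      q_true <- papp_cm_s[[dir]] * area_cm2 * c0_uM * times_min * 60  # nmol
      q_noisy <- q_true * lognormal_noise(length(q_true), sigma)
      if (max(q_noisy) > 0.1 * c0_uM * donor_volume_mL) {
        warning("generated transport exceeds 10% of donor amount (sink broken)",
                call. = FALSE)
      }
      # forward sampling-replacement bookkeeping: measured concentrations
      conc <- numeric(length(q_noisy))
      removed <- 0
      for (i in seq_along(q_noisy)) {
        present <- q_noisy[i] - removed
        conc[i] <- present / receiver_volume_mL
        removed <- removed + conc[i] * sample_volume_mL
      }
      transport_assay(direction = dir, c0_uM = c0_uM, area_cm2 = area_cm2,
                      times_min = times_min, receiver_conc_nmol_mL = conc,
                      receiver_volume_mL = receiver_volume_mL,
                      donor_volume_mL = donor_volume_mL,
                      sample_volume_mL = sample_volume_mL,
                      dilution_corrected = FALSE)
    })
    stats::setNames(out, names(papp_cm_s))
  })
}

#' Generate an equilibrium-dialysis time course
#'
#' The buffer/matrix concentration ratio approaches the true unbound
#' fraction as `fu * (1 - exp(-rate * t))`; the matrix concentration is held
#' at `matrix_conc`. With `rate = 0` the device never equilibrates (the
#' degenerate case [fraction_unbound()] must flag).
#'
#' @param fu True unbound fraction, in (0, 1].
#' @param rate_per_h Equilibration rate constant, 1/h (>= 0).
#' @param times_h Sampling times, h (default the 4/8/18/24 h design).
#' @param matrix_conc Matrix concentration (arbitrary units, default 1).
#' @param sigma Lognormal residual log-sd on the buffer concentrations.
#' @param seed RNG seed.
#' @return A [binding_timecourse()].
#' @export
gen_dialysis_timecourse <- function(fu, rate_per_h, times_h = c(4, 8, 18, 24),
                                    matrix_conc = 1, sigma = 0, seed = 0L) {
  assert_scalar(fu, "fu", lo = 0, hi = 1, lo_open = TRUE)
  assert_scalar(rate_per_h, "rate_per_h", lo = 0)
  buffer <- with_rng(seed, {
    matrix_conc * fu * (1 - exp(-rate_per_h * times_h)) *
      lognormal_noise(length(times_h), sigma)
  })
  binding_timecourse(times_h = times_h, buffer = buffer,
                     matrix_conc = rep(matrix_conc, length(times_h)))
}

#' Generate interval urine/feces excretion records
#'
#' Total recovery per matrix is `fe * dose`; the total is spread across the
#' collection intervals by a fixed first-order excretion-time profile
#' (rate `k_exc_per_h`), normalized so the noise-free interval amounts sum
#' exactly to `fe * dose`.
#'
#' @param fe_urine,fe_feces True dose fractions excreted unchanged
#'   (`fe_urine + fe_feces` must not exceed 1).
#' @param dose_ug Dose, ug.
#' @param urine_intervals,feces_intervals Two-column matrices of interval
#'   start/end times, h (defaults: the 0-48 h urine and feces designs).
#' @param k_exc_per_h First-order spreading rate (default 0.2/h).
#' @param urine_volume_mL Collected urine volume per interval (default 5).
#' @param sigma Lognormal residual log-sd on interval amounts.
#' @param seed RNG seed.
#' @return A data frame of excretion records suitable for
#'   [cumulative_excretion()].
#' @export
gen_excretion_records <- function(fe_urine, fe_feces, dose_ug,
                                  urine_intervals = cbind(
                                    c(0, 2, 4, 6, 10, 24, 36),
                                    c(2, 4, 6, 10, 24, 36, 48)),
                                  feces_intervals = cbind(
                                    c(0, 10, 24, 36),
                                    c(10, 24, 36, 48)),
                                  k_exc_per_h = 0.2, urine_volume_mL = 5,
                                  sigma = 0, seed = 0L) {
  assert_scalar(fe_urine, "fe_urine", lo = 0, hi = 1)
  assert_scalar(fe_feces, "fe_feces", lo = 0, hi = 1)
  if (fe_urine + fe_feces > 1) {
    stop("fe_urine + fe_feces exceeds 1: more than the dose excreted", call. = FALSE)
  }
  assert_scalar(dose_ug, "dose_ug", lo = 0)
  spread <- function(intervals, total) {
    w <- exp(-k_exc_per_h * intervals[, 1]) - exp(-k_exc_per_h * intervals[, 2])
    total * w / sum(w)
  }
  with_rng(seed, {
    u_amt <- spread(urine_intervals, fe_urine * dose_ug) *
      lognormal_noise(nrow(urine_intervals), sigma)
    f_amt <- spread(feces_intervals, fe_feces * dose_ug) *
      lognormal_noise(nrow(feces_intervals), sigma)
    rbind(
      data.frame(matrix = "urine",
                 t_start_h = urine_intervals[, 1], t_end_h = urine_intervals[, 2],
                 amount_ug = NA_real_,
                 conc_ug_per_mL = u_amt / urine_volume_mL,
                 volume_mL = urine_volume_mL, stringsAsFactors = FALSE),
      data.frame(matrix = "feces",
                 t_start_h = feces_intervals[, 1], t_end_h = feces_intervals[, 2],
                 amount_ug = f_amt, conc_ug_per_mL = NA_real_,
                 volume_mL = NA_real_, stringsAsFactors = FALSE)
    )
  })
}

#' Generate a concentration-dependent CYP inhibition curve
#'
#' The noise-free curve is `inhibition(c) = 100 * c^h / (c^h + IC50^h)`.
#' What the plate reader actually measures is the remaining enzymatic
#' activity (a fluorescence ratio against the vehicle control), so the
#' multiplicative lognormal error is applied to the activity ratio
#' `1 - inhibition/100` and the noisy inhibition is derived from it; strongly
#' inhibited wells are therefore precise in inhibition units, as in the real
#' assay. Values are truncated to the physical reporting window [-10, 110]%.
#'
#' @param ic50_uM True IC50, uM (> 0).
#' @param hill Hill slope (default 1).
#' @param concentrations_uM Tested concentrations, uM (default a 0.59-10 uM
#'   dilution series).
#' @param sigma Lognormal residual log-sd on the measured per-well activity
#'   ratio.
#' @param n_replicates Wells per concentration; the reported inhibition is
#'   the replicate mean (default 3, the usual plate design).
#' @param seed RNG seed.
#' @return A data frame: `conc_uM`, `inhibition_pct`.
#' @export
gen_inhibition_curve <- function(ic50_uM, hill = 1,
                                 concentrations_uM = c(0.59, 1.25, 2.5, 5, 10),
                                 sigma = 0, n_replicates = 3L, seed = 0L) {
  assert_scalar(ic50_uM, "ic50_uM", lo = 0, lo_open = TRUE)
  assert_scalar(hill, "hill", lo = 0, lo_open = TRUE)
  assert_scalar(n_replicates, "n_replicates", lo = 1)
  if (any(concentrations_uM < 0)) stop("negative concentration", call. = FALSE)
  inh <- with_rng(seed, {
    ch <- concentrations_uM^hill
    activity <- 1 - ch / (ch + ic50_uM^hill)
    wells <- vapply(activity, function(a) {
      mean(a * lognormal_noise(n_replicates, sigma))
    }, numeric(1))
    pmin(110, pmax(-10, 100 * (1 - wells)))
  })
  data.frame(conc_uM = concentrations_uM, inhibition_pct = inh)
}
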