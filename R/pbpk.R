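# Whole-body flow-limited rat PBPK model: physiology container, model
# construction (back-calculated hepatic intrinsic clearance, calibrated
# first-order absorption), ODE simulation, and prediction scoring.

# Canonical perfused-tissue names used by the simulator.
.PBPK_TISSUES <- c("lung", "brain", "heart", "kidneys", "muscles", "adipose",
                   "skin", "bone", "testes", "spleen", "gut", "liver", "rest")

# Observed-data tissue labels that map onto simulator compartments.
.TISSUE_ALIASES <- c(lungs = "lung", muscle = "muscles", kidney = "kidneys",
                     fat = "adipose")

normalize_tissue <- function(x) {
  x <- tolower(x)
  ifelse(x %in% names(.TISSUE_ALIASES), .TISSUE_ALIASES[x], x)
}

#' The shipped rat physiology table (volumes and blood flows)
#'
#' Tissue volumes (mL/kg) and regional blood flows (mL/h/kg) for a reference
#' 250 g rat, from the standard physiological compilations (Davies & Morris
#' 1993; Brown et al. 1997). The `lung` row's flow is the cardiac output;
#' the `liver` row's flow is the hepatic arterial supply only, with the
#' portal contribution arriving via the gut and spleen rows (hepatic arterial
#' + portal = 3480 mL/h/kg, i.e. 14.5 mL/min for a 250 g rat). A
#' `rest`-of-body row closes the volume and flow balances. Validated so the
#' flows into the venous pool sum exactly to cardiac output.
#'
#' @return A data frame of class `physiology_table` with columns
#'   `compartment`, `volume_mL_kg`, `flow_mL_h_kg`.
#' @export
rat_physiology <- function() {
  df <- utils::read.csv(ratpbpk_extdata("rat_physiology.csv"),
                        stringsAsFactors = FALSE)
  validate_physiology(df)
  class(df) <- c("physiology_table", "data.frame")
  df
}

validate_physiology <- function(df) {
  needed <- c(.PBPK_TISSUES, "arterial_blood", "venous_blood")
  missing <- setdiff(needed, df$compartment)
  if (length(missing)) {
    stop("physiology table is missing compartment(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$volume_mL_kg <= 0)) stop("non-positive compartment volume", call. = FALSE)
  flow <- function(n) df$flow_mL_h_kg[df$compartment == n]
  co <- flow("lung")
  q_h <- flow("liver") + flow("gut") + flow("spleen")
  venous_in <- sum(vapply(setdiff(.PBPK_TISSUES, c("lung", "gut", "spleen", "liver")),
                          flow, numeric(1))) + q_h
  if (abs(venous_in - co) > 1e-6 * co) {
    stop(sprintf("tissue flows into the venous pool (%.6g) do not sum to cardiac output (%.6g)",
                 venous_in, co), call. = FALSE)
  }
  invisible(df)
}

#' Build a whole-body flow-limited PBPK model specification
#'
#' Assembles compound parameters, physiology, and per-tissue partition
#' coefficients into a fully determined ODE system. Measured Kp values are
#' taken from `kp_table`; tissues absent from it (typically skin and bone)
#' are predicted by [rr_kp_predict()]; the rest-of-body compartment uses
#' Kp = 1. Elimination is hepatic: the unbound intrinsic clearance (times
#' fu) is back-calculated from the observed in-vivo clearance by inverting
#' the well-stirred relation, `CLint*fu = Q_h * CL_iv / (Q_h - CL_iv / R)`.
#' For oral dosing the first-order absorption surrogate is parameterized by
#' `fa*Fg = F_observed / Fh` (with `Fh = 1 - CL_iv / (Q_h * R)`) and an
#' absorption rate `ka` calibrated by bisection over [0.1, 10]/h so the
#' simulated Tmax matches the observed one.
#'
#' @param config A [study_config()] (supplies fu, B/P, dose, route, and the
#'   compound inputs for partition prediction).
#' @param cl_iv_mL_h_kg Observed in-vivo (intravenous) clearance, mL/h/kg.
#' @param physiology A physiology table; defaults to [rat_physiology()].
#' @param kp_table Measured Kp table; defaults to [rat_tissue_kp()].
#' @param f_observed Observed absolute oral bioavailability (0, 1]; required
#'   for an oral model.
#' @param tmax_observed_h Observed oral Tmax, h; used to calibrate `ka`.
#' @param ka_per_h Absorption rate constant; overrides calibration if given.
#' @param cl_renal_mL_h_kg Renal clearance (default 0; urinary recovery of
#'   the motivating compound is negligible).
#' @return An object of class `pbpk_model_spec`.
#' @export
build_pbpk_model <- function(config, cl_iv_mL_h_kg,
                             physiology = rat_physiology(),
                             kp_table = rat_tissue_kp(),
                             f_observed = NULL, tmax_observed_h = NULL,
                             ka_per_h = NULL, cl_renal_mL_h_kg = 0) {
  stopifnot(inherits(config, "study_config"))
  assert_scalar(cl_iv_mL_h_kg, "cl_iv_mL_h_kg", lo = 0)
  validate_physiology(physiology)
  r_bp <- config$blood_plasma_ratio
  flow <- function(n) physiology$flow_mL_h_kg[physiology$compartment == n]
  vol <- function(n) physiology$volume_mL_kg[physiology$compartment == n]
  q_h <- flow("liver") + flow("gut") + flow("spleen")

  # Kp per perfused tissue: measured where available, predicted otherwise.
  kp_meas <- stats::setNames(kp_table$kp, normalize_tissue(kp_table$tissue))
  kp <- stats::setNames(rep(NA_real_, length(.PBPK_TISSUES)), .PBPK_TISSUES)
  for (tn in .PBPK_TISSUES) {
    if (tn %in% names(kp_meas)) kp[tn] <- kp_meas[[tn]]
  }
  kp["rest"] <- 1
  unmeasured <- names(kp)[is.na(kp)]
  kp_prov <- stats::setNames(
    ifelse(.PBPK_TISSUES %in% unmeasured, "predicted",
           ifelse(.PBPK_TISSUES == "rest", "assumed", "measured")),
    .PBPK_TISSUES)
  if (length(unmeasured)) {
    pred <- rr_kp_predict(config, tissues = unmeasured)
    kp[pred$tissue] <- pred$kp
  }
  if (any(is.na(kp) | kp <= 0)) {
    stop("missing or non-positive Kp for tissue(s): ",
         paste(names(kp)[is.na(kp) | kp <= 0], collapse = ", "), call. = FALSE)
  }

  # Hepatic extraction feasibility, then invert the well-stirred relation.
  e_h <- cl_iv_mL_h_kg / (q_h * r_bp)
  if (e_h >= 1) {
    stop(sprintf("infeasible model: CL_iv (%.3g) implies hepatic extraction >= 1 at Q_h = %.3g",
                 cl_iv_mL_h_kg, q_h), call. = FALSE)
  }
  clint_fu <- q_h * cl_iv_mL_h_kg / (q_h - cl_iv_mL_h_kg / r_bp)
  fh <- 1 - e_h

  fa_fg <- NA_real_
  ka <- if (is.null(ka_per_h)) NA_real_ else ka_per_h
  spec <- structure(
    list(
      tissues = data.frame(
        name = .PBPK_TISSUES,
        volume_mL_kg = vapply(.PBPK_TISSUES, vol, numeric(1)),
        flow_mL_h_kg = vapply(.PBPK_TISSUES, flow, numeric(1)),
        kp = unname(kp[.PBPK_TISSUES]),
        provenance = unname(kp_prov[.PBPK_TISSUES]),
        stringsAsFactors = FALSE
      ),
      v_art = vol("arterial_blood"), v_ven = vol("venous_blood"),
      cardiac_output = flow("lung"), q_hepatic = q_h,
      fu = config$fu_plasma, r_bp = r_bp,
      clint_fu_mL_h_kg = clint_fu, cl_renal_mL_h_kg = cl_renal_mL_h_kg,
      fh = fh, ka_per_h = ka, fa_fg = fa_fg, lag_h = 0,
      dose_mg_kg = config$dose, route = config$route,
      compound = config$compound
    ),
    class = "pbpk_model_spec"
  )

  if (config$route == "po") {
    if (is.null(f_observed)) {
      stop("an oral model needs `f_observed` to set fa*Fg", call. = FALSE)
    }
    assert_scalar(f_observed, "f_observed", lo = 0, hi = 1, lo_open = TRUE)
    fa_fg <- f_observed / fh
    if (fa_fg > 1) {
      warning(sprintf("F_observed/Fh = %.3f > 1; capping fa*Fg at 1", fa_fg),
              call. = FALSE)
      fa_fg <- 1
    }
    spec$fa_fg <- fa_fg
    if (is.null(ka_per_h)) {
      if (is.null(tmax_observed_h)) {
        stop("an oral model needs `ka_per_h` or `tmax_observed_h`", call. = FALSE)
      }
      spec$ka_per_h <- calibrate_ka(spec, tmax_observed_h)
    } else {
      spec$ka_per_h <- ka_per_h
    }
  }
  spec
}

# Bisection on ka over [0.1, 10]/h so that simulated oral Tmax matches the
# observed value. Tmax is a decreasing function of ka.
calibrate_ka <- function(spec, tmax_target_h, grid_step = 0.01) {
  sim_tmax <- function(ka) {
    spec$ka_per_h <- ka
    grid <- seq(0, max(4 * tmax_target_h, 6), by = grid_step)
    sim <- pbpk_simulate(spec, times = grid)
    sim$time[which.max(sim$plasma)]
  }
  lo <- 0.1; hi <- 10
  f_lo <- sim_tmax(lo) - tmax_target_h
  f_hi <- sim_tmax(hi) - tmax_target_h
  if (f_lo <= 0) return(lo)   # even the slowest allowed absorption peaks early
  if (f_hi >= 0) return(hi)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    f_mid <- sim_tmax(mid) - tmax_target_h
    if (abs(f_mid) <= grid_step) return(mid)
    if (f_mid > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-3) break
  }
  (lo + hi) / 2
}

#' @export
print.pbpk_model_spec <- function(x, ...) {
  cat(sprintf("<pbpk_model_spec> %s | %g mg/kg %s\n",
              x$compound, x$dose_mg_kg, x$route))
  cat(sprintf("  fu %.4f | B/P %.2f | CLint*fu %.4g mL/h/kg | Q_h %.4g mL/h/kg | Fh %.3f\n",
              x$fu, x$r_bp, x$clint_fu_mL_h_kg, x$q_hepatic, x$fh))
  if (x$route == "po") {
    cat(sprintf("  ka %.3g /h | fa*Fg %.3f\n", x$ka_per_h, x$fa_fg))
  }
  cat(sprintf("  %d perfused tissues (Kp %.3g-%.3g)\n",
              nrow(x$tissues), min(x$tissues$kp), max(x$tissues$kp)))
  invisible(x)
}

#' Simulate a whole-body flow-limited PBPK model
#'
#' Solves the flow-limited mass balances with `deSolve::lsoda` (relative
#' tolerance 1e-8, absolute 1e-10 ug/mL). Each non-eliminating tissue obeys
#' `V_T dC_T/dt = Q_T R (C_art - C_T / Kp_T)`; the lung sits in series
#' between the venous and arterial pools; the liver receives the hepatic
#' artery plus the gut and spleen outflows, eliminates at `CLint*fu *
#' C_L / Kp_L`, and (orally) receives first-order input `ka * A_lumen` with
#' `A_lumen(0) = fa*Fg * dose`. All concentrations are plasma-referenced;
#' blood-borne fluxes carry the blood-to-plasma ratio R. The returned table
#' includes the amounts eliminated and remaining in the gut lumen and the
#' relative mass-balance residual at every output time.
#'
#' @param spec A [build_pbpk_model()] specification.
#' @param times Output time grid, h (default 0-24 at 0.05 h).
#' @param dose_mg_kg Dose override, mg/kg.
#' @param route Route override, `"iv"` or `"po"`.
#' @return A data frame of class `pbpk_sim`: `time`, `plasma` (venous),
#'   `arterial`, one column per tissue, `amount_eliminated_ug_kg`,
#'   `amount_lumen_ug_kg`, `mass_balance_residual`.
#' @export
pbpk_simulate <- function(spec, times = seq(0, 24, by = 0.05),
                          dose_mg_kg = spec$dose_mg_kg, route = spec$route) {
  stopifnot(inherits(spec, "pbpk_model_spec"))
  route <- match.arg(route, c("iv", "po"))
  assert_scalar(dose_mg_kg, "dose_mg_kg", lo = 0)
  if (any(diff(times) <= 0) || times[1] < 0) {
    stop("output times must be non-negative and strictly increasing", call. = FALSE)
  }
  tis <- spec$tissues
  nt <- nrow(tis)
  v <- stats::setNames(tis$volume_mL_kg, tis$name)
  q <- stats::setNames(tis$flow_mL_h_kg, tis$name)
  kp <- stats::setNames(tis$kp, tis$name)
  r <- spec$r_bp
  co <- spec$cardiac_output
  q_h <- spec$q_hepatic
  clint <- spec$clint_fu_mL_h_kg
  cl_ren <- spec$cl_renal_mL_h_kg
  ka <- if (route == "po") spec$ka_per_h else 0
  dose_ug <- dose_mg_kg * 1000
  if (route == "po" && dose_ug > 0 &&
      (!is.finite(ka) || !is.finite(spec$fa_fg))) {
    stop("oral simulation needs calibrated `ka_per_h` and `fa_fg`", call. = FALSE)
  }

  # Gut and spleen are ordinary perfused tissues (arterial inflow); only
  # their outflow routing differs, draining to the liver instead of the
  # venous pool. Lung, liver and kidneys have bespoke equations.
  plain <- setdiff(tis$name, c("lung", "liver", "kidneys"))
  state <- c(
    a_lumen = if (route == "po") spec$fa_fg * dose_ug else 0,
    c_ven = if (route == "iv") dose_ug / (spec$v_ven * r) else 0,
    c_art = 0,
    stats::setNames(rep(0, nt), paste0("c_", tis$name)),
    a_elim = 0
  )

  derivs <- function(t, y, parms) {
    cv <- y[["c_ven"]]; ca <- y[["c_art"]]
    ct <- stats::setNames(y[paste0("c_", tis$name)], tis$name)
    out <- function(n) ct[[n]] / kp[[n]]   # venous plasma-equivalent leaving n
    d <- numeric(length(y))
    names(d) <- names(y)
    d[["a_lumen"]] <- -ka * y[["a_lumen"]]
    d[["c_art"]] <- co * (out("lung") - ca) / spec$v_art
    for (n in plain) {
      d[[paste0("c_", n)]] <- q[[n]] * r * (ca - out(n)) / v[[n]]
    }
    d[["c_kidneys"]] <- (q[["kidneys"]] * r * (ca - out("kidneys")) -
                           cl_ren * out("kidneys")) / v[["kidneys"]]
    d[["c_lung"]] <- co * r * (cv - out("lung")) / v[["lung"]]
    d[["c_liver"]] <- (q[["liver"]] * r * ca +
                         q[["gut"]] * r * out("gut") +
                         q[["spleen"]] * r * out("spleen") -
                         q_h * r * out("liver") -
                         clint * out("liver") +
                         ka * y[["a_lumen"]]) / v[["liver"]]
    venous_in <- sum(vapply(setdiff(tis$name, c("lung", "gut", "spleen", "liver")),
                            function(n) q[[n]] * r * out(n), numeric(1))) +
      q_h * r * out("liver")
    d[["c_ven"]] <- (venous_in - co * r * cv) / spec$v_ven
    d[["a_elim"]] <- clint * out("liver") + cl_ren * out("kidneys")
    list(d)
  }

  sol <- deSolve::lsoda(y = state, times = times, func = derivs, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed to converge; see deSolve diagnostics", call. = FALSE)
  }
  sol <- as.data.frame(sol)
  if (min(vapply(sol[-1], min, numeric(1))) < -1e-8) {
    stop("negative state encountered; solver tolerances too loose", call. = FALSE)
  }

  in_body <- as.matrix(sol[paste0("c_", tis$name)]) %*% v[tis$name] +
    spec$v_art * r * sol$c_art + spec$v_ven * r * sol$c_ven
  available <- if (route == "po") spec$fa_fg * dose_ug else dose_ug
  residual <- if (dose_ug > 0) {
    abs(available - (in_body[, 1] + sol$a_elim + sol$a_lumen)) / dose_ug
  } else {
    rep(0, nrow(sol))
  }

  out <- data.frame(time = sol$time, plasma = sol$c_ven, arterial = sol$c_art)
  for (n in tis$name) out[[n]] <- sol[[paste0("c_", n)]]
  out$amount_eliminated_ug_kg <- sol$a_elim
  out$amount_lumen_ug_kg <- sol$a_lumen
  out$mass_balance_residual <- residual
  attr(out, "dose_mg_kg") <- dose_mg_kg
  attr(out, "route") <- route
  class(out) <- c("pbpk_sim", "data.frame")
  out
}

#' Score simulated against observed concentration-time profiles
#'
#' For every tissue present in both the simulation and the observed set,
#' computes predicted and observed AUC (linear trapezoid over the observed
#' time window), Cmax, and (for oral data) Tmax; reports the
#' predicted/observed ratio, the fold error `max(ratio, 1/ratio)`, and a
#' pass flag at the conventional 2-fold acceptance criterion.
#'
#' @param sim A [pbpk_simulate()] result.
#' @param observed A list of [conc_profile()] objects (or a single one).
#' @param fold_criterion Acceptance bound on the fold error (default 2).
#' @return A data frame: `tissue`, `parameter`, `predicted`, `observed`,
#'   `ratio`, `fold_error`, `pass`.
#' @export
evaluate_prediction <- function(sim, observed, fold_criterion = 2) {
  stopifnot(inherits(sim, "pbpk_sim"))
  if (inherits(observed, "conc_profile")) observed <- list(observed)
  rows <- list()
  for (p in observed) {
    tn <- normalize_tissue(p$tissue)
    if (!tn %in% names(sim)) next
    keep <- !is.na(p$conc)
    t_obs <- p$times[keep]; c_obs <- p$conc[keep]
    window <- sim$time >= 0 & sim$time <= max(t_obs)
    t_sim <- sim$time[window]; c_sim <- sim[[tn]][window]
    obs_m <- .trapz_moments(t_obs, c_obs)
    sim_m <- .trapz_moments(t_sim, c_sim)
    metrics <- list(
      auc = c(sim_m$auc, obs_m$auc),
      cmax = c(max(c_sim), max(c_obs))
    )
    if (attr(sim, "route") == "po") {
      metrics$tmax <- c(t_sim[which.max(c_sim)], t_obs[which.max(c_obs)])
    }
    for (metric in names(metrics)) {
      pr <- metrics[[metric]][1]; ob <- metrics[[metric]][2]
      ratio <- pr / ob
      fold <- max(ratio, 1 / ratio)
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tn, parameter = metric, predicted = pr, observed = ob,
        ratio = ratio, fold_error = fold, pass = fold <= fold_criterion,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    stop("no observed tissue matches a simulated compartment", call. = FALSE)
  }
  do.call(rbind, rows)
}
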