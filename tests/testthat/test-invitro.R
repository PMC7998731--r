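test_that("apparent permeability recovers the generating Papp", {
  # at these permeabilities ~30% of the 0.5 mL donor crosses in 120 min, so
  # both the generator and the analysis legitimately flag the sink violation
  for (pa in c(18.5e-6, 22.6e-6, 15.5e-6)) {
    expect_warning(tr <- gen_transport_assay(setNames(pa, "a2b"), sigma = 0),
                   "sink")
    expect_warning(est <- papp(tr$a2b), "sink")
    expect_true(est$ok)
    expect_false(est$sink_ok)
    expect_equal(est$papp_cm_s, pa, tolerance = 1e-10)
  }
  # all-zero receiver series is a legitimate zero, not a failure
  zero <- gen_transport_assay(c(a2b = 0), sigma = 0)
  expect_equal(papp(zero$a2b)$papp_cm_s, 0)

  # doubling C0 with identical receiver record halves Papp
  tr <- suppressWarnings(gen_transport_assay(c(a2b = 18.5e-6), sigma = 0))
  double <- transport_assay("a2b", c0_uM = 2, area_cm2 = 1.12,
                            times_min = tr$a2b$times_min,
                            receiver_conc_nmol_mL = tr$a2b$receiver_conc_nmol_mL,
                            receiver_volume_mL = 1.5, donor_volume_mL = 0.5,
                            sample_volume_mL = 0.2)
  expect_equal(suppressWarnings(papp(double))$papp_cm_s, 18.5e-6 / 2,
               tolerance = 1e-10)
})

test_that("dilution correction is required and undoes sampling replacement", {
  tr <- suppressWarnings(gen_transport_assay(c(a2b = 18.5e-6), sigma = 0))
  # ignoring the correction underestimates the slope
  naive <- tr$a2b
  naive$dilution_corrected <- TRUE
  p_naive <- suppressWarnings(papp(naive))
  p_corr <- suppressWarnings(papp(tr$a2b))
  expect_lt(p_naive$papp_cm_s, 18.5e-6)
  expect_gt(p_corr$papp_cm_s, p_naive$papp_cm_s)
})

test_that("efflux ratio is a plain quotient with guarded inputs", {
  expect_equal(efflux_ratio(22.6e-6, 18.5e-6), 1.2216, tolerance = 1e-4)
  expect_equal(efflux_ratio(15.7e-6, 15.5e-6), 1.013, tolerance = 1e-3)
  expect_equal(efflux_ratio(5e-6, 5e-6), 1)
  expect_error(efflux_ratio(5e-6, 0), "papp_a2b")
})

test_that("unbound fraction is read from the equilibrated dialysis plateau", {
  dia <- gen_dialysis_timecourse(0.0363, rate_per_h = 5, sigma = 0)
  fu <- fraction_unbound(dia)
  expect_true(fu$equilibrated)
  expect_equal(fu$fu, 0.0363, tolerance = 1e-3)
  expect_equal(fu$percent_bound, 96.37, tolerance = 1e-2)

  mic <- gen_dialysis_timecourse(0.623, rate_per_h = 5, sigma = 0)
  expect_equal(fraction_unbound(mic)$fu, 0.623, tolerance = 1e-3)

  ident <- binding_timecourse(c(4, 8, 18, 24), rep(2, 4), rep(2, 4))
  res <- fraction_unbound(ident)
  expect_equal(res$fu, 1)
  expect_equal(res$percent_bound, 0)

  # a device that never equilibrates is a flagged failure with trajectory
  stuck <- gen_dialysis_timecourse(0.5, rate_per_h = 0, sigma = 0)
  out <- fraction_unbound(stuck)
  expect_false(out$equilibrated)
  expect_true(is.na(out$fu))
  expect_length(out$ratio, 4L)
})

test_that("plateau estimator recovers fu within 2% on average at 5% noise", {
  reps <- 200
  est <- vapply(seq_len(reps), function(i) {
    dia <- gen_dialysis_timecourse(0.0363, rate_per_h = 5, sigma = 0.05,
                                   seed = 1000 + i)
    fraction_unbound(dia)$fu
  }, numeric(1))
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.0363) / 0.0363, 0.02)
})

test_that("depletion rate and intrinsic clearance follow the scaling chain", {
  dep <- gen_depletion_assay(log(2) / 17.1, fu_mic = 0.623, sigma = 0)
  rate <- depletion_rate(dep)
  expect_false(rate$stable)
  expect_equal(rate$ke_per_min, log(2) / 17.1, tolerance = 1e-10)
  expect_equal(rate$t_half_min, 17.1, tolerance = 1e-10)
  expect_equal(rate$ke_per_min, 0.04053, tolerance = 1e-3)

  ci <- clint(rate$ke_per_min, fu_mic = 0.623)
  expect_equal(signif(ci$clint_L_h_kg, 3), 14.0)
  # without the binding correction the scaled clearance drops to 8.7
  expect_equal(signif(clint(rate$ke_per_min, fu_mic = 1)$clint_L_h_kg, 2), 8.7)
  expect_equal(clint(0, fu_mic = 0.623)$clint_L_h_kg, 0)
  expect_error(clint(0.04, fu_mic = 0), "fu_mic")

  # clint is linear in ke
  expect_equal(clint(0.08, fu_mic = 0.623)$clint_L_h_kg,
               2 * clint(0.04, fu_mic = 0.623)$clint_L_h_kg, tolerance = 1e-12)

  flat <- depletion_assay(c(5, 15, 30, 60), rep(100, 4))
  expect_true(depletion_rate(flat)$stable)
  expect_equal(depletion_rate(flat)$ke_per_min, 0)
})

test_that("well-stirred hepatic clearance reproduces the IVIVE benchmark", {
  q <- flow_per_kg(14.5, 0.25)
  expect_equal(q, 3480)
  ws <- well_stirred_clh(q, 13975.76, 0.0363, 1)
  expect_equal(signif(ws$clh_mL_h_kg, 3), 443)
  expect_equal(ws$fh, 1 - ws$extraction)
  expect_equal(well_stirred_clh(q, 0, 0.0363)$clh_mL_h_kg, 0)
  # flow limit: CLh -> Q R as CLint fu -> infinity
  expect_equal(well_stirred_clh(q, 1e12, 0.5, 1)$clh_mL_h_kg, q,
               tolerance = 1e-6)

  # monotone in each argument, bounded by the flow limit
  base <- well_stirred_clh(q, 14000, 0.0363)$clh_mL_h_kg
  expect_gt(well_stirred_clh(q * 1.2, 14000, 0.0363)$clh_mL_h_kg, base)
  expect_gt(well_stirred_clh(q, 14000 * 1.2, 0.0363)$clh_mL_h_kg, base)
  expect_gt(well_stirred_clh(q, 14000, 0.0363 * 1.2)$clh_mL_h_kg, base)
  expect_lt(base, q)
})

test_that("IC50 fitting recovers truth and censors out-of-range potencies", {
  curve <- gen_inhibition_curve(4.66, sigma = 0)
  fit <- ic50_fit(curve$conc_uM, curve$inhibition_pct)
  expect_false(fit$censored)
  expect_equal(fit$ic50_uM, 4.66, tolerance = 1e-6)

  # an exactly-50% observation pins the IC50 at that concentration
  exact <- ic50_fit(c(1, 4.66, 10),
                    100 * c(1, 4.66, 10) / (c(1, 4.66, 10) + 4.66))
  expect_equal(exact$ic50_uM, 4.66, tolerance = 1e-6)

  # weak inhibition never crossing 50% reports a lower bound
  weak <- ic50_fit(c(0.59, 1.25, 2.5, 5, 10), c(2, 5, 11, 20, 35.7))
  expect_true(weak$censored)
  expect_true(is.na(weak$ic50_uM))
  expect_equal(weak$ic50_lower_bound_uM, 10)

  # fitted-slope mode recovers a non-unit Hill coefficient
  steep <- gen_inhibition_curve(3, hill = 2,
                                concentrations_uM = c(0.5, 1, 2, 4, 8, 16),
                                sigma = 0)
  fs <- ic50_fit(steep$conc_uM, steep$inhibition_pct, hill = "fitted")
  expect_equal(fs$ic50_uM, 3, tolerance = 1e-4)
  expect_equal(fs$hill, 2, tolerance = 1e-4)
})

test_that("IC50 recovery stays accurate and censoring-safe under noise", {
  reps <- 500
  err <- vapply(seq_len(reps), function(i) {
    cv <- gen_inhibition_curve(4.66, sigma = 0.1, seed = 2000 + i)
    f <- suppressWarnings(ic50_fit(cv$conc_uM, cv$inhibition_pct))
    if (f$censored) return(NA_real_)
    abs(f$ic50_uM - 4.66) / 4.66
  }, numeric(1))
  expect_lt(median(err, na.rm = TRUE), 0.05)

  # grossly non-monotone data still fit, but with a warning attached
  expect_warning(ic50_fit(c(1, 2, 4, 8), c(30, 70, 40, 80)), "non-monotone")

  # true IC50 beyond the tested range: always reported as a bound
  censored <- vapply(seq_len(200), function(i) {
    cv <- gen_inhibition_curve(25, sigma = 0.1, seed = 3000 + i)
    ic50_fit(cv$conc_uM, cv$inhibition_pct)$censored
  }, logical(1))
  expect_true(all(censored))
})

test_that("interaction indices follow their defining arithmetic", {
  idx <- ddi_indices(cmax_total_uM = 1.60, fu_p = 0.0363, dose_mg = 775,
                     mw_g_mol = 441.465, ki_uM = 4.66)
  expect_equal(signif(idx$imax_u_over_ki, 2), 0.012)
  expect_false(idx$systemic_flag)
  # the gut index from the stated dose/250 mL definition
  expect_equal(idx$igut_uM, 775 / 441.465 / 0.25 * 1000, tolerance = 1e-12)
  expect_equal(idx$igut_over_ki, 1506.6, tolerance = 1e-3)
  expect_true(idx$gut_flag)

  # index vanishes with the unbound fraction
  tiny <- ddi_indices(1.60, 1e-6, 775, 441.465, 4.66)
  expect_lt(tiny$imax_u_over_ki, 1e-6)
})
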