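cl_iv_ref <- flow_per_kg(3.16, 0.25)  # 758.4 mL/h/kg

test_that("model construction back-calculates hepatic parameters", {
  spec <- build_pbpk_model(supinoxin_config(route = "iv"), cl_iv_ref)
  # hepatic inflow equals the IVIVE blood flow for a 250 g rat
  expect_equal(spec$q_hepatic, 3480)
  expect_equal(spec$fh, 1 - cl_iv_ref / 3480, tolerance = 1e-12)
  expect_equal(spec$fh, 0.782, tolerance = 1e-3)
  # inverting the well-stirred relation returns the input clearance
  ws <- well_stirred_clh(spec$q_hepatic, spec$clint_fu_mL_h_kg, 1, 1)
  expect_equal(ws$clh_mL_h_kg, cl_iv_ref, tolerance = 1e-9)

  # measured Kps carried through; skin/bone predicted; rest assumed
  tis <- spec$tissues
  expect_equal(tis$kp[tis$name == "liver"], 4.76)
  expect_equal(tis$kp[tis$name == "lung"], 1.08)
  expect_identical(tis$provenance[tis$name %in% c("skin", "bone")],
                   rep("predicted", 2))
  expect_identical(tis$provenance[tis$name == "rest"], "assumed")

  # infeasible extraction is rejected
  expect_error(build_pbpk_model(supinoxin_config(route = "iv"), 4000),
               "extraction")
})

test_that("oral absorption calibration hits the observed F and Tmax", {
  spec <- build_pbpk_model(supinoxin_config(), cl_iv_ref,
                           f_observed = 0.572, tmax_observed_h = 0.75)
  expect_equal(spec$fa_fg, 0.572 / spec$fh, tolerance = 1e-12)
  expect_equal(spec$fa_fg, 0.731, tolerance = 1e-3)
  sim <- pbpk_simulate(spec, times = seq(0, 6, by = 0.01))
  expect_equal(sim$time[which.max(sim$plasma)], 0.75, tolerance = 0.03)

  expect_error(build_pbpk_model(supinoxin_config(), cl_iv_ref),
               "f_observed")
})

test_that("zero dose yields an identically zero system", {
  spec <- build_pbpk_model(supinoxin_config(route = "iv"), cl_iv_ref)
  sim <- pbpk_simulate(spec, times = seq(0, 4, by = 0.5), dose_mg_kg = 0,
                       route = "iv")
  cols <- setdiff(names(sim), c("time", "mass_balance_residual"))
  expect_true(all(vapply(sim[cols], function(x) all(x == 0), logical(1))))
})

test_that("mass is conserved without elimination and balanced with it", {
  spec <- build_pbpk_model(supinoxin_config(route = "iv"), cl_iv_ref)
  closed <- spec
  closed$clint_fu_mL_h_kg <- 0
  sim <- pbpk_simulate(closed, times = seq(0, 24, by = 0.25), dose_mg_kg = 5,
                       route = "iv")
  tis <- closed$tissues
  in_body <- as.matrix(sim[, tis$name]) %*% tis$volume_mL_kg +
    closed$v_art * sim$arterial + closed$v_ven * sim$plasma
  expect_lt(max(abs(in_body - 5000)) / 5000, 1e-6)

  open <- pbpk_simulate(spec, times = seq(0, 24, by = 0.25), dose_mg_kg = 5,
                        route = "iv")
  expect_lt(max(open$mass_balance_residual), 1e-6)
})

test_that("the simulated system is linear in dose", {
  spec <- build_pbpk_model(supinoxin_config(route = "iv"), cl_iv_ref)
  s1 <- pbpk_simulate(spec, times = seq(0, 6, by = 0.1), dose_mg_kg = 1,
                      route = "iv")
  s2 <- pbpk_simulate(spec, times = seq(0, 6, by = 0.1), dose_mg_kg = 2,
                      route = "iv")
  rel <- abs(s2$plasma[-1] - 2 * s1$plasma[-1]) / (2 * s1$plasma[-1])
  expect_lt(max(rel), 1e-6)
})

test_that("terminal tissue/plasma ratios approach Kp under fast perfusion", {
  phys <- rat_physiology()
  phys$flow_mL_h_kg <- phys$flow_mL_h_kg * 100
  spec <- build_pbpk_model(supinoxin_config(route = "iv"), cl_iv_ref,
                           physiology = phys)
  sim <- pbpk_simulate(spec, times = seq(0, 24, by = 0.05), dose_mg_kg = 5,
                       route = "iv")
  last <- nrow(sim)
  for (tn in c("adipose", "muscles", "brain", "gut")) {
    kp_in <- spec$tissues$kp[spec$tissues$name == tn]
    ratio <- sim[[tn]][last] / sim$plasma[last]
    expect_lt(abs(ratio - kp_in) / kp_in, 0.05)
  }
})

test_that("simulated NCA Vss approximates the Kp-volume sum", {
  spec <- build_pbpk_model(supinoxin_config(route = "iv"), cl_iv_ref)
  grid <- sort(unique(c(seq(0, 0.25, by = 2e-4), seq(0.25, 72, by = 0.02))))
  sim <- pbpk_simulate(spec, times = grid, dose_mg_kg = 5, route = "iv")
  tz <- function(x) sum(diff(sim$time) * (head(x, -1) + tail(x, -1)) / 2)
  lam <- -coef(lm(log(tail(sim$plasma, 200)) ~ tail(sim$time, 200)))[[2]]
  clast <- tail(sim$plasma, 1); tlast <- tail(sim$time, 1)
  aucinf <- tz(sim$plasma) + clast / lam
  aumcinf <- tz(sim$time * sim$plasma) + clast * tlast / lam + clast / lam^2
  vss_nca <- (5000 / aucinf) * (aumcinf / aucinf)
  vss_sum <- sum(spec$tissues$kp * spec$tissues$volume_mL_kg) +
    spec$v_art + spec$v_ven
  expect_lt(abs(vss_nca - vss_sum) / vss_sum, 0.10)
})

test_that("prediction scoring reports ratios, fold errors and pass flags", {
  spec <- build_pbpk_model(supinoxin_config(), cl_iv_ref,
                           f_observed = 0.572, ka_per_h = 1.65)
  sim <- pbpk_simulate(spec, times = seq(0, 24, by = 0.05))
  # identity: observe the simulation itself on its own grid
  obs <- conc_profile("o1", "plasma", "po", 5, sim$time, sim$plasma)
  ev <- evaluate_prediction(sim, obs)
  expect_equal(ev$ratio[ev$parameter == "cmax"], 1, tolerance = 1e-9)
  expect_equal(ev$ratio[ev$parameter == "tmax"], 1, tolerance = 1e-9)
  expect_equal(ev$ratio[ev$parameter == "auc"], 1, tolerance = 1e-9)
  expect_true(all(ev$pass))

  # boundary arithmetic of the 2-fold acceptance criterion
  expect_true(max(7.0 / 3.51, 3.51 / 7.0) <= 2)
  expect_false(max(1.7 / 3.51, 3.51 / 1.7) <= 2)

  expect_error(evaluate_prediction(sim,
    conc_profile("o2", "tail", "po", 5, c(1, 2), c(1, 0.5))), "no observed")
})
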