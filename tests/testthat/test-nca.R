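test_that("trapezoid moments match hand integration", {
  expect_equal(auc_trapz(make_profile(c(0, 1), c(1, 1)))$auc, 1)
  tri <- auc_trapz(make_profile(c(0, 2), c(2, 0)))
  expect_equal(tri$auc, 2)
  expect_equal(tri$aumc, 4 / 3)  # int t(2-t) dt over [0,2], linear segment

  # dense exponential approaches the analytic integral
  t <- seq(0.01, 10, by = 0.01)
  dense <- auc_trapz(make_profile(t, exp(-t)))
  expect_equal(dense$auc, 1 - exp(-10) - (1 - exp(-0.01)), tolerance = 1e-4)

  # BLQ points are excluded, not imputed
  p_blq <- make_profile(c(0, 1, 2, 3), c(2, NA, 1, 0.5))
  expect_equal(auc_trapz(p_blq)$auc,
               oracle_trapz(c(0, 2, 3), c(2, 1, 0.5)))

  expect_error(auc_trapz(make_profile(c(1, 2), c(1, 1)), upper = 0.5),
               "before the first")
})

test_that("AUC is additive over an interior cut, interpolated or sampled", {
  p <- make_profile(IV_TIMES, 10 * exp(-0.3 * IV_TIMES), dose = 5)
  whole <- auc_trapz(p)$auc
  for (cut in c(1, 4.2)) {   # a sample point and an interpolated point
    left <- auc_trapz(p, upper = cut)$auc
    keep <- p$times >= cut
    t_right <- c(cut, p$times[keep][p$times[keep] > cut])
    c_right <- approx(p$times, p$conc, xout = t_right)$y
    right <- oracle_trapz(t_right, c_right)
    expect_equal(left + right, whole, tolerance = 1e-12)
  }
})

test_that("terminal slope fitting matches the brute-force oracle", {
  # exact log-linear data: lambda recovered to machine accuracy
  t <- c(1, 3, 7, 10, 24)
  p <- make_profile(t, 10 * exp(-0.3465 * t))
  fit <- fit_lambda_z(p)
  expect_equal(fit$lambda_z, 0.3465, tolerance = 1e-10)
  expect_equal(fit$t_half, 2.0, tolerance = 1e-3)
  expect_equal(fit$t_half * fit$lambda_z, 0.693)   # reporting identity

  # biexponential disposition on the IV sampling grid
  bi <- 5 * exp(-2 * IV_TIMES) + 1 * exp(-0.25 * IV_TIMES)
  pb <- make_profile(IV_TIMES, bi, dose = 1)
  fb <- fit_lambda_z(pb)
  oracle <- oracle_lambda_z(IV_TIMES, bi)
  expect_equal(fb$lambda_z, oracle$lambda, tolerance = 1e-12)
  expect_equal(fb$n_points, oracle$k)
  expect_lt(abs(fb$lambda_z - 0.25) / 0.25, 0.05)

  # flat terminal phase is a flagged failure, not a number
  flat <- make_profile(c(0.5, 1, 2, 4, 8), c(3, 1, 1, 1, 1))
  expect_false(fit_lambda_z(flat)$ok)

  expect_error(fit_lambda_z(make_profile(c(1, 2, 3), c(3, 2, 1))), ">= 3")
})

test_that("noise-free exponential data reproduce the generating constant", {
  for (lam in c(0.1, 0.3465, 1.2)) {
    p <- make_profile(IV_TIMES, 8 * exp(-lam * IV_TIMES))
    expect_lt(abs(fit_lambda_z(p)$lambda_z - lam) / lam, 1e-8)
  }
})

test_that("derived NCA parameters follow their defining ratios", {
  # mean-level arithmetic from the 5 mg/kg intravenous study
  expect_equal(5000 / 6.13, 815.66, tolerance = 1e-4)
  t <- seq(0.05, 36, by = 0.05)
  truth <- list(cl_mL_h_kg = 691, v_mL_kg = 2040)
  p <- gen_disposition_profiles(truth, t, 1, "iv", sigma = 0)$profiles[[1]]
  res <- nca_summarize(p, back_extrapolate = TRUE)
  expect_lt(abs(res$cl - 691) / 691, 0.01)
  expect_lt(abs(res$vss - 2040) / 2040, 0.02)
  expect_gte(res$aucinf, res$auclast)
  expect_equal(res$vss, res$mrt * res$cl, tolerance = 1e-12)

  # oral bioavailability against a paired intravenous exposure
  po <- gen_disposition_profiles(list(cl_mL_h_kg = 691, v_mL_kg = 2040,
                                      ka_per_h = 2, f = 0.573),
                                 t, 1, "po", sigma = 0)$profiles[[1]]
  rpo <- nca_summarize(po, paired_iv_aucinf = res$aucinf)
  expect_equal(rpo$f, 0.573, tolerance = 0.01)
  expect_equal(3.51 / 6.13, 0.5726, tolerance = 1e-4)  # mean-level F, 5 mg/kg

  expect_error(nca_param(rpo, "cl"), "undefined")
  expect_error(nca_param(res, "f"), "undefined")
  expect_equal(nca_param(res, "cl"), res$cl)
})

test_that("dose proportionality holds exactly on linear synthetic truth", {
  truth <- list(cl_mL_h_kg = 717, v_mL_kg = 2110)
  lo <- nca_summarize(gen_disposition_profiles(truth, IV_TIMES, 0.5, "iv",
                                               sigma = 0)$profiles[[1]])
  hi <- nca_summarize(gen_disposition_profiles(truth, IV_TIMES, 5, "iv",
                                               sigma = 0)$profiles[[1]])
  expect_equal(hi$auclast / lo$auclast, 10, tolerance = 1e-10)
  expect_equal(hi$cmax / lo$cmax, 10, tolerance = 1e-10)
  expect_equal(hi$cl, lo$cl, tolerance = 1e-10)
  expect_equal(hi$vss, lo$vss, tolerance = 1e-10)
  expect_equal(hi$t_half, lo$t_half, tolerance = 1e-10)
})

test_that("sparse destructive-sampling AUC averages concentrations first", {
  t_design <- c(0.33, 1, 3, 7, 24)
  conc <- 12 * exp(-0.3 * t_design)
  three <- data.frame(time_h = rep(t_design, each = 3),
                      conc_ug_per_mL = rep(conc, each = 3))
  single <- oracle_trapz(t_design, conc)
  expect_equal(sparse_tissue_auc(three)$auc, single, tolerance = 1e-12)

  # unbalanced animals: mean per time, not pooled regression
  jit <- data.frame(time_h = c(1, 1, 3), conc_ug_per_mL = c(2, 4, 1))
  expect_equal(sparse_tissue_auc(jit)$auc, oracle_trapz(c(1, 3), c(3, 1)))

  expect_error(sparse_tissue_auc(three, expected_times = c(t_design, 12)),
               "12")
  expect_error(sparse_tissue_auc(data.frame(time_h = c(1, 1),
                                            conc_ug_per_mL = c(1, 2))),
               ">= 2 distinct")
})

test_that("profiles scaled to a target integral reproduce the tissue table", {
  # build a liver-like mean profile integrating to the tabulated 24.31
  t_design <- c(0.33, 1, 3, 7, 24)
  shape <- 10 * exp(-0.25 * t_design)
  scale <- 24.31 / oracle_trapz(t_design, shape)
  df <- data.frame(time_h = rep(t_design, each = 3),
                   conc_ug_per_mL = rep(shape * scale, each = 3))
  expect_equal(sparse_tissue_auc(df)$auc, 24.31, tolerance = 1e-10)
})
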