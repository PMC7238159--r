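test_that("DSC crystallinity is a normalized cumulative integral", {
  # rectangular heat-flow pulse: alpha grows linearly over the pulse
  tg <- thermogram(time = 0:100, heat_flow = c(rep(0, 20), rep(2, 41), rep(0, 40)))
  cv <- relative_crystallinity_dsc(tg, t0 = 20, t_inf = 60)
  expect_equal(cv$alpha, seq(0, 1, length.out = 41), tolerance = 1e-9)
  expect_equal(cv$alpha[length(cv$alpha)], 1)

  # synthetic exotherm matches the closed-form Avrami curve
  tg2 <- gen_dsc_isothermal(kinetic_truth(2, 1000, 0), 1, 8000, seed = 1)
  cv2 <- relative_crystallinity_dsc(tg2, t0 = 0, t_inf = 8000)
  expect_lt(max(abs(cv2$alpha - alpha_avrami(cv2$time, 2, 1000))), 1e-3)

  # instrument drift anchored on the flat pre/post-exotherm baseline is
  # removed by the linear option
  tgd <- gen_dsc_isothermal(kinetic_truth(2, 1000, 2000), 1, 12000, seed = 1)
  tgd$heat_flow <- tgd$heat_flow + seq(0.3, 0.1, length.out = length(tgd$time))
  cvd <- relative_crystallinity_dsc(tgd, t0 = 0, t_inf = 12000,
                                    baseline = "linear")
  expect_lt(max(abs(cvd$alpha - alpha_avrami(cvd$time, 2, 1000, 2000))), 5e-3)

  expect_error(relative_crystallinity_dsc(tg, t0 = 60, t_inf = 20), "t0 < t_inf")
  neg <- thermogram(0:10, rep(-1, 11))
  expect_error(relative_crystallinity_dsc(neg, t0 = 0, t_inf = 10),
               "non-positive total enthalpy")
})

test_that("permittivity tracking interpolates in log frequency", {
  st <- truth_alpha_process()
  kt <- kinetic_truth(3, 2000, 1000)
  ser <- gen_bds_crystallization_series(st, kt, 300, 68, seed = 1)
  tr <- static_permittivity_track(ser, f_track = ser[[1]]$frequency[10])
  expect_equal(tr$eps[1], ser[[1]]$eps_real[10])       # exact at a grid point
  expect_true(all(diff(tr$eps) <= 1e-12))              # monotone decay
  expect_error(static_permittivity_track(ser, f_track = 1e8), "outside")
})

test_that("normalized permittivity maps the static decay onto [0, 1]", {
  flat <- data.frame(time = 0:10 * 300, eps = rep(8, 11))
  expect_error(normalized_permittivity(flat), "no crystallization")

  ramp <- data.frame(time = 0:10 * 300, eps = seq(10, 4, length.out = 11))
  cv <- normalized_permittivity(ramp, eps_start = 10, eps_end = 4)
  expect_equal(cv$alpha[1], 0)
  expect_equal(cv$alpha[11], 1)
  expect_equal(cv$source, "BDS")
})

test_that("induction time is recovered by the inflection criterion", {
  tg <- gen_dsc_isothermal(truth_dsc_neat(), 10, 30000, seed = 1)
  cv <- relative_crystallinity_dsc(tg, t0 = 0, t_inf = 30000)
  expect_equal(estimate_induction_time(cv), 8800, tolerance = 100 / 8800)

  # no induction period: returns exactly zero
  tg0 <- gen_dsc_isothermal(kinetic_truth(2, 1000, 0), 2, 8000, seed = 1)
  cv0 <- relative_crystallinity_dsc(tg0, t0 = 0, t_inf = 8000)
  expect_identical(estimate_induction_time(cv0), 0)

  # slow first-order kinetics with a long induction period
  tgs <- gen_dsc_isothermal(kinetic_truth(1.0, 740 * 60, 29750), 60, 3e5, seed = 1)
  cvs <- relative_crystallinity_dsc(tgs, t0 = 0, t_inf = max(tgs$time))
  expect_equal(estimate_induction_time(cvs), 29750, tolerance = 250 / 29750)
})

test_that("the ln-time derivative has the Avrami peak properties", {
  tg <- gen_dsc_isothermal(kinetic_truth(2.5, 2000, 0), 2, 16000, seed = 1)
  cv <- relative_crystallinity_dsc(tg, t0 = 0, t_inf = 16000)
  d <- avramov_derivative(cv, t0 = 0)
  ct <- characteristic_time(d)
  # maximum value n/e and location at tau
  expect_equal(ct$alpha_prime_max, 2.5 / exp(1), tolerance = 1e-2)
  expect_equal(ct$tau_cr_s, 2000, tolerance = 1e-2)
  expect_equal(ct$alpha_at_peak, 1 - exp(-1), tolerance = 1e-2)

  # doubling tau shifts the peak by ln 2, same apex
  tg2 <- gen_dsc_isothermal(kinetic_truth(2.5, 4000, 0), 2, 32000, seed = 1)
  cv2 <- relative_crystallinity_dsc(tg2, t0 = 0, t_inf = 32000)
  ct2 <- characteristic_time(avramov_derivative(cv2, t0 = 0))
  expect_equal(ct2$ln_peak - ct$ln_peak, log(2), tolerance = 1e-2)
  expect_equal(ct2$alpha_prime_max, ct$alpha_prime_max, tolerance = 1e-2)

  # flat curve: derivative vanishes everywhere
  flatc <- kinetic_curve(1:200 * 10, rep(0.5, 200))
  dflat <- avramov_derivative(flatc, t0 = 0)
  expect_lt(max(abs(dflat$dalpha)), 1e-12)
})

test_that("characteristic time converges with grid refinement", {
  tg <- gen_dsc_isothermal(kinetic_truth(3.8, 55 * 60, 0), 5, 22000, seed = 1)
  cv <- relative_crystallinity_dsc(tg, t0 = 0, t_inf = 22000)
  errs <- vapply(c(201L, 401L, 801L), function(ng) {
    ct <- characteristic_time(avramov_derivative(cv, 0, study_config(ln_grid_n = ng)))
    abs(ct$tau_cr_min - 55)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))   # finer grids never worse
  expect_lt(errs[3], 0.1)                # and the fine grid is accurate
})

test_that("both dimensionality estimators agree with truth", {
  expect_equal(n_from_derivative_max(0.368), 1)
  expect_equal(round(n_from_derivative_max(1.57), 1), 4.3)
  expect_equal(round(n_from_derivative_max(0.488), 3), 1.326)
  expect_error(n_from_derivative_max(0), "> 0")
  expect_equal(n_from_ln_times(0, exp(1)), 1)
  expect_error(n_from_ln_times(2, 1), "ln_t2 > ln_t1")

  # analytic curve, several exponents: noiseless recovery within 1%
  for (n in c(1.326, 2, 3.8)) {
    tau <- 1500
    tg <- gen_dsc_isothermal(kinetic_truth(n, tau, 0), 2,
                             ceiling(tau * (14)^(1 / n)) + 2000, seed = 1)
    cv <- relative_crystallinity_dsc(tg, t0 = 0, t_inf = max(tg$time))
    fit <- avramov(cv, t0 = 0)
    expect_equal(fit$n_derivative, n, tolerance = 0.01)
    expect_equal(fit$n_tangent, n, tolerance = 0.01)
    expect_equal(fit$tau_cr_s, tau, tolerance = 0.01)
    # Avramov self-consistency: inflection at 1 - 1/e
    expect_equal(fit$alpha_at_inflection, 1 - exp(-1), tolerance = 0.015)
  }
})

test_that("tangent construction is exact for the n = 2 analytic curve", {
  tg <- gen_dsc_isothermal(kinetic_truth(2, 1000, 0), 1, 8000, seed = 1)
  cv <- relative_crystallinity_dsc(tg, t0 = 0, t_inf = 8000)
  tan <- n_from_tangent(cv, t0 = 0, tau_cr = 1000)
  # slope at tau is n/e, so ln t2 - ln t1 = e/2 and n = 2
  expect_equal(tan$slope, 2 / exp(1), tolerance = 5e-3)
  expect_equal(tan$ln_t2 - tan$ln_t1, exp(1) / 2, tolerance = 5e-3)
  expect_equal(tan$n, 2, tolerance = 5e-3)
  expect_error(n_from_tangent(cv, t0 = 0, tau_cr = 1e6), "interior")
})

test_that("DSC and BDS branches share one Avramov code path", {
  kt <- kinetic_truth(2.2, 1800, 900)
  tg <- gen_dsc_isothermal(kt, 5, 16000, seed = 1)
  cv_dsc <- relative_crystallinity_dsc(tg, t0 = 0, t_inf = 16000)
  cv_bds <- kinetic_curve(cv_dsc$time, cv_dsc$alpha, source = "BDS")
  f1 <- avramov(cv_dsc)
  f2 <- avramov(cv_bds)
  for (fld in c("t0_s", "tau_cr_s", "n_derivative", "n_tangent"))
    expect_identical(f1[[fld]], f2[[fld]])
  expect_identical(f2$source, "BDS")
})

test_that("nucleation and growth scales follow the dimensional analysis", {
  expect_equal(unclass(nucleation_scales(1, 1))[c("t0_char", "xi")],
               list(t0_char = 1, xi = 1))
  ns <- nucleation_scales(16, 1)
  expect_equal(ns$t0_char, 0.5)
  expect_equal(ns$xi, 0.5)
  # homogeneity: V -> 16 V scales t0 by 16^(-3/4), xi by 2
  base <- nucleation_scales(2, 3)
  scaled <- nucleation_scales(2, 48)
  expect_equal(scaled$t0_char / base$t0_char, 16^(-3 / 4))
  expect_equal(scaled$xi / base$xi, 2)
  expect_error(nucleation_scales(-1, 1), "positive")
})
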