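test_that("DSC generator integrates to the total enthalpy and is deterministic", {
  truth <- truth_dsc_neat()
  tg <- gen_dsc_isothermal(truth, sampling_dt = 10, duration = 30000, seed = 1)
  # trapezoid quadrature oracle over the exotherm
  area <- pracma::trapz(tg$time, tg$heat_flow)
  expect_equal(area, truth$total_enthalpy, tolerance = 1e-3)

  # n = 1: rate is maximal right at t0 and decays monotonically
  tg1 <- gen_dsc_isothermal(kinetic_truth(1, 1000, 500), 1, 8000, seed = 1)
  on <- tg1$time > 500
  expect_equal(which.max(tg1$heat_flow), which(on)[1])
  expect_true(all(diff(tg1$heat_flow[on]) <= 0))

  noisy <- kinetic_truth(2, 1000, 0, noise_sd = 0.01)
  a <- gen_dsc_isothermal(noisy, 5, 6000, seed = 7)
  b <- gen_dsc_isothermal(noisy, 5, 6000, seed = 7)
  expect_identical(a$heat_flow, b$heat_flow)
  expect_false(identical(
    a$heat_flow, gen_dsc_isothermal(noisy, 5, 6000, seed = 8)$heat_flow))
})

test_that("generators leave the session RNG state untouched", {
  set.seed(123)
  expected <- rnorm(3)
  set.seed(123)
  invisible(gen_dsc_isothermal(kinetic_truth(2, 1000, 0, noise_sd = 1),
                               10, 5000, seed = 42))
  invisible(gen_dcp_table(84.3, noise_sd = 0.02, seed = 42))
  expect_identical(rnorm(3), expected)
})

test_that("crystallization spectra series encodes alpha in the permittivity decay", {
  st <- truth_alpha_process()
  kt <- kinetic_truth(3, 2000, 1000)
  ser <- gen_bds_crystallization_series(st, kt, interval = 300, n_spectra = 68,
                                        seed = 1)
  expect_length(ser, 68)
  # crystallization complete: last spectrum has lost its dielectric strength
  last <- ser[[length(ser)]]
  expect_equal(max(abs(last$eps_real - st$eps_inf)), 0, tolerance = 1e-6)

  # noiseless chain: normalized permittivity reproduces alpha exactly
  cv <- normalized_permittivity(static_permittivity_track(ser, f_track = 1))
  expect_equal(cv$alpha, alpha_avrami(cv$time, kt$n, kt$tau_cr, kt$t0),
               tolerance = 1e-6)

  # a day of spectra at the standard 300 s interval
  ser24 <- gen_bds_crystallization_series(st, kt, interval = 300,
                                          n_spectra = 289, seed = 1,
                                          frequency = c(1, 10, 100))
  expect_equal(ser24[[289]]$elapsed_time, 86400)
  expect_error(gen_bds_crystallization_series(st, kt, n_spectra = 1), ">= 2")
})

test_that("temperature series follows the VFT law and Arrhenius secondaries", {
  st <- truth_alpha_process()
  vp <- vft_rows$neat
  sp <- gen_bds_temperature_series(st, vp, temps = 314, seed = 1)[[1]]
  i <- which.max(sp$eps_imag)
  f_expected <- 1 / (2 * pi * tau_vft(314, vp))
  # argmax matches the VFT peak frequency within grid resolution (1/8 decade)
  expect_lt(abs(log10(sp$frequency[i]) - log10(f_expected)), 1 / 8)

  expect_error(gen_bds_temperature_series(st, vp, temps = c(314, 200)),
               "Vogel temperature")

  # Ea = 0 secondary process: identical relaxation at all temperatures
  sec <- list(list(delta_eps = 0.5, a = 0.4, log10_tau_inf = -4, Ea_kJmol = 0))
  ser <- gen_bds_temperature_series(st, vp, temps = c(320, 340, 360), seed = 1,
                                    secondary = sec)
  # subtract the alpha contribution by comparing high-frequency tails where
  # the slow secondary (tau = 1e-4 s) dominates is messy; instead check the
  # secondary-only generator path via a negligible alpha strength
  st0 <- spectral_truth(list(list(delta_eps = 1e-10, tau_hn = 1e-9, a = 1, b = 1)),
                        eps_inf = 3)
  ser0 <- gen_bds_temperature_series(st0, vp, temps = c(320, 340, 360), seed = 1,
                                     secondary = sec)
  expect_equal(ser0[[1]]$eps_imag, ser0[[3]]$eps_imag, tolerance = 1e-6)
  expect_length(ser, 3)
})

test_that("heat-capacity table crosses zero at the immobilized composition", {
  tbl <- gen_dcp_table(84.3, dcp_pure = 0.4,
                       drug_loads = c(50, 55, 64, 73, 82, 91, 100))
  # linear above the breakpoint, zero crossing at w* = 15.7 wt.% drug
  fit <- lm(delta_cp ~ drug_load, data = tbl)
  expect_equal(unname(-coef(fit)[1] / coef(fit)[2]), 15.7, tolerance = 1e-9)

  # two exact points determine the capacity
  two <- gen_dcp_table(70, dcp_pure = 0.4, drug_loads = c(60, 100))
  expect_equal(fit_dcp_line(two)$ms_capacity, 70, tolerance = 1e-9)

  # no adsorption: proportional through the origin
  tbl100 <- gen_dcp_table(100, dcp_pure = 0.4, drug_loads = c(25, 50, 100))
  expect_equal(tbl100$delta_cp, 0.4 * tbl100$drug_load / 100, tolerance = 1e-12)

  # below the breakpoint the step is clipped at zero
  clip <- gen_dcp_table(84.3, drug_loads = c(5, 10, 50, 100))
  expect_equal(clip$delta_cp[1:2], c(0, 0))
  expect_error(gen_dcp_table(0), "0, 100")
  expect_error(gen_dcp_table(50, drug_loads = c(-5, 50)), "0, 100")
})
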