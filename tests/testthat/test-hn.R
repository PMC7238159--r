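test_that("HN model reduces to its closed-form special cases", {
  f <- default_freq_grid(1e-3, 1e3, 16)
  tau <- 1 / (2 * pi)  # Debye peak exactly at 1 Hz
  deb <- hn_model(f, list(list(delta_eps = 4, tau_hn = tau, a = 1, b = 1)))
  i <- which.max(deb$eps_imag)
  expect_equal(f[i], 1)
  expect_equal(max(deb$eps_imag), 4 / 2, tolerance = 1e-6)

  # pure ohmic conduction: slope -1 on the log-log loss
  cond <- hn_model(f, list(), eps_inf = 3, sigma_dc = 1e-10)
  slope <- diff(log10(cond$eps_imag)) / diff(log10(f))
  expect_equal(slope, rep(-1, length(f) - 1), tolerance = 1e-12)

  # independent closed-form evaluation (polar form) for arbitrary shape
  a <- 0.8; b <- 0.6; th <- 2e-4; de <- 8.9; einf <- 3
  om <- 2 * pi * f
  theta <- atan(sin(pi * a / 2) / ((om * th)^-a + cos(pi * a / 2)))
  r <- (1 + 2 * (om * th)^a * cos(pi * a / 2) + (om * th)^(2 * a))^(-b / 2)
  ref_real <- einf + de * r * cos(b * theta)
  ref_imag <- de * r * sin(b * theta)
  got <- hn_model(f, list(list(delta_eps = de, tau_hn = th, a = a, b = b)),
                  eps_inf = einf)
  expect_equal(got$eps_real, ref_real, tolerance = 1e-12)
  expect_equal(got$eps_imag, ref_imag, tolerance = 1e-12)
})

test_that("loss-peak time matches the HN peak formula and its limits", {
  expect_equal(tau_max_from_hn(list(tau_hn = 3, a = 1, b = 1)), 3)
  expect_equal(tau_max_from_hn(list(tau_hn = 3, a = 0.4, b = 1)), 3)

  # numerical argmax oracle on a dense log grid, random shapes
  set.seed(11)
  for (k in 1:25) {
    a <- runif(1, 0.2, 1); b <- runif(1, 0.2, 1); th <- 10^runif(1, -6, 0)
    tm <- tau_max_from_hn(list(tau_hn = th, a = a, b = b))
    lf0 <- log10(1 / (2 * pi * sqrt(tm * th)))   # bracket both time scales
    lf <- seq(lf0 - 4, lf0 + 4, length.out = 8001)
    ei <- function(x) hn_model(10^x, list(list(delta_eps = 1, tau_hn = th,
                                               a = a, b = b)))$eps_imag
    i <- which.max(ei(lf))
    opt <- optimize(function(x) -ei(x), lf[c(i - 1, i + 1)], tol = 1e-10)
    expect_equal(tm, 1 / (2 * pi * 10^opt$minimum), tolerance = 1e-3)
  }
})

test_that("HN fits recover generator truth", {
  st <- truth_alpha_process()
  sp <- gen_bds_crystallization_series(st, kinetic_truth(2, 1e9, 0), 300, 2,
                                       seed = 1)[[1]]
  fit <- fit_hn(sp, 1, fit_real = TRUE)
  truth <- st$processes[[1]]
  expect_equal(fit$processes[[1]]$delta_eps, truth$delta_eps, tolerance = 1e-3)
  expect_equal(fit$processes[[1]]$tau_hn, truth$tau_hn, tolerance = 1e-3)
  expect_equal(fit$processes[[1]]$a, truth$a, tolerance = 1e-3)
  expect_equal(fit$processes[[1]]$b, truth$b, tolerance = 1e-3)
  expect_equal(fit$eps_inf, st$eps_inf, tolerance = 1e-3)
  expect_equal(dielectric_strength(fit, 1), 8.9, tolerance = 1e-2)
  expect_error(dielectric_strength(fit, 3), "out of range")

  # Debye input, free shape: exponents must be driven to 1
  std <- spectral_truth(list(list(delta_eps = 5, tau_hn = 1e-3, a = 1, b = 1)),
                        eps_inf = 3)
  spd <- gen_bds_crystallization_series(std, kinetic_truth(2, 1e9, 0), 300, 2,
                                        seed = 1)[[1]]
  fd <- fit_hn(spd, 1)
  expect_equal(fd$processes[[1]]$a, 1, tolerance = 1e-3)
  expect_equal(fd$processes[[1]]$b, 1, tolerance = 1e-3)
})

test_that("HN fit is scale-equivariant in frequency", {
  st <- truth_alpha_process()
  sp <- gen_bds_crystallization_series(st, kinetic_truth(2, 1e9, 0), 300, 2,
                                       seed = 1)[[1]]
  fit1 <- fit_hn(sp, 1)
  sc <- 100
  sp2 <- dielectric_spectrum(sp$frequency * sc, sp$eps_real, sp$eps_imag,
                             temperature = sp$temperature)
  fit2 <- fit_hn(sp2, 1)
  expect_equal(fit2$processes[[1]]$a, fit1$processes[[1]]$a, tolerance = 1e-4)
  expect_equal(fit2$processes[[1]]$b, fit1$processes[[1]]$b, tolerance = 1e-4)
  expect_equal(fit2$processes[[1]]$tau_hn * sc, fit1$processes[[1]]$tau_hn,
               tolerance = 1e-4)
})

test_that("static-limit identity holds for conductivity-free fits", {
  st <- spectral_truth(list(list(delta_eps = 6, tau_hn = 1e-2, a = 0.7, b = 0.8)),
                       eps_inf = 4)
  sp <- gen_bds_crystallization_series(st, kinetic_truth(2, 1e9, 0), 300, 2,
                                       seed = 1,
                                       frequency = default_freq_grid(1e-4, 1e6))[[1]]
  fit <- fit_hn(sp, 1, fit_real = TRUE)
  total <- sum(vapply(fit$processes, `[[`, 1, "delta_eps")) + fit$eps_inf
  expect_equal(total, sp$eps_real[1], tolerance = 5e-3)
})

test_that("two Cole-Cole secondary processes are resolved and ordered", {
  st <- spectral_truth(list(list(delta_eps = 0.5, tau_hn = 1e-3, a = 0.4, b = 1),
                            list(delta_eps = 0.3, tau_hn = 1e-6, a = 0.3, b = 1)),
                       eps_inf = 3)
  sp <- gen_bds_crystallization_series(st, kinetic_truth(2, 1e9, 0), 300, 2,
                                       seed = 1)[[1]]
  fit <- fit_secondary_cole_cole(sp)
  expect_true(all(vapply(fit$processes, `[[`, 1, "b") == 1))
  # slow-to-fast labeling: beta before gamma
  expect_gt(fit$processes[[1]]$tau_max, fit$processes[[2]]$tau_max)
  expect_equal(fit$processes[[1]]$tau_hn, 1e-3, tolerance = 0.05)
  expect_equal(fit$processes[[2]]$tau_hn, 1e-6, tolerance = 0.05)
  expect_equal(fit$processes[[1]]$a, 0.4, tolerance = 0.02)

  # one real process, two fitted: the spurious one is flagged degenerate
  st1 <- spectral_truth(list(list(delta_eps = 0.5, tau_hn = 1e-3, a = 0.4, b = 1)),
                        eps_inf = 3)
  sp1 <- gen_bds_crystallization_series(st1, kinetic_truth(2, 1e9, 0), 300, 2,
                                        seed = 1)[[1]]
  f1 <- fit_secondary_cole_cole(sp1, n_processes = 2)
  expect_true(any(f1$degenerate))
})

test_that("noisy HN + conductivity fits stay within tolerance", {
  st <- truth_alpha_process(noise_sd = 0.02, sigma_dc = 1e-10)
  errs <- sapply(1:5, function(s) {
    sp <- gen_bds_crystallization_series(st, kinetic_truth(2, 1e9, 0), 300, 2,
                                         seed = s)[[1]]
    fit <- fit_hn(sp, 1, include_conductivity = TRUE)
    p <- fit$processes[[1]]
    c(abs(p$delta_eps / 8.9 - 1), abs(p$tau_hn / 1e-3 - 1),
      abs(p$a - 0.8), abs(p$b - 0.6))
  })
  expect_lt(max(errs[1, ]), 0.05)   # delta_eps within 5%
  expect_lt(max(errs[2, ]), 0.05)   # tau_HN within 5%
  expect_lt(max(errs[3, ]), 0.05)   # a within 0.05
  expect_lt(max(errs[4, ]), 0.05)   # b within 0.05
})
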