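# Synthetic-data generators. Every generator is a pure function of
# (truth, seed): the RNG state of the calling session is left untouched and
# regenerating with the same seed is bit-identical.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Avrami crystallization kinetics (closed form)
#'
#' Relative crystallinity alpha(t) = 1 - exp(-((t - t0)/tau)^n) for t > t0
#' and 0 before. This is the unique sigmoid for which the Avramov
#' constructions are exact: the maximum of d alpha / d ln(t - t0) equals n/e
#' and sits at t - t0 = tau, where alpha = 1 - 1/e.
#'
#' @param t Times in seconds.
#' @param n Avrami exponent, > 0.
#' @param tau Characteristic crystallization time in seconds, > 0.
#' @param t0 Induction time in seconds, >= 0.
#' @return alpha(t), same length as `t`.
#' @export
alpha_avrami <- function(t, n, tau, t0 = 0) {
  stopifnot(n > 0, tau > 0, t0 >= 0)
  a <- numeric(length(t))
  on <- t > t0
  a[on] <- 1 - exp(-((t[on] - t0) / tau)^n)
  a
}

.dalpha_dt_avrami <- function(t, n, tau, t0 = 0) {
  d <- numeric(length(t))
  on <- t > t0
  x <- (t[on] - t0) / tau
  d[on] <- (n / tau) * x^(n - 1) * exp(-x^n)
  d
}

#' Ground-truth parameters for a synthetic crystallization run
#'
#' @param n Avrami exponent.
#' @param tau_cr Characteristic crystallization time in seconds.
#' @param t0 Induction time in seconds.
#' @param total_enthalpy Total exotherm area in mJ.
#' @param noise_sd Additive Gaussian noise on the heat flow, in mW.
#' @return An object of class `"kinetic_truth"`.
#' @export
kinetic_truth <- function(n, tau_cr, t0 = 0, total_enthalpy = 100, noise_sd = 0) {
  stopifnot(n > 0, tau_cr > 0, t0 >= 0, noise_sd >= 0)
  structure(list(n = n, tau_cr = tau_cr, t0 = t0,
                 total_enthalpy = total_enthalpy, noise_sd = noise_sd),
            class = "kinetic_truth")
}

#' Ground-truth parameters for synthetic dielectric spectra
#'
#' @param processes List of relaxation processes, each a list with fields
#'   `delta_eps` (> 0), `tau_hn` (seconds), `a` and `b` (shape exponents in
#'   (0, 1]; `b = 1` is a Cole-Cole process).
#' @param eps_inf High-frequency limit permittivity (>= 1).
#' @param sigma_dc dc conductivity in S/m (>= 0).
#' @param noise_sd Relative (multiplicative log-normal) noise on eps' and
#'   eps''.
#' @return An object of class `"spectral_truth"`.
#' @export
spectral_truth <- function(processes, eps_inf = 3, sigma_dc = 0, noise_sd = 0) {
  for (p in processes) {
    stopifnot(p$delta_eps > 0, p$tau_hn > 0,
              p$a > 0, p$a <= 1, p$b > 0, p$b <= 1)
  }
  stopifnot(eps_inf >= 1, sigma_dc >= 0, noise_sd >= 0)
  structure(list(processes = processes, eps_inf = eps_inf,
                 sigma_dc = sigma_dc, noise_sd = noise_sd),
            class = "spectral_truth")
}

#' Default broadband frequency grid
#'
#' Logarithmic grid, 8 points per decade from 0.1 Hz to 1 MHz (57 points),
#' the window of a typical broadband dielectric experiment.
#'
#' @param fmin,fmax Grid limits in Hz.
#' @param points_per_decade Grid density.
#' @return Frequencies in Hz.
#' @export
default_freq_grid <- function(fmin = 1e-1, fmax = 1e6, points_per_decade = 8) {
  10^seq(log10(fmin), log10(fmax), by = 1 / points_per_decade)
}

#' Generate a synthetic isothermal DSC thermogram
#'
#' Heat flow is the Avrami crystallization rate scaled by the total enthalpy,
#' `heat_flow(t) = total_enthalpy * d alpha/dt + N(0, noise_sd)`, so the
#' exotherm integrates to `total_enthalpy` (exothermic positive).
#'
#' @param truth A [kinetic_truth()].
#' @param sampling_dt Sampling interval in seconds, > 0.
#' @param duration Run length in seconds; should exceed `t0 + 5 * tau_cr` for
#'   a complete exotherm.
#' @param seed Integer RNG seed.
#' @param temperature Hold temperature in kelvin.
#' @return A [thermogram()].
#' @examples
#' tg <- gen_dsc_isothermal(kinetic_truth(n = 3.8, tau_cr = 3300, t0 = 8800),
#'                          sampling_dt = 10, duration = 30000, seed = 1)
#' @export
gen_dsc_isothermal <- function(truth, sampling_dt, duration, seed = 1,
                               temperature = 363) {
  if (sampling_dt <= 0) stop("amorphkin: `sampling_dt` must be > 0", call. = FALSE)
  t <- seq(0, duration, by = sampling_dt)
  hf <- truth$total_enthalpy * .dalpha_dt_avrami(t, truth$n, truth$tau_cr, truth$t0)
  if (truth$noise_sd > 0) {
    hf <- hf + .with_seed(seed, stats::rnorm(length(t), 0, truth$noise_sd))
  }
  thermogram(time = t, heat_flow = hf, temperature = temperature,
             label = sprintf("synthetic Avrami n=%g tau=%g", truth$n, truth$tau_cr))
}

.apply_spectrum_noise <- function(sp, noise_sd) {
  if (noise_sd <= 0) return(sp)
  nf <- length(sp$frequency)
  sp$eps_real <- sp$eps_real * exp(stats::rnorm(nf, 0, noise_sd))
  sp$eps_imag <- sp$eps_imag * exp(stats::rnorm(nf, 0, noise_sd))
  sp
}

#' Generate a dielectric spectra series during isothermal crystallization
#'
#' Spectrum k is taken at elapsed time `(k - 1) * interval`; its dielectric
#' strength decays with the crystallized fraction,
#' `delta_eps(t) = delta_eps * (1 - alpha(t))`, all other relaxation
#' parameters held fixed. Crystallization converts relaxing amorphous
#' material into a crystal that no longer contributes to the static
#' permittivity, which is what a time-dependent dielectric experiment tracks.
#'
#' @param truth A single-process [spectral_truth()].
#' @param kinetic A [kinetic_truth()] driving alpha(t).
#' @param interval Time between consecutive spectra, seconds (> 0).
#' @param n_spectra Number of spectra (>= 2).
#' @param seed Integer RNG seed.
#' @param frequency Frequency grid in Hz.
#' @param temperature Hold temperature in kelvin.
#' @return A `"spectra_series"` list of [dielectric_spectrum()] objects
#'   tagged with `elapsed_time`.
#' @export
gen_bds_crystallization_series <- function(truth, kinetic, interval = 300,
                                           n_spectra = 289, seed = 1,
                                           frequency = default_freq_grid(),
                                           temperature = 363) {
  if (interval <= 0) stop("amorphkin: `interval` must be > 0", call. = FALSE)
  if (n_spectra < 2) stop("amorphkin: need `n_spectra` >= 2", call. = FALSE)
  times <- (seq_len(n_spectra) - 1) * interval
  alph <- alpha_avrami(times, kinetic$n, kinetic$tau_cr, kinetic$t0)
  series <- .with_seed(seed, lapply(seq_len(n_spectra), function(k) {
    procs <- lapply(truth$processes, function(p) {
      p$delta_eps <- p$delta_eps * (1 - alph[k])
      p
    })
    ev <- .hn_eval(frequency, procs, truth$eps_inf, truth$sigma_dc)
    sp <- dielectric_spectrum(frequency, ev$eps_real, pmax(ev$eps_imag, 0),
                              temperature = temperature,
                              elapsed_time = times[k])
    .apply_spectrum_noise(sp, truth$noise_sd)
  }))
  structure(series, class = "spectra_series")
}

#' VFT parameter set
#'
#' Convenience container for Vogel-Fulcher-Tammann parameters
#' `tau(T) = tau_inf * exp(D * T0 / (T - T0))`. Supply either the strength
#' parameter `D` or the product `DT0` (in kelvin, as tabulated in dielectric
#' studies).
#'
#' @param log10_tau_inf log10 of the pre-exponential time in seconds.
#' @param T0 Vogel temperature in kelvin.
#' @param D Strength parameter (dimensionless).
#' @param DT0 Product D * T0 in kelvin.
#' @return An object of class `"vft_params"`.
#' @export
vft_params <- function(log10_tau_inf, T0, D = NULL, DT0 = NULL) {
  if (is.null(D) && is.null(DT0)) {
    stop("amorphkin: supply `D` or `DT0`", call. = FALSE)
  }
  if (is.null(D)) D <- DT0 / T0
  if (is.null(DT0)) DT0 <- D * T0
  stopifnot(T0 > 0, D > 0, abs(DT0 - D * T0) < 1e-9 * DT0)
  structure(list(log10_tau_inf = log10_tau_inf, T0 = T0, D = D, DT0 = DT0),
            class = "vft_params")
}

#' Evaluate a VFT law
#'
#' @param Temp Temperatures in kelvin, all > `vft$T0`.
#' @param vft A [vft_params()].
#' @return Relaxation times in seconds.
#' @export
tau_vft <- function(Temp, vft) {
  if (any(Temp <= vft$T0)) {
    stop("amorphkin: temperatures must exceed the Vogel temperature T0",
         call. = FALSE)
  }
  10^vft$log10_tau_inf * exp(vft$DT0 / (Temp - vft$T0))
}

#' Generate a temperature series of dielectric spectra
#'
#' The structural (alpha) relaxation time follows the supplied VFT law; the
#' peak relaxation time of the generated loss peak at each temperature equals
#' `tau_vft(T)`. Optional sub-Tg secondary processes (Cole-Cole shapes)
#' follow Arrhenius laws. With `shape = "kww"` the alpha loss peak is a
#' one-sided-Fourier-transform KWW curve with stretching exponent
#' `beta_kww` instead of an HN shape — useful for generating series whose
#' time-temperature-superposed master curve has an exactly known KWW shape.
#'
#' @param truth A [spectral_truth()]; the first process is the alpha process
#'   whose `tau_hn` is overridden by the VFT law (its shape parameters are
#'   kept).
#' @param vft A [vft_params()] for the alpha process.
#' @param temps Temperatures in kelvin (all > `vft$T0` when an alpha process
#'   is generated).
#' @param seed Integer RNG seed.
#' @param frequency Frequency grid in Hz.
#' @param shape `"hn"` (default) or `"kww"` for the alpha peak.
#' @param beta_kww KWW stretching exponent, required for `shape = "kww"`.
#' @param secondary Optional list of secondary processes, each a list with
#'   `delta_eps`, `a`, `log10_tau_inf`, `Ea_kJmol` (Arrhenius activation
#'   energy in kJ/mol).
#' @return A `"spectra_series"` tagged with `temperature`.
#' @export
gen_bds_temperature_series <- function(truth, vft, temps, seed = 1,
                                       frequency = default_freq_grid(),
                                       shape = c("hn", "kww"),
                                       beta_kww = NULL,
                                       secondary = NULL) {
  shape <- match.arg(shape)
  if (shape == "kww" && is.null(beta_kww)) {
    stop("amorphkin: `beta_kww` required for shape = 'kww'", call. = FALSE)
  }
  if (any(temps <= vft$T0)) {
    stop("amorphkin: temperatures must exceed the Vogel temperature T0",
         call. = FALSE)
  }
  R <- 8.314
  alpha_proc <- truth$processes[[1]]
  series <- .with_seed(seed, lapply(temps, function(Temp) {
    tmax <- tau_vft(Temp, vft)
    if (shape == "hn") {
      p <- alpha_proc
      # place the loss-peak maximum at 1/(2 pi tau_vft(T))
      p$tau_hn <- tmax *
        (sin(pi * p$a / (2 + 2 * p$b)))^(1 / p$a) *
        (sin(pi * p$a * p$b / (2 + 2 * p$b)))^(-1 / p$a)
      procs <- list(p)
      ev <- .hn_eval(frequency, procs, truth$eps_inf, truth$sigma_dc)
      er <- ev$eps_real
      ei <- ev$eps_imag
    } else {
      ei <- alpha_proc$delta_eps *
        kww_loss(2 * pi * frequency, tau_k = tmax, beta = beta_kww)
      er <- rep(truth$eps_inf, length(frequency))
      if (truth$sigma_dc > 0) {
        ei <- ei + truth$sigma_dc / (.EPS0 * 2 * pi * frequency)
      }
    }
    if (!is.null(secondary)) {
      for (s in secondary) {
        tau_s <- 10^s$log10_tau_inf * exp(s$Ea_kJmol * 1000 / (R * Temp))
        ev2 <- .hn_eval(frequency,
                        list(list(delta_eps = s$delta_eps, tau_hn = tau_s,
                                  a = s$a, b = 1)), 0, 0)
        er <- er + ev2$eps_real
        ei <- ei + ev2$eps_imag
      }
    }
    sp <- dielectric_spectrum(frequency, er, pmax(ei, 0), temperature = Temp)
    .apply_spectrum_noise(sp, truth$noise_sd)
  }))
  structure(series, class = "spectra_series")
}

#' Generate a heat-capacity-step composition table
#'
#' Emulates the Hempel loading-capacity experiment: the glass-transition
#' heat-capacity step of a drug / mesoporous-silica mixture is linear in the
#' drug load and extrapolates to zero at the load `w* = 100 - capacity`,
#' where the whole drug fraction is immobilized on the silica surface.
#' Below `w*` no glass transition is detectable and the step is zero.
#'
#' @param capacity_ms_wtpct Monomolecular loading capacity in wt.% of
#'   mesoporous silica, in (0, 100].
#' @param dcp_pure Heat-capacity step of the pure amorphous drug, J/(g K).
#' @param drug_loads Drug loads in wt.%, each in (0, 100].
#' @param noise_sd Relative (multiplicative log-normal) noise on the steps.
#' @param seed Integer RNG seed.
#' @return A data frame with columns `drug_load` (wt.%) and `delta_cp`
#'   (J/(g K)), class `c("dcp_table", "data.frame")`.
#' @examples
#' gen_dcp_table(84.3, dcp_pure = 0.4,
#'               drug_loads = c(50, 55, 64, 73, 82, 91, 100))
#' @export
gen_dcp_table <- function(capacity_ms_wtpct, dcp_pure = 0.4,
                          drug_loads = c(50, 55, 64, 73, 82, 91, 100),
                          noise_sd = 0, seed = 1) {
  if (capacity_ms_wtpct <= 0 || capacity_ms_wtpct > 100) {
    stop("amorphkin: capacity must lie in (0, 100]", call. = FALSE)
  }
  if (any(drug_loads <= 0 | drug_loads > 100)) {
    stop("amorphkin: drug loads must lie in (0, 100]", call. = FALSE)
  }
  wstar <- 100 - capacity_ms_wtpct
  dcp <- dcp_pure * pmax(drug_loads - wstar, 0) / (100 - wstar)
  if (noise_sd > 0) {
    dcp <- .with_seed(seed, dcp * exp(stats::rnorm(length(dcp), 0, noise_sd)))
  }
  structure(data.frame(drug_load = drug_loads, delta_cp = dcp),
            class = c("dcp_table", "data.frame"))
}
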