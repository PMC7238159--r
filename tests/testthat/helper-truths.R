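# Shared ground truths for the synthetic studies. Kinetic parameters follow
# the isothermal crystallization of supercooled simvastatin at 363 K
# (DSC and dielectric experiments); VFT parameters follow its structural
# relaxation.

# DSC experiment, neat drug: n = 3.8, tau_cr = 55 min, t0 = 8800 s
truth_dsc_neat <- function(noise_sd = 0) {
  kinetic_truth(n = 3.8, tau_cr = 55 * 60, t0 = 8800,
                total_enthalpy = 100, noise_sd = noise_sd)
}

# dielectric experiment, drug + large-particle silica:
# n = 1.026, tau_cr = 737 min, t0 = 29750 s
truth_bds_syl3050 <- function(noise_sd = 0) {
  kinetic_truth(n = 1.026, tau_cr = 737 * 60, t0 = 29750,
                total_enthalpy = 100, noise_sd = noise_sd)
}

# structural relaxation VFT parameter sets (log10 tau_inf, T0 / K, D*T0 / K)
vft_rows <- list(
  neat    = vft_params(-15.68, T0 = 244.01, DT0 = 2386),
  syl3050 = vft_params(-15.23, T0 = 246.23, DT0 = 2240),
  syl244  = vft_params(-15.18, T0 = 247.64, DT0 = 2183)
)

# single alpha-process spectral truth (dielectric strength of the neat drug)
truth_alpha_process <- function(noise_sd = 0, sigma_dc = 0) {
  spectral_truth(list(list(delta_eps = 8.9, tau_hn = 1e-3, a = 0.8, b = 0.6)),
                 eps_inf = 3, sigma_dc = sigma_dc, noise_sd = noise_sd)
}

# multiplicative heat-flow noise at a relative level, applied on top of a
# noiseless generated thermogram
add_mult_noise <- function(tg, rel_sd, seed) {
  set.seed(seed)
  tg$heat_flow <- tg$heat_flow * exp(stats::rnorm(length(tg$heat_flow), 0, rel_sd))
  tg
}
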