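#' Isothermal DSC thermogram
#'
#' Container for a sampled heat-flow trace recorded at constant temperature.
#' Heat flow is stored with the exothermic direction positive, so that the
#' crystallization exotherm integrates to a positive enthalpy; readers for
#' instruments using the opposite convention can negate on import (see
#' [read_thermogram()]).
#'
#' @param time Numeric vector of sampling times in seconds, strictly
#'   increasing.
#' @param heat_flow Numeric vector of heat evolution rate dH/dt in mW, same
#'   length as `time`.
#' @param temperature Hold temperature in kelvin (scalar, > 0).
#' @param label Free-text sample label.
#'
#' @return An object of class `"thermogram"`: a list with fields `time`,
#'   `heat_flow`, `temperature`, `label`.
#' @examples
#' tg <- thermogram(time = 0:10, heat_flow = dnorm(0:10, 5, 2), temperature = 363)
#' print(tg)
#' @export
thermogram <- function(time, heat_flow, temperature = 363, label = "") {
  time <- as.numeric(time)
  heat_flow <- as.numeric(heat_flow)
  if (length(time) != length(heat_flow)) {
    stop("amorphkin: `time` and `heat_flow` must have equal length", call. = FALSE)
  }
  if (length(time) == 0L) stop("amorphkin: empty thermogram", call. = FALSE)
  if (any(!is.finite(time)) || any(!is.finite(heat_flow))) {
    stop("amorphkin: non-finite values in thermogram", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("amorphkin: `time` must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0) {
    stop("amorphkin: `temperature` must be a single positive kelvin value", call. = FALSE)
  }
  structure(
    list(time = time, heat_flow = heat_flow,
         temperature = as.numeric(temperature), label = as.character(label)),
    class = "thermogram"
  )
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %d points, t = [%g, %g] s, T = %g K%s\n",
              length(x$time), x$time[1], x$time[length(x$time)], x$temperature,
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}

#' Complex dielectric permittivity spectrum
#'
#' One broadband dielectric spectrum, epsilon*(omega) = eps' - i eps'',
#' sampled on a strictly increasing frequency grid, tagged either with the
#' measurement temperature or (for time-dependent crystallization runs) the
#' elapsed time of the isothermal hold.
#'
#' @param frequency Frequencies in Hz, strictly increasing, all > 0.
#' @param eps_real Real part eps' (dimensionless), same length as `frequency`.
#' @param eps_imag Imaginary (loss) part eps'' >= 0, same length.
#' @param temperature Temperature in kelvin.
#' @param elapsed_time Optional elapsed time in seconds since the start of an
#'   isothermal hold (`NA` for pure temperature scans).
#'
#' @return An object of class `"dielectric_spectrum"`.
#' @export
dielectric_spectrum <- function(frequency, eps_real, eps_imag,
                                temperature = NA_real_, elapsed_time = NA_real_) {
  frequency <- as.numeric(frequency)
  eps_real <- as.numeric(eps_real)
  eps_imag <- as.numeric(eps_imag)
  n <- length(frequency)
  if (length(eps_real) != n || length(eps_imag) != n) {
    stop("amorphkin: frequency, eps_real, eps_imag must have equal length", call. = FALSE)
  }
  if (n == 0L) stop("amorphkin: empty spectrum", call. = FALSE)
  if (any(frequency <= 0)) stop("amorphkin: frequencies must be > 0", call. = FALSE)
  if (any(diff(frequency) <= 0)) {
    stop("amorphkin: frequency grid must be strictly increasing", call. = FALSE)
  }
  if (any(eps_imag < 0)) stop("amorphkin: eps_imag must be >= 0", call. = FALSE)
  structure(
    list(frequency = frequency, eps_real = eps_real, eps_imag = eps_imag,
         temperature = as.numeric(temperature),
         elapsed_time = as.numeric(elapsed_time)),
    class = "dielectric_spectrum"
  )
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  tag <- if (!is.na(x$elapsed_time)) sprintf("t = %g s", x$elapsed_time)
         else sprintf("T = %g K", x$temperature)
  cat(sprintf("<dielectric_spectrum> %d points, f = [%g, %g] Hz, %s\n",
              length(x$frequency), min(x$frequency), max(x$frequency), tag))
  invisible(x)
}

#' Relative crystallinity curve
#'
#' Relative degree of crystallization alpha(t) in \[0, 1\] versus time,
#' derived either from the DSC exotherm (normalized cumulative heat) or from
#' the normalized decay of the static dielectric permittivity. `t0` records
#' the induction time once it has been determined; raw curves carry `t0 = 0`.
#'
#' @param time Times in seconds.
#' @param alpha Relative crystallinity; values outside \[0, 1\] by more than
#'   `clip_tol` are rejected, smaller excursions are clipped.
#' @param t0 Induction time in seconds (>= 0).
#' @param source `"DSC"` or `"BDS"`.
#' @param clip_tol Tolerance for clipping alpha to \[0, 1\].
#'
#' @return An object of class `"kinetic_curve"`.
#' @export
kinetic_curve <- function(time, alpha, t0 = 0, source = c("DSC", "BDS"),
                          clip_tol = 1e-9) {
  source <- match.arg(source)
  time <- as.numeric(time)
  alpha <- as.numeric(alpha)
  if (length(time) != length(alpha)) {
    stop("amorphkin: `time` and `alpha` must have equal length", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("amorphkin: `time` must be strictly increasing", call. = FALSE)
  }
  if (any(alpha < -clip_tol) || any(alpha > 1 + clip_tol)) {
    stop("amorphkin: `alpha` outside [0, 1] beyond clipping tolerance", call. = FALSE)
  }
  alpha <- pmin(pmax(alpha, 0), 1)
  if (t0 < 0) stop("amorphkin: `t0` must be >= 0", call. = FALSE)
  structure(
    list(time = time, alpha = alpha, t0 = as.numeric(t0), source = source),
    class = "kinetic_curve"
  )
}

#' @export
print.kinetic_curve <- function(x, ...) {
  cat(sprintf("<kinetic_curve> [%s] %d points, alpha in [%.3f, %.3f], t0 = %g s\n",
              x$source, length(x$time), min(x$alpha), max(x$alpha), x$t0))
  invisible(x)
}

#' Characteristic nucleation-and-growth scales
#'
#' From the nucleation rate N (dimension L^-3 t^-1) and linear crystal growth
#' rate V (L t^-1), dimensional analysis of three-dimensional nucleation gives
#' a characteristic time t0 = (N V^3)^(-1/4) and a characteristic size
#' xi = (V / N)^(1/4). The competition between xi and the macroscopic sample
#' size controls the kinetic regime of crystallization in confined geometries.
#'
#' @param N Nucleation rate, > 0.
#' @param V Linear growth rate, > 0.
#' @return An object of class `"nucleation_scales"` with fields `N`, `V`,
#'   `t0_char`, `xi`.
#' @examples
#' nucleation_scales(N = 16, V = 1) # t0_char = 0.5, xi = 0.5
#' @export
nucleation_scales <- function(N, V) {
  if (!is.numeric(N) || N <= 0 || !is.numeric(V) || V <= 0) {
    stop("amorphkin: N and V must be positive", call. = FALSE)
  }
  structure(
    list(N = N, V = V,
         t0_char = (N * V^3)^(-1 / 4),
         xi = (V / N)^(1 / 4)),
    class = "nucleation_scales"
  )
}

#' @export
print.nucleation_scales <- function(x, ...) {
  cat(sprintf("<nucleation_scales> N = %g, V = %g -> t0 = %g, xi = %g\n",
              x$N, x$V, x$t0_char, x$xi))
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles the numerical knobs shared by the kinetics stages. Defaults follow
#' the package's standard Avramov construction: an 11-point quadratic
#' Savitzky-Golay window for the ln-time derivative, an induction-time target
#' of alpha = 1 - 1/e at the inflection with tolerance 0.005.
#'
#' @param sg_window Odd integer >= 5, Savitzky-Golay window length (points on
#'   the resampled ln-time grid) applied to alpha before differencing.
#' @param sg_order Polynomial order of the smoothing window.
#' @param ln_grid_n Number of points of the uniform ln(t - t0) resampling grid.
#' @param deriv_span Span (in ln-time units) of the Richardson-extrapolated
#'   central differences that estimate d alpha / d ln(t - t0).
#' @param peak_window Half-width (ln-time units) of the window of the
#'   iterated local-quadratic fit that locates the derivative maximum.
#' @param t0_tol Tolerance on alpha at the inflection for the induction-time
#'   bisection, in (0, 0.1).
#' @param f_track Tracking frequency in Hz at which eps'(t) is read off for
#'   the dielectric kinetics branch.
#' @param seed Integer seed forwarded to stochastic routines.
#'
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(sg_window = 11L, sg_order = 2L, ln_grid_n = 801L,
                         deriv_span = 0.2, peak_window = 0.15,
                         t0_tol = 0.005, f_track = 1e5, seed = 1L) {
  sg_window <- as.integer(sg_window)
  if (sg_window < 5L || sg_window %% 2L == 0L) {
    stop("amorphkin: `sg_window` must be an odd integer >= 5", call. = FALSE)
  }
  if (t0_tol <= 0 || t0_tol >= 0.1) {
    stop("amorphkin: `t0_tol` must lie in (0, 0.1)", call. = FALSE)
  }
  if (sg_order < 1L || sg_order >= sg_window) {
    stop("amorphkin: `sg_order` must satisfy 1 <= order < window", call. = FALSE)
  }
  if (deriv_span <= 0 || peak_window <= 0) {
    stop("amorphkin: `deriv_span` and `peak_window` must be > 0", call. = FALSE)
  }
  structure(
    list(sg_window = sg_window, sg_order = as.integer(sg_order),
         ln_grid_n = as.integer(ln_grid_n), deriv_span = deriv_span,
         peak_window = peak_window, t0_tol = t0_tol,
         f_track = f_track, seed = as.integer(seed)),
    class = "study_config"
  )
}
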