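# Kohlrausch-Williams-Watts loss curves and time-temperature-superposition
# master plots. The KWW loss is the one-sided Fourier (sine) transform of
# the negative time derivative of the stretched-exponential correlation
# function phi(t) = exp(-(t/tau_k)^beta):
#   eps''(omega) proportional to  Int_0^inf (-dphi/dt) sin(omega t) dt.

# 10-point Gauss-Legendre nodes/weights on [-1, 1]
.GL10 <- local({
  x <- c(-0.9739065285171717, -0.8650633666889845, -0.6794095682990244,
         -0.4333953941292472, -0.1488743389816312)
  w <- c(0.0666713443086881, 0.1494513491505806, 0.2190863625159820,
         0.2692667193099963, 0.2955242247147529)
  list(x = c(x, -rev(x)), w = c(w, rev(w)))
})

# Int_0^inf beta u^(beta-1) exp(-u^beta) sin(c u) du  for a scalar c > 0.
# The u -> w = u^beta substitution removes the u^(beta-1) singularity:
#   Int_0^inf exp(-w) sin(c w^(1/beta)) dw.
# For slowly oscillating integrands (few sine zeros inside the decay range)
# this is evaluated directly by adaptive quadrature; otherwise integration
# proceeds between consecutive zeros of sin(c u) (Longman's method) with
# 10-point Gauss per half-period and repeated averaging of the alternating
# partial sums.
.kww_sine_integral <- function(c, beta, rel_tol = 1e-10) {
  u_cut <- (-log(1e-16))^(1 / beta)
  n_zero <- floor(c * u_cut / pi)
  if (n_zero < 8) {
    w_cut <- -log(.Machine$double.xmin) * 0.9
    return(stats::integrate(function(w) exp(-w) * sin(c * w^(1 / beta)),
                            0, w_cut, rel.tol = rel_tol, abs.tol = 0,
                            subdivisions = 400L)$value)
  }
  half <- pi / c
  # first half-period via the w-substitution (handles the u -> 0 behavior)
  s0 <- stats::integrate(function(w) exp(-w) * sin(c * w^(1 / beta)),
                         0, half^beta, rel.tol = rel_tol, abs.tol = 0,
                         subdivisions = 200L)$value
  K <- min(n_zero - 1L, 400L)
  lefts <- half * seq_len(K)
  hw <- half / 2
  centers <- lefts + hw
  u <- rep(centers, each = 10L) + hw * rep(.GL10$x, times = K)
  g <- beta * u^(beta - 1) * exp(-u^beta) * sin(c * u)
  terms <- hw * colSums(matrix(.GL10$w * g, nrow = 10L))
  partial <- s0 + cumsum(terms)
  if (K < n_zero - 1L) {
    # truncated before natural decay: accelerate the alternating tail
    m <- min(30L, K)
    a <- partial[(K - m + 1L):K]
    while (length(a) > 1L) a <- (a[-1L] + a[-length(a)]) / 2
    return(a)
  }
  partial[K]
}

#' Normalized KWW dielectric loss curve
#'
#' Evaluates the loss spectrum of the stretched-exponential relaxation
#' function on an angular-frequency grid and normalizes it to unit peak
#' height. For `beta = 1` this is the Debye loss
#' `omega tau / (1 + (omega tau)^2)` (normalized); smaller `beta` broadens
#' the peak, mostly on its high-frequency flank.
#'
#' @param omega Angular frequencies in rad/s, > 0.
#' @param tau_k KWW relaxation time in seconds.
#' @param beta Stretching exponent in (0, 1].
#' @param rel_tol Quadrature relative tolerance.
#' @return Normalized eps''(omega), unit peak on the grid.
#' @examples
#' w <- 10^seq(-3, 3, by = 0.05)
#' plot(w, kww_loss(w, 1, 0.6), log = "x", type = "l")
#' @export
kww_loss <- function(omega, tau_k = 1, beta = 0.6, rel_tol = 1e-10) {
  if (beta <= 0 || beta > 1) stop("amorphkin: beta must lie in (0, 1]", call. = FALSE)
  if (any(omega <= 0)) stop("amorphkin: omega must be > 0", call. = FALSE)
  vals <- vapply(omega * tau_k, .kww_sine_integral, numeric(1),
                 beta = beta, rel_tol = rel_tol)
  vals / max(vals)
}

#' Build a time-temperature-superposition master plot
#'
#' Normalizes each loss spectrum by its peak (eps''/eps''_max versus
#' log10 f) and shifts it horizontally to superimpose on the spectrum at the
#' reference temperature; vertical shifts are not allowed. Spectra are
#' processed from the nearest temperature outward, each shifted by
#' golden-section minimization of the squared log-loss mismatch against the
#' merged curve accumulated so far, then pooled. A temperature-invariant
#' peak shape (time-temperature superposition) makes the pooled points
#' collapse onto a single curve whose shifts equal
#' `log10(tau(T) / tau(T_ref))`.
#'
#' @param series A `"spectra_series"` tagged with temperature (>= 3
#'   spectra).
#' @param T_ref Reference temperature in kelvin; must match one spectrum
#'   within 0.5 K.
#' @param search_halfwidth Half-width (decades) of the shift search window
#'   around the peak-alignment guess.
#' @return An object of class `"master_plot"`: `shifts` (decades, named by
#'   temperature; 0 at the reference), `curve` (data frame
#'   `log_f_over_fmax`, `loss_norm`, `temperature`), `f_peak_ref` (Hz),
#'   `T_ref`.
#' @export
build_master_plot <- function(series, T_ref, search_halfwidth = 1) {
  stopifnot(length(series) >= 3)
  temps <- vapply(series, `[[`, 1, "temperature")
  if (any(is.na(temps))) stop("amorphkin: series lacks temperature tags", call. = FALSE)
  iref <- which.min(abs(temps - T_ref))
  if (abs(temps[iref] - T_ref) > 0.5) {
    stop("amorphkin: no spectrum at the reference temperature ", T_ref, " K",
         call. = FALSE)
  }
  norm_curve <- function(sp) {
    y <- sp$eps_imag
    ly <- log10(pmax(y, .Machine$double.xmin))
    lf <- log10(sp$frequency)
    # parabolic refinement when the loss maximum is interior; otherwise the
    # grid maximum (peak outside the window - only the flank is usable)
    pk <- tryCatch(.parabolic_peak(lf, ly),
                   error = function(e) {
                     i <- which.max(ly)
                     list(x = lf[i], y = ly[i])
                   })
    list(x = lf, y = ly - pk$y, fpk = 10^pk$x)
  }
  curves <- lapply(series, norm_curve)
  ref <- curves[[iref]]
  pool_x <- ref$x
  pool_y <- ref$y
  shifts <- numeric(length(series))
  shifts[iref] <- 0
  ord <- order(abs(temps - temps[iref]))
  for (i in ord) {
    if (i == iref) next
    cv <- curves[[i]]
    s0 <- log10(ref$fpk / cv$fpk)
    obj <- function(s) {
      xs <- cv$x + s
      o <- order(pool_x)
      yhat <- stats::approx(pool_x[o], pool_y[o], xout = xs)$y
      ok <- !is.na(yhat)
      if (sum(ok) < 3) return(1e6)
      mean((cv$y[ok] - yhat[ok])^2)
    }
    opt <- stats::optimize(obj, c(s0 - search_halfwidth, s0 + search_halfwidth),
                           tol = 1e-6)
    if (opt$objective >= 1e6) {
      stop("amorphkin: spectrum at ", temps[i],
           " K has no overlap with the master curve after shifting", call. = FALSE)
    }
    shifts[i] <- opt$minimum
    pool_x <- c(pool_x, cv$x + opt$minimum)
    pool_y <- c(pool_y, cv$y)
  }
  o <- order(temps)
  curve <- do.call(rbind, lapply(seq_along(series), function(i) {
    cv <- curves[[i]]
    data.frame(log_f_over_fmax = cv$x + shifts[i] - log10(ref$fpk),
               loss_norm = 10^cv$y, temperature = temps[i])
  }))
  curve <- curve[order(curve$log_f_over_fmax), , drop = FALSE]
  structure(
    list(shifts = stats::setNames(shifts[o], temps[o]),
         curve = curve, f_peak_ref = ref$fpk, T_ref = temps[iref]),
    class = "master_plot"
  )
}

#' @export
print.master_plot <- function(x, ...) {
  cat(sprintf("<master_plot> %d spectra superposed on T_ref = %g K (f_peak = %.3g Hz)\n",
              length(x$shifts), x$T_ref, x$f_peak_ref))
  cat("  shifts [decades]:\n")
  print(round(x$shifts, 3))
  invisible(x)
}

#' @export
plot.master_plot <- function(x, ...) {
  graphics::plot(x$curve$log_f_over_fmax, x$curve$loss_norm, log = "y",
                 xlab = expression(log[10](f / f[max])),
                 ylab = expression(epsilon * "''" / epsilon[max] * "''"), ...)
  invisible(x)
}

#' Fit the KWW shape to a master curve
#'
#' Least squares of the normalized KWW loss over (beta, tau) against the
#' merged master curve, on log10 of the normalized loss. Points with a
#' normalized loss below `floor` are excluded (far wings, where
#' conductivity or secondary processes would dominate real data).
#'
#' @param master A `"master_plot"`.
#' @param floor Lower cut on the normalized loss.
#' @param beta_init,beta_lower,beta_upper Initial value and box for beta.
#' @return An object of class `"kww_fit"`: `beta_kww`, `tau_kww` (seconds,
#'   at the reference temperature), `T_ref`, `shifts`, `residual_norm`,
#'   `se` (approximate standard errors for beta and log10 tau).
#' @export
fit_kww <- function(master, floor = 5e-3, beta_init = 0.7,
                    beta_lower = 0.2, beta_upper = 1) {
  stopifnot(inherits(master, "master_plot"))
  keep <- master$curve$loss_norm >= floor
  x <- master$curve$log_f_over_fmax[keep]  # log10 (f / f_max,ref)
  y <- log10(master$curve$loss_norm[keep])
  if (diff(range(x)) < 2) {
    stop("amorphkin: master curve must span at least two decades", call. = FALSE)
  }
  # reduced frequency: fn = f / f_max; model tau in reduced time units
  resid_fn <- function(par) {
    beta <- par[1]
    tau_red <- 10^par[2]
    m <- kww_loss(2 * pi * 10^x, tau_k = tau_red, beta = beta, rel_tol = 1e-8)
    log10(pmax(m, .Machine$double.xmin)) - y
  }
  fit <- minpack.lm::nls.lm(par = c(beta_init, log10(1 / (2 * pi))),
                            lower = c(beta_lower, -4), upper = c(beta_upper, 4),
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 9)) {
    stop("amorphkin: KWW fit did not converge", call. = FALSE)
  }
  se <- tryCatch(as.numeric(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) rep(NA_real_, 2))
  structure(
    list(beta_kww = fit$par[1],
         tau_kww = 10^fit$par[2] / master$f_peak_ref,
         T_ref = master$T_ref,
         shifts = master$shifts,
         residual_norm = sqrt(sum(fit$fvec^2)),
         se = stats::setNames(se, c("beta_kww", "log10_tau_red"))),
    class = "kww_fit"
  )
}

#' @export
print.kww_fit <- function(x, ...) {
  cat(sprintf("KWW fit at T_ref = %g K: beta_KWW = %.3f (se %.3g), tau_KWW = %.4g s\n",
              x$T_ref, x$beta_kww, x$se[1], x$tau_kww))
  invisible(x)
}

#' @export
coef.kww_fit <- function(object, ...) {
  c(beta_kww = object$beta_kww, tau_kww = object$tau_kww)
}
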