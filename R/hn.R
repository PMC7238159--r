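# Havriliak-Negami / Cole-Cole deconvolution of broadband dielectric
# spectra. The model for P processes plus dc conductivity is
#   eps*(omega) = eps_inf + sum_p  d_eps_p / (1 + (i omega tau_p)^a_p)^b_p
#                 + sigma_dc / (eps0 i omega),
# with eps*(omega) = eps' - i eps''. a and b are the symmetric and
# asymmetric broadening exponents; b = 1 is the (symmetric) Cole-Cole case
# and a = b = 1 the Debye case.

# vacuum permittivity, F/m
.EPS0 <- 8.8541878128e-12

.hn_eval <- function(frequency, processes, eps_inf, sigma_dc) {
  omega <- 2 * pi * frequency
  eps <- complex(real = rep(eps_inf, length(omega)), imaginary = 0)
  for (p in processes) {
    eps <- eps + p$delta_eps / (1 + (1i * omega * p$tau_hn)^p$a)^p$b
  }
  ei <- -Im(eps)
  if (sigma_dc > 0) ei <- ei + sigma_dc / (.EPS0 * omega)
  list(eps_real = Re(eps), eps_imag = ei)
}

#' Evaluate the Havriliak-Negami model
#'
#' Computes eps'(f) and eps''(f) for a sum of HN processes plus an ohmic
#' dc-conductivity term (which contributes `sigma_dc / (eps0 * 2 pi f)` to
#' the loss only).
#'
#' @param frequency Frequencies in Hz, > 0.
#' @param processes List of processes: each a list with `delta_eps`,
#'   `tau_hn` (s), `a`, `b`.
#' @param eps_inf High-frequency limit permittivity.
#' @param sigma_dc dc conductivity in S/m.
#' @return A list with numeric vectors `eps_real` and `eps_imag`.
#' @examples
#' f <- default_freq_grid()
#' m <- hn_model(f, list(list(delta_eps = 8.9, tau_hn = 1e-4, a = 0.8, b = 0.6)),
#'               eps_inf = 3, sigma_dc = 0)
#' @export
hn_model <- function(frequency, processes, eps_inf = 0, sigma_dc = 0) {
  if (any(frequency <= 0)) stop("amorphkin: frequencies must be > 0", call. = FALSE)
  for (p in processes) {
    stopifnot(p$delta_eps >= 0, p$tau_hn > 0, p$a > 0, p$a <= 1, p$b > 0, p$b <= 1)
  }
  .hn_eval(frequency, processes, eps_inf, sigma_dc)
}

#' Loss-peak relaxation time of an HN process
#'
#' Closed form for the relaxation time at the maximum of the single-process
#' dielectric loss,
#' `tau_max = tau_hn * sin(pi a / (2 + 2 b))^(-1/a) * sin(pi a b / (2 + 2 b))^(1/a)`.
#' For a Cole-Cole process (b = 1) and a Debye process (a = b = 1) this
#' reduces to `tau_max = tau_hn`. This is the structural relaxation time
#' tau_alpha reported from loss-spectrum fits.
#'
#' @param p A process: list with `tau_hn`, `a`, `b`.
#' @return tau_max in seconds.
#' @examples
#' tau_max_from_hn(list(tau_hn = 1, a = 0.8, b = 0.6))
#' @export
tau_max_from_hn <- function(p) {
  stopifnot(p$tau_hn > 0, p$a > 0, p$a <= 1, p$b > 0, p$b <= 1)
  p$tau_hn * sin(pi * p$a / (2 + 2 * p$b))^(-1 / p$a) *
    sin(pi * p$a * p$b / (2 + 2 * p$b))^(1 / p$a)
}

# crude loss-peak finder: indices of the k largest interior local maxima of
# log eps''; falls back to log-spaced positions when fewer are resolvable
.find_loss_peaks <- function(spectrum, k) {
  y <- log10(pmax(spectrum$eps_imag, .Machine$double.xmin))
  n <- length(y)
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(loc) >= k) {
    loc <- loc[order(y[loc], decreasing = TRUE)][seq_len(k)]
  } else {
    extra <- round(seq(n * 0.25, n * 0.75, length.out = k - length(loc)))
    loc <- c(loc, extra)
  }
  sort(loc)
}

.hn_pack <- function(procs, eps_inf, sigma_dc, include_conductivity, fix_b) {
  par <- c()
  for (p in procs) {
    par <- c(par, log10(p$delta_eps), log10(p$tau_hn), p$a,
             if (!fix_b) p$b)
  }
  par <- c(par, eps_inf)
  if (include_conductivity) par <- c(par, log10(max(sigma_dc, 1e-16)))
  par
}

.hn_unpack <- function(par, n_processes, include_conductivity, fix_b) {
  per <- if (fix_b) 3L else 4L
  procs <- vector("list", n_processes)
  for (j in seq_len(n_processes)) {
    o <- (j - 1L) * per
    procs[[j]] <- list(delta_eps = 10^par[o + 1], tau_hn = 10^par[o + 2],
                       a = par[o + 3], b = if (fix_b) 1 else par[o + 4])
  }
  eps_inf <- par[n_processes * per + 1L]
  sigma_dc <- if (include_conductivity) 10^par[n_processes * per + 2L] else 0
  list(processes = procs, eps_inf = eps_inf, sigma_dc = sigma_dc)
}

#' Fit the Havriliak-Negami model to a dielectric spectrum
#'
#' Least squares on log10 eps'' over the log-frequency grid (uniform
#' weights), optionally jointly with relative residuals on eps'. The fit is
#' restarted from several randomized initial points; the best residual wins,
#' ties broken by the smaller parameter-vector norm. Internal parameters are
#' log10(delta_eps) and log10(tau_hn) with box constraints on all shape
#' parameters.
#'
#' @param spectrum A [dielectric_spectrum()] covering the loss peak(s).
#' @param n_processes Number of HN processes.
#' @param include_conductivity Add the ohmic dc-conductivity term.
#' @param fit_real Also fit eps' (joint objective).
#' @param init Optional initial guess: list with `processes` (list of
#'   `delta_eps`, `tau_hn`, `a`, `b`), `eps_inf`, `sigma_dc`.
#' @param lower,upper Optional named bounds overrides, as lists with
#'   elements `a`, `b`, `log10_tau`, `log10_delta_eps`, `eps_inf`,
#'   `log10_sigma` (each a length-2 range is not needed; `lower` and
#'   `upper` each carry scalars).
#' @param n_starts Number of randomized restarts.
#' @param seed RNG seed for the restarts.
#' @param fix_b Fix all asymmetric exponents b at 1 (Cole-Cole fit).
#' @param max_restart_error Error when no start converges.
#' @return An object of class `"hn_fit"`: `processes` (each with added
#'   `tau_max`), `eps_inf`, `sigma_dc`, `residual_norm`, `se` (approximate
#'   standard errors, `NA` when the Jacobian is singular), `degenerate`
#'   (logical per process: dielectric strength collapsed), plus the data.
#'   Processes are ordered by decreasing `tau_max` (slow first).
#' @export
fit_hn <- function(spectrum, n_processes = 1, include_conductivity = FALSE,
                   fit_real = FALSE, init = NULL, lower = NULL, upper = NULL,
                   n_starts = 8, seed = 1, fix_b = FALSE,
                   max_restart_error = TRUE) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  f <- spectrum$frequency
  y_imag <- log10(pmax(spectrum$eps_imag, .Machine$double.xmin))
  per <- if (fix_b) 3L else 4L
  np <- n_processes * per + 1L + as.integer(include_conductivity)

  lo_def <- list(log10_delta_eps = -4, log10_tau = -12, a = 0.05, b = 0.05,
                 eps_inf = 1, log10_sigma = -16)
  hi_def <- list(log10_delta_eps = 4, log10_tau = 6, a = 1, b = 1,
                 eps_inf = 100, log10_sigma = 2)
  for (nm in names(lower)) lo_def[[nm]] <- lower[[nm]]
  for (nm in names(upper)) hi_def[[nm]] <- upper[[nm]]
  lo <- c(rep(c(lo_def$log10_delta_eps, lo_def$log10_tau, lo_def$a,
                if (!fix_b) lo_def$b), n_processes), lo_def$eps_inf,
          if (include_conductivity) lo_def$log10_sigma)
  hi <- c(rep(c(hi_def$log10_delta_eps, hi_def$log10_tau, hi_def$a,
                if (!fix_b) hi_def$b), n_processes), hi_def$eps_inf,
          if (include_conductivity) hi_def$log10_sigma)

  resid_fn <- function(par) {
    m <- .hn_unpack(par, n_processes, include_conductivity, fix_b)
    ev <- .hn_eval(f, m$processes, m$eps_inf, m$sigma_dc)
    r <- log10(pmax(ev$eps_imag, .Machine$double.xmin)) - y_imag
    if (fit_real) r <- c(r, (ev$eps_real - spectrum$eps_real) /
                           pmax(abs(spectrum$eps_real), 1e-6))
    r
  }

  if (is.null(init)) {
    pk <- .find_loss_peaks(spectrum, n_processes)
    height <- max(spectrum$eps_imag)
    init <- list(
      processes = lapply(pk, function(i) {
        list(delta_eps = max(2 * spectrum$eps_imag[i], 1e-3),
             tau_hn = 1 / (2 * pi * f[i]), a = 0.8, b = if (fix_b) 1 else 0.8)
      }),
      eps_inf = max(min(spectrum$eps_real), 1),
      sigma_dc = if (include_conductivity)
        max(spectrum$eps_imag[1] * .EPS0 * 2 * pi * f[1] * 0.5, 1e-15) else 0)
    init$processes <- init$processes[order(-vapply(init$processes,
                                                   `[[`, 1, "tau_hn"))]
  }
  p0 <- .hn_pack(init$processes, init$eps_inf, init$sigma_dc,
                 include_conductivity, fix_b)
  p0 <- pmin(pmax(p0, lo), hi)

  best <- NULL
  .with_seed(seed, {
    for (s in seq_len(n_starts)) {
      ps <- if (s == 1L) p0 else {
        pert <- p0 + stats::rnorm(np, 0, c(rep(c(0.3, 0.7, 0.1, if (!fix_b) 0.1),
                                               n_processes), 0.2,
                                           if (include_conductivity) 0.5))
        pmin(pmax(pert, lo), hi)
      }
      fit <- tryCatch(
        minpack.lm::nls.lm(par = ps, lower = lo, upper = hi, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 400)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rn <- sqrt(sum(fit$fvec^2))
      if (is.null(best) || rn < best$rn - 1e-12 ||
          (abs(rn - best$rn) <= 1e-12 &&
           sum(fit$par^2) < sum(best$fit$par^2))) {
        best <- list(fit = fit, rn = rn)
      }
    }
  })
  if (is.null(best)) {
    if (max_restart_error) {
      stop("amorphkin: HN fit failed to converge from any start", call. = FALSE)
    }
    return(NULL)
  }
  fit <- best$fit
  m <- .hn_unpack(fit$par, n_processes, include_conductivity, fix_b)
  m$processes <- lapply(m$processes, function(p) {
    p$tau_max <- tau_max_from_hn(p)
    p
  })
  ord <- order(-vapply(m$processes, `[[`, 1, "tau_max"))
  m$processes <- m$processes[ord]
  se <- tryCatch({
    cv <- summary(fit)$coefficients[, "Std. Error"]
    as.numeric(cv)
  }, error = function(e) rep(NA_real_, np))
  # degenerate processes: collapsed dielectric strength, or a pair of
  # processes whose peak times are closer than half a decade (unresolved
  # splitting of a single feature) - the weaker of such a pair is flagged
  total <- sum(vapply(m$processes, `[[`, 1, "delta_eps"))
  degen <- vapply(m$processes, function(p) p$delta_eps < 0.01 * total,
                  logical(1))
  if (length(m$processes) > 1L) {
    ltau <- log10(vapply(m$processes, `[[`, 1, "tau_max"))
    dstr <- vapply(m$processes, `[[`, 1, "delta_eps")
    for (i in seq_along(ltau)[-1]) {
      for (j in seq_len(i - 1L)) {
        if (abs(ltau[i] - ltau[j]) < 0.5) {
          k <- if (dstr[i] < dstr[j]) i else j
          degen[k] <- TRUE
        }
      }
    }
  }
  structure(
    list(processes = m$processes, eps_inf = m$eps_inf, sigma_dc = m$sigma_dc,
         residual_norm = best$rn, se = se, degenerate = degen,
         include_conductivity = include_conductivity, fix_b = fix_b,
         spectrum = spectrum, niter = fit$niter),
    class = "hn_fit"
  )
}

#' Fit two Cole-Cole processes to a sub-Tg spectrum
#'
#' Below the glass transition the spectra show two local secondary
#' relaxations (beta, slower; gamma, faster); both are symmetric, so each is
#' fitted with a Cole-Cole shape (HN with b fixed at 1). Conductivity is off
#' by default, as ionic transport is frozen in the glass. Output processes
#' are ordered slow-to-fast, so `processes[[1]]` is beta and
#' `processes[[2]]` is gamma.
#'
#' @param spectrum A [dielectric_spectrum()] with two resolvable loss
#'   features.
#' @param n_processes Number of Cole-Cole processes (default 2).
#' @param include_conductivity Usually `FALSE` below Tg.
#' @param ... Passed to [fit_hn()] (`init`, bounds, `n_starts`, `seed`).
#' @return An `"hn_fit"` with all `b = 1`.
#' @export
fit_secondary_cole_cole <- function(spectrum, n_processes = 2,
                                    include_conductivity = FALSE, ...) {
  fit_hn(spectrum, n_processes = n_processes,
         include_conductivity = include_conductivity, fix_b = TRUE, ...)
}

#' Dielectric strength of a fitted process
#'
#' @param fit An `"hn_fit"`.
#' @param index Process index (slow-to-fast ordering).
#' @return delta_eps of that process.
#' @export
dielectric_strength <- function(fit, index = 1) {
  stopifnot(inherits(fit, "hn_fit"))
  if (index < 1 || index > length(fit$processes)) {
    stop("amorphkin: process index out of range", call. = FALSE)
  }
  fit$processes[[index]]$delta_eps
}

#' @export
print.hn_fit <- function(x, ...) {
  kind <- if (x$fix_b) "Cole-Cole" else "Havriliak-Negami"
  cat(sprintf("%s fit: %d process(es), residual norm %.3g\n",
              kind, length(x$processes), x$residual_norm))
  for (j in seq_along(x$processes)) {
    p <- x$processes[[j]]
    cat(sprintf("  [%d] delta_eps = %.4g, tau_HN = %.4g s (tau_max = %.4g s), a = %.3f, b = %.3f%s\n",
                j, p$delta_eps, p$tau_hn, p$tau_max, p$a, p$b,
                if (x$degenerate[j]) "  [degenerate]" else ""))
  }
  cat(sprintf("  eps_inf = %.4g", x$eps_inf))
  if (x$include_conductivity) cat(sprintf(", sigma_dc = %.4g S/m", x$sigma_dc))
  cat("\n")
  invisible(x)
}

#' @export
coef.hn_fit <- function(object, ...) {
  out <- c()
  for (j in seq_along(object$processes)) {
    p <- object$processes[[j]]
    v <- c(p$delta_eps, p$tau_hn, p$a, p$b, p$tau_max)
    names(v) <- paste0(c("delta_eps", "tau_hn", "a", "b", "tau_max"), j)
    out <- c(out, v)
  }
  c(out, eps_inf = object$eps_inf, sigma_dc = object$sigma_dc)
}

#' @export
predict.hn_fit <- function(object, frequency = object$spectrum$frequency, ...) {
  .hn_eval(frequency, object$processes, object$eps_inf, object$sigma_dc)
}

#' @export
residuals.hn_fit <- function(object, ...) {
  ev <- predict(object)
  log10(pmax(ev$eps_imag, .Machine$double.xmin)) -
    log10(pmax(object$spectrum$eps_imag, .Machine$double.xmin))
}

#' @export
plot.hn_fit <- function(x, ...) {
  sp <- x$spectrum
  ev <- predict(x)
  graphics::plot(sp$frequency, sp$eps_imag, log = "xy",
                 xlab = "f [Hz]", ylab = expression(epsilon * "''"), ...)
  graphics::lines(sp$frequency, ev$eps_imag)
  invisible(x)
}
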