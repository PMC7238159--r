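# Temperature dependence of relaxation times: Vogel-Fulcher-Tammann fits of
# the structural (alpha) process with derived Tg and fragility, Arrhenius
# fits of sub-Tg secondary processes, and the assembled relaxation map.

#' Fit the Vogel-Fulcher-Tammann law to tau(T)
#'
#' Nonlinear least squares of `log10 tau = log10_tau_inf +
#' DT0 * log10(e) / (T - T0)` — the VFT law `tau = tau_inf * exp(D T0 /
#' (T - T0))` — fitted in log10-tau space with uniform weights because
#' relaxation times span many decades. The internal parameterization is
#' (log10_tau_inf, DT0, T0), which conditions better than (tau_inf, D, T0);
#' D is derived. The glass-transition temperature at `tau = tau_g` and the
#' fragility index are attached.
#'
#' @param temperature Temperatures in kelvin (>= 4 points).
#' @param tau Structural relaxation times in seconds.
#' @param tau_g Glass-transition criterion in seconds (default 100 s).
#' @param T0_init Optional starting value for the Vogel temperature.
#' @return An object of class `"vft_fit"` with `log10_tau_inf`, `D`, `T0`,
#'   `DT0`, `Tg`, `m_p`, `se` (standard errors of the internal parameters),
#'   `cov`, and the data.
#' @examples
#' v <- vft_params(-15.68, T0 = 244.01, DT0 = 2386)
#' Temp <- seq(330, 362, by = 2)
#' fit <- fit_vft(Temp, tau_vft(Temp, v))
#' coef(fit)
#' @export
fit_vft <- function(temperature, tau, tau_g = 100, T0_init = NULL) {
  stopifnot(length(temperature) == length(tau))
  if (length(temperature) < 4) {
    stop("amorphkin: VFT fit needs at least 4 points", call. = FALSE)
  }
  if (any(tau <= 0)) stop("amorphkin: relaxation times must be > 0", call. = FALSE)
  y <- log10(tau)
  Tmin <- min(temperature)
  if (is.null(T0_init)) T0_init <- Tmin - 60
  resid_fn <- function(par) {
    par[1] + par[2] * log10(exp(1)) / (temperature - par[3]) - y
  }
  fit <- minpack.lm::nls.lm(
    par = c(-14, max((y[which.min(temperature)] + 14) *
                       (Tmin - T0_init) / log10(exp(1)), 100), T0_init),
    lower = c(-30, 1, 1), upper = c(0, 1e5, Tmin - 1e-3),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 9)) {
    stop("amorphkin: VFT fit did not converge", call. = FALSE)
  }
  lti <- fit$par[1]; DT0 <- fit$par[2]; T0 <- fit$par[3]
  if (T0 >= Tmin) {
    stop("amorphkin: fitted Vogel temperature exceeds the lowest data point",
         call. = FALSE)
  }
  covm <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  se <- tryCatch(as.numeric(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) rep(NA_real_, 3))
  obj <- structure(
    list(log10_tau_inf = lti, DT0 = DT0, T0 = T0, D = DT0 / T0,
         se = stats::setNames(se, c("log10_tau_inf", "DT0", "T0")),
         cov = covm, tau_g = tau_g,
         temperature = temperature, tau = tau,
         residual_norm = sqrt(sum(fit$fvec^2))),
    class = "vft_fit"
  )
  obj$Tg <- tg_from_vft(obj, tau_g)
  # range advisory is a report-level concern; see fragility()
  obj$m_p <- suppressWarnings(fragility(obj, tau_g))
  obj
}

#' Glass-transition temperature from a VFT fit
#'
#' Solves `tau(Tg) = tau_g` in closed form:
#' `Tg = T0 + DT0 * log10(e) / (log10(tau_g) - log10_tau_inf)`. The
#' conventional dielectric criterion is `tau_g = 100 s`.
#'
#' @param v A `"vft_fit"` or [vft_params()].
#' @param tau_g Relaxation time defining Tg, seconds.
#' @return Tg in kelvin.
#' @examples
#' tg_from_vft(vft_params(-15.68, T0 = 244.01, DT0 = 2386)) # ~303 K
#' @export
tg_from_vft <- function(v, tau_g = 100) {
  if (log10(tau_g) <= v$log10_tau_inf) {
    stop("amorphkin: tau_g must exceed the high-temperature limit tau_inf",
         call. = FALSE)
  }
  v$T0 + v$DT0 * log10(exp(1)) / (log10(tau_g) - v$log10_tau_inf)
}

#' Fragility index from a VFT fit
#'
#' Steepness of the relaxation map at the glass transition,
#' `m_p = d log10 tau / d(Tg/T)` evaluated at `T = Tg`; in closed form for
#' the VFT law, `m_p = DT0 * Tg / (ln 10 * (Tg - T0)^2)`. Typical molecular
#' glass formers fall between 50 (strong) and 100 (fragile); values outside
#' that range trigger a warning, not an error.
#'
#' @param v A `"vft_fit"` or [vft_params()].
#' @param tau_g Relaxation time defining Tg, seconds.
#' @return The fragility index m_p (dimensionless).
#' @examples
#' fragility(vft_params(-15.68, T0 = 244.01, DT0 = 2386)) # ~91
#' @export
fragility <- function(v, tau_g = 100) {
  Tg <- tg_from_vft(v, tau_g)
  m_p <- v$DT0 * Tg / (log(10) * (Tg - v$T0)^2)
  if (m_p < 50 || m_p > 100) {
    warning("amorphkin: fragility ", signif(m_p, 3),
            " outside the typical 50-100 range", call. = FALSE)
  }
  m_p
}

#' @export
print.vft_fit <- function(x, ...) {
  cat("Vogel-Fulcher-Tammann fit\n")
  cat(sprintf("  log10 tau_inf = %.3f (se %.3g)\n", x$log10_tau_inf, x$se[1]))
  cat(sprintf("  T0            = %.2f K (se %.3g)\n", x$T0, x$se[3]))
  cat(sprintf("  D T0          = %.0f K (se %.3g);  D = %.3f\n",
              x$DT0, x$se[2], x$D))
  cat(sprintf("  Tg(tau = %g s) = %.1f K,  fragility m_p = %.1f\n",
              x$tau_g, x$Tg, x$m_p))
  invisible(x)
}

#' @export
coef.vft_fit <- function(object, ...) {
  c(log10_tau_inf = object$log10_tau_inf, DT0 = object$DT0, T0 = object$T0,
    D = object$D, Tg = object$Tg, m_p = object$m_p)
}

#' @export
predict.vft_fit <- function(object, temperature = object$temperature, ...) {
  10^(object$log10_tau_inf +
        object$DT0 * log10(exp(1)) / (temperature - object$T0))
}

#' @export
residuals.vft_fit <- function(object, ...) {
  log10(object$tau) - log10(predict(object))
}

#' Fit the Arrhenius law to a secondary-relaxation tau(T)
#'
#' Linear regression of `ln tau` on `1/T`; the activation energy is
#' `Ea = slope * R`, reported in kJ/mol (R = 8.314 J/(mol K)). Sub-Tg
#' secondary (beta, gamma) relaxations are local motions and follow this
#' law.
#'
#' @param temperature Temperatures in kelvin (>= 2 distinct values).
#' @param tau Relaxation times in seconds.
#' @return An object of class `"arrhenius_fit"` with `Ea_kJmol`,
#'   `log10_tau_inf`, `se`, `cov` and the data.
#' @examples
#' Temp <- seq(180, 290, by = 10)
#' tau <- 10^-16 * exp(55e3 / (8.314 * Temp))
#' fit_arrhenius(Temp, tau)
#' @export
fit_arrhenius <- function(temperature, tau) {
  stopifnot(length(temperature) == length(tau))
  if (length(unique(temperature)) < 2) {
    stop("amorphkin: Arrhenius fit needs >= 2 distinct temperatures", call. = FALSE)
  }
  if (any(tau <= 0)) stop("amorphkin: relaxation times must be > 0", call. = FALSE)
  R <- 8.314
  x <- 1 / temperature
  fit <- stats::lm(log(tau) ~ x)
  cf <- stats::coef(fit)
  covm <- suppressWarnings(stats::vcov(fit))  # zero-residual fits are fine
  se <- sqrt(diag(covm))
  structure(
    list(Ea_kJmol = unname(cf[2]) * R / 1000,
         log10_tau_inf = unname(cf[1]) / log(10),
         se = c(Ea_kJmol = unname(se[2]) * R / 1000,
                log10_tau_inf = unname(se[1]) / log(10)),
         cov = covm, temperature = temperature, tau = tau,
         residual_norm = sqrt(sum(stats::residuals(fit)^2))),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: Ea = %.2f kJ/mol (se %.3g), log10 tau_inf = %.2f\n",
              x$Ea_kJmol, x$se[1], x$log10_tau_inf))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(Ea_kJmol = object$Ea_kJmol, log10_tau_inf = object$log10_tau_inf)
}

#' @export
predict.arrhenius_fit <- function(object, temperature = object$temperature, ...) {
  10^object$log10_tau_inf * exp(object$Ea_kJmol * 1000 / (8.314 * temperature))
}

#' @export
residuals.arrhenius_fit <- function(object, ...) {
  log10(object$tau) - log10(predict(object))
}

#' Assemble a relaxation map
#'
#' Merges the structural (alpha) VFT fit and any secondary Arrhenius fits
#' into one serializable map: per process, the measured (T, log10 tau)
#' points and the model curve sampled on a dense temperature grid.
#'
#' @param alpha_fit A `"vft_fit"` for the structural process.
#' @param secondary_fits Named list of `"arrhenius_fit"` objects (e.g.
#'   `list(beta = ..., gamma = ...)`); names must be unique and not
#'   `"alpha"`.
#' @param grid_n Points of the dense model grid per process.
#' @return An object of class `"relaxation_map"`: list of per-process
#'   entries with `label`, `temperature`, `log10_tau`, `model` (data frame
#'   `temperature`, `log10_tau`), `fit`.
#' @export
assemble_relaxation_map <- function(alpha_fit, secondary_fits = list(),
                                    grid_n = 200) {
  stopifnot(inherits(alpha_fit, "vft_fit"))
  labels <- c("alpha", names(secondary_fits))
  if (anyDuplicated(labels) || any(!nzchar(labels))) {
    stop("amorphkin: process labels must be unique and non-empty", call. = FALSE)
  }
  entry <- function(label, Temp, tau, fit) {
    grid <- seq(min(Temp), max(Temp), length.out = grid_n)
    o <- order(Temp)
    list(label = label, temperature = Temp[o], log10_tau = log10(tau[o]),
         model = data.frame(temperature = grid,
                            log10_tau = log10(predict(fit, temperature = grid))),
         fit = fit)
  }
  out <- list(alpha = entry("alpha", alpha_fit$temperature, alpha_fit$tau,
                            alpha_fit))
  for (nm in names(secondary_fits)) {
    ft <- secondary_fits[[nm]]
    stopifnot(inherits(ft, "arrhenius_fit"))
    out[[nm]] <- entry(nm, ft$temperature, ft$tau, ft)
  }
  structure(out, class = "relaxation_map")
}

#' @export
print.relaxation_map <- function(x, ...) {
  cat(sprintf("<relaxation_map> %d process(es): %s\n", length(x),
              paste(vapply(x, `[[`, "", "label"), collapse = ", ")))
  invisible(x)
}

#' @export
plot.relaxation_map <- function(x, ...) {
  allT <- unlist(lapply(x, `[[`, "temperature"))
  ally <- unlist(lapply(x, `[[`, "log10_tau"))
  graphics::plot(1000 / allT, ally, type = "n",
                 xlab = "1000 / T [1/K]", ylab = expression(log[10] * tau ~ "[s]"),
                 ...)
  for (j in seq_along(x)) {
    e <- x[[j]]
    graphics::points(1000 / e$temperature, e$log10_tau, pch = j)
    graphics::lines(1000 / e$model$temperature, e$model$log10_tau, lty = j)
  }
  invisible(x)
}
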