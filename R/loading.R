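# Hempel loading-capacity estimation: the heat-capacity step at the glass
# transition of drug / mesoporous-silica mixtures is linear in drug load
# and extrapolates to zero at the load where the entire drug fraction is
# immobilized on the silica surface.

#' Fit the heat-capacity-step line and extrapolate the loading capacity
#'
#' Ordinary least squares of `delta_cp` on drug load (wt.%). The drug load
#' at which the line crosses zero, `w* = -intercept/slope`, is the
#' composition where no mobile (glass-forming) drug remains; the
#' monomolecular loading capacity of the silica is `100 - w*` in wt.% of
#' mesoporous silica. Mixtures with no detectable glass transition
#' (`delta_cp <= 0`, below the breakpoint) carry no information about the
#' line and are excluded by default.
#'
#' @param points A data frame with columns `drug_load` (wt.%, in (0, 100\])
#'   and `delta_cp` (J/(g K), >= 0), e.g. from [gen_dcp_table()].
#' @param exclude_below_breakpoint Drop points with `delta_cp <= 0` before
#'   the regression.
#' @return An object of class `"dcp_fit"`: `slope`, `intercept`,
#'   `drug_load_at_zero` (wt.% drug), `ms_capacity` (wt.% silica),
#'   standard errors (`se`, including `ms_capacity` by the delta method),
#'   `out_of_range` flag, `n_used`, and the retained data.
#' @examples
#' tbl <- gen_dcp_table(84.3, dcp_pure = 0.4)
#' fit_dcp_line(tbl)$ms_capacity # 84.3
#' @export
fit_dcp_line <- function(points, exclude_below_breakpoint = TRUE) {
  stopifnot(is.data.frame(points),
            all(c("drug_load", "delta_cp") %in% names(points)))
  if (any(points$drug_load <= 0 | points$drug_load > 100)) {
    stop("amorphkin: drug loads must lie in (0, 100]", call. = FALSE)
  }
  if (any(points$delta_cp < 0)) {
    stop("amorphkin: delta_cp must be >= 0", call. = FALSE)
  }
  used <- if (exclude_below_breakpoint) points[points$delta_cp > 0, , drop = FALSE]
          else points
  if (length(unique(used$drug_load)) < 2) {
    stop("amorphkin: need at least 2 distinct drug loads above the breakpoint",
         call. = FALSE)
  }
  fit <- stats::lm(delta_cp ~ drug_load, data = used)
  cf <- stats::coef(fit)
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  if (!(slope > 0)) {
    stop("amorphkin: non-positive slope - delta_cp must increase with drug ",
         "load; extrapolation invalid", call. = FALSE)
  }
  covm <- suppressWarnings(stats::vcov(fit))  # zero-residual fits are fine
  w0 <- -intercept / slope
  # delta method for w0 = -intercept/slope
  g <- c(-1 / slope, intercept / slope^2)
  w0_var <- as.numeric(t(g) %*% covm %*% g)
  if (!is.finite(w0_var) || w0_var < 0) w0_var <- 0
  structure(
    list(slope = slope, intercept = intercept,
         drug_load_at_zero = w0, ms_capacity = 100 - w0,
         se = c(slope = sqrt(covm[2, 2]), intercept = sqrt(covm[1, 1]),
                ms_capacity = sqrt(w0_var)),
         out_of_range = (w0 < 0 || w0 > 100),
         n_used = nrow(used), data = used,
         residual_norm = sqrt(sum(stats::residuals(fit)^2))),
    class = "dcp_fit"
  )
}

#' @export
print.dcp_fit <- function(x, ...) {
  cat(sprintf("Loading-capacity fit (%d points)\n", x$n_used))
  cat(sprintf("  delta_Cp = %.4g + %.4g * w  [J/(g K), w in wt.%% drug]\n",
              x$intercept, x$slope))
  cat(sprintf("  zero crossing w* = %.1f wt.%% drug%s\n", x$drug_load_at_zero,
              if (x$out_of_range) "  [outside 0-100!]" else ""))
  cat(sprintf("  monomolecular loading capacity = %.1f +/- %.1f wt.%% MS\n",
              x$ms_capacity, x$se["ms_capacity"]))
  invisible(x)
}

#' @export
coef.dcp_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope,
    drug_load_at_zero = object$drug_load_at_zero,
    ms_capacity = object$ms_capacity)
}

#' @export
predict.dcp_fit <- function(object, drug_load = object$data$drug_load, ...) {
  pmax(object$intercept + object$slope * drug_load, 0)
}

#' @export
residuals.dcp_fit <- function(object, ...) {
  object$data$delta_cp - (object$intercept + object$slope * object$data$drug_load)
}

#' Compare two loading capacities
#'
#' Difference of the monomolecular loading capacities of two silica
#' materials, with the standard error propagated in quadrature.
#'
#' @param a,b `"dcp_fit"` objects.
#' @return An object of class `"capacity_comparison"` with `difference`
#'   (wt.% MS, a minus b), `se`, and the inputs' capacities.
#' @export
compare_capacities <- function(a, b) {
  stopifnot(inherits(a, "dcp_fit"), inherits(b, "dcp_fit"))
  if (a$out_of_range || b$out_of_range) {
    stop("amorphkin: cannot compare out-of-range capacity fits", call. = FALSE)
  }
  structure(
    list(capacity_a = a$ms_capacity, capacity_b = b$ms_capacity,
         difference = a$ms_capacity - b$ms_capacity,
         se = sqrt(a$se[["ms_capacity"]]^2 + b$se[["ms_capacity"]]^2)),
    class = "capacity_comparison"
  )
}

#' @export
print.capacity_comparison <- function(x, ...) {
  cat(sprintf("Capacity difference: %.2f - %.2f = %.2f +/- %.2f wt.%% MS\n",
              x$capacity_a, x$capacity_b, x$difference, x$se))
  invisible(x)
}
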