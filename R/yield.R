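## Inverse analysis: quantum yield from the initial slope of dA266 vs
## absorbed dose; photostationary plateau and dose-to-equilibrium.

#' Construct a dose-response table
#'
#' @param doses_J Non-decreasing absorbed energy doses (J), starting at 0.
#' @param delta_A_266 Signed absorbance change at the probe (OD).
#' @param probe_nm Probe wavelength, fixed at 266 nm.
#' @return A data frame of class `"dose_response"`.
#' @export
dose_response <- function(doses_J, delta_A_266, probe_nm = 266) {
  if (length(doses_J) != length(delta_A_266))
    stop("doses_J and delta_A_266 must have equal length")
  if (doses_J[1] != 0) stop("doses must start at 0")
  if (any(diff(doses_J) < 0)) stop("doses must be non-decreasing")
  dr <- data.frame(dose_J = as.numeric(doses_J),
                   dA266_OD = as.numeric(delta_A_266))
  attr(dr, "probe_nm") <- probe_nm
  class(dr) <- c("dose_response", "data.frame")
  dr
}

#' Select the initial linear range of a dose-response
#'
#' Returns the longest prefix (>= 4 points) whose quadratic-fit curvature
#' term is statistically indistinguishable from zero (t-test, alpha =
#' 0.05), excluding points beyond 25% of the estimated plateau response.
#' If the response is indistinguishable from noise, or no prefix is
#' admissible, the first 4 points are returned with `warning_flag = TRUE`.
#'
#' @param dr A `dose_response` (>= 4 points).
#' @param alpha Significance level of the curvature test.
#' @return List with `from`, `to` (index span), `warning_flag`, `reason`.
#' @export
select_linear_range <- function(dr, alpha = 0.05) {
  stopifnot(inherits(dr, "dose_response"))
  n <- nrow(dr)
  if (n < 4) stop("select_linear_range needs at least 4 points")
  D <- dr$dose_J; y <- dr$dA266_OD
  scale_y <- max(abs(y), .Machine$double.eps)

  ## plateau estimate: saturating-exponential fit if saturation is visible
  plateau <- Inf
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(y ~ a * (1 - exp(-D / d0)),
                        start = list(a = max(abs(y)) * sign(sum(y)),
                                     d0 = max(D) / 2),
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (is.finite(cf["d0"]) && cf["d0"] > 0 && max(D) >= 2 * cf["d0"])
      plateau <- abs(cf["a"])
  }

  ## no-detectable-signal guard: fallback when the trend is below noise
  lf <- stats::lm(y ~ D)
  sd_res <- suppressWarnings(summary(lf)$sigma)
  if (is.finite(sd_res) && sd_res > 0 &&
      abs(stats::coef(lf)[2]) * (max(D) - min(D)) < 3 * sd_res) {
    return(list(from = 1L, to = 4L, warning_flag = TRUE,
                reason = "response indistinguishable from noise"))
  }

  for (k in n:4) {
    if (any(abs(y[1:k]) > 0.25 * plateau)) next
    Dk <- D[1:k]; yk <- y[1:k]
    qf <- stats::lm(yk ~ Dk + I(Dk^2))
    cs <- suppressWarnings(summary(qf)$coefficients)
    if (nrow(cs) < 3 || any(!is.finite(cs[3, ]))) {
      ## rank-deficient or zero-residual quadratic: admissible only if the
      ## curvature coefficient itself is negligible
      curv <- stats::coef(qf)[3]
      if (!is.finite(curv) ||
          abs(curv) * max(Dk)^2 < 1e-9 * scale_y)
        return(list(from = 1L, to = k, warning_flag = FALSE,
                    reason = "curvature numerically zero"))
      next
    }
    if (abs(stats::coef(qf)[3]) * max(Dk)^2 < 1e-9 * scale_y ||
        cs[3, 4] > alpha)
      return(list(from = 1L, to = k, warning_flag = FALSE,
                  reason = "curvature not significant"))
  }
  list(from = 1L, to = 4L, warning_flag = TRUE,
       reason = "no admissible linear prefix; first 4 points used")
}

#' Quantum yield from a dose-response curve
#'
#' Ordinary least squares (free intercept) over the selected linear range
#' gives the initial slope s (OD/J); the quantum yield follows from
#' Phi = s V N_A E_ph / (delta_eps_266 l): molecules converted per joule
#' divided by photons per joule absorbed. A 40% relative uncertainty is
#' attached to the result.
#'
#' @param dr A `dose_response`.
#' @param delta_eps_266 Probe absorption contrast repaired - damaged
#'   (M^-1 cm^-1), > 0.
#' @param cell A `sample_cell`.
#' @param mean_photon_energy_J Mean energy of an absorbed photon (J); see
#'   [mean_photon_energy()].
#' @param linear_range Optional precomputed range from
#'   [select_linear_range()].
#' @return An object of class `"qy_fit"`: quantum yield `phi` (fraction),
#'   `phi_percent`, `abs_uncertainty_percent` (0.40 x phi_percent), the
#'   fitted slope/intercept/R^2, the linear range and flags.
#' @export
fit_quantum_yield <- function(dr, delta_eps_266, cell, mean_photon_energy_J,
                              linear_range = NULL) {
  stopifnot(inherits(dr, "dose_response"), inherits(cell, "sample_cell"))
  if (!is.finite(delta_eps_266) || delta_eps_266 <= 0)
    stop("delta_eps_266 must be > 0")
  if (is.null(linear_range)) linear_range <- select_linear_range(dr)
  idx <- linear_range$from:linear_range$to
  fit <- stats::lm(dA266_OD ~ dose_J, data = dr[idx, ])
  fit_summary <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  flag <- NULL
  phi <- slope * cell$volume_L * photo_constants$N_A * mean_photon_energy_J /
    (delta_eps_266 * cell$path_length_cm)
  if (slope < 0) {
    phi <- 0
    flag <- "net damage regime"
  }
  phi <- min(phi, 1)
  out <- list(phi = phi, phi_percent = 100 * phi,
              abs_uncertainty_percent = 0.40 * 100 * phi,
              slope_OD_per_J = slope,
              fit_intercept = unname(stats::coef(fit)[1]),
              fit_r_squared = fit_summary$r.squared,
              linear_range = linear_range,
              flags = c(flag,
                        if (linear_range$warning_flag) "linear-range fallback"),
              delta_eps_266 = delta_eps_266,
              mean_photon_energy_J = mean_photon_energy_J,
              cell = cell, data = dr, lm_fit = fit)
  class(out) <- "qy_fit"
  out
}

#' Mean absorbed photon energy of a scenario at time zero
#'
#' energy_dose_rate / total absorbed photon rate from
#' [absorption_partition()] for the initial composition; for a 15 nm band
#' at 285 nm this differs from the monochromatic h c / lambda_center value
#' by well under 1%.
#'
#' @param scheme A `reaction_scheme`.
#' @param bm A `beam`.
#' @param cell A `sample_cell`.
#' @param c0_M Initial concentrations (damaged, repaired\[, side\]).
#' @param monochromatic If `TRUE`, return h c / lambda at the beam's
#'   photon-weighted mean wavelength instead.
#' @return Energy per absorbed photon (J).
#' @export
mean_photon_energy <- function(scheme, bm, cell, c0_M,
                               monochromatic = FALSE) {
  if (monochromatic) {
    lam <- bm$emission$wavelengths_nm
    w <- bm$emission$values * lam
    lbar <- trapz(lam, w * lam) / trapz(lam, w)
    return(photo_constants$h_J_s * photo_constants$c_m_s / (lbar * 1e-9))
  }
  if (length(c0_M) == 2) c0_M <- c(c0_M, 0)
  part <- absorption_partition(scheme_epsilons(scheme), c0_M, cell, bm)
  if (part$total_photon_rate <= 0)
    stop("sample absorbs no photons; mean photon energy undefined")
  part$energy_dose_rate_W / part$total_photon_rate
}

#' @export
print.qy_fit <- function(x, ...) {
  cat("Quantum-yield fit (initial-slope dose-response analysis)\n")
  cat(sprintf("  Phi = %.2f %% (+/- %.2f %%, 40%% rule)\n",
              x$phi_percent, round(x$abs_uncertainty_percent, 2)))
  cat(sprintf("  slope = %.4g OD/J, intercept = %.3g OD, R^2 = %.4f\n",
              x$slope_OD_per_J, x$fit_intercept, x$fit_r_squared))
  cat(sprintf("  linear range: points %d-%d of %d%s\n",
              x$linear_range$from, x$linear_range$to, nrow(x$data),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "),
                                          "]") else ""))
  invisible(x)
}

#' @export
summary.qy_fit <- function(object, ...) {
  s <- summary(object$lm_fit)
  structure(list(qy = object, lm_summary = s), class = "summary.qy_fit")
}

#' @export
print.summary.qy_fit <- function(x, ...) {
  print(x$qy)
  cat("\nLinear-range OLS detail:\n")
  print(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
coef.qy_fit <- function(object, ...) {
  c(phi = object$phi, slope_OD_per_J = object$slope_OD_per_J,
    intercept_OD = object$fit_intercept)
}

#' @export
predict.qy_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  object$fit_intercept + object$slope_OD_per_J * newdata$dose_J
}

#' @export
residuals.qy_fit <- function(object, ...) {
  object$data$dA266_OD - predict(object)
}

#' @export
plot.qy_fit <- function(x, ...) {
  graphics::plot(x$data$dose_J, x$data$dA266_OD * 1e3,
                 xlab = "absorbed dose (J)", ylab = expression(Delta * A[266] ~ "(mOD)"),
                 pch = 19, ...)
  idx <- x$linear_range$from:x$linear_range$to
  graphics::points(x$data$dose_J[idx], x$data$dA266_OD[idx] * 1e3, col = 2,
                   pch = 19)
  graphics::abline(a = x$fit_intercept * 1e3, b = x$slope_OD_per_J * 1e3,
                   col = 2)
  invisible(x)
}

#' Fit the saturating approach to the photostationary state
#'
#' Nonlinear least squares of f(D) = f_pss (1 - exp(-D / D0)) to repair
#' fraction versus absorbed dose. The dose to equilibrium is reported with
#' the 5% convention, -D0 log(0.05).
#'
#' @param x A `time_course`, or a data frame with columns `dose_J` and
#'   `repair_fraction`, or a `dose_response` (then `delta_eps_266`, `c0_M`
#'   and `path_length_cm` are needed to convert dA266 to a fraction).
#' @param delta_eps_266,c0_M,path_length_cm Conversion parameters used
#'   only for `dose_response` input.
#' @return An object of class `"pss_fit"` with `plateau_fraction`,
#'   `D0_J`, `dose_to_equilibrium_J`, data and the nls fit.
#' @export
fit_pss_approach <- function(x, delta_eps_266 = NULL, c0_M = NULL,
                             path_length_cm = 1) {
  if (inherits(x, "dose_response")) {
    if (is.null(delta_eps_266) || is.null(c0_M))
      stop("dose_response input needs delta_eps_266 and c0_M")
    d <- data.frame(dose_J = x$dose_J,
                    repair_fraction = x$dA266_OD /
                      (delta_eps_266 * c0_M * path_length_cm))
  } else {
    if (!all(c("dose_J", "repair_fraction") %in% names(x)))
      stop("need columns dose_J and repair_fraction")
    d <- as.data.frame(x)[, c("dose_J", "repair_fraction")]
  }
  fmax <- max(d$repair_fraction)
  if (fmax <= 0) stop("plateau not reached in data")
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(repair_fraction ~ fpss * (1 - exp(-dose_J / D0)),
                        data = d,
                        start = list(fpss = fmax,
                                     D0 = max(d$dose_J) / 3),
                        control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) stop("plateau fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf["fpss"] < 0 || cf["D0"] <= 0)
    stop("plateau fit failed: non-physical parameters")
  ## pre-condition: data must span >= 80% of the apparent plateau
  if (fmax < 0.8 * cf["fpss"] || max(d$dose_J) < cf["D0"])
    stop("plateau not reached in data")
  out <- list(plateau_fraction = unname(cf["fpss"]),
              D0_J = unname(cf["D0"]),
              dose_to_equilibrium_J = unname(-cf["D0"] * log(0.05)),
              data = d, nls_fit = fit)
  class(out) <- "pss_fit"
  out
}

#' @export
print.pss_fit <- function(x, ...) {
  cat("Photostationary-state fit: f(D) = f_pss (1 - exp(-D/D0))\n")
  cat(sprintf("  plateau repair fraction = %.1f %%\n",
              100 * x$plateau_fraction))
  cat(sprintf("  D0 = %.3g J; dose to equilibrium (5%% convention) = %.2f J\n",
              x$D0_J, x$dose_to_equilibrium_J))
  invisible(x)
}

#' @export
summary.pss_fit <- function(object, ...) summary(object$nls_fit, ...)

#' @export
coef.pss_fit <- function(object, ...) {
  c(f_pss = object$plateau_fraction, D0_J = object$D0_J)
}

#' @export
predict.pss_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  object$plateau_fraction * (1 - exp(-newdata$dose_J / object$D0_J))
}

#' @export
residuals.pss_fit <- function(object, ...) {
  object$data$repair_fraction - predict(object)
}

#' @export
plot.pss_fit <- function(x, ...) {
  graphics::plot(x$data$dose_J, x$data$repair_fraction,
                 xlab = "absorbed dose (J)", ylab = "repair fraction",
                 pch = 19, ...)
  Dg <- seq(0, max(x$data$dose_J), length.out = 200)
  graphics::lines(Dg, predict(x, data.frame(dose_J = Dg)), col = 2)
  graphics::abline(h = x$plateau_fraction, lty = 2, col = "grey50")
  invisible(x)
}

#' Report the 40% uncertainty rule
#'
#' Absolute uncertainty attached to a quantum yield or plateau value:
#' 0.40 x value, optionally rounded to two decimals as printed alongside
#' percent-scale yields.
#'
#' @param value_percent Value on the percent scale.
#' @param digits Rounding digits (default 2).
#' @return Rounded absolute uncertainty.
#' @export
uncertainty_40pct <- function(value_percent, digits = 2) {
  round(0.40 * value_percent, digits)
}
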