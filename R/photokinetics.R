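## Forward model: reversible damaged <-> repaired photoreaction under
## polychromatic irradiation, optional irreversible side channel, and the
## photostationary-state solver.

#' Construct a photoactive species
#'
#' @param label One of `"damaged"`, `"repaired"`, `"side"`.
#' @param epsilon Molar absorption `spectrum`.
#' @param epsilon_probe_266 Optional molar absorption coefficient at the
#'   266 nm probe; defaults to the interpolated value and must agree with
#'   it within 1%.
#' @return An object of class `"photo_species"`.
#' @export
photo_species <- function(label = c("damaged", "repaired", "side"),
                          epsilon, epsilon_probe_266 = NULL) {
  label <- match.arg(label)
  stopifnot(inherits(epsilon, "spectrum"))
  if (epsilon$kind != "molar_absorption")
    stop("species epsilon must be a molar_absorption spectrum")
  at266 <- spectrum_at(epsilon, 266)
  if (is.na(at266)) at266 <- 0
  if (is.null(epsilon_probe_266)) epsilon_probe_266 <- at266
  if (at266 > 0 && abs(epsilon_probe_266 - at266) > 0.01 * at266)
    stop("epsilon_probe_266 inconsistent (>1%) with epsilon at 266 nm")
  structure(list(label = label, epsilon = epsilon,
                 epsilon_probe_266 = epsilon_probe_266),
            class = "photo_species")
}

#' Construct a reversible photoreaction scheme
#'
#' Species interconvert per photon they absorb: a damaged oligomer converts
#' to the repaired one with quantum yield `phi_repair`, the repaired one
#' back to damaged with `phi_damage`, and optionally to an inert side
#' product with `phi_side`.
#'
#' @param damaged,repaired `photo_species` for the two oligomers.
#' @param phi_repair,phi_damage,phi_side Quantum yields in \[0, 1\]
#'   (fraction per absorbed photon); `phi_damage + phi_side <= 1`.
#' @param side Optional `photo_species` for the side product (defaults to a
#'   transparent species when `phi_side > 0`).
#' @return An object of class `"reaction_scheme"`.
#' @export
reaction_scheme <- function(damaged, repaired, phi_repair, phi_damage,
                            phi_side = 0, side = NULL) {
  stopifnot(inherits(damaged, "photo_species"),
            inherits(repaired, "photo_species"))
  phis <- c(phi_repair = phi_repair, phi_damage = phi_damage,
            phi_side = phi_side)
  if (any(!is.finite(phis)) || any(phis < 0) || any(phis > 1))
    stop("quantum yields must lie in [0, 1]")
  if (phi_damage + phi_side > 1)
    stop("phi_damage + phi_side must not exceed 1 (same-origin channels)")
  if (is.null(side)) {
    g <- damaged$epsilon$wavelengths_nm
    side <- photo_species("side",
                          spectrum(g, rep(0, length(g)), "molar_absorption"))
  }
  structure(list(species = list(damaged = damaged, repaired = repaired,
                                side = side),
                 phi_repair = phi_repair, phi_damage = phi_damage,
                 phi_side = phi_side),
            class = "reaction_scheme")
}

scheme_epsilons <- function(scheme) {
  lapply(scheme$species, function(s) s$epsilon)
}

#' Photochemical rate vector
#'
#' dC/dt (M/s) for state `c(damaged, repaired, side)` under a beam:
#' dc_repaired/dt = (phi_repair R_damaged - (phi_damage + phi_side)
#' R_repaired) / (N_A V), with absorbed photon rates R_i from
#' [absorption_partition()]. Total concentration is conserved exactly
#' (the side product is tracked explicitly).
#'
#' @param concentrations_M Named or ordered vector (damaged, repaired, side).
#' @param scheme A `reaction_scheme`.
#' @param bm A `beam`.
#' @param cell A `sample_cell`.
#' @return List with `dC_dt_M_s` (per species), `energy_dose_rate_W`,
#'   `photon_rate_per_species`.
#' @export
rate_vector <- function(concentrations_M, scheme, bm, cell) {
  stopifnot(inherits(scheme, "reaction_scheme"))
  if (length(concentrations_M) == 2)
    concentrations_M <- c(concentrations_M, 0)
  if (any(concentrations_M < 0))
    stop("negative concentration input rejected")
  part <- absorption_partition(scheme_epsilons(scheme), concentrations_M,
                               cell, bm)
  R <- part$photon_rate_per_species  # damaged, repaired, side
  NV <- photo_constants$N_A * cell$volume_L
  d_rep <- (scheme$phi_repair * R[1] -
              (scheme$phi_damage + scheme$phi_side) * R[2]) / NV
  d_dam <- (-scheme$phi_repair * R[1] + scheme$phi_damage * R[2]) / NV
  d_side <- scheme$phi_side * R[2] / NV
  list(dC_dt_M_s = c(damaged = d_dam, repaired = d_rep, side = d_side),
       energy_dose_rate_W = part$energy_dose_rate_W,
       photon_rate_per_species = R)
}

#' Simulate an irradiation time course
#'
#' Integrates the photoreaction with a stiff-capable adaptive solver
#' (deSolve::lsoda, rtol 1e-8, atol 1e-12 M) and tracks the cumulative
#' energy dose absorbed by the whole sample. The 266 nm probe absorbance
#' is sum eps_i(266) c_i l.
#'
#' @param scheme A `reaction_scheme`.
#' @param bm A `beam`.
#' @param cell A `sample_cell`.
#' @param c0_M Initial concentrations (damaged, repaired\[, side\]) in M.
#' @param t_grid_s Increasing time grid starting at 0 (s).
#' @param rtol,atol Solver tolerances.
#' @return A data frame of class `"time_course"` with columns `time_s`,
#'   `dose_J`, `c_damaged_M`, `c_repaired_M`, `c_side_M`, `A266_OD`,
#'   `dA266_OD`, `repair_fraction` (c_repaired / initial c_damaged).
#' @export
simulate_time_course <- function(scheme, bm, cell, c0_M, t_grid_s,
                                 rtol = 1e-8, atol = 1e-12) {
  if (length(c0_M) == 2) c0_M <- c(c0_M, 0)
  if (any(c0_M < 0)) stop("initial concentrations must be nonnegative")
  if (t_grid_s[1] != 0 || any(diff(t_grid_s) <= 0))
    stop("t_grid_s must increase from 0")
  eps266 <- vapply(scheme$species, function(s) s$epsilon_probe_266,
                   numeric(1))
  if (length(t_grid_s) == 1) {           # no exposure: initial state, dose 0
    A0 <- sum(eps266 * c0_M) * cell$path_length_cm
    tc <- data.frame(time_s = 0, dose_J = 0, c_damaged_M = c0_M[1],
                     c_repaired_M = c0_M[2], c_side_M = c0_M[3],
                     A266_OD = A0, dA266_OD = 0,
                     repair_fraction = if (c0_M[1] > 0) c0_M[2] / c0_M[1]
                                       else c0_M[2] / sum(c0_M))
    class(tc) <- c("time_course", "data.frame")
    return(tc)
  }
  deriv <- function(t, y, parms) {
    rv <- rate_vector(pmax(y[1:3], 0), scheme, bm, cell)
    list(c(rv$dC_dt_M_s, rv$energy_dose_rate_W))
  }
  out <- deSolve::lsoda(y = c(c0_M, 0), times = t_grid_s, func = deriv,
                        parms = NULL, rtol = rtol, atol = c(rep(atol, 3), 1e-12))
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("integrator failure (istate %d) at t ~ %.3g s, state [%s]",
                 attr(out, "istate")[1], max(out[, 1]),
                 paste(signif(out[nrow(out), -1], 4), collapse = ", ")))
  conc <- out[, 2:4, drop = FALSE]
  A266 <- as.numeric(conc %*% eps266) * cell$path_length_cm
  tc <- data.frame(time_s = out[, 1], dose_J = out[, 5],
                   c_damaged_M = conc[, 1], c_repaired_M = conc[, 2],
                   c_side_M = conc[, 3], A266_OD = A266,
                   dA266_OD = A266 - A266[1],
                   repair_fraction = if (c0_M[1] > 0) conc[, 2] / c0_M[1]
                                     else conc[, 2] / sum(c0_M))
  class(tc) <- c("time_course", "data.frame")
  tc
}

#' Write a time course as CSV
#' @param tc A `time_course`.
#' @param path Output path.
#' @export
write_time_course_csv <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
}

#' Photostationary repair fraction
#'
#' Composition reached when photon-driven repair and damage formation
#' balance. `analytic_thin` uses the optically thin closed form
#' f = phi_rep eps_bar_D / (phi_rep eps_bar_D + phi_dam eps_bar_R) with
#' photon-weighted effective epsilons; `ode_limit` integrates the full
#' model until the fraction stops changing with dose (|df/dDose| < tol).
#' Undefined when an irreversible side channel is present.
#'
#' @param scheme A `reaction_scheme` with `phi_side = 0`.
#' @param bm A `beam`.
#' @param cell A `sample_cell`.
#' @param mode `"analytic_thin"` or `"ode_limit"`.
#' @param c0_M Initial concentrations for `ode_limit` (default all damaged
#'   at 30 uM); the limit is independent of the start.
#' @param tol Convergence tolerance on |df/dDose| (per J) for `ode_limit`.
#' @return Repaired fraction in \[0, 1\] of the total oligomer pool.
#' @export
pss_fraction <- function(scheme, bm, cell,
                         mode = c("analytic_thin", "ode_limit"),
                         c0_M = c(30e-6, 0), tol = 1e-6) {
  mode <- match.arg(mode)
  if (scheme$phi_side > 0)
    stop("no stationary state: irreversible channel present")
  if (mode == "analytic_thin") {
    eD <- effective_epsilon(scheme$species$damaged$epsilon, bm)
    eR <- effective_epsilon(scheme$species$repaired$epsilon, bm)
    num <- scheme$phi_repair * eD
    den <- num + scheme$phi_damage * eR
    if (den == 0) stop("both quantum yields are zero; PSS undefined")
    return(num / den)
  }
  ## ode_limit: integrate in doubling windows until the fraction is flat
  if (length(c0_M) == 2) c0_M <- c(c0_M, 0)
  ctot <- sum(c0_M)
  ## dose scale from the analytic estimate of the rate constant
  eD <- effective_epsilon(scheme$species$damaged$epsilon, bm)
  eR <- effective_epsilon(scheme$species$repaired$epsilon, bm)
  rv0 <- rate_vector(c0_M, scheme, bm, cell)
  ## characteristic time from total absorbed photon rate
  Rtot <- sum(rv0$photon_rate_per_species)
  if (Rtot <= 0) stop("beam does not excite the sample; PSS unreachable")
  k_est <- (scheme$phi_repair * eD + scheme$phi_damage * eR) /
    max(eD, eR) * Rtot / (photo_constants$N_A * cell$volume_L * ctot)
  t_win <- 2 / k_est
  y <- c0_M
  f_prev <- y[2] / ctot
  for (i in 1:60) {
    tc <- simulate_time_course(scheme, bm, cell, y, c(0, t_win / 2, t_win))
    y <- c(tc$c_damaged_M[3], tc$c_repaired_M[3], tc$c_side_M[3])
    f_now <- y[2] / ctot
    dDose <- tc$dose_J[3] - tc$dose_J[2]
    if (dDose > 0 && abs(f_now - tc$c_repaired_M[2] / ctot) / dDose < tol)
      return(f_now)
    f_prev <- f_now
    t_win <- t_win * 1.5
  }
  stop("photostationary state not converged; last fraction ", f_prev)
}
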