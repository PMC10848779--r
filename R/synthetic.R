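## Synthetic-data generator: every input the pipeline consumes, with the
## statistical structure the analysis assumes, seed-reproducible, and with
## noiseless truth channels kept beside the observables.

default_phi_repair <- c(TTAG = 0.0058, GATT = 0.0044)
default_pss_target <- c(TTAG = 0.40, GATT = 0.33)

#' Scenario configuration for the irradiation experiment generator
#'
#' Defaults emulate the measured study conditions: ~30 uM damaged
#' tetranucleotide, an LED centered at 285 nm (15 nm FWHM, 0.36 mW at the
#' sample), 1 cm path. The repair quantum yield defaults to the reported
#' value for the chosen sequence (TTAG 0.58%, GATT 0.44%) and
#' `phi_damage = NULL` requests the calibration in which the analytic
#' photostationary level equals the reported plateau (TTAG 40%, GATT
#' 33%). The probe contrast `delta_eps_266` is a configurable synthetic
#' stand-in (default 16000 M^-1 cm^-1 per oligomer), not a measured
#' coefficient.
#'
#' @param sequence_label `"TTAG"` or `"GATT"`.
#' @param c0_M Initial damaged-oligomer concentration (M).
#' @param beam List `center_nm`, `fwhm_nm`, `power_mW`.
#' @param cell List `path_length_cm`, `volume_L`.
#' @param phi_repair,phi_damage,phi_side Quantum yields; `NULL`
#'   `phi_repair` takes the sequence default, `NULL` `phi_damage` is
#'   calibrated to `pss_target`.
#' @param pss_target Photostationary repair fraction used for the
#'   `phi_damage` calibration; `NULL` takes the sequence default.
#' @param delta_eps_266 Probe absorption contrast (M^-1 cm^-1).
#' @param sigma_OD Gaussian noise SD on each absorbance observable (OD).
#' @param chrom_noise_frac Chromatogram noise as a fraction of the
#'   largest pure-peak amplitude.
#' @param schedule_s Exposure time grid (s) starting at 0.
#' @param grid_nm Common wavelength grid (nm).
#' @param rng_seed Integer seed recorded in every output.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(sequence_label = c("TTAG", "GATT"),
                            c0_M = 30e-6,
                            beam = list(center_nm = 285, fwhm_nm = 15,
                                        power_mW = 0.36),
                            cell = list(path_length_cm = 1, volume_L = 1e-3),
                            phi_repair = NULL, phi_damage = NULL,
                            phi_side = 0, pss_target = NULL,
                            delta_eps_266 = 16000,
                            sigma_OD = 1e-3,
                            chrom_noise_frac = 0.01,
                            schedule_s = seq(0, 600, by = 60),
                            grid_nm = seq(220, 340, by = 1),
                            rng_seed = 1L) {
  sequence_label <- match.arg(sequence_label)
  if (is.null(phi_repair)) phi_repair <- default_phi_repair[[sequence_label]]
  if (is.null(pss_target)) pss_target <- default_pss_target[[sequence_label]]
  cfg <- list(sequence_label = sequence_label, c0_M = c0_M, beam = beam,
              cell = cell, phi_repair = phi_repair, phi_damage = phi_damage,
              phi_side = phi_side, pss_target = pss_target,
              delta_eps_266 = delta_eps_266, sigma_OD = sigma_OD,
              chrom_noise_frac = chrom_noise_frac,
              schedule_s = schedule_s, grid_nm = grid_nm,
              rng_seed = as.integer(rng_seed))
  bad <- character(0)
  pos <- function(x) length(x) == 1 && is.finite(x) && x > 0
  if (!pos(c0_M)) bad <- c(bad, "c0_M")
  if (!pos(beam$center_nm) || !pos(beam$fwhm_nm) || !pos(beam$power_mW))
    bad <- c(bad, "beam")
  if (!pos(cell$path_length_cm) || !pos(cell$volume_L)) bad <- c(bad, "cell")
  if (!is.finite(phi_repair) || phi_repair < 0 || phi_repair > 1)
    bad <- c(bad, "phi_repair")
  if (!is.null(phi_damage) &&
      (!is.finite(phi_damage) || phi_damage < 0 || phi_damage > 1))
    bad <- c(bad, "phi_damage")
  if (!is.finite(phi_side) || phi_side < 0 || phi_side > 1)
    bad <- c(bad, "phi_side")
  if (!is.finite(pss_target) || pss_target <= 0 || pss_target >= 1)
    bad <- c(bad, "pss_target")
  if (!is.finite(delta_eps_266) || delta_eps_266 < 0)
    bad <- c(bad, "delta_eps_266")
  if (!is.finite(sigma_OD) || sigma_OD < 0) bad <- c(bad, "sigma_OD")
  if (length(schedule_s) < 2 || schedule_s[1] != 0 ||
      any(diff(schedule_s) <= 0)) bad <- c(bad, "schedule_s")
  if (length(bad))
    stop("invalid scenario configuration; offending field(s): ",
         paste(bad, collapse = ", "))
  class(cfg) <- "scenario_config"
  cfg
}

## damaged-tetramer absorption: one purine-dominated band whose red edge
## carries the 285 nm excitation (~3.3e3 M^-1 cm^-1 there); the repaired
## spectrum adds the thymine-recovery difference band at 266 nm scaled so
## the probe contrast equals delta_eps_266 exactly
scenario_epsilons <- function(cfg) {
  g <- cfg$grid_nm
  eps_dam <- 15000 * exp(-(g - 256)^2 / (2 * 16.7^2))
  diff_band <- exp(-(g - 266)^2 / (2 * 9^2))
  diff_band <- diff_band / diff_band[which(g == 266)]
  eps_rep <- eps_dam + cfg$delta_eps_266 * diff_band
  list(damaged = spectrum(g, eps_dam, "molar_absorption"),
       repaired = spectrum(g, eps_rep, "molar_absorption"))
}

#' Instantiate a scenario: reaction scheme, beam and cell
#'
#' Builds parametric absorption spectra for the damaged and repaired
#' species (the repaired minus damaged contrast at 266 nm equals the
#' configured `delta_eps_266` exactly), the LED beam and the cell, and
#' calibrates `phi_damage` to the configured photostationary target when
#' it is not given explicitly.
#'
#' @param cfg A `scenario_config`.
#' @return List with `scheme`, `beam`, `cell`, `c0_M`, `phi_damage`,
#'   `pss_analytic`, `config`.
#' @export
generate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$delta_eps_266 == 0)
    warning("probe-blind scenario: delta_eps_266 = 0, the 266 nm probe cannot see repair")
  eps <- scenario_epsilons(cfg)
  emission <- resample_to_grid(gaussian_emission(cfg$beam$center_nm,
                                                 cfg$beam$fwhm_nm),
                               cfg$grid_nm)
  bm <- beam(emission, cfg$beam$power_mW * 1e-3)
  cl <- sample_cell(cfg$cell$path_length_cm, cfg$cell$volume_L)
  phi_damage <- cfg$phi_damage
  if (is.null(phi_damage)) {
    eD <- effective_epsilon(eps$damaged, bm)
    eR <- effective_epsilon(eps$repaired, bm)
    f <- cfg$pss_target
    phi_damage <- cfg$phi_repair * eD * (1 - f) / (eR * f)
  }
  scheme <- reaction_scheme(photo_species("damaged", eps$damaged),
                            photo_species("repaired", eps$repaired),
                            phi_repair = cfg$phi_repair,
                            phi_damage = phi_damage,
                            phi_side = cfg$phi_side)
  pss <- if (cfg$phi_side == 0)
    pss_fraction(scheme, bm, cl, "analytic_thin") else NA_real_
  list(scheme = scheme, beam = bm, cell = cl, c0_M = c(cfg$c0_M, 0, 0),
       phi_damage = phi_damage, pss_analytic = pss, config = cfg)
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a full irradiation experiment
#'
#' Integrates the forward model over the exposure schedule and emits the
#' observables the analysis consumes: a noisy 266 nm dose-response,
#' difference spectra per exposure, an HPLC-style chromatogram per
#' exposure synthesized from the true composition, and the noiseless
#' truth (time course, quantum yields, analytic photostationary level).
#' Fully reproducible from `rng_seed`; the caller's RNG state is
#' untouched.
#'
#' @param cfg A `scenario_config`.
#' @return List with `dose_response` (noisy), `diff_spectra` (matrix
#'   wavelength x exposure, noisy), `chromatograms` (list), `time_course`
#'   (noiseless truth), `truth`, `scenario`, `config`.
#' @export
simulate_experiment <- function(cfg) {
  sc <- generate_scenario(cfg)
  tc <- simulate_time_course(sc$scheme, sc$beam, sc$cell, sc$c0_M,
                             cfg$schedule_s)
  eps <- scheme_epsilons(sc$scheme)
  g <- cfg$grid_nm
  l <- sc$cell$path_length_cm
  with_preserved_rng(cfg$rng_seed, {
    dr <- dose_response(tc$dose_J,
                        tc$dA266_OD + stats::rnorm(nrow(tc), 0, cfg$sigma_OD))
    dc <- cbind(tc$c_damaged_M - tc$c_damaged_M[1],
                tc$c_repaired_M - tc$c_repaired_M[1],
                tc$c_side_M - tc$c_side_M[1])
    epsmat <- vapply(eps, function(e) e$values, numeric(length(g)))
    dspec <- epsmat %*% t(dc) * l
    if (cfg$sigma_OD > 0)
      dspec <- dspec + matrix(stats::rnorm(length(dspec), 0, cfg$sigma_OD),
                              nrow(dspec))
    rownames(dspec) <- g
    colnames(dspec) <- paste0("t", tc$time_s, "s")
    amp_max <- 1 / (0.12 * sqrt(2 * pi))
    chroms <- lapply(seq_len(nrow(tc)), function(i) {
      pool <- tc$c_damaged_M[i] + tc$c_repaired_M[i]
      synthesize_chromatogram(
        c(damaged = tc$c_damaged_M[i] / pool,
          repaired = tc$c_repaired_M[i] / pool),
        noise_sd = cfg$chrom_noise_frac * amp_max)
    })
    list(dose_response = dr, diff_spectra = dspec, chromatograms = chroms,
         time_course = tc,
         truth = list(phi_repair = cfg$phi_repair,
                      phi_damage = sc$phi_damage,
                      pss_analytic = sc$pss_analytic,
                      rng_seed = cfg$rng_seed),
         scenario = sc, config = cfg)
  })
}

#' Run the quantum-yield extraction on a simulated experiment
#'
#' Convenience wrapper: selects the linear range of the simulated
#' dose-response and applies the initial-slope analysis with the
#' scenario's own cell and probe contrast, exactly as one would analyze
#' measured data.
#'
#' @param sim Output of [simulate_experiment()].
#' @return A `qy_fit`.
#' @export
recover_quantum_yield <- function(sim) {
  sc <- sim$scenario
  Eph <- mean_photon_energy(sc$scheme, sc$beam, sc$cell, sc$c0_M)
  fit_quantum_yield(sim$dose_response,
                    delta_eps_266 = sim$config$delta_eps_266,
                    cell = sc$cell, mean_photon_energy_J = Eph)
}

#' Extend a scenario to a long-dose schedule
#'
#' Replaces the exposure schedule so the cumulative absorbed dose reaches
#' `multiple` times the characteristic dose D0 = f_pss E_ph N_A V c0 /
#' phi_repair of the saturating approach, with `n_points` equally spaced
#' exposures (times estimated from the initial absorbed-power rate).
#'
#' @param cfg A `scenario_config`.
#' @param n_points Number of exposures after time zero.
#' @param multiple Target dose in units of D0.
#' @return The modified `scenario_config`.
#' @export
with_long_dose_schedule <- function(cfg, n_points = 25, multiple = 5) {
  sc <- generate_scenario(cfg)
  Eph <- mean_photon_energy(sc$scheme, sc$beam, sc$cell, sc$c0_M)
  D0 <- sc$pss_analytic * Eph * photo_constants$N_A * sc$cell$volume_L *
    cfg$c0_M / cfg$phi_repair
  p0 <- rate_vector(sc$c0_M, sc$scheme, sc$beam, sc$cell)$energy_dose_rate_W
  t_end <- multiple * D0 / p0
  cfg$schedule_s <- seq(0, t_end, length.out = n_points + 1)
  cfg
}

## ---- idealized stacked-purine geometry for ensemble fixtures ----

## planar purine template: regular six-ring (bond 1.39 A) fused to a
## regular five-ring across the C4-C5 edge, glycosidic N9 carrying C1'
purine_template <- function() {
  r6 <- 1.39
  hex_names <- c("C4", "C5", "C6", "N1", "C2", "N3")
  hex <- t(vapply(0:5, function(k)
    c(r6 * cos(k * pi / 3), r6 * sin(k * pi / 3), 0), numeric(3)))
  rownames(hex) <- hex_names
  r5 <- 1.39 / (2 * sin(pi / 5))
  mid <- (hex["C4", ] + hex["C5", ]) / 2
  u <- mid / sqrt(sum(mid^2))
  ctr5 <- mid + (r5 * cos(pi / 5)) * u
  ang <- function(p) atan2(p[2] - ctr5[2], p[1] - ctr5[1])
  a_C4 <- ang(hex["C4", ])
  ## cycle N9-C4-C5-N7-C8 runs clockwise from C4 here (-72 deg steps)
  pent_at <- function(theta) ctr5 + r5 * c(cos(theta), sin(theta), 0)
  pent <- rbind(N9 = pent_at(a_C4 + 2 * pi / 5),
                N7 = pent_at(a_C4 - 2 * 2 * pi / 5),
                C8 = pent_at(a_C4 - 3 * 2 * pi / 5))
  rbind(hex, pent)
}

## Z-matrix style placement: position d bonded to c with given length,
## angle d-c-b and dihedral d-c-b-a
place_atom_zmatrix <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180; ph <- torsion_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## build one purine nucleotide (base ring template + C1'/O4') with the
## requested glycosidic torsion chi
build_purine_nucleotide <- function(base_type, chi_deg, residue_id = 1) {
  tmpl <- purine_template()
  r5 <- 1.39 / (2 * sin(pi / 5))
  ctr5 <- colMeans(tmpl[c("N9", "C4", "C5", "N7", "C8"), ]) # pentagon centroid
  u9 <- tmpl["N9", ] - ctr5; u9 <- u9 / sqrt(sum(u9^2))
  C1p <- tmpl["N9", ] + 1.47 * u9
  O4p <- place_atom_zmatrix(tmpl["C4", ], tmpl["N9", ], C1p,
                            bond = 1.42, angle_deg = 109.5,
                            torsion_deg = chi_deg)
  atoms <- rbind(tmpl, `C1'` = C1p, `O4'` = O4p)
  nucleotide_structure(residue_id, base_type, atoms)
}

rotate_z <- function(xyz, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  out <- xyz %*% t(R)
  rownames(out) <- rownames(xyz)
  out
}

transform_nucleotide <- function(nuc, R = diag(3), shift = c(0, 0, 0)) {
  atoms <- nuc$atoms %*% t(R)
  atoms <- sweep(atoms, 2, shift, `+`)
  rownames(atoms) <- rownames(nuc$atoms)
  nucleotide_structure(nuc$residue_id, nuc$base_type, atoms)
}

#' Generate an ensemble of idealized stacked purine pairs
#'
#' Builds A/G pairs stacked at the given rise with a B-DNA-like twist,
#' drawing each base's glycosidic class from `class_probabilities` and
#' its chi from the class center (anti -120 deg, syn +60 deg) plus
#' Gaussian angular noise. True class labels are kept as an attribute.
#'
#' @param n_frames Number of frames.
#' @param class_probabilities Named probabilities over
#'   `c("anti-anti", "anti-syn", "syn-anti", "syn-syn")` (base1-base2);
#'   must sum to 1.
#' @param geometry_noise Chi noise SD (degrees).
#' @param rise_A Inter-plane separation (Angstrom).
#' @param twist_deg Helical twist between the bases.
#' @param slide_A Length-2 in-plane displacement of the upper base.
#' @param rng_seed Seed.
#' @return List of frames `list(base1 = A, base2 = G)` with attribute
#'   `class_labels`.
#' @export
generate_stacked_frames <- function(n_frames,
                                    class_probabilities = c("anti-anti" = 1),
                                    geometry_noise = 8,
                                    rise_A = 3.4, twist_deg = 36,
                                    slide_A = c(1.0, 0.5),
                                    rng_seed = 1L) {
  if (abs(sum(class_probabilities) - 1) > 1e-9)
    stop("class probabilities must sum to 1")
  classes <- names(class_probabilities)
  if (is.null(classes) ||
      !all(classes %in% c("anti-anti", "anti-syn", "syn-anti", "syn-syn")))
    stop("class_probabilities must be named with '<class1>-<class2>' labels")
  centers <- c(anti = -120, syn = 60)
  with_preserved_rng(rng_seed, {
    labels <- sample(classes, n_frames, replace = TRUE,
                     prob = class_probabilities)
    frames <- lapply(seq_len(n_frames), function(i) {
      cl <- strsplit(labels[i], "-")[[1]]
      chi1 <- centers[[cl[1]]] + stats::rnorm(1, 0, geometry_noise)
      chi2 <- centers[[cl[2]]] + stats::rnorm(1, 0, geometry_noise)
      wrap <- function(x) ((x + 180) %% 360) - 180 + 360 * (x == -180)
      b1 <- build_purine_nucleotide("A", wrap(chi1), residue_id = 1)
      b2 <- build_purine_nucleotide("G", wrap(chi2), residue_id = 2)
      th <- twist_deg * pi / 180
      R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                  3, 3)
      b2 <- transform_nucleotide(b2, R, c(slide_A[1], slide_A[2], rise_A))
      list(base1 = b1, base2 = b2)
    })
    attr(frames, "class_labels") <- labels
    frames
  })
}
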