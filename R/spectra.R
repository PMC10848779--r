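## Wavelength-resolved bookkeeping: spectra, photon flux, competitive
## absorption, absorbed photon/energy rates.

#' Physical constants used throughout the package
#'
#' CODATA values: Planck constant `h_J_s`, speed of light `c_m_s`,
#' Avogadro constant `N_A`, and the eV/nm conversion constant
#' `eV_nm = 1239.84198` (so that E\[eV\] = eV_nm / lambda\[nm\]).
#'
#' @format A named list with elements `h_J_s`, `c_m_s`, `N_A`, `eV_nm`.
#' @export
photo_constants <- list(
  h_J_s = 6.62607015e-34,
  c_m_s = 2.99792458e8,
  N_A   = 6.02214076e23,
  eV_nm = 1239.84198
)

trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Construct a spectrum
#'
#' A spectrum pairs a strictly increasing wavelength grid (nm, within
#' 200--700) with nonnegative values: either a molar decadic absorption
#' coefficient epsilon(lambda) in M^-1 cm^-1 (`kind = "molar_absorption"`)
#' or a normalized emission density in nm^-1 (`kind = "emission_density"`,
#' trapezoid integral 1 within 1e-6).
#'
#' @param wavelengths_nm Strictly increasing numeric vector in \[200, 700\].
#' @param values Nonnegative numeric vector, same length.
#' @param kind `"molar_absorption"` or `"emission_density"`.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavelengths_nm, values,
                     kind = c("molar_absorption", "emission_density")) {
  kind <- match.arg(kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths_nm and values must have equal length")
  if (length(wavelengths_nm) < 2)
    stop("a spectrum needs at least two points")
  if (any(!is.finite(wavelengths_nm)) || any(!is.finite(values)))
    stop("non-finite entries in spectrum")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths_nm must be strictly increasing")
  if (min(wavelengths_nm) < 200 || max(wavelengths_nm) > 700)
    stop("wavelengths_nm must lie within [200, 700] nm")
  if (any(values < 0))
    stop("spectrum values must be nonnegative")
  if (kind == "emission_density") {
    I <- trapz(wavelengths_nm, values)
    if (abs(I - 1) > 1e-6)
      stop(sprintf("emission density must integrate to 1 (got %.8f)", I))
  }
  structure(list(wavelengths_nm = wavelengths_nm, values = values, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.1f-%.1f nm>\n",
              x$kind, length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Read a spectrum from a two-column CSV
#'
#' Expects a header and columns `wavelength_nm,value`.
#'
#' @param path CSV file path.
#' @param kind Spectrum kind, see [spectrum()].
#' @return A `spectrum`.
#' @export
read_spectrum_csv <- function(path, kind = "molar_absorption") {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d)))
    stop("spectrum CSV needs columns wavelength_nm,value")
  spectrum(d$wavelength_nm, d$value, kind = kind)
}

#' Write a spectrum to CSV
#' @param spec A `spectrum`.
#' @param path Output path.
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(data.frame(wavelength_nm = spec$wavelengths_nm,
                              value = spec$values),
                   path, row.names = FALSE)
}

#' Gaussian LED emission spectrum
#'
#' Models an LED band as a Gaussian in wavelength, truncated at +/- 3 sigma
#' and renormalized to unit trapezoid integral. The default grid spacing is
#' 0.25 nm, fine enough to resolve a 15 nm wide band.
#'
#' @param center_nm Band center (nm).
#' @param fwhm_nm Full width at half maximum (nm).
#' @param grid Optional wavelength grid; default covers +/- 3 sigma.
#' @return A `spectrum` of kind `emission_density`.
#' @export
gaussian_emission <- function(center_nm, fwhm_nm, grid = NULL) {
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  if (is.null(grid))
    grid <- seq(center_nm - 3 * sigma, center_nm + 3 * sigma,
                length.out = max(9, round(24 * sigma) + 1))
  v <- exp(-(grid - center_nm)^2 / (2 * sigma^2))
  v <- v / trapz(grid, v)
  spectrum(grid, v, kind = "emission_density")
}

#' Construct a beam
#'
#' A beam couples a normalized emission spectrum with the total average
#' radiant power at the sample position.
#'
#' @param emission A `spectrum` of kind `emission_density`.
#' @param power_W Total power (W), > 0 (0 allowed to express a dark beam).
#' @return An object of class `"beam"`.
#' @export
beam <- function(emission, power_W) {
  stopifnot(inherits(emission, "spectrum"))
  if (emission$kind != "emission_density")
    stop("beam emission must be an emission_density spectrum")
  if (!is.finite(power_W) || power_W < 0)
    stop("power_W must be a nonnegative number")
  structure(list(emission = emission, power_W = power_W), class = "beam")
}

#' Construct a sample cell
#'
#' @param path_length_cm Optical path length (cm), > 0.
#' @param volume_L Illuminated solution volume (L), > 0.
#' @param temperature_note Free-text note.
#' @return An object of class `"sample_cell"`.
#' @export
sample_cell <- function(path_length_cm = 1, volume_L = 1e-3,
                        temperature_note = "room temperature") {
  if (!is.finite(path_length_cm) || path_length_cm <= 0)
    stop("path_length_cm must be > 0")
  if (!is.finite(volume_L) || volume_L <= 0)
    stop("volume_L must be > 0")
  structure(list(path_length_cm = path_length_cm, volume_L = volume_L,
                 temperature_note = temperature_note),
            class = "sample_cell")
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; outside the spectrum's support the value is 0.
#' Emission spectra are renormalized to unit integral on the new grid.
#' The grid may extend at most 5 nm beyond the spectrum's support.
#'
#' @param spec A `spectrum`.
#' @param grid Strictly increasing wavelength grid (nm).
#' @return A `spectrum` on `grid`.
#' @export
resample_to_grid <- function(spec, grid) {
  stopifnot(inherits(spec, "spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0))
    stop("grid must be strictly increasing (non-monotone grid rejected)")
  lo <- min(spec$wavelengths_nm); hi <- max(spec$wavelengths_nm)
  ## absorption coefficients must not be extrapolated; emission bands may
  ## be embedded in a wider grid (zero outside their support)
  if (spec$kind == "molar_absorption" &&
      (min(grid) < lo - 5 || max(grid) > hi + 5))
    stop("grid extends more than 5 nm beyond the spectrum support")
  v <- stats::approx(spec$wavelengths_nm, spec$values, xout = grid,
                     rule = 1)$y
  v[is.na(v)] <- 0
  if (spec$kind == "emission_density") {
    I <- trapz(grid, v)
    if (I <= 0) stop("resampled emission has zero integral on this grid")
    v <- v / I
  }
  spectrum(grid, v, kind = spec$kind)
}

#' Per-wavelength photon rate of a beam
#'
#' q(lambda) = P s(lambda) lambda / (h c), in photons s^-1 nm^-1, so that
#' the energy integral of q(lambda) h c / lambda recovers the beam power.
#'
#' @param bm A `beam`.
#' @return Data frame with `wavelength_nm` and `photons_per_s_nm`.
#' @export
photon_flux_density <- function(bm) {
  stopifnot(inherits(bm, "beam"))
  lam <- bm$emission$wavelengths_nm
  q <- bm$power_W * bm$emission$values * (lam * 1e-9) /
    (photo_constants$h_J_s * photo_constants$c_m_s)
  data.frame(wavelength_nm = lam, photons_per_s_nm = q)
}

#' Competitive Beer-Lambert absorption partition
#'
#' Given species absorption spectra on a common grid, concentrations, cell
#' and beam, computes per-species absorbance A_i(lambda) = eps_i c_i l,
#' total absorbance, per-species absorbed photon rates
#' R_i = integral q(lambda) (1 - 10^-A_tot) A_i / A_tot dlambda, and the
#' total absorbed energy rate (W). Where A_tot < 1e-6 the absorbed factor
#' is evaluated by its series ln(10) A_i to avoid 0/0.
#'
#' @param epsilons List of `spectrum` objects (molar_absorption) on one grid.
#' @param concentrations_M Species concentrations (M), >= 0.
#' @param cell A `sample_cell`.
#' @param bm A `beam` whose emission shares the same grid.
#' @return List with `A` (matrix, wavelength x species), `A_tot`,
#'   `photon_rate_per_species` (photons/s), `total_photon_rate`,
#'   `energy_dose_rate_W`, and `wavelength_nm`.
#' @export
absorption_partition <- function(epsilons, concentrations_M, cell, bm) {
  stopifnot(inherits(cell, "sample_cell"), inherits(bm, "beam"))
  if (length(epsilons) != length(concentrations_M))
    stop("one concentration per spectrum required")
  if (any(concentrations_M < 0))
    stop("concentrations must be nonnegative")
  lam <- bm$emission$wavelengths_nm
  for (e in epsilons) {
    if (!inherits(e, "spectrum") || e$kind != "molar_absorption")
      stop("epsilons must be molar_absorption spectra")
    if (length(e$wavelengths_nm) != length(lam) ||
        any(abs(e$wavelengths_nm - lam) > 1e-9))
      stop("mismatched wavelength grids; resample to a common grid first")
  }
  eps <- vapply(epsilons, function(e) e$values, numeric(length(lam)))
  eps <- matrix(eps, nrow = length(lam))
  A <- sweep(eps, 2, concentrations_M * cell$path_length_cm, `*`)
  A_tot <- rowSums(A)
  q <- photon_flux_density(bm)$photons_per_s_nm
  ## absorbed fraction per unit A_i: (1 - 10^-A_tot)/A_tot, series for tiny A
  fac <- ifelse(A_tot < 1e-6, log(10) * (1 - log(10) * A_tot / 2),
                (1 - 10^(-A_tot)) / pmax(A_tot, .Machine$double.xmin))
  absorbed_per_A <- q * fac              # photons s^-1 nm^-1 per unit absorbance
  R <- vapply(seq_len(ncol(A)), function(i) trapz(lam, absorbed_per_A * A[, i]),
              numeric(1))
  E_ph <- photo_constants$h_J_s * photo_constants$c_m_s / (lam * 1e-9)
  energy_rate <- trapz(lam, absorbed_per_A * A_tot * E_ph)
  list(wavelength_nm = lam, A = A, A_tot = A_tot,
       photon_rate_per_species = R,
       total_photon_rate = sum(R),
       energy_dose_rate_W = energy_rate)
}

#' Photon-weighted effective absorption coefficient
#'
#' epsilon_bar = integral s(lambda) lambda eps(lambda) dlambda /
#' integral s(lambda) lambda dlambda over the beam support; the weight
#' s(lambda) lambda is proportional to the photon flux density.
#'
#' @param epsilon A molar_absorption `spectrum`.
#' @param bm A `beam`.
#' @return Effective epsilon (M^-1 cm^-1).
#' @export
effective_epsilon <- function(epsilon, bm) {
  stopifnot(inherits(epsilon, "spectrum"), inherits(bm, "beam"))
  if (epsilon$kind != "molar_absorption")
    stop("epsilon must be a molar_absorption spectrum")
  lam <- bm$emission$wavelengths_nm
  if (max(lam) < min(epsilon$wavelengths_nm) ||
      min(lam) > max(epsilon$wavelengths_nm))
    stop("beam outside spectrum support")
  eps <- stats::approx(epsilon$wavelengths_nm, epsilon$values, xout = lam,
                       rule = 2)$y
  w <- bm$emission$values * lam
  trapz(lam, w * eps) / trapz(lam, w)
}

#' Interpolate a spectrum at one wavelength
#' @param spec A `spectrum`.
#' @param lambda_nm Wavelength (nm).
#' @return Interpolated value.
#' @export
spectrum_at <- function(spec, lambda_nm) {
  stats::approx(spec$wavelengths_nm, spec$values, xout = lambda_nm,
                rule = 1)$y
}
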