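# shared fixtures, built in code

# optically thin variant of the default scenario (peak A_tot ~ 0.03)
thin_config <- function(sequence_label = "TTAG", ...) {
  scenario_config(sequence_label, c0_M = 2e-6, sigma_OD = 0, ...)
}

# narrow quasi-monochromatic beam at a given wavelength
mono_beam <- function(center_nm = 285, power_W = 0.36e-3) {
  g <- center_nm + c(-2e-3, 0, 2e-3)
  v <- c(0, 1, 0)
  v <- v / photorepair:::trapz(g, v)
  beam(spectrum(g, v, "emission_density"), power_W)
}

# flat absorption spectrum on a small grid around 285 nm
flat_epsilon <- function(value, grid = seq(280, 290, by = 0.5)) {
  spectrum(grid, rep(value, length(grid)), "molar_absorption")
}

# two-state scheme with flat epsilons on the mono-beam grid
flat_scheme <- function(eps_d = 4000, eps_r = 6000, phi_r = 0.005,
                        phi_d = 0.003, phi_s = 0,
                        grid = seq(280, 290, by = 0.5)) {
  reaction_scheme(photo_species("damaged", flat_epsilon(eps_d, grid)),
                  photo_species("repaired", flat_epsilon(eps_r, grid)),
                  phi_repair = phi_r, phi_damage = phi_d, phi_side = phi_s)
}

mono_beam_on <- function(grid, center_nm = 285, power_W = 0.36e-3,
                         fwhm_nm = 1) {
  resample_to_grid(gaussian_emission(center_nm, fwhm_nm), grid) |>
    beam(power_W)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_move <- function(nuc, R, shift) {
  photorepair:::transform_nucleotide(nuc, R, shift)
}
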