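test_that("rate vector: dark beam, conservation, and a hand-evaluated case", {
  grid <- seq(280, 290, by = 0.5)
  cell <- sample_cell(1, 1e-3)
  sch <- flat_scheme(grid = grid)
  dark <- beam(mono_beam_on(grid)$emission, 0)
  expect_equal(rate_vector(c(3e-5, 0, 0), sch, dark, cell)$dC_dt_M_s,
               c(damaged = 0, repaired = 0, side = 0))
  ## one-way reaction conserves the pool exactly
  sch1 <- flat_scheme(phi_d = 0, grid = grid)
  rv <- rate_vector(c(3e-5, 0, 0), sch1, mono_beam_on(grid), cell)
  expect_gt(rv$dC_dt_M_s[["repaired"]], 0)
  expect_equal(sum(rv$dC_dt_M_s), 0)
  ## hand-evaluated quasi-monochromatic case: A_tot = 0.1, P = 0.36 mW
  bm <- mono_beam(285, 0.36e-3)
  g3 <- bm$emission$wavelengths_nm
  sch2 <- reaction_scheme(
    photo_species("damaged", flat_epsilon(1e4, g3)),
    photo_species("repaired", flat_epsilon(1e4, g3)),
    phi_repair = 0.005, phi_damage = 0)
  conc <- c(1e-5, 0, 0)                      # A_tot = 1e4 * 1e-5 * 1 = 0.1
  rv2 <- rate_vector(conc, sch2, bm, cell)
  Q <- 0.36e-3 * 285e-9 / (photo_constants$h_J_s * photo_constants$c_m_s)
  oracle <- 0.005 * Q * (1 - 10^(-0.1)) / (photo_constants$N_A * 1e-3)
  expect_equal(rv2$dC_dt_M_s[["repaired"]], oracle, tolerance = 1e-9)
  expect_error(rate_vector(c(-1e-6, 0, 0), sch, mono_beam_on(grid), cell),
               "negative")
})

test_that("a zero-length schedule returns the initial state with zero dose", {
  grid <- seq(280, 290, by = 0.5)
  tc <- simulate_time_course(flat_scheme(grid = grid), mono_beam_on(grid),
                             sample_cell(1, 1e-3), c(3e-5, 0), 0)
  expect_equal(nrow(tc), 1)
  expect_equal(tc$dose_J, 0)
  expect_equal(tc$c_damaged_M, 3e-5)
  expect_equal(tc$repair_fraction, 0)
})

test_that("one-way photoreaction drives the repair fraction monotonically to 1", {
  grid <- seq(280, 290, by = 0.5)
  sch <- flat_scheme(phi_r = 0.01, phi_d = 0, grid = grid)
  tc <- simulate_time_course(sch, mono_beam_on(grid), sample_cell(1, 2e-4),
                             c(3e-5, 0), seq(0, 2e5, length.out = 40))
  ## monotone up to the solver's relative tolerance near the plateau
  expect_true(all(diff(tc$repair_fraction) >= -1e-7))
  expect_gt(utils::tail(tc$repair_fraction, 1), 0.999)
  expect_true(all(diff(tc$dose_J) >= 0))
})

test_that("optically thin kinetics match the closed-form two-state exponential", {
  bm <- mono_beam(285, 0.36e-3)
  g3 <- bm$emission$wavelengths_nm
  eps_d <- 5e3; eps_r <- 8e3; phi_r <- 0.006; phi_d <- 0.004
  cell <- sample_cell(1, 1e-3)
  sch <- reaction_scheme(photo_species("damaged", flat_epsilon(eps_d, g3)),
                         photo_species("repaired", flat_epsilon(eps_r, g3)),
                         phi_repair = phi_r, phi_damage = phi_d)
  c0 <- 5e-8                                 # peak A_tot = 4e-4: thin
  Q <- 0.36e-3 * 285e-9 / (photo_constants$h_J_s * photo_constants$c_m_s)
  k <- log(10) * Q * (phi_r * eps_d + phi_d * eps_r) /
    (photo_constants$N_A * cell$volume_L)
  f_pss <- phi_r * eps_d / (phi_r * eps_d + phi_d * eps_r)
  t_grid <- seq(0, 3 / k, length.out = 25)
  tc <- simulate_time_course(sch, bm, cell, c(c0, 0), t_grid)
  oracle <- f_pss * (1 - exp(-k * t_grid))
  expect_equal(tc$repair_fraction, oracle, tolerance = 1e-3)
})

test_that("total oligomer concentration is conserved to 1e-9 M without a side channel", {
  set.seed(11)
  grid <- seq(260, 310, by = 1)
  cell <- sample_cell(1, 1e-3)
  for (rep in 1:4) {
    sch <- flat_scheme(eps_d = runif(1, 2e3, 2e4), eps_r = runif(1, 2e3, 2e4),
                       phi_r = runif(1, 1e-3, 2e-2),
                       phi_d = runif(1, 1e-3, 2e-2), grid = grid)
    bm <- beam(resample_to_grid(gaussian_emission(285, 15), grid),
               runif(1, 1e-4, 1e-3))
    c0 <- runif(1, 1e-5, 5e-5)
    tc <- simulate_time_course(sch, bm, cell, c(c0 * 0.7, c0 * 0.3),
                               seq(0, 5e4, length.out = 12))
    tot <- tc$c_damaged_M + tc$c_repaired_M + tc$c_side_M
    expect_lt(max(abs(tot - c0)), 1e-9)
    ## no overshoot: the two-state repair fraction approaches its limit
    ## monotonically (up to solver tolerance)
    expect_true(all(diff(tc$repair_fraction) > -1e-7) ||
                  all(diff(tc$repair_fraction) < 1e-7))
  }
})

test_that("an irreversible side channel drains the oligomer pool as specified", {
  grid <- seq(280, 290, by = 0.5)
  sch <- flat_scheme(phi_s = 0.002, grid = grid)
  cell <- sample_cell(1, 1e-3)
  rv <- rate_vector(c(1e-5, 2e-5, 0), sch, mono_beam_on(grid), cell)
  R_rep <- rv$photon_rate_per_species[2]
  expect_equal(rv$dC_dt_M_s[["damaged"]] + rv$dC_dt_M_s[["repaired"]],
               -0.002 * R_rep / (photo_constants$N_A * cell$volume_L))
  expect_equal(sum(rv$dC_dt_M_s), 0)         # side product is tracked
  expect_error(pss_fraction(sch, mono_beam_on(grid), cell),
               "irreversible")
})

test_that("halving the power and doubling the duration leaves fraction-vs-dose unchanged", {
  grid <- seq(260, 310, by = 1)
  sch <- flat_scheme(grid = grid)
  cell <- sample_cell(1, 1e-3)
  em <- resample_to_grid(gaussian_emission(285, 15), grid)
  t_grid <- seq(0, 4e4, length.out = 15)
  tc1 <- simulate_time_course(sch, beam(em, 4e-4), cell, c(3e-5, 0), t_grid)
  tc2 <- simulate_time_course(sch, beam(em, 2e-4), cell, c(3e-5, 0),
                              2 * t_grid)
  expect_equal(tc2$dose_J, tc1$dose_J, tolerance = 1e-7)
  expect_equal(tc2$repair_fraction, tc1$repair_fraction, tolerance = 1e-6)
})

test_that("photostationary state: limits, symmetry and independence of the start", {
  grid <- seq(280, 290, by = 0.5)
  cell <- sample_cell(1, 1e-3)
  bm <- mono_beam_on(grid)
  ## phi_damage = 0: everything repairs
  expect_equal(pss_fraction(flat_scheme(phi_d = 0, grid = grid), bm, cell,
                            "analytic_thin"), 1)
  ## symmetric scheme: half and half
  sym <- flat_scheme(eps_d = 5e3, eps_r = 5e3, phi_r = 0.004, phi_d = 0.004,
                     grid = grid)
  expect_equal(pss_fraction(sym, bm, cell, "analytic_thin"), 0.5)
  ## ode limit independent of the initial composition
  sch <- flat_scheme(eps_d = 4e3, eps_r = 7e3, phi_r = 0.006, phi_d = 0.003,
                     grid = grid)
  f_from_damaged <- pss_fraction(sch, bm, cell, "ode_limit",
                                 c0_M = c(3e-5, 0))
  f_from_repaired <- pss_fraction(sch, bm, cell, "ode_limit",
                                  c0_M = c(0, 3e-5))
  expect_lt(abs(f_from_damaged - f_from_repaired), 1e-4)
})

test_that("analytic-thin and ODE-limit photostationary states agree when thin", {
  set.seed(23)
  grid <- seq(280, 290, by = 0.5)
  cell <- sample_cell(1, 1e-3)
  bm <- mono_beam_on(grid)
  for (rep in 1:3) {
    sch <- flat_scheme(eps_d = runif(1, 2e3, 1e4),
                       eps_r = runif(1, 2e3, 1e4),
                       phi_r = runif(1, 2e-3, 1e-2),
                       phi_d = runif(1, 2e-3, 1e-2), grid = grid)
    ## peak A_tot <= 0.05 for c0 = 5e-6 and eps <= 1e4
    fa <- pss_fraction(sch, bm, cell, "analytic_thin")
    fo <- pss_fraction(sch, bm, cell, "ode_limit", c0_M = c(5e-6, 0))
    expect_equal(fo, fa, tolerance = 0.01)
  }
})

test_that("species probe coefficients must match their spectra at 266 nm", {
  g <- seq(250, 300, 1)
  eps <- spectrum(g, rep(1e4, length(g)))
  expect_error(photo_species("damaged", eps, epsilon_probe_266 = 1.2e4),
               "inconsistent")
  expect_equal(photo_species("damaged", eps)$epsilon_probe_266, 1e4)
})
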