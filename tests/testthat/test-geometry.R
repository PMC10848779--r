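test_that("dihedral angles: cis is 0, trans is 180, sign matches the field convention", {
  a <- c(-0.5, 1, 0); b <- c(0, 0, 0); c3 <- c(1.5, 0, 0)
  expect_equal(dihedral_angle(a, b, c3, c(2.0, 1, 0)), 0)      # eclipsed
  expect_equal(dihedral_angle(a, b, c3, c(2.0, -1, 0)), 180)   # anti
  ## randomized agreement with the bio3d torsion oracle
  set.seed(14)
  for (i in 1:10) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 bio3d::torsion.xyz(as.numeric(t(p))), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("chi torsion is rigid-motion invariant and uses the right atoms", {
  set.seed(21)
  nuc <- photorepair:::build_purine_nucleotide("G", -123)
  chi0 <- chi_torsion(nuc)
  expect_equal(chi0, -123, tolerance = 1e-9)
  for (i in 1:8) {
    moved <- rigid_move(nuc, random_rotation(), rnorm(3, sd = 10))
    expect_equal(chi_torsion(moved), chi0, tolerance = 1e-9)
  }
  ## a missing torsion atom is reported by name
  broken <- nuc
  broken$atoms <- broken$atoms[setdiff(rownames(broken$atoms), "O4'"), ]
  expect_error(nucleotide_structure(1, "G", broken$atoms), "O4'")
})

test_that("syn/anti classification partitions the circle with documented boundaries", {
  expect_equal(classify_glycosidic(0), "syn")
  expect_equal(classify_glycosidic(180), "anti")
  expect_equal(classify_glycosidic(-90.01), "anti")
  expect_equal(classify_glycosidic(90), "syn")
  expect_equal(classify_glycosidic(-90), "anti")
  expect_error(classify_glycosidic(270), "-180")
  chis <- seq(-179.9, 180, by = 0.1)
  expect_true(all(classify_glycosidic(chis) %in% c("syn", "anti")))
})

test_that("stacking overlap: eclipsed rings give the full ring area, distant give 0", {
  b1 <- photorepair:::build_purine_nucleotide("A", -120)
  b2 <- rigid_move(b1, diag(3), c(0, 0, 3.4))
  ov <- stacking_overlap_area(b1, b2)
  hex_area <- 3 * sqrt(3) / 2 * 1.39^2
  pent_area <- 5 * 1.39^2 / (4 * tan(pi / 5))
  expect_equal(as.numeric(ov), hex_area + pent_area, tolerance = 1e-9)
  expect_equal(attr(ov, "rise_A"), 3.4, tolerance = 1e-9)
  far <- rigid_move(b1, diag(3), c(20, 0, 3.4))
  expect_equal(as.numeric(stacking_overlap_area(b1, far)), 0)
  ## overlap never exceeds the smaller ring-system area
  expect_lte(as.numeric(ov), hex_area + pent_area + 1e-12)
})

test_that("stacking overlap agrees with Monte-Carlo point sampling within 2%", {
  skip_if_not_installed("mgcv")
  frames <- generate_stacked_frames(3, c("anti-anti" = 1),
                                    geometry_noise = 10, rng_seed = 31)
  set.seed(31)
  for (fr in frames) {
    ringsA <- photorepair:::base_ring_coords(fr$base1)
    ringsB <- photorepair:::base_ring_coords(fr$base2)
    pl <- photorepair:::fit_plane(do.call(rbind, ringsA))
    pa <- lapply(ringsA, photorepair:::project_to_plane, plane = pl)
    pb <- lapply(ringsB, photorepair:::project_to_plane, plane = pl)
    mine <- sum(photorepair:::overlap_in_plane(ringsA, ringsB, pl))
    pts <- rbind(do.call(rbind, pa), do.call(rbind, pb))
    n <- 2e5
    P <- cbind(runif(n, min(pts[, 1]), max(pts[, 1])),
               runif(n, min(pts[, 2]), max(pts[, 2])))
    inside <- function(polys)
      Reduce(`|`, lapply(polys, function(pg) mgcv::in.out(rbind(pg, pg[1, ]), P)))
    mc <- mean(inside(pa) & inside(pb)) *
      diff(range(pts[, 1])) * diff(range(pts[, 2]))
    expect_equal(mine, mc, tolerance = 0.02)
  }
})

test_that("overlap is symmetric in its arguments and rigid-motion invariant", {
  set.seed(37)
  frames <- generate_stacked_frames(3, c("anti-syn" = 1), rng_seed = 5)
  for (fr in frames) {
    oAB <- stacking_overlap_area(fr$base1, fr$base2)
    oBA <- stacking_overlap_area(fr$base2, fr$base1)
    expect_equal(as.numeric(oAB), as.numeric(oBA), tolerance = 1e-9)
    R <- random_rotation(); sh <- rnorm(3, sd = 25)
    oMoved <- stacking_overlap_area(rigid_move(fr$base1, R, sh),
                                    rigid_move(fr$base2, R, sh))
    expect_equal(as.numeric(oMoved), as.numeric(oAB), tolerance = 1e-6)
    expect_equal(attr(oMoved, "rise_A"), attr(oAB, "rise_A"),
                 tolerance = 1e-6)
  }
})

test_that("degenerate collinear ring atoms are rejected", {
  nuc <- photorepair:::build_purine_nucleotide("A", -120)
  squashed <- nuc$atoms
  squashed[, 2:3] <- 0                       # flatten everything onto a line
  line_nuc <- nucleotide_structure(1, "A", squashed)
  expect_error(stacking_overlap_area(line_nuc, nuc), "collinear")
})

test_that("conformer census counts deterministic mixtures exactly", {
  anti <- generate_stacked_frames(6, c("anti-anti" = 1), geometry_noise = 0,
                                  rng_seed = 1)
  syn <- generate_stacked_frames(4, c("syn-syn" = 1), geometry_noise = 0,
                                 rng_seed = 2)
  census <- conformer_census(c(anti, syn))
  expect_equal(unname(census$fractions["anti-anti"]), 0.6)
  expect_equal(unname(census$fractions["syn-syn"]), 0.4)
  expect_equal(sum(census$fractions), 1)
  uniform <- conformer_census(anti)
  expect_equal(unname(uniform$fractions["anti-anti"]), 1)
  expect_error(conformer_census(list()), "at least one")
})

test_that("census recovers generator class probabilities within binomial error", {
  n <- 2000
  frames <- generate_stacked_frames(n, c("anti-anti" = 0.5, "syn-syn" = 0.5),
                                    geometry_noise = 8, rng_seed = 77)
  census <- conformer_census(frames)
  se3 <- 3 * sqrt(0.25 / n)
  expect_lt(abs(census$fractions[["anti-anti"]] - 0.5), se3 + 0.01)
})

test_that("frames with a missing base are skipped and counted", {
  frames <- generate_stacked_frames(5, c("anti-anti" = 1), rng_seed = 3)
  broken <- frames[[1]]
  broken$base1$atoms <- broken$base1$atoms[
    setdiff(rownames(broken$base1$atoms), "C1'"), ]
  census <- conformer_census(c(frames[2:5], list(broken)))
  expect_equal(census$n_skipped, 1L)
  expect_equal(sum(census$counts), 4L)
})

test_that("multi-model PDB round trip preserves torsions and classes", {
  frames <- generate_stacked_frames(3, c("anti-anti" = 0.5, "syn-syn" = 0.5),
                                    rng_seed = 12)
  f <- tempfile(fileext = ".pdb")
  write_frames_pdb(frames, f)
  back <- read_structure_frames(f)
  expect_length(back, 3)
  for (i in 1:3) {
    pair <- list(base1 = back[[i]][["1"]], base2 = back[[i]][["2"]])
    expect_equal(chi_torsion(pair$base1), chi_torsion(frames[[i]]$base1),
                 tolerance = 0.01)
    expect_equal(stack_metrics(pair$base1, pair$base2)$class2,
                 stack_metrics(frames[[i]]$base1, frames[[i]]$base2)$class2)
  }
  unlink(f)
})

test_that("the per-frame metrics table reports both torsions, classes and overlap", {
  frames <- generate_stacked_frames(4, c("anti-anti" = 1), rng_seed = 8)
  tab <- stack_metrics_table(frames)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("chi1_deg", "class1", "chi2_deg", "class2",
                    "overlap_A2", "rise_A") %in% names(tab)))
  expect_true(all(tab$class1 == "anti" & tab$class2 == "anti"))
  expect_true(all(tab$overlap_A2 >= 0))
})
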