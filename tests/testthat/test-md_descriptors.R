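# Chromophore geometry and fluctuation descriptors.

test_that("dihedral matches the fixed sign convention and symmetry cases", {
  # planar cis and trans
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180)
  # frozen hand-computed case fixing the sign convention
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
               -90)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral is invariant to atom-order reversal and negated by mirror", {
  set.seed(4)
  for (i in 1:25) {
    p <- lapply(1:4, function(.) rnorm(3))
    d <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_equal(dihedral(p[[4]], p[[3]], p[[2]], p[[1]]), d,
                 tolerance = 1e-9)
    mir <- lapply(p, function(x) x * c(1, 1, -1))
    expect_equal(dihedral(mir[[1]], mir[[2]], mir[[3]], mir[[4]]), -d,
                 tolerance = 1e-9)
  }
})

test_that("descriptors are invariant under global rigid motion", {
  tr <- make_trajectory(trajectory_recipe(
    n_frames = 40, dihedral_targets = list(torsion15 = c(20, 5)),
    jitter_sigma = 0.05, seed = 13))
  d0 <- compute_descriptors(tr)
  set.seed(99)
  co <- tr$coords
  for (f in seq_len(dim(co)[1])) {
    R <- rand_rotation_matrix()
    co[f, , ] <- co[f, , ] %*% t(R) +
      matrix(runif(3, -10, 10), dim(co)[2], 3, byrow = TRUE)
  }
  d1 <- compute_descriptors(trajectory(tr$atoms, co))
  for (f in c("torsion15_median", "angle3_median", "torsion3_median",
              "torsion12_median", "rmsf_auc")) {
    expect_equal(d1[[f]], d0[[f]], tolerance = 1e-6)
  }
})

test_that("bond angle agrees with the law-of-cosines oracle", {
  expect_equal(bond_angle(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0)), 180)
  expect_equal(bond_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  set.seed(5)
  for (i in 1:25) {
    p <- lapply(1:3, function(.) rnorm(3, sd = 3))
    expect_equal(bond_angle(p[[1]], p[[2]], p[[3]]),
                 oracle_angle(p[[1]], p[[2]], p[[3]]), tolerance = 1e-9)
  }
  expect_error(bond_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length")
})

test_that("angle series median is circular-aware", {
  # constant series
  tr <- make_trajectory(trajectory_recipe(
    n_frames = 4, dihedral_targets = list(torsion15 = c(3.64, 0)),
    jitter_sigma = 0, seed = 1))
  expect_equal(angle_series_median(tr, "torsion15"), 3.64)

  # wrap case: alternating +179/-179 must give 180, not 0
  expect_equal(circular_median_deg(c(179, -179, 179, -179)), 180)
  expect_equal(circular_median_deg(c(10, 20, 30)), 20)

  # wrapped-normal parameter recovery near the seam
  set.seed(21)
  x <- wrap_deg(175 + rnorm(5000, 0, 10))
  expect_equal(circular_median_deg(x), 175, tolerance = 0.5)
})

test_that("RMSF is zero for static and rigid-motion-only trajectories", {
  tr <- toy_trajectory(n_atoms = 6, n_frames = 5)
  expect_equal(max(rmsf_per_atom(tr)), 0, tolerance = 1e-9)

  set.seed(8)
  co <- tr$coords
  for (f in 1:5) {
    R <- rand_rotation_matrix()
    co[f, , ] <- co[f, , ] %*% t(R) + matrix(rnorm(3, 0, 5), 6, 3,
                                             byrow = TRUE)
  }
  moved <- trajectory(tr$atoms, co)
  expect_equal(max(rmsf_per_atom(moved)), 0, tolerance = 1e-9)
})

test_that("isotropic jitter gives the closed-form RMSF", {
  set.seed(31)
  nat <- 60; nfr <- 5000; sigma <- 0.2
  base <- matrix(runif(nat * 3, 0, 20), nat, 3)
  co <- array(0, c(nfr, nat, 3))
  for (f in seq_len(nfr)) {
    co[f, , ] <- base + matrix(rnorm(nat * 3, 0, sigma), nat, 3)
  }
  r <- rmsf_per_atom(trajectory(paste0("A", seq_len(nat)), co))
  # expectation sigma*sqrt(3), slightly shrunk by the 6-DOF rigid fit
  expect_equal(mean(r), sigma * sqrt(3), tolerance = 0.03)
  expect_equal(mean(r), sigma * sqrt(3 * (1 - 2 / nat)), tolerance = 0.01)
})

test_that("RMSF area scales linearly with fluctuation amplitude", {
  aucs <- vapply(c(0.01, 0.02, 0.04), function(s) {
    tr <- make_trajectory(trajectory_recipe(
      n_frames = 400, dihedral_targets = list(), jitter_sigma = s,
      seed = 17))
    rmsf_auc(rmsf_per_atom(tr))
  }, numeric(1))
  expect_equal(aucs[2] / aucs[1], 2, tolerance = 0.1)
  expect_equal(aucs[3] / aucs[2], 2, tolerance = 0.1)
})

test_that("RMSF AUC handles trivial profiles", {
  expect_equal(rmsf_auc(rep(0.5, 10)), 0.5 * 9)
  expect_equal(rmsf_auc(c(0, 1, 0)), 1)
  expect_error(rmsf_auc(0.3), "at least 2")
})

test_that("degenerate inputs raise errors", {
  expect_error(rmsf_per_atom(toy_trajectory(n_frames = 1)), "2 frames")
  co <- array(1, c(3, 4, 3))
  expect_error(rmsf_per_atom(trajectory(paste0("A", 1:4), co)),
               "degenerate")
  tr <- toy_trajectory()
  expect_error(compute_descriptors(tr), "C7")
  expect_error(angle_series_median(tr, c("A1", "A2", "Zz")), "Zz")
})

test_that("descriptor TSV and trajectory dialects round-trip", {
  tr <- make_trajectory(trajectory_recipe(
    n_frames = 3, dihedral_targets = list(torsion15 = c(3.64, 0)),
    jitter_sigma = 0, seed = 2))
  d <- compute_descriptors(tr, pigment_id = "Rh2-1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_descriptors_tsv(d, f)
  back <- read_descriptors_tsv(f)[[1]]
  expect_equal(back$torsion15_median, d$torsion15_median, tolerance = 1e-6)
  expect_equal(back$pigment_id, "Rh2-1")

  ft <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, ft)
  tr2 <- read_trajectory_tsv(ft)
  expect_equal(tr2$atoms, tr$atoms)
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-9)

  fp <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, fp)
  tr3 <- read_trajectory_pdb(fp)
  expect_equal(tr3$atoms, tr$atoms)
  expect_equal(tr3$coords, tr$coords, tolerance = 1e-3)  # PDB prints 3 dp
  d3 <- compute_descriptors(tr3, pigment_id = "Rh2-1")
  expect_equal(d3$torsion15_median, d$torsion15_median, tolerance = 0.01)
})
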