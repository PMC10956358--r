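# Frozen reference values for fixtures/traj_oracle.xyz (5 frames, 12 atoms,
# elements C/N/O/H/S) computed with an established Python trajectory-analysis
# library: mass-weighted RMSD with superposition vs frame 1, mass-weighted
# radius of gyration per frame, and RMSF after two-pass alignment to the
# mean structure.
ORACLE_RMSD <- c(0, 0.85551167, 0.5995231, 0.59201637, 0.7565947)
ORACLE_RG <- c(3.12628983, 3.44612994, 3.32151971, 3.29261161, 3.23954465)
ORACLE_RMSF <- c(0.35770673, 0.6632491, 0.2541344, 0.40973923, 0.43678513,
                 0.41521636, 0.35719883, 0.33129784, 0.3281573, 0.6243111,
                 0.3886868, 0.6637352)
# total Shrake-Rupley SASA of fixtures/sasa_oracle.xyz (30 atoms, Bondi
# radii, probe 1.4 A, 960 points) from an independent structure library
ORACLE_SASA_TOTAL <- 1068.611572265625

test_that("superposition recovers rigid motions and minimizes RMSD", {
  set.seed(5)
  ref <- matrix(rnorm(30, 0, 2), 10, 3)
  # identity case
  fit0 <- superpose(ref, ref)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  for (i in 1:20) {
    set.seed(100 + i)
    ang <- runif(3, -pi, pi)
    Rz <- matrix(c(cos(ang[1]), -sin(ang[1]), 0,
                   sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                   -sin(ang[2]), 0, cos(ang[2])), 3, 3)
    rot <- Rz %*% Ry
    moved <- ref %*% rot + rep(runif(3, -5, 5), each = 10)
    fit <- superpose(moved, ref, weights = runif(10, 0.5, 2))
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
    expect_lt(fit$rmsd, 1e-8)
  }
  # collinear configuration is rejected
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line + 0.1), "degenerate|collinear")
})

test_that("RMSD follows the mass-weighted formula and hand arithmetic", {
  # copies of the reference give all zeros
  ref <- matrix(rnorm(30), 10, 3)
  arr <- array(rep(ref, each = 4), dim = c(4, 10, 3))
  traj <- trajectory(arr)
  expect_equal(rmsd_series(traj, ref), rep(0, 4), tolerance = 1e-10)
  # single atom displaced 2 A among 10 equal masses, no fit: 2/sqrt(10)
  moved <- ref
  moved[1, 1] <- moved[1, 1] + 2
  tr2 <- trajectory(array(moved, dim = c(1, 10, 3)))
  expect_equal(rmsd_series(tr2, ref, fit = FALSE), 2 / sqrt(10),
               tolerance = 1e-12)
  expect_equal(rmsd_series(tr2, ref, fit = FALSE), 0.6325, tolerance = 1e-4)
})

test_that("fitted RMSD is invariant to rigid motion of all frames", {
  sim <- gen_trajectory(n_frames = 8, n_atoms = 15, jitter_sd = 0.4,
                        seed = 12)
  base <- rmsd_series(sim$trajectory, sim$reference)
  ang <- 0.8
  rot <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3)
  arr <- sim$trajectory$coords
  for (f in 1:8) arr[f, , ] <- arr[f, , ] %*% rot + rep(c(3, -2, 7), each = 15)
  moved <- trajectory(arr, masses = sim$trajectory$masses)
  expect_equal(rmsd_series(moved, sim$reference), base, tolerance = 1e-8)
})

test_that("trajectory metrics match the external-library oracle", {
  traj <- read_xyz(fixture_path("traj_oracle.xyz"))
  expect_equal(rmsd_series(traj), ORACLE_RMSD, tolerance = 1e-6)
  expect_equal(radius_of_gyration(traj), ORACLE_RG, tolerance = 1e-6)
  expect_equal(rmsf(traj), ORACLE_RMSF, tolerance = 1e-6)
})

test_that("RMSF matches its closed-form expectation and handles edge cases", {
  # static trajectory: all zeros
  ref <- matrix(rnorm(24), 8, 3)
  static <- trajectory(array(rep(ref, each = 5), dim = c(5, 8, 3)))
  expect_equal(rmsf(static), rep(0, 8), tolerance = 1e-10)
  expect_error(rmsf(trajectory(ref)), "2 frames")
  # i.i.d. isotropic jitter sd 0.5: RMSF -> 0.5 * sqrt(3) (no alignment,
  # which would absorb part of the fluctuation)
  sim <- gen_trajectory(n_frames = 10000, n_atoms = 5, jitter_sd = 0.5,
                        seed = 99)
  f <- rmsf(sim$trajectory, align_first = FALSE)
  expect_true(all(abs(f - 0.5 * sqrt(3)) / (0.5 * sqrt(3)) < 0.05))
})

test_that("RMSF and Rg are invariant to global translation", {
  sim <- gen_trajectory(n_frames = 12, n_atoms = 10, jitter_sd = 0.3,
                        seed = 7)
  arr <- sim$trajectory$coords
  for (f in 1:12) arr[f, , ] <- arr[f, , ] + rep(c(100, -50, 25), each = 10)
  shifted <- trajectory(arr, masses = sim$trajectory$masses)
  expect_equal(rmsf(shifted, align_first = FALSE),
               rmsf(sim$trajectory, align_first = FALSE), tolerance = 1e-9)
  expect_equal(radius_of_gyration(shifted),
               radius_of_gyration(sim$trajectory), tolerance = 1e-9)
})

test_that("radius of gyration follows its mass-weighted definition", {
  # single atom: 0
  expect_equal(radius_of_gyration(trajectory(matrix(c(1, 2, 3), 1, 3))), 0)
  # two equal masses at (+-d, 0, 0): Rg = d
  d <- 2.7
  two <- trajectory(matrix(c(-d, 0, 0, d, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(radius_of_gyration(two), d, tolerance = 1e-12)
})

test_that("hydrogen bonds require both distance and angle criteria", {
  # linear D-H...A, H...A = 2.0 A: counted
  geom <- function(angle_deg, ha_dist) {
    th <- (180 - angle_deg) * pi / 180
    rbind(c(-1, 0, 0),                                 # donor
          c(0, 0, 0),                                  # hydrogen
          c(ha_dist * cos(th), ha_dist * sin(th), 0))  # acceptor
  }
  run <- function(angle_deg, ha_dist, ...) {
    traj <- trajectory(array(geom(angle_deg, ha_dist), dim = c(1, 3, 3)),
                       elements = c("N", "H", "O"))
    hbond_count(traj, donors = 1, hydrogens = 2, acceptors = 3, ...)
  }
  expect_equal(run(180, 2.0)$counts, 1)
  expect_equal(run(120, 2.0)$counts, 0)  # angle fails
  expect_equal(run(180, 3.6)$counts, 0)  # distance fails
  expect_equal(run(151, 3.4)$counts, 1)  # just inside both windows
  expect_equal(run(149, 2.0)$counts, 0)
  # donor-acceptor distance mode uses the D...A separation instead
  expect_equal(run(180, 2.6, distance_mode = "DA")$counts, 0)  # D..A = 3.6
  expect_equal(run(180, 2.3, distance_mode = "DA")$counts, 1)  # D..A = 3.3
  # occupancy across frames
  arr <- array(0, dim = c(2, 3, 3))
  arr[1, , ] <- geom(180, 2.0)
  arr[2, , ] <- geom(180, 5.0)
  hb <- hbond_count(trajectory(arr, elements = c("N", "H", "O")),
                    donors = 1, hydrogens = 2, acceptors = 3)
  expect_equal(hb$occupancy$occupancy, 0.5)
  expect_error(hbond_count(trajectory(arr), donors = 1, hydrogens = c(2, 3),
                           acceptors = 3), "donor assignment")
})

test_that("SASA matches sphere analytics, additivity, and the oracle", {
  # isolated atom: 4 pi (r + probe)^2 within 1% at 960 points
  s1 <- sasa(matrix(0, 1, 3), radii = 1.7)
  expect_equal(s1$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # disjoint spheres are additive
  two <- rbind(c(0, 0, 0), c(100, 0, 0))
  s2 <- sasa(two, radii = c(1.7, 1.52))
  expect_equal(s2$total,
               4 * pi * (1.7 + 1.4)^2 * mean(s2$per_atom[1] > 0) +
                 4 * pi * (1.52 + 1.4)^2,
               tolerance = 0.02 * s2$total)
  expect_equal(s2$per_atom[1] + s2$per_atom[2], s2$total)
  # full burial: center of a tight cage has zero accessible area
  cage <- rbind(c(0, 0, 0), 3 * rbind(diag(3), -diag(3)))
  s3 <- sasa(cage, radii = rep(2.5, 7))
  expect_lt(s3$per_atom[1] / s3$total, 0.01)
  # external-library oracle on the 30-atom cluster (2%)
  traj <- read_xyz(fixture_path("sasa_oracle.xyz"))
  s4 <- sasa(matrix(traj$coords[1, , ], ncol = 3), elements = traj$elements)
  expect_equal(s4$total, ORACLE_SASA_TOTAL,
               tolerance = 0.02 * ORACLE_SASA_TOTAL)
  expect_error(sasa(matrix(0, 1, 3), elements = "Xx"), "radius")
})

test_that("coordinate PCA conserves variance and finds planar motion", {
  sim <- gen_trajectory(n_frames = 40, n_atoms = 8, jitter_sd = 0.3,
                        seed = 21)
  pc <- pca_coords(sim$trajectory, align_first = FALSE)
  expect_true(all(diff(pc$eigenvalues) <= 1e-10))
  M <- matrix(sim$trajectory$coords, nrow = 40)
  total_var <- sum(apply(M, 2, var))
  expect_equal(sum(pc$eigenvalues), total_var, tolerance = 1e-8)
  # motion confined to a plane: components beyond the second vanish
  t_grid <- seq(0, 4 * pi, length.out = 60)
  base <- matrix(rnorm(15, 0, 3), 5, 3)
  arr <- array(0, dim = c(60, 5, 3))
  for (f in 1:60) {
    arr[f, , ] <- base
    arr[f, 1, 1] <- base[1, 1] + 2 * sin(t_grid[f])
    arr[f, 2, 2] <- base[2, 2] + 1.5 * cos(t_grid[f])
  }
  pc2 <- pca_coords(trajectory(arr), align_first = FALSE)
  expect_lt(pc2$eigenvalues[3] / pc2$eigenvalues[1], 1e-10)
  expect_error(pca_coords(sim$trajectory, n_components = 100),
               "fewer frames")
})

test_that("free-energy landscapes are zero-anchored and scale with kT", {
  set.seed(31)
  x <- c(rnorm(600, -2, 0.3), rnorm(600, 2, 0.3))
  y <- c(rnorm(600, -1, 0.3), rnorm(600, 1, 0.3))
  g <- fel_grid(x, y, temperature_K = 310, bins = 30)
  occ <- !is.na(g$delta_g)
  expect_equal(min(g$delta_g[occ]), 0)
  expect_equal(sum(g$probability), 1, tolerance = 1e-12)
  # two equal-weight basins: two local minima within 0.2 kT of each other
  kt <- 0.0019872041 * 310
  half1 <- g$delta_g[g$x_edges[-31] < 0, , drop = FALSE]
  half2 <- g$delta_g[g$x_edges[-31] >= 0, , drop = FALSE]
  expect_lt(abs(min(half1, na.rm = TRUE) - min(half2, na.rm = TRUE)) / kt,
            0.2)
  # doubling the temperature doubles every finite delta G
  g2 <- fel_grid(x, y, temperature_K = 620, bins = 30)
  expect_equal(g2$delta_g[occ], 2 * g$delta_g[occ], tolerance = 1e-10)
  expect_error(fel_grid(rep(1, 100), rnorm(100)), "constant")
})

test_that("two-basin synthetic trajectories show two occupied FEL minima", {
  sim <- gen_trajectory(n_frames = 400, n_atoms = 10, jitter_sd = 0.15,
                        basins = 2, basin_offset = 4, seed = 17)
  pc <- pca_coords(sim$trajectory, align_first = FALSE, n_components = 2)
  g <- fel_grid(pc$projections[, 1], pc$projections[, 2], bins = 25)
  # both basins hold near-zero free-energy bins
  b1 <- pc$projections[sim$basin == 1L, 1]
  b2 <- pc$projections[sim$basin == 2L, 1]
  expect_gt(abs(mean(b1) - mean(b2)), 2)  # basins separate on PC1
  mins_by_half <- sapply(split(seq_len(25), g$x_edges[-26] > 0), function(ix)
    min(g$delta_g[ix, ], na.rm = TRUE))
  kt <- 0.0019872041 * 310
  expect_true(all(mins_by_half < 0.5 * kt))
})

test_that("XYZ and PDB round trips preserve coordinates and elements", {
  sim <- gen_trajectory(n_frames = 3, n_atoms = 6, jitter_sd = 0.2,
                        seed = 41)
  traj <- sim$trajectory
  f1 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(traj, f1)
  b1 <- read_xyz(f1)
  expect_equal(b1$coords, traj$coords, tolerance = 1e-7)
  expect_equal(b1$elements, traj$elements)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(traj, f2)
  b2 <- read_pdb_models(f2)
  expect_equal(b2$n_frames, 3)
  expect_equal(b2$coords, traj$coords, tolerance = 1e-3)  # PDB 3-decimal grid
  expect_equal(b2$elements, traj$elements)
})
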