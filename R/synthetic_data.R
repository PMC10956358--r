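# Default target correlation among the four synthetic descriptors; the
# magnitudes (max |r| ~ 0.58) mimic realistic mild multicollinearity among
# topological/autocorrelation descriptors.
default_descriptor_correlation <- function() {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.156
  C[1, 3] <- C[3, 1] <- -0.211
  C[1, 4] <- C[4, 1] <- -0.386
  C[2, 3] <- C[3, 2] <- -0.346
  C[2, 4] <- C[4, 2] <- -0.365
  C[3, 4] <- C[4, 3] <- 0.577
  C
}

#' Generate a synthetic QSAR dataset with known ground truth
#'
#' Emulates a small inhibitor series: `n` compounds, `p` descriptors drawn
#' from a multivariate normal with a target correlation structure (Cholesky
#' transform of i.i.d. normals), and a linear activity signal plus Gaussian
#' noise, `y = a0 + sum_j a_j x_j + N(0, noise_sd^2)`.  Defaults state a
#' 28-compound set with 4 descriptors whose coefficient magnitudes and
#' residual scale (0.15 pIC50 units) match a strong small-series model;
#' descriptor means/scales are chosen so each descriptor contributes an
#' activity spread of roughly 0.3 pIC50 units and activities land in the
#' 5-8 pIC50 range.
#'
#' @param n_compounds Number of compounds (default 28).
#' @param n_descriptors Number of descriptors (default 4).
#' @param true_intercept Intercept of the generating model.
#' @param true_coefs Generating coefficients (length `n_descriptors`).
#' @param noise_sd Residual standard deviation (default 0.15).
#' @param descriptor_means,descriptor_sds Per-descriptor location/scale.
#' @param descriptor_correlation Target correlation matrix
#'   (positive-definite); default mimics mild multicollinearity, identity
#'   when `n_descriptors != 4` and no matrix is given.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A list with `dataset` (a [qsar_dataset()]) and `truth`
#'   (`intercept`, `coefs`, `noise_sd`, `noise` vector).
#' @export
gen_qsar_dataset <- function(n_compounds = 28L, n_descriptors = 4L,
                             true_intercept = 6.2,
                             true_coefs = c(-0.002, 52, 0.43, 0.28),
                             noise_sd = 0.15,
                             descriptor_means = c(1000, 0.03, 1, 2),
                             descriptor_sds = c(150, 0.005, 0.7, 1.2),
                             descriptor_correlation = NULL,
                             seed = 1L) {
  p <- as.integer(n_descriptors)
  if (length(true_coefs) != p) {
    true_coefs <- rep_len(true_coefs, p)
  }
  if (length(descriptor_means) != p) descriptor_means <- rep_len(descriptor_means, p)
  if (length(descriptor_sds) != p) descriptor_sds <- rep_len(descriptor_sds, p)
  if (is.null(descriptor_correlation)) {
    descriptor_correlation <- if (p == 4L) default_descriptor_correlation()
                              else diag(p)
  }
  ev <- eigen(descriptor_correlation, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("descriptor_correlation is not positive-definite", call. = FALSE)
  }
  U <- chol(descriptor_correlation)
  restore <- local_rng(seed)
  on.exit(restore())
  Z <- matrix(stats::rnorm(n_compounds * p), n_compounds, p)
  X <- Z %*% U
  X <- sweep(sweep(X, 2, descriptor_sds, "*"), 2, descriptor_means, "+")
  colnames(X) <- paste0("D", seq_len(p))
  noise <- stats::rnorm(n_compounds, 0, noise_sd)
  y <- true_intercept + drop(X %*% true_coefs) + noise
  ds <- qsar_dataset(ids = sprintf("cpd_%02d", seq_len(n_compounds)),
                     descriptors = X, pic50 = y)
  list(dataset = ds,
       truth = list(intercept = true_intercept,
                    coefs = stats::setNames(true_coefs, colnames(X)),
                    noise_sd = noise_sd, noise = noise))
}

#' Generate a synthetic ranked screen
#'
#' Active scores are drawn from `N(separation, 1)` and decoy scores from
#' `N(0, 1)`; the screen is ranked by score, so large separations approach
#' a perfect ranking and `separation = 0` is the null.
#'
#' @param n_actives,n_decoys Class sizes (default 22 actives, 6 decoys).
#' @param separation Mean score gap between actives and decoys.
#' @param seed Integer seed.
#' @return A [ranked_screen()].
#' @export
gen_ranked_screen <- function(n_actives = 22L, n_decoys = 6L,
                              separation = 2, seed = 1L) {
  if (n_actives < 1L || n_decoys < 1L) stop("sizes must be >= 1", call. = FALSE)
  restore <- local_rng(seed)
  on.exit(restore())
  scores <- c(stats::rnorm(n_actives, separation, 1),
              stats::rnorm(n_decoys, 0, 1))
  ranked_screen(
    ids = c(sprintf("act_%03d", seq_len(n_actives)),
            sprintf("dec_%03d", seq_len(n_decoys))),
    scores = scores,
    active = rep(c(TRUE, FALSE), c(n_actives, n_decoys)))
}

#' Generate a synthetic trajectory
#'
#' Builds a random reference geometry and perturbs it per frame with
#' i.i.d. Gaussian jitter; with `basins = 2` the second half of the frames
#' is additionally displaced along a random direction by `basin_offset`,
#' giving two occupied minima on a free-energy landscape.
#'
#' @param n_frames,n_atoms Sizes (>= 1).
#' @param jitter_sd Per-coordinate Gaussian jitter (Angstrom).
#' @param basins 1 or 2 conformational basins.
#' @param basin_offset Basin separation (Angstrom, default 3).
#' @param seed Integer seed.
#' @return A list with `trajectory` (a [trajectory()] of carbon atoms),
#'   `reference` (atoms x 3), and `basin` (per-frame integer label).
#' @export
gen_trajectory <- function(n_frames = 100L, n_atoms = 20L, jitter_sd = 0.1,
                           basins = 1L, basin_offset = 3, seed = 1L) {
  if (n_frames < 1L || n_atoms < 1L) stop("sizes must be >= 1", call. = FALSE)
  restore <- local_rng(seed)
  on.exit(restore())
  ref <- matrix(stats::rnorm(n_atoms * 3, 0, 3), n_atoms, 3)
  basin <- rep(1L, n_frames)
  if (basins == 2L) basin[seq_len(n_frames) > n_frames / 2] <- 2L
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  arr <- array(0, dim = c(n_frames, n_atoms, 3L))
  for (f in seq_len(n_frames)) {
    X <- ref + matrix(stats::rnorm(n_atoms * 3, 0, jitter_sd), n_atoms, 3)
    if (basin[f] == 2L) X <- X + rep(basin_offset * dir, each = n_atoms)
    arr[f, , ] <- X
  }
  list(trajectory = trajectory(arr, elements = rep("C", n_atoms)),
       reference = ref, basin = basin)
}

#' Generate synthetic per-frame MM/GBSA components
#'
#' Each component is drawn i.i.d. normal around its stated mean; defaults
#' use magnitudes typical of a kinase-inhibitor complex (vdW ~ -37,
#' electrostatics ~ -30, GB solvation ~ +43, surface ~ -5 kcal/mol).
#'
#' @param means Named numeric vector `(vdwaals, eel, egb, esurf)` of
#'   component means (kcal/mol).
#' @param sds Per-component standard deviations (default 2 kcal/mol each).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return List of [energy_components()] objects.
#' @export
gen_mmgbsa_frames <- function(means = c(vdwaals = -37.44, eel = -30,
                                        egb = 43.19, esurf = -4.97),
                              sds = c(vdwaals = 2, eel = 2, egb = 2,
                                      esurf = 0.5),
                              n_frames = 100L, seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  comp <- c("vdwaals", "eel", "egb", "esurf")
  means <- means[comp]; sds <- rep_len(sds, 4)
  restore <- local_rng(seed)
  on.exit(restore())
  lapply(seq_len(n_frames), function(i) {
    v <- stats::rnorm(4, means, sds)
    energy_components(v[1], v[2], v[3], v[4])
  })
}
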