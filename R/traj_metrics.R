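#' Weighted rigid-body superposition (Kabsch fit)
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD
#' between a mobile structure and a reference, via SVD of the weighted
#' cross-covariance with the reflection corrected to keep `det(R) = +1`.
#'
#' @param mobile Numeric `atoms x 3` matrix to move.
#' @param reference Numeric `atoms x 3` matrix to fit onto.
#' @param weights Per-atom weights (typically masses); default uniform.
#' @return A list with `rotation` (3 x 3, applied to centered row vectors),
#'   `translation`, `fitted` (transformed mobile coordinates), and `rmsd`
#'   (weighted, after the fit).
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stop("mobile and reference must be matching atoms x 3 matrices",
         call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 atoms", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  mu_m <- colSums(mobile * w)
  mu_r <- colSums(reference * w)
  Xc <- sweep(mobile, 2, mu_m)
  Yc <- sweep(reference, 2, mu_r)
  sv_x <- svd(Xc * sqrt(w))$d
  if (sv_x[2] < 1e-10 * max(sv_x[1], 1)) {
    stop("degenerate (collinear) configuration; rotation ill-defined",
         call. = FALSE)
  }
  C <- crossprod(Xc * w, Yc)
  sv <- svd(C)
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- Xc %*% R + rep(mu_r, each = n)
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(rotation = R, translation = mu_r - drop(mu_m %*% R),
       fitted = fitted, rmsd = rmsd)
}

weights_for <- function(traj, mass_weighted) {
  if (mass_weighted) traj$masses else rep(1, traj$n_atoms)
}

#' Per-frame RMSD against a reference structure
#'
#' \deqn{RMSD(t) = \sqrt{\sum_i m_i |r_i(t) - r_i^{ref}|^2 / \sum_i m_i}}
#' with each frame optionally least-squares fitted onto the reference first.
#'
#' @param traj A [trajectory()].
#' @param reference Reference coordinates (`atoms x 3`); defaults to the
#'   first frame.
#' @param mass_weighted Use atomic masses as weights (default `TRUE`).
#' @param fit Superpose each frame onto the reference first (default `TRUE`).
#' @return Numeric vector of per-frame RMSD values (Angstrom).
#' @export
rmsd_series <- function(traj, reference = NULL, mass_weighted = TRUE,
                        fit = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(reference)) reference <- frame_coords(traj, 1L)
  reference <- as.matrix(reference)
  if (nrow(reference) != traj$n_atoms) {
    stop("reference atom count mismatch", call. = FALSE)
  }
  wts <- weights_for(traj, mass_weighted)
  w <- wts / sum(wts)
  vapply(seq_len(traj$n_frames), function(f) {
    X <- frame_coords(traj, f)
    if (fit) {
      superpose(X, reference, wts)$rmsd
    } else {
      sqrt(sum(w * rowSums((X - reference)^2)))
    }
  }, numeric(1))
}

# mean structure after aligning every frame to `ref`; returns aligned array
align_frames <- function(traj, ref, wts) {
  arr <- traj$coords
  for (f in seq_len(traj$n_frames)) {
    arr[f, , ] <- superpose(frame_coords(traj, f), ref, wts)$fitted
  }
  arr
}

#' Per-atom root-mean-square fluctuation
#'
#' \deqn{RMSF_i = \sqrt{(1/T) \sum_t |r_i(t) - \bar r_i|^2}} with
#' \eqn{\bar r_i} the time-averaged position.  With `align_first = TRUE`
#' frames are superposed onto an iteratively refined mean structure (two
#' passes: align to the first frame, average, re-align to that average).
#'
#' @param traj A [trajectory()] with at least 2 frames.
#' @param align_first Remove global rotation/translation first (default
#'   `TRUE`).
#' @param mass_weighted Mass-weight the superposition (default `TRUE`).
#' @return Numeric vector of per-atom RMSF values (Angstrom).
#' @export
rmsf <- function(traj, align_first = TRUE, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$n_frames < 2L) stop("need at least 2 frames", call. = FALSE)
  arr <- traj$coords
  if (align_first) {
    wts <- weights_for(traj, mass_weighted)
    arr <- align_frames(traj, frame_coords(traj, 1L), wts)
    mean1 <- apply(arr, c(2, 3), mean)
    tmp <- trajectory(arr, masses = traj$masses)
    arr <- align_frames(tmp, mean1, wts)
  }
  mean_pos <- apply(arr, c(2, 3), mean)
  dev2 <- sweep(arr, c(2, 3), mean_pos)^2
  sqrt(apply(dev2, 2, sum) / traj$n_frames)
}

#' Per-frame radius of gyration
#'
#' \deqn{R_g = \sqrt{\sum_i m_i |r_i - r_{cm}|^2 / \sum_i m_i}} with
#' \eqn{r_{cm}} the per-frame center of mass.
#'
#' @param traj A [trajectory()].
#' @return Numeric vector of per-frame Rg values (Angstrom).
#' @export
radius_of_gyration <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  w <- traj$masses / sum(traj$masses)
  vapply(seq_len(traj$n_frames), function(f) {
    X <- frame_coords(traj, f)
    cm <- colSums(X * w)
    sqrt(sum(w * rowSums(sweep(X, 2, cm)^2)))
  }, numeric(1))
}

#' Hydrogen-bond counting over a trajectory
#'
#' A donor-hydrogen-acceptor triple is counted as bonded in a frame when
#' the hydrogen-acceptor distance is below `dist_cutoff` (3.5 Angstrom by
#' default; set `distance_mode = "DA"` for the conventional donor-acceptor
#' reading) and the D-H...A angle lies within `angle_range` (150-210
#' degrees, i.e. within 30 degrees of linear).
#'
#' @param traj A [trajectory()].
#' @param donors,hydrogens Parallel integer vectors of covalently bonded
#'   donor and hydrogen atom indices.
#' @param acceptors Integer vector of acceptor atom indices.
#' @param dist_cutoff Distance cutoff in Angstrom (default 3.5).
#' @param angle_range D-H...A angle window in degrees (default
#'   `c(150, 210)`).
#' @param distance_mode `"HA"` (hydrogen-acceptor, the default) or `"DA"`
#'   (donor-acceptor).
#' @return A list with `counts` (per-frame bond counts) and `occupancy`
#'   (data.frame donor, hydrogen, acceptor, occupancy = fraction of frames
#'   bonded).
#' @export
hbond_count <- function(traj, donors, hydrogens, acceptors,
                        dist_cutoff = 3.5, angle_range = c(150, 210),
                        distance_mode = c("HA", "DA")) {
  stopifnot(inherits(traj, "trajectory"))
  distance_mode <- match.arg(distance_mode)
  donors <- as.integer(donors); hydrogens <- as.integer(hydrogens)
  acceptors <- as.integer(acceptors)
  if (length(donors) != length(hydrogens)) {
    stop("every hydrogen needs a donor assignment (parallel vectors)",
         call. = FALSE)
  }
  # fold the angle window about 180 deg into a single half-width
  half <- max(abs(angle_range - 180))
  pairs <- expand.grid(dh = seq_along(donors), a = seq_along(acceptors))
  pairs <- pairs[acceptors[pairs$a] != donors[pairs$dh] &
                 acceptors[pairs$a] != hydrogens[pairs$dh], , drop = FALSE]
  n_pairs <- nrow(pairs)
  bonded <- matrix(FALSE, traj$n_frames, n_pairs)
  for (f in seq_len(traj$n_frames)) {
    X <- frame_coords(traj, f)
    D <- X[donors[pairs$dh], , drop = FALSE]
    H <- X[hydrogens[pairs$dh], , drop = FALSE]
    A <- X[acceptors[pairs$a], , drop = FALSE]
    ref <- if (distance_mode == "HA") H else D
    dist <- sqrt(rowSums((A - ref)^2))
    v1 <- D - H; v2 <- A - H
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    bonded[f, ] <- dist < dist_cutoff & abs(ang - 180) <= half
  }
  occupancy <- data.frame(
    donor = donors[pairs$dh], hydrogen = hydrogens[pairs$dh],
    acceptor = acceptors[pairs$a],
    occupancy = colMeans(bonded))
  list(counts = rowSums(bonded), occupancy = occupancy)
}

# deterministic quasi-uniform unit sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe over each atom's van der Waals sphere using a
#' deterministic golden-spiral point lattice; a surface point is accessible
#' when it lies outside every neighbouring atom's expanded sphere.
#'
#' @param frame Numeric `atoms x 3` coordinate matrix (Angstrom).
#' @param radii Per-atom van der Waals radii (Angstrom), or `NULL` to look
#'   them up (Bondi set) from `elements`.
#' @param elements Element symbols, used when `radii` is `NULL`.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_sphere_points Points per atom (default 960).
#' @return A list with `total` and `per_atom` SASA (Angstrom^2).
#' @export
sasa <- function(frame, radii = NULL, elements = NULL, probe = 1.4,
                 n_sphere_points = 960L) {
  frame <- as.matrix(frame)
  n <- nrow(frame)
  if (is.null(radii)) {
    if (is.null(elements)) stop("supply radii or elements", call. = FALSE)
    unknown <- setdiff(unique(elements), names(BONDI_RADII))
    if (length(unknown)) {
      stop("no van der Waals radius for element(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    radii <- unname(BONDI_RADII[elements])
  }
  if (length(radii) != n) stop("one radius per atom required", call. = FALSE)
  pts <- sphere_points(n_sphere_points)
  expanded <- radii + probe
  d2 <- as.matrix(stats::dist(frame))^2
  per_atom <- vapply(seq_len(n), function(i) {
    nb <- which(d2[i, ] < (expanded[i] + expanded)^2 & seq_len(n) != i)
    surf <- pts * expanded[i] + rep(frame[i, ], each = n_sphere_points)
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(surf, 2, frame[j, ])^2)
      acc <- acc & dj2 > expanded[j]^2
      if (!any(acc)) break
    }
    4 * pi * expanded[i]^2 * mean(acc)
  }, numeric(1))
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Principal component analysis of trajectory coordinates
#'
#' Frames are optionally aligned (removing global rotation/translation),
#' flattened to `frames x (3 * atoms)`, mean-centered, and decomposed; the
#' eigenvalues of the coordinate covariance matrix are returned sorted
#' descending together with the per-frame projections, and their sum equals
#' the total coordinate variance.
#'
#' @param traj A [trajectory()] with at least 3 frames.
#' @param align_first Superpose frames onto the first frame (default
#'   `TRUE`).
#' @param n_components Number of components to keep (default all).
#' @return A list with `eigenvalues`, `eigenvectors` (columns), and
#'   `projections` (frames x components).
#' @export
pca_coords <- function(traj, align_first = TRUE, n_components = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$n_frames < 3L) stop("need at least 3 frames", call. = FALSE)
  arr <- traj$coords
  if (align_first) {
    arr <- align_frames(traj, frame_coords(traj, 1L), traj$masses)
  }
  M <- matrix(arr, nrow = traj$n_frames)   # frames x (atoms*3)
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (!is.null(n_components)) {
    n_components <- as.integer(n_components)
    if (n_components > length(ev)) {
      stop("fewer frames than requested components", call. = FALSE)
    }
    keep <- seq_len(n_components)
  } else {
    keep <- seq_along(ev)
  }
  list(eigenvalues = ev[keep],
       eigenvectors = pc$rotation[, keep, drop = FALSE],
       projections = pc$x[, keep, drop = FALSE])
}

# Boltzmann constant, kcal/(mol K)
KB_KCAL <- 0.0019872041

#' Two-dimensional free-energy landscape
#'
#' Bins two order-parameter series (e.g. PC1/PC2, or RMSD vs radius of
#' gyration) into a 2-D probability histogram and converts it to relative
#' free energy \eqn{\Delta G(R) = -k_B T (\ln P(R) - \ln P_{max})}, so the
#' most populated bin sits at exactly 0 and empty bins are `NA` (masked,
#' never infinite arithmetic).
#'
#' @param x,y Equal-length numeric order-parameter series.
#' @param temperature_K Temperature in kelvin (default 310).
#' @param bins Number of bins per axis (default 50).
#' @return An object of class `fes_grid`: `x_edges`, `y_edges`,
#'   `probability` (bins x bins), `delta_g` (kcal/mol, `NA` for empty
#'   bins), `temperature_K`.
#' @export
fel_grid <- function(x, y, temperature_K = 310, bins = 50L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("constant order-parameter series (zero range)", call. = FALSE)
  }
  x_edges <- seq(min(x), max(x), length.out = bins + 1L)
  y_edges <- seq(min(y), max(y), length.out = bins + 1L)
  ix <- findInterval(x, x_edges, rightmost.closed = TRUE)
  iy <- findInterval(y, y_edges, rightmost.closed = TRUE)
  counts <- matrix(0, bins, bins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  P <- counts / length(x)
  occupied <- P > 0
  dg <- matrix(NA_real_, bins, bins)
  dg[occupied] <- -KB_KCAL * temperature_K * (log(P[occupied]) - log(max(P)))
  structure(
    list(x_edges = x_edges, y_edges = y_edges, probability = P,
         delta_g = dg, temperature_K = temperature_K),
    class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("fes_grid: %d x %d bins, T = %g K, %d occupied bin(s)\n",
              nrow(x$probability), ncol(x$probability), x$temperature_K,
              sum(x$probability > 0)))
  invisible(x)
}

#' Write a free-energy grid as a CSV matrix
#'
#' @param grid A `fes_grid`.
#' @param path Output CSV path (delta G matrix, rows = x bins).
#' @return `path`, invisibly.
#' @export
write_fes_csv <- function(grid, path) {
  stopifnot(inherits(grid, "fes_grid"))
  utils::write.csv(grid$delta_g, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-frame or per-atom metric series as CSV
#'
#' @param values Numeric vector.
#' @param path Output path.
#' @param index_name Name of the index column (`"frame"` or `"atom"`).
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(values, path, index_name = "frame") {
  df <- data.frame(seq_along(values), values)
  names(df) <- c(index_name, "value")
  write_csv_full(df, path)
  invisible(path)
}
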