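# Element lookup tables: atomic masses (amu) and Bondi van der Waals
# radii (Angstrom) for the elements a ligand/protein trajectory will contain.
ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904, Na = 22.990,
  Mg = 24.305, K = 39.098, Ca = 40.078, Zn = 65.38, Fe = 55.845)

BONDI_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Na = 2.27, Mg = 1.73,
  K = 2.75, Zn = 1.39)

#' Construct a molecular dynamics trajectory
#'
#' Coordinates are stored as a `frames x atoms x 3` array in Angstrom.
#' Masses default to a standard-element lookup from `elements`; both can be
#' supplied directly for synthetic systems.
#'
#' @param coords Numeric array `frames x atoms x 3` (or a single
#'   `atoms x 3` matrix for a one-frame trajectory).
#' @param elements Optional character vector of element symbols (one per
#'   atom), used to look up masses and van der Waals radii.
#' @param masses Optional positive numeric vector of atomic masses (amu).
#' @param times Optional per-frame times (ns).
#' @return An object of class `trajectory`: `coords`, `elements`, `masses`,
#'   `n_frames`, `n_atoms`, `times`.
#' @export
trajectory <- function(coords, elements = NULL, masses = NULL, times = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be a frames x atoms x 3 array", call. = FALSE)
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  n_atoms <- dim(coords)[2]
  if (is.null(masses)) {
    if (is.null(elements)) {
      masses <- rep(1, n_atoms)
    } else {
      if (length(elements) != n_atoms) stop("elements length mismatch", call. = FALSE)
      unknown <- setdiff(unique(elements), names(ELEMENT_MASSES))
      if (length(unknown)) {
        stop("unknown element(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      }
      masses <- unname(ELEMENT_MASSES[elements])
    }
  }
  if (length(masses) != n_atoms || any(masses <= 0)) {
    stop("masses must be positive, one per atom", call. = FALSE)
  }
  if (!is.null(times) && length(times) != dim(coords)[1]) {
    stop("times length must equal frame count", call. = FALSE)
  }
  structure(
    list(coords = coords, elements = elements, masses = masses,
         n_frames = dim(coords)[1], n_atoms = n_atoms, times = times),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", x$n_frames, "frames x", x$n_atoms, "atoms\n")
  invisible(x)
}

# single frame as an atoms x 3 matrix
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a multi-frame XYZ file
#'
#' Standard XYZ blocks (atom count line, comment line, `element x y z`
#' records) concatenated per frame; coordinates in Angstrom.
#'
#' @param path XYZ file path.
#' @return A [trajectory()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list(); elements <- NULL; i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ atom count at line ", i, call. = FALSE)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("malformed XYZ coordinates near line ", i, call. = FALSE)
    if (is.null(elements)) {
      elements <- el
    } else if (!identical(elements, el)) {
      stop("atom identities differ across XYZ frames", call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  arr <- array(0, dim = c(length(frames), length(elements), 3L))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  trajectory(arr, elements = elements)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj A [trajectory()] with elements (defaults to `"C"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  el <- if (is.null(traj$elements)) rep("C", traj$n_atoms) else traj$elements
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(c(as.character(traj$n_atoms), paste("frame", f)), con)
    X <- frame_coords(traj, f)
    writeLines(sprintf("%s %.8f %.8f %.8f", el, X[, 1], X[, 2], X[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-model PDB file
#'
#' Parses ATOM/HETATM records in MODEL/ENDMDL blocks (or a single implicit
#' model) using the fixed PDB column layout; the element is taken from
#' columns 77-78 when present, else inferred from the atom name.
#'
#' @param path PDB file path.
#' @return A [trajectory()].
#' @export
read_pdb_models <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  atom_mask <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grepl("^MODEL", lines)
  model_id <- cumsum(model_starts)
  if (!any(model_starts)) model_id <- rep(1L, length(lines))
  keep <- which(atom_mask)
  if (!length(keep)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  parse_atoms <- function(idx) {
    ln <- lines[idx]
    xyz <- cbind(as.numeric(substr(ln, 31, 38)),
                 as.numeric(substr(ln, 39, 46)),
                 as.numeric(substr(ln, 47, 54)))
    el <- trimws(substr(ln, 77, 78))
    fallback <- gsub("[^A-Za-z]", "", trimws(substr(ln, 13, 16)))
    el[el == ""] <- substr(fallback[el == ""], 1, 1)
    el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
    list(xyz = xyz, el = el)
  }
  by_model <- split(keep, model_id[keep])
  parsed <- lapply(by_model, parse_atoms)
  el <- parsed[[1]]$el
  for (p in parsed) {
    if (!identical(p$el, el)) stop("atom identities differ across models", call. = FALSE)
  }
  arr <- array(0, dim = c(length(parsed), length(el), 3L))
  for (f in seq_along(parsed)) arr[f, , ] <- parsed[[f]]$xyz
  trajectory(arr, elements = el)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  el <- if (is.null(traj$elements)) rep("C", traj$n_atoms) else traj$elements
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    X <- frame_coords(traj, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s MOL A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(traj$n_atoms), substr(el, 1, 4), X[, 1], X[, 2], X[, 3],
      toupper(el)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
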