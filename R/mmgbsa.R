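#' MM/GBSA energy components
#'
#' A validated bundle of the four per-snapshot MM/GBSA terms, all in
#' kcal/mol (AMBER convention): van der Waals, electrostatic, generalized
#' Born solvation, and nonpolar surface contributions.
#'
#' @param vdwaals,eel,egb,esurf Finite numeric scalars (kcal/mol).
#' @return An object of class `energy_components`.
#' @export
energy_components <- function(vdwaals, eel, egb, esurf) {
  vals <- c(vdwaals = vdwaals, eel = eel, egb = egb, esurf = esurf)
  miss <- names(vals)[vapply(list(vdwaals, eel, egb, esurf),
                             function(v) is.null(v) || length(v) != 1L ||
                               !is.finite(v), logical(1))]
  if (length(miss)) {
    stop("missing or non-finite component(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(as.list(vals), class = "energy_components")
}

#' Binding free-energy totals from MM/GBSA components
#'
#' `G_gas = vdwaals + eel`, `G_solv = egb + esurf`,
#' `total = G_gas + G_solv`, computed as exact sums of the stored
#' components.
#'
#' @param components An [energy_components()] object.
#' @return An object of class `binding_energy_report` with `components`,
#'   `g_gas`, `g_solv`, `total` (kcal/mol).
#' @export
binding_totals <- function(components) {
  stopifnot(inherits(components, "energy_components"))
  g_gas <- components$vdwaals + components$eel
  g_solv <- components$egb + components$esurf
  structure(
    list(components = components, g_gas = g_gas, g_solv = g_solv,
         total = g_gas + g_solv),
    class = "binding_energy_report")
}

#' @export
print.binding_energy_report <- function(x, ...) {
  cat("MM/GBSA totals (kcal/mol)\n")
  cat(sprintf("  G_gas = %.2f  G_solv = %.2f  total = %.2f\n",
              x$g_gas, x$g_solv, x$total))
  if (!is.null(x$component_sd)) {
    cat(sprintf("  per-component sd over %d frame(s)\n", x$n_frames))
  }
  invisible(x)
}

#' Aggregate per-frame MM/GBSA components
#'
#' Component-wise arithmetic mean and sample standard deviation across
#' frames; totals are computed on the means (equivalently, the mean of the
#' per-frame totals, since the totals are linear).
#'
#' @param frames List of [energy_components()] objects (>= 1).
#' @return A `binding_energy_report` whose `components` hold the means,
#'   plus `component_sd` (named; `NA` for a single frame) and `n_frames`.
#' @export
aggregate_frames <- function(frames) {
  if (!length(frames)) stop("no frames supplied", call. = FALSE)
  stopifnot(all(vapply(frames, inherits, logical(1), "energy_components")))
  comp_names <- c("vdwaals", "eel", "egb", "esurf")
  M <- vapply(frames, function(f) unlist(f[comp_names]),
              numeric(length(comp_names)))
  means <- rowMeans(M)
  sds <- apply(M, 1, stats::sd)
  rep <- binding_totals(energy_components(means[["vdwaals"]], means[["eel"]],
                                          means[["egb"]], means[["esurf"]]))
  rep$component_sd <- sds
  rep$n_frames <- length(frames)
  rep
}

#' Read a per-frame MM/GBSA component table from CSV
#'
#' Columns `frame`, `VDWAALS`, `EEL`, `EGB`, `ESURF`; row order preserved.
#'
#' @param path CSV path.
#' @return List of [energy_components()] objects, one per row.
#' @export
read_component_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "VDWAALS", "EEL", "EGB", "ESURF")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in need[-1]) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))[1L]
      stop("non-numeric value in column ", col, " at row ", bad, call. = FALSE)
    }
  }
  lapply(seq_len(nrow(df)), function(i) {
    energy_components(df$VDWAALS[i], df$EEL[i], df$EGB[i], df$ESURF[i])
  })
}

#' Write a per-frame MM/GBSA component table to CSV
#'
#' Round-trips with [read_component_table()].
#'
#' @param frames List of [energy_components()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(frames, path) {
  stopifnot(all(vapply(frames, inherits, logical(1), "energy_components")))
  df <- data.frame(frame = seq_along(frames),
                   VDWAALS = vapply(frames, `[[`, numeric(1), "vdwaals"),
                   EEL = vapply(frames, `[[`, numeric(1), "eel"),
                   EGB = vapply(frames, `[[`, numeric(1), "egb"),
                   ESURF = vapply(frames, `[[`, numeric(1), "esurf"))
  write_csv_full(df, path)
  invisible(path)
}
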