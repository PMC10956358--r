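#' Construct a ranked virtual screen
#'
#' Orders ligands best-first by score (higher is better) with a stable sort,
#' so score ties keep their input order.
#'
#' @param ids Character vector of ligand identifiers.
#' @param scores Numeric screening scores (higher = better).
#' @param active Logical vector of activity labels.
#' @return An object of class `ranked_screen`: data frame `entries`
#'   (`id`, `score`, `active`, sorted best-first), `n_actives`, `n_decoys`.
#' @export
ranked_screen <- function(ids, scores, active) {
  ids <- as.character(ids)
  active <- as.logical(active)
  if (length(ids) != length(scores) || length(ids) != length(active)) {
    stop("ids, scores and active must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(active)) stop("missing values", call. = FALSE)
  ord <- order(-scores, seq_along(scores))
  entries <- data.frame(id = ids[ord], score = scores[ord],
                        active = active[ord], stringsAsFactors = FALSE)
  structure(
    list(entries = entries,
         n_actives = sum(active), n_decoys = sum(!active)),
    class = "ranked_screen")
}

#' @export
print.ranked_screen <- function(x, ...) {
  cat("ranked_screen:", x$n_actives, "actives,", x$n_decoys, "decoys\n")
  invisible(x)
}

check_two_classes <- function(screen) {
  stopifnot(inherits(screen, "ranked_screen"))
  if (screen$n_actives < 1L || screen$n_decoys < 1L) {
    stop("need at least one active and one decoy", call. = FALSE)
  }
}

#' Read / write a ranked screen as CSV
#'
#' Columns `id`, `score`, `active` (0/1).
#'
#' @param path CSV path.
#' @return A `ranked_screen`.
#' @export
read_screen_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "score", "active")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ranked_screen(df$id, df$score, df$active == 1 | df$active == TRUE)
}

#' @rdname read_screen_csv
#' @param screen A `ranked_screen`.
#' @export
write_screen_csv <- function(screen, path) {
  stopifnot(inherits(screen, "ranked_screen"))
  df <- screen$entries
  df$active <- as.integer(df$active)
  write_csv_full(df, path)
  invisible(path)
}

#' ROC AUC of a ranked screen
#'
#' The Mann-Whitney probability that a randomly chosen active outscores a
#' randomly chosen decoy, with score ties credited 0.5 (midranks).
#'
#' @param screen A [ranked_screen()] with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(screen) {
  check_two_classes(screen)
  e <- screen$entries
  r <- rank(e$score)                      # midranks handle ties at 0.5
  na <- screen$n_actives; nd <- screen$n_decoys
  (sum(r[e$active]) - na * (na + 1) / 2) / (na * nd)
}

#' BEDROC and RIE early-recognition metrics
#'
#' Exponentially weighted enrichment following the standard
#' Truchon-Bayly formulation.  With active ranks `r_i` (1 = best) among `N`
#' ligands and `Ra = n_actives / N`:
#' \deqn{RIE = \frac{\sum_i e^{-\alpha r_i / N}}
#'   {Ra\,(1 - e^{-\alpha}) / (e^{\alpha/N} - 1)}}
#' and BEDROC is the min-max normalization of RIE onto `[0, 1]`, equal to 1
#' exactly for a perfect ranking.  Large `alpha` focuses the metric on the
#' very top of the list (`alpha = 160.9` weights roughly the top 1%).
#'
#' @param screen A [ranked_screen()].
#' @param alpha Positive early-recognition exponent (default 160.9).
#' @return A list with elements `bedroc`, `rie`, `alpha`.
#' @export
bedroc_rie <- function(screen, alpha = 160.9) {
  check_two_classes(screen)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  e <- screen$entries
  N <- nrow(e)
  ranks <- which(e$active)
  ra <- screen$n_actives / N
  rie <- sum(exp(-alpha * ranks / N)) /
    (ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  bedroc <- rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
  list(bedroc = bedroc, rie = rie, alpha = alpha)
}

#' Enrichment factor at a top fraction
#'
#' `EF(f) = (actives among the top ceiling(f * N) ligands / n_actives) / f`.
#'
#' @param screen A [ranked_screen()].
#' @param top_fraction Fraction of the list, in `(0, 1]`.
#' @return The enrichment factor (0 when no actives are in the slice).
#' @export
enrichment_factor <- function(screen, top_fraction) {
  check_two_classes(screen)
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  }
  e <- screen$entries
  n_top <- ceiling(top_fraction * nrow(e))
  if (n_top < 1L) stop("empty top slice", call. = FALSE)
  (sum(e$active[seq_len(n_top)]) / screen$n_actives) / top_fraction
}

#' Accumulation curve and its area (AUAC)
#'
#' Fraction of actives found versus fraction of the ranked list screened;
#' the area is computed by the trapezoid rule over the per-ligand step
#' curve (including the origin), so the curve is monotone non-decreasing
#' and ends at 1.
#'
#' @param screen A [ranked_screen()].
#' @return A list with `curve` (data.frame `fraction_screened`,
#'   `fraction_actives_found`) and `auac`.
#' @export
accumulation_curve <- function(screen) {
  check_two_classes(screen)
  e <- screen$entries
  N <- nrow(e)
  found <- cumsum(e$active) / screen$n_actives
  x <- c(0, seq_len(N) / N)
  yv <- c(0, found)
  auac <- sum(diff(x) * (utils::head(yv, -1) + utils::tail(yv, -1)) / 2)
  list(curve = data.frame(fraction_screened = x,
                          fraction_actives_found = yv),
       auac = auac)
}

#' Percent of actives recovered at a decoy fraction
#'
#' Finds the rank at which `ceiling(decoy_fraction * n_decoys)` decoys have
#' been retrieved and reports the percentage of actives ranked at or above
#' that point (the ROC-style "top x% of decoys" reading).
#'
#' @param screen A [ranked_screen()].
#' @param decoy_fraction Fraction of decoys, in `(0, 1]` (default 0.2).
#' @return Percent of actives recovered (full precision; display rounds to
#'   one decimal).
#' @export
actives_at_decoy_fraction <- function(screen, decoy_fraction = 0.2) {
  check_two_classes(screen)
  if (decoy_fraction <= 0 || decoy_fraction > 1) {
    stop("decoy_fraction must be in (0, 1]", call. = FALSE)
  }
  e <- screen$entries
  target <- ceiling(decoy_fraction * screen$n_decoys)
  rank_at <- which(cumsum(!e$active) == target)[1L]
  100 * sum(e$active[seq_len(rank_at)]) / screen$n_actives
}

#' Full enrichment report for a ranked screen
#'
#' @param screen A [ranked_screen()].
#' @param alpha BEDROC/RIE exponent.
#' @param ef_fractions Top fractions for enrichment factors.
#' @param decoy_fractions Decoy fractions for active-recovery percentages.
#' @return An object of class `enrichment_report`.
#' @export
enrichment_report <- function(screen, alpha = 160.9,
                              ef_fractions = c(0.01, 0.05, 0.2),
                              decoy_fractions = 0.2) {
  br <- bedroc_rie(screen, alpha)
  ef <- vapply(ef_fractions, function(f) enrichment_factor(screen, f),
               numeric(1))
  names(ef) <- format(ef_fractions)
  arec <- vapply(decoy_fractions,
                 function(f) actives_at_decoy_fraction(screen, f), numeric(1))
  names(arec) <- format(decoy_fractions)
  structure(
    list(roc_auc = roc_auc(screen), bedroc = br$bedroc, rie = br$rie,
         alpha = alpha, ef = ef, auac = accumulation_curve(screen)$auac,
         actives_at_decoy_fraction = arec,
         n_actives = screen$n_actives, n_decoys = screen$n_decoys),
    class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("enrichment report (%d actives / %d decoys)\n",
              x$n_actives, x$n_decoys))
  cat(sprintf("  ROC AUC = %.3f  BEDROC(alpha=%.1f) = %.3f  RIE = %.3f  AUAC = %.3f\n",
              x$roc_auc, x$alpha, x$bedroc, x$rie, x$auac))
  cat("  EF:", paste(names(x$ef), format(x$ef, digits = 3), sep = "=",
                     collapse = "  "), "\n")
  cat("  actives at decoy fraction:",
      paste(names(x$actives_at_decoy_fraction),
            paste0(format(round(x$actives_at_decoy_fraction, 1)), "%"),
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}
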