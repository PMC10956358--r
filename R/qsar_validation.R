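#' Leave-one-out cross-validation Q2
#'
#' For each observation the model is refit without it and the held-out
#' activity predicted; `q2 = 1 - PRESS / sum((y - mean(y))^2)` with the mean
#' taken over the full training set.  `q2 > 0.5` is the conventional bar for
#' a predictive model and is reported as `predictive_flag`.
#'
#' The refits use an explicit loop (not the hat-matrix shortcut) so the same
#' code path supports non-linear models through `fit_fun`/`predict_fun`
#' hooks; the shortcut identity `e_i / (1 - h_ii)` is used as an independent
#' oracle in the test-suite.
#'
#' @param X Descriptor matrix (n x p).
#' @param y Activity vector.
#' @param ids Optional compound ids for the per-compound predictions.
#' @param fit_fun Function `(X, y) -> model` (default [fit_mlr()]).
#' @param predict_fun Function `(model, X) -> yhat` (default
#'   [predict.mlr_model()] via `predict`).
#' @return An object of class `loocv_result`: `q2`, `press`,
#'   `per_compound_loo_prediction` (named), `predictive_flag`.
#' @export
loocv_q2 <- function(X, y, ids = NULL, fit_fun = fit_mlr,
                     predict_fun = function(m, X) predict(m, X)) {
  X <- as_design(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (identical(fit_fun, fit_mlr) && n < ncol(X) + 3L) {
    stop("need n >= p + 3 for leave-one-out with an MLR refit", call. = FALSE)
  }
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- tryCatch(fit_fun(X[-i, , drop = FALSE], y[-i]),
                  error = function(e) {
                    stop("LOO refit failed for fold ", i, " (", ids[i], "): ",
                         conditionMessage(e), call. = FALSE)
                  })
    pred[i] <- predict_fun(m, X[i, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  q2 <- 1 - press / sum((y - mean(y))^2)
  names(pred) <- ids
  structure(
    list(q2 = q2, press = press, per_compound_loo_prediction = pred,
         predictive_flag = q2 > 0.5),
    class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV: Q2 = %.4f, PRESS = %.4f, predictive (Q2 > 0.5): %s\n",
              x$q2, x$press, x$predictive_flag))
  invisible(x)
}

#' Golbraikh-Tropsha external-validation criteria
#'
#' Evaluates the standard external-validation battery on a test set:
#' `q2_ext = 1 - sum((yhat - y)^2) / sum((y - y_train_mean)^2)`, the squared
#' Pearson correlation `r2`, through-origin slopes
#' `k = sum(y * yhat) / sum(yhat^2)` and `k' = sum(y * yhat) / sum(y^2)`,
#' the through-origin determination coefficients `r0_sq` (observed vs
#' predicted) and `r0_prime_sq` (predicted vs observed), their normalized
#' gaps, and Lin's concordance correlation coefficient.  Each criterion is
#' flagged against its conventional threshold: Q2 > 0.5, R2 > 0.6,
#' |r0^2 - r0'^2| < 0.3, both (R2 - r0^2)/R2 and (R2 - r0'^2)/R2 < 0.1,
#' and 0.85 < k, k' < 1.15.
#'
#' @param y_test Observed test-set activities (length >= 3, not constant).
#' @param y_pred Predicted test-set activities.
#' @param y_train_mean Mean activity of the training set.
#' @return An object of class `gt_report` with all statistics and
#'   `criterion_flags` (named logical; `NA` when r2 == 0 makes the delta
#'   criteria undefined).
#' @export
golbraikh_tropsha <- function(y_test, y_pred, y_train_mean) {
  y <- as.numeric(y_test); yh <- as.numeric(y_pred)
  if (length(y) != length(yh) || length(y) < 3L) {
    stop("need matched test vectors of length >= 3", call. = FALSE)
  }
  if (stats::var(y) == 0) stop("y_test is constant", call. = FALSE)
  q2_ext <- 1 - sum((yh - y)^2) / sum((y - y_train_mean)^2)
  r2 <- stats::cor(y, yh)^2
  k <- sum(y * yh) / sum(yh^2)
  kp <- sum(y * yh) / sum(y^2)
  # through-origin determination coefficients (observed-vs-predicted and
  # the converse); denominators are centered total sums of squares
  r0_sq <- 1 - sum((y - k * yh)^2) / sum((y - mean(y))^2)
  r0p_sq <- 1 - sum((yh - kp * y)^2) / sum((yh - mean(yh))^2)
  delta1 <- if (r2 > 0) (r2 - r0_sq) / r2 else NA_real_
  delta2 <- if (r2 > 0) (r2 - r0p_sq) / r2 else NA_real_
  abs_diff_r0 <- abs(r0_sq - r0p_sq)
  mu_y <- mean(y); mu_h <- mean(yh)
  ccc <- 2 * mean((y - mu_y) * (yh - mu_h)) /
    (mean((y - mu_y)^2) + mean((yh - mu_h)^2) + (mu_y - mu_h)^2)
  flags <- c(q2_ext = q2_ext > 0.5,
             r2 = r2 > 0.6,
             abs_diff_r0 = abs_diff_r0 < 0.3,
             delta1 = if (is.na(delta1)) NA else delta1 < 0.1,
             delta2 = if (is.na(delta2)) NA else delta2 < 0.1,
             k = k > 0.85 && k < 1.15,
             k_prime = kp > 0.85 && kp < 1.15)
  structure(
    list(q2_ext = q2_ext, r2 = r2, r0_sq = r0_sq, r0_prime_sq = r0p_sq,
         k = k, k_prime = kp, delta1 = delta1, delta2 = delta2,
         abs_diff_r0 = abs_diff_r0, ccc = ccc, criterion_flags = flags),
    class = "gt_report")
}

#' @export
print.gt_report <- function(x, ...) {
  cat("Golbraikh-Tropsha external validation\n")
  cat(sprintf("  Q2ext = %.4f  R2 = %.4f  CCC = %.4f\n", x$q2_ext, x$r2, x$ccc))
  cat(sprintf("  k = %.4f  k' = %.4f  |r0^2 - r0'^2| = %.4f\n",
              x$k, x$k_prime, x$abs_diff_r0))
  status <- ifelse(is.na(x$criterion_flags), "NA",
                   ifelse(x$criterion_flags, "pass", "FAIL"))
  cat("  flags:", paste(names(x$criterion_flags), status, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Y-randomization (response permutation) test
#'
#' Refits the model after randomly permuting the activity vector `n_perm`
#' times and compares the chance-level statistics with the original model.
#' The penalized statistic is `cRp^2 = r * sqrt(r2 - mean(r2_perm))`,
#' clamped at 0 (with a warning flag) when the radicand is negative.  The
#' model is judged valid when every permuted r2 is below the original r2
#' and `cRp^2 > 0.5`.
#'
#' @param X Descriptor matrix.
#' @param y Activity vector (not constant).
#' @param n_perm Number of permutations (default 10).
#' @param seed Integer seed.
#' @return An object of class `yrand_result`: `original` (r, r2, q2),
#'   `permuted_runs` (data.frame r, r2, q2), `avg_r`, `avg_r2`, `avg_q2`,
#'   `crp2`, `crp2_clamped`, `valid`, `seed`.
#' @export
y_randomization <- function(X, y, n_perm = 10L, seed = 1L) {
  X <- as_design(X)
  y <- as.numeric(y)
  if (stats::var(y) == 0) stop("y is constant", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  run_stats <- function(yy) {
    m <- fit_mlr(X, yy)
    r <- stats::cor(yy, m$fitted)
    c(r = r, r2 = r^2, q2 = loocv_q2(X, yy)$q2)
  }
  orig <- run_stats(y)
  restore <- local_rng(seed)
  on.exit(restore())
  runs <- t(vapply(seq_len(n_perm), function(i) run_stats(sample(y)),
                   numeric(3)))
  runs <- as.data.frame(runs)
  avg_r2 <- mean(runs$r2)
  radicand <- orig[["r2"]] - avg_r2
  clamped <- radicand < 0
  if (clamped) {
    warning("mean permuted r2 exceeds original r2; cRp^2 clamped at 0")
  }
  crp2 <- if (clamped) 0 else orig[["r"]] * sqrt(radicand)
  structure(
    list(original = as.list(orig), permuted_runs = runs,
         avg_r = mean(runs$r), avg_r2 = avg_r2, avg_q2 = mean(runs$q2),
         crp2 = crp2, crp2_clamped = clamped,
         valid = all(runs$r2 < orig[["r2"]]) && crp2 > 0.5,
         seed = as.integer(seed)),
    class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat(sprintf("Y-randomization (%d runs, seed %d)\n",
              nrow(x$permuted_runs), x$seed))
  cat(sprintf("  original: r = %.3f  r2 = %.3f  q2 = %.3f\n",
              x$original$r, x$original$r2, x$original$q2))
  cat(sprintf("  averages: r = %.3f  r2 = %.3f  q2 = %.3f\n",
              x$avg_r, x$avg_r2, x$avg_q2))
  cat(sprintf("  cRp^2 = %.3f  valid: %s\n", x$crp2, x$valid))
  invisible(x)
}

#' Leverage-based applicability domain (Williams plot data)
#'
#' Computes hat-matrix leverages `h_i = x_i' (X'X)^-1 x_i` on the
#' intercept-augmented training design (so training leverages sum to k + 1),
#' the warning leverage `h* = 3 (k + 1) / n`, and standardized residuals
#' `e_i / s` with `s = sqrt(SSE / (n - k - 1))` from the training residuals.
#' Points with `h > h*` or `|standardized residual| > 3` are flagged as
#' outliers (reasons `"leverage"` / `"residual"`).
#'
#' @param X_train Training descriptor matrix (full rank with intercept).
#' @param residuals_train Training residuals (same order as rows).
#' @param X_test Optional test descriptor matrix.
#' @param residuals_test Optional test residuals.
#' @param h_star Warning leverage; default `3 * (k + 1) / n` with
#'   `k = ncol(X_train)` and `n = nrow(X_train)`.
#' @param resid_cutoff Standardized-residual cutoff (default 3).
#' @return An object of class `domain_result`: `leverages` (named),
#'   `h_star`, `std_residuals`, `outliers` (data.frame id/set/reason),
#'   `williams_table` (data.frame id, h, std_residual, set).
#' @export
applicability_domain <- function(X_train, residuals_train, X_test = NULL,
                                 residuals_test = NULL, h_star = NULL,
                                 resid_cutoff = 3) {
  X_train <- as_design(X_train)
  n <- nrow(X_train); k <- ncol(X_train)
  A <- cbind(1, X_train)
  dec <- qr(A)
  if (dec$rank < ncol(A)) stop("singular training design", call. = FALSE)
  R <- qr.R(dec)[seq_len(ncol(A)), , drop = FALSE]
  # h_i = || R^-T a_i ||^2 ; avoids forming (A'A)^-1
  lev_of <- function(M) {
    B <- forwardsolve(t(R), t(cbind(1, M)))
    colSums(B^2)
  }
  h_train <- lev_of(X_train)
  if (is.null(h_star)) h_star <- 3 * (k + 1) / n
  if (length(residuals_train) != n) {
    stop("residuals_train length mismatch", call. = FALSE)
  }
  s <- sqrt(sum(residuals_train^2) / (n - k - 1))
  id_of <- function(M, prefix) {
    if (!is.null(rownames(M))) rownames(M) else paste0(prefix, seq_len(nrow(M)))
  }
  ids_tr <- id_of(X_train, "train_")
  tab <- data.frame(id = ids_tr, h = unname(h_train),
                    std_residual = residuals_train / s,
                    set = "train", stringsAsFactors = FALSE)
  if (!is.null(X_test)) {
    X_test <- as_design(X_test)
    if (!identical(colnames(X_test), colnames(X_train))) {
      stop("X_test columns must match X_train", call. = FALSE)
    }
    if (is.null(residuals_test) || length(residuals_test) != nrow(X_test)) {
      stop("residuals_test required with X_test, one per row", call. = FALSE)
    }
    tab_te <- data.frame(id = id_of(X_test, "test_"),
                         h = unname(lev_of(X_test)),
                         std_residual = residuals_test / s,
                         set = "test", stringsAsFactors = FALSE)
    tab <- rbind(tab, tab_te)
  }
  lev_out <- tab$h > h_star
  res_out <- abs(tab$std_residual) > resid_cutoff
  outliers <- data.frame(
    id = c(tab$id[lev_out], tab$id[res_out]),
    set = c(tab$set[lev_out], tab$set[res_out]),
    reason = c(rep("leverage", sum(lev_out)), rep("residual", sum(res_out))),
    stringsAsFactors = FALSE)
  lev_all <- tab$h
  names(lev_all) <- tab$id
  std_all <- tab$std_residual
  names(std_all) <- tab$id
  structure(
    list(leverages = lev_all, h_star = h_star, std_residuals = std_all,
         outliers = outliers, williams_table = tab, s = s),
    class = "domain_result")
}

#' @export
print.domain_result <- function(x, ...) {
  cat(sprintf("applicability domain: h* = %.4f, %d point(s), %d outlier(s)\n",
              x$h_star, nrow(x$williams_table), nrow(x$outliers)))
  invisible(x)
}

#' Write a Williams table to CSV
#'
#' @param domain A `domain_result` from [applicability_domain()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_williams_csv <- function(domain, path) {
  stopifnot(inherits(domain, "domain_result"))
  write_csv_full(domain$williams_table, path)
  invisible(path)
}
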