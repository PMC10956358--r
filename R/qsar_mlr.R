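#' Fit an ordinary least-squares multiple linear regression QSAR model
#'
#' Fits `y = a0 + sum_j a_j x_j` by QR factorization of the
#' intercept-augmented design (no explicit inversion of X'X, which matters
#' for small, partially correlated descriptor sets).
#'
#' @param X Numeric matrix (n x p) of descriptors with column names.
#' @param y Numeric activity vector of length n.
#' @return An object of class `mlr_model` with `intercept`, `coefficients`
#'   (named by descriptor), `descriptor_names`, `n_train`, `fitted`,
#'   `residuals`.
#' @export
fit_mlr <- function(X, y) {
  X <- as_design(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in design or response", call. = FALSE)
  }
  if (n < p + 2) {
    stop("need n >= p + 2 observations (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  }
  A <- cbind(`(Intercept)` = 1, X)
  dec <- qr(A)
  if (dec$rank < ncol(A)) {
    dropped <- colnames(A)[dec$pivot[seq(dec$rank + 1L, ncol(A))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(dec, y)
  fitted <- drop(A %*% beta)
  structure(
    list(intercept = unname(beta[1L]),
         coefficients = beta[-1L],
         descriptor_names = colnames(X),
         n_train = n,
         fitted = fitted,
         residuals = y - fitted),
    class = "mlr_model")
}

as_design <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("mlr_model fit on", x$n_train, "compounds\n")
  cat("  intercept:", format(x$intercept, digits = 6), "\n")
  for (nm in x$descriptor_names) {
    cat("  ", nm, ":", format(x$coefficients[[nm]], digits = 6), "\n")
  }
  invisible(x)
}

#' Predict activities from an MLR model
#'
#' @param object An `mlr_model`.
#' @param newdata Numeric matrix or data frame whose columns match the
#'   model's descriptors in name and order.
#' @param ... Unused.
#' @return Numeric vector of predicted activities.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!identical(colnames(X), object$descriptor_names)) {
    stop("descriptor columns mismatch; expected [",
         paste(object$descriptor_names, collapse = ", "), "], received [",
         paste(colnames(X), collapse = ", "), "]", call. = FALSE)
  }
  drop(object$intercept + X %*% object$coefficients)
}

#' Fit statistics for observed vs calculated activities
#'
#' Computes the standard regression summary for a model with `p`
#' explanatory variables fit on `n` observations:
#' \deqn{R^2 = 1 - SSE/SST,\quad
#'       R^2_{adj} = ((n-1) R^2 - p)/(n - 1 - p),\quad
#'       MSE = SSE/n,}
#' the ANOVA F statistic \eqn{F = (SSR/SSE)\,(n-p-1)/p}, the residual
#' standard deviation `s = sqrt(SSE/(n-p-1))`, MAE, and the
#' Gaussian-likelihood Bayesian information criterion
#' `BIC = n log(SSE/n) + (p+1) log(n)`.
#'
#' A perfect fit reports `f_stat = Inf` (not an error).
#'
#' @param y_obs Observed activities.
#' @param y_cal Calculated (fitted or predicted) activities.
#' @param n Number of observations (defaults to `length(y_obs)`).
#' @param p Number of explanatory variables.
#' @return A list of class `fit_metrics`: `r2`, `r2_adj`, `mse`, `rmse`,
#'   `mae`, `f_stat`, `s`, `bic`, `n`, `p`.
#' @export
fit_metrics <- function(y_obs, y_cal, n = length(y_obs), p) {
  y_obs <- as.numeric(y_obs); y_cal <- as.numeric(y_cal)
  if (length(y_obs) != length(y_cal) || length(y_obs) < 3L) {
    stop("y_obs and y_cal must have equal length >= 3", call. = FALSE)
  }
  if (p < 1L) stop("p must be >= 1", call. = FALSE)
  if (n - 1L - p <= 0L) {
    stop("n - 1 - p must be positive (n = ", n, ", p = ", p, ")", call. = FALSE)
  }
  ybar <- mean(y_obs)
  sst <- sum((y_obs - ybar)^2)
  if (sst == 0) stop("y_obs has zero variance; R^2 undefined", call. = FALSE)
  sse <- sum((y_obs - y_cal)^2)
  ssr <- sum((y_cal - ybar)^2)
  r2 <- 1 - sse / sst
  r2_adj <- ((n - 1) * r2 - p) / (n - 1 - p)
  mse <- sse / n
  f_stat <- if (sse == 0) Inf else (ssr / sse) * (n - p - 1) / p
  structure(
    list(r2 = r2, r2_adj = r2_adj, mse = mse, rmse = sqrt(mse),
         mae = mean(abs(y_obs - y_cal)),
         f_stat = f_stat,
         s = sqrt(sse / (n - p - 1)),
         bic = n * log(sse / n) + (p + 1) * log(n),
         n = n, p = p),
    class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("fit_metrics (n = %d, p = %d)\n", x$n, x$p))
  cat(sprintf("  R2 = %.4f  R2adj = %.4f  RMSE = %.4f  MAE = %.4f\n",
              x$r2, x$r2_adj, x$rmse, x$mae))
  cat(sprintf("  s = %.4f  F = %.4g  BIC = %.4g\n", x$s, x$f_stat, x$bic))
  invisible(x)
}

#' Serialize an MLR model to JSON
#'
#' @param model An `mlr_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
mlr_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "mlr_model"))
  obj <- list(type = "mlr_model",
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              descriptor_names = model$descriptor_names,
              n_train = model$n_train)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore an MLR model from JSON
#'
#' @param path File path or JSON string produced by [mlr_to_json()].
#' @return An `mlr_model` (without fitted values/residuals).
#' @export
mlr_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$type, "mlr_model")) stop("not an mlr_model JSON", call. = FALSE)
  coefs <- unlist(obj$coefficients)
  structure(
    list(intercept = obj$intercept,
         coefficients = coefs[obj$descriptor_names],
         descriptor_names = obj$descriptor_names,
         n_train = obj$n_train,
         fitted = NULL, residuals = NULL),
    class = "mlr_model")
}
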