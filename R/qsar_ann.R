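#' Train a small feed-forward neural-network regressor
#'
#' Single hidden layer with logistic (sigmoid) activation and identity
#' output, matching the classic QSAR architecture (e.g. 4-3-1 for four
#' descriptors and three hidden units: 4*3 + 3 + 3 + 1 = 19 parameters).
#' Inputs and target are z-scored on training statistics; predictions are
#' returned in original units.  Training minimizes mean squared error with
#' a conjugate-gradient method from a seeded uniform [-0.5, 0.5] weight
#' initialization, so a given seed always yields identical weights.
#'
#' @param X Descriptor matrix (n x p), n >= 8.
#' @param y Activity vector.
#' @param hidden_units Hidden layer width (default 3; >= 1).
#' @param seed Integer seed for weight initialization.
#' @param max_iter Maximum conjugate-gradient iterations.
#' @param tol Relative convergence tolerance on the loss.
#' @return An object of class `mlp_model`: `layer_sizes`, `W1`, `b1`, `w2`,
#'   `b2`, scalers (`x_center`, `x_scale`, `y_center`, `y_scale`),
#'   `descriptor_names`, `final_loss`, `converged`, `config`.
#' @export
train_mlp <- function(X, y, hidden_units = 3L, seed = 1L, max_iter = 2000L,
                      tol = 1e-10) {
  X <- as_design(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X); h <- as.integer(hidden_units)
  if (n < 8L) stop("need n >= 8 observations", call. = FALSE)
  if (h < 1L) stop("hidden_units must be >= 1", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite inputs", call. = FALSE)
  }
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (y_scale == 0) y_scale <- 1
  Z <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  t_std <- (y - y_center) / y_scale

  n_par <- p * h + h + h + 1L
  unpack <- function(theta) {
    list(W1 = matrix(theta[seq_len(p * h)], p, h),
         b1 = theta[p * h + seq_len(h)],
         w2 = theta[p * h + h + seq_len(h)],
         b2 = theta[n_par])
  }
  loss <- function(theta) {
    par <- unpack(theta)
    H <- stats::plogis(Z %*% par$W1 + rep(par$b1, each = n))
    yhat <- drop(H %*% par$w2) + par$b2
    v <- mean((yhat - t_std)^2)
    if (!is.finite(v)) stop("non-finite training loss", call. = FALSE)
    v
  }
  grad <- function(theta) {
    par <- unpack(theta)
    A1 <- Z %*% par$W1 + rep(par$b1, each = n)
    H <- stats::plogis(A1)
    yhat <- drop(H %*% par$w2) + par$b2
    d <- 2 * (yhat - t_std) / n            # dL/dyhat
    dW2 <- drop(crossprod(H, d))
    db2 <- sum(d)
    dH <- outer(d, par$w2)
    dA1 <- dH * H * (1 - H)
    dW1 <- crossprod(Z, dA1)
    c(as.vector(dW1), colSums(dA1), dW2, db2)
  }
  restore <- local_rng(seed)
  theta0 <- stats::runif(n_par, -0.5, 0.5)
  restore()
  fit <- stats::optim(theta0, loss, grad, method = "CG",
                      control = list(maxit = as.integer(max_iter),
                                     reltol = tol))
  par <- unpack(fit$par)
  structure(
    list(layer_sizes = c(p, h, 1L),
         W1 = par$W1, b1 = par$b1, w2 = par$w2, b2 = par$b2,
         x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale,
         descriptor_names = colnames(X),
         final_loss = fit$value,
         converged = fit$convergence == 0L,
         config = list(hidden_units = h, seed = as.integer(seed),
                       max_iter = as.integer(max_iter), tol = tol,
                       algorithm = "conjugate-gradient")),
    class = "mlp_model")
}

#' Number of trainable parameters of an MLP
#'
#' @param model An `mlp_model`.
#' @return Integer parameter count `p*h + h + h + 1`.
#' @export
mlp_n_parameters <- function(model) {
  p <- model$layer_sizes[1L]; h <- model$layer_sizes[2L]
  as.integer(p * h + h + h + 1L)
}

#' Predict activities from an MLP model
#'
#' `yhat = w2' sigmoid(W1' z(x) + b1) + b2`, destandardized to original
#' activity units; vectorized over rows.
#'
#' @param object An `mlp_model`.
#' @param newdata Matrix/data frame whose columns match the training
#'   descriptors in name and order.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!identical(colnames(X), object$descriptor_names)) {
    stop("descriptor columns mismatch; expected [",
         paste(object$descriptor_names, collapse = ", "), "], received [",
         paste(colnames(X), collapse = ", "), "]", call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  H <- stats::plogis(Z %*% object$W1 + rep(object$b1, each = nrow(Z)))
  std <- drop(H %*% object$w2) + object$b2
  std * object$y_scale + object$y_center
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model %d-%d-1 (%d parameters), final loss %.4g, %s\n",
              x$layer_sizes[1], x$layer_sizes[2], mlp_n_parameters(x),
              x$final_loss,
              if (x$converged) "converged" else "max-iter reached"))
  invisible(x)
}

#' Serialize an MLP model to JSON
#'
#' @param model An `mlp_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
mlp_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(type = "mlp_model",
              layer_sizes = model$layer_sizes,
              W1 = as.vector(model$W1), b1 = model$b1,
              w2 = model$w2, b2 = model$b2,
              x_center = unname(model$x_center),
              x_scale = unname(model$x_scale),
              y_center = model$y_center, y_scale = model$y_scale,
              descriptor_names = model$descriptor_names,
              final_loss = model$final_loss,
              converged = model$converged,
              config = model$config)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore an MLP model from JSON
#'
#' @param path File path or JSON string produced by [mlp_to_json()].
#' @return An `mlp_model`.
#' @export
mlp_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$type, "mlp_model")) stop("not an mlp_model JSON", call. = FALSE)
  p <- obj$layer_sizes[1L]; h <- obj$layer_sizes[2L]
  structure(
    list(layer_sizes = as.integer(obj$layer_sizes),
         W1 = matrix(obj$W1, p, h), b1 = obj$b1, w2 = obj$w2, b2 = obj$b2,
         x_center = stats::setNames(obj$x_center, obj$descriptor_names),
         x_scale = stats::setNames(obj$x_scale, obj$descriptor_names),
         y_center = obj$y_center, y_scale = obj$y_scale,
         descriptor_names = obj$descriptor_names,
         final_loss = obj$final_loss, converged = obj$converged,
         config = obj$config),
    class = "mlp_model")
}
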