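# Per-joint-variable regression network: 192 inputs -> three 10-node fully
# connected layers each followed by ReLU -> one linear output; mean squared
# error loss. The network is small on purpose (2161 parameters) so that a
# full-batch quasi-Newton fit converges in seconds and the trained model
# could run online. Forward and backward passes are hand-written vectorized
# matrix arithmetic; optimization uses stats::optim L-BFGS-B, which is
# deterministic given the seeded initialization.

#' Regressor configuration
#'
#' @param hidden_widths Hidden-layer widths (default `c(10, 10, 10)`, each
#'   followed by ReLU).
#' @param max_iterations L-BFGS iteration cap (default 1000).
#' @param tolerance Relative convergence tolerance on the loss (default
#'   1e-6).
#' @param standardize_inputs Standardize each feature to zero mean / unit sd
#'   using training-set statistics (default TRUE).
#' @param min_rows Minimum training rows required.
#' @param seed Integer seed for weight initialization.
#' @return A list of class `regressor_config`.
#' @export
regressor_config <- function(hidden_widths = c(10L, 10L, 10L),
                             max_iterations = 1000L,
                             tolerance = 1e-6,
                             standardize_inputs = TRUE,
                             min_rows = 100L,
                             seed = 1L) {
  if (any(hidden_widths <= 0)) {
    stop_sonokin("hidden widths must be positive", "config_error")
  }
  structure(
    list(
      hidden_widths = as.integer(hidden_widths),
      max_iterations = as.integer(max_iterations),
      tolerance = tolerance,
      standardize_inputs = isTRUE(standardize_inputs),
      min_rows = as.integer(min_rows),
      seed = as.integer(seed)
    ),
    class = "regressor_config"
  )
}

# Layer sizes including input and output.
mlp_dims <- function(n_inputs, hidden_widths) {
  c(n_inputs, hidden_widths, 1L)
}

mlp_n_params <- function(dims) {
  sum(dims[-length(dims)] * dims[-1] + dims[-1])
}

# Unflatten a parameter vector into per-layer weight matrices and biases.
mlp_unpack <- function(par, dims) {
  L <- length(dims) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  pos <- 0
  for (l in seq_len(L)) {
    nw <- dims[l] * dims[l + 1]
    W[[l]] <- matrix(par[pos + seq_len(nw)], dims[l], dims[l + 1])
    pos <- pos + nw
    b[[l]] <- par[pos + seq_len(dims[l + 1])]
    pos <- pos + dims[l + 1]
  }
  list(W = W, b = b)
}

# Forward pass; keeps activations for backprop when wanted.
mlp_forward <- function(X, W, b, keep = FALSE) {
  L <- length(W)
  A <- X
  acts <- if (keep) vector("list", L + 1) else NULL
  if (keep) acts[[1]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% W[[l]]
    Z <- sweep(Z, 2, b[[l]], "+")
    A <- if (l < L) pmax(Z, 0) else Z
    if (keep) acts[[l + 1]] <- A
  }
  list(yhat = drop(A), acts = acts)
}

# MSE loss and its gradient w.r.t. the flat parameter vector.
mlp_loss_grad <- function(par, X, y, dims) {
  p <- mlp_unpack(par, dims)
  fw <- mlp_forward(X, p$W, p$b, keep = TRUE)
  n <- length(y)
  resid <- fw$yhat - y
  loss <- mean(resid^2)

  L <- length(p$W)
  delta <- matrix(2 * resid / n, ncol = 1)
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1) {
    A_prev <- fw$acts[[l]]
    gW[[l]] <- crossprod(A_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(p$W[[l]])) * (fw$acts[[l]] > 0)
    }
  }
  grad <- unlist(purrr::map2(gW, gb, ~ c(as.numeric(.x), .y)))
  list(loss = loss, grad = grad)
}

# Seeded He-style initialization.
mlp_init <- function(dims, seed) {
  withr_seed(seed, {
    L <- length(dims) - 1
    par <- numeric(0)
    for (l in seq_len(L)) {
      sd0 <- sqrt(2 / dims[l])
      par <- c(par, rnorm(dims[l] * dims[l + 1], 0, sd0), rep(0, dims[l + 1]))
    }
    par
  })
}

dataset_matrix <- function(data) {
  xcols <- grep("^x\\d+$", names(data), value = TRUE)
  if (length(xcols) == 0) {
    stop_sonokin("no feature columns (x001...) found in data", "shape_error")
  }
  as.matrix(data[, xcols])
}

#' Train one joint-variable regressor
#'
#' Fits the 192-10-10-10-1 ReLU network to a supervised dataset (rows from
#' [build_supervised_dataset()]; multiple training trials may be
#' `dplyr::bind_rows()`-ed together — feature rows never mix across trials).
#' Inputs are standardized per feature and the label is centered and scaled
#' internally using training-set statistics; reported losses are on the
#' original label scale. Full-batch L-BFGS minimizes the MSE; the same seed
#' and data reproduce the model exactly.
#'
#' @param data Tibble with a `label` column and `x001`..`x192` features.
#' @param config A [regressor_config()].
#' @return An object of class `us_regressor`.
#' @export
train_regressor <- function(data, config = regressor_config()) {
  X <- dataset_matrix(data)
  y <- data$label
  if (nrow(X) < config$min_rows) {
    stop_sonokin(
      sprintf("training needs at least %d rows, got %d", config$min_rows, nrow(X)),
      "config_error"
    )
  }
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop_sonokin("non-finite features or labels", "value_error")
  }

  if (config$standardize_inputs) {
    x_center <- colMeans(X)
    x_scale <- apply(X, 2, sd)
    x_scale[x_scale < 1e-12] <- 1
  } else {
    x_center <- rep(0, ncol(X))
    x_scale <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)
  y_scale <- sd(y)
  if (y_scale < 1e-12) y_scale <- 1
  ys <- (y - y_center) / y_scale

  dims <- mlp_dims(ncol(X), config$hidden_widths)
  par0 <- mlp_init(dims, config$seed)

  trace_env <- new.env()
  trace_env$loss <- numeric(0)
  cache <- new.env()
  eval_at <- function(par) {
    key <- par
    if (is.null(cache$par) || !identical(cache$par, key)) {
      cache$par <- key
      cache$val <- mlp_loss_grad(par, Xs, ys, dims)
    }
    cache$val
  }
  fn <- function(par) {
    v <- eval_at(par)$loss
    trace_env$loss <- c(trace_env$loss, v)
    v
  }
  gr <- function(par) eval_at(par)$grad

  fit <- optim(
    par0, fn, gr,
    method = "L-BFGS-B",
    control = list(
      maxit = config$max_iterations,
      factr = config$tolerance / .Machine$double.eps
    )
  )
  converged <- fit$convergence == 0
  if (!converged) {
    warning(sprintf(
      "regressor for '%s' did not converge within %d iterations (code %d)",
      data$variable[1] %||% "?", config$max_iterations, fit$convergence
    ))
  }

  structure(
    list(
      params = fit$par,
      dims = dims,
      x_center = x_center,
      x_scale = x_scale,
      y_center = y_center,
      y_scale = y_scale,
      variable_name = if ("variable" %in% names(data)) data$variable[1] else NA_character_,
      loss_trace = trace_env$loss * y_scale^2,
      final_loss = fit$value * y_scale^2,
      n_iter = fit$counts[["function"]],
      converged = converged,
      config = config
    ),
    class = "us_regressor"
  )
}

#' Predict kinematics from feature rows
#'
#' @param object A trained `us_regressor`.
#' @param newdata Tibble with `x001`..`x192` columns, or a numeric matrix
#'   with 192 columns.
#' @param ... Unused.
#' @return Numeric vector of predictions on the original label scale.
#' @export
predict.us_regressor <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else dataset_matrix(newdata)
  if (ncol(X) != object$dims[1]) {
    stop_sonokin(
      sprintf("feature rows have width %d, model expects %d",
              ncol(X), object$dims[1]),
      "shape_error"
    )
  }
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  p <- mlp_unpack(object$params, object$dims)
  mlp_forward(Xs, p$W, p$b)$yhat * object$y_scale + object$y_center
}

#' @export
print.us_regressor <- function(x, ...) {
  cat(sprintf(
    "<us_regressor> %s: %s network, %d parameters, final MSE %.4g%s\n",
    x$variable_name,
    paste(x$dims, collapse = "-"),
    mlp_n_params(x$dims),
    x$final_loss,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Tidy a trained regressor into per-layer rows
#'
#' @param x A `us_regressor`.
#' @param ... Unused.
#' @return A tibble with one row per layer: sizes, parameter counts and
#'   weight norms.
#' @export
tidy.us_regressor <- function(x, ...) {
  p <- mlp_unpack(x$params, x$dims)
  L <- length(p$W)
  tibble(
    layer = seq_len(L),
    inputs = x$dims[-length(x$dims)],
    outputs = x$dims[-1],
    activation = c(rep("relu", L - 1), "linear"),
    n_weights = purrr::map_int(p$W, length),
    n_biases = purrr::map_int(p$b, length),
    weight_norm = purrr::map_dbl(p$W, ~ sqrt(sum(.x^2)))
  )
}

#' One-row model summary
#'
#' @param x A `us_regressor`.
#' @param ... Unused.
#' @return A tibble with the fitted variable, parameter count, final
#'   training MSE/RMSE, iteration count and convergence flag.
#' @export
glance.us_regressor <- function(x, ...) {
  tibble(
    variable = x$variable_name,
    n_params = mlp_n_params(x$dims),
    final_mse = x$final_loss,
    final_rmse = sqrt(x$final_loss),
    n_iter = x$n_iter,
    converged = x$converged
  )
}
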