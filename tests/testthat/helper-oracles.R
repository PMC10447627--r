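# Independent oracles, coded separately from the package paths they check.

# Brute-force truncated-window moving average (explicit loop).
oracle_envelope <- function(x, window) {
  half <- (window - 1) %/% 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# End-to-end frame reduction in one independently written function:
# mean-offset rectification, truncated moving average, deep-end trim,
# contiguous window means.
oracle_frame_features <- function(samples, window = 77, trim = 37,
                                  n_windows = 48, win_len = 20) {
  rect <- abs(samples - mean(samples))
  env <- oracle_envelope(rect, window)
  kept <- env[1:(length(env) - trim)]
  out <- numeric(n_windows)
  for (k in seq_len(n_windows)) {
    out[k] <- mean(kept[((k - 1) * win_len + 1):(k * win_len)])
  }
  out
}

# Textbook bilinear-transform design of a 2nd-order low-pass Butterworth:
# analog prototype 1 / (s^2 + sqrt(2) s + 1), frequency prewarping
# K = tan(pi fc / fs).
oracle_butter2 <- function(fc, fs) {
  K <- tan(pi * fc / fs)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  b0 <- K^2 * norm
  list(
    b = c(b0, 2 * b0, b0),
    a = c(1, 2 * (K^2 - 1) * norm, (1 - sqrt(2) * K + K^2) * norm)
  )
}

# Per-row forward pass of a trained regressor with explicit scalar loops.
oracle_forward <- function(model, X) {
  dims <- model$dims
  L <- length(dims) - 1
  # unpack flat parameter vector the same way the layout is documented:
  # for each layer, column-major weight matrix then biases
  pos <- 0
  W <- list(); b <- list()
  for (l in 1:L) {
    nw <- dims[l] * dims[l + 1]
    W[[l]] <- matrix(model$params[pos + 1:nw], dims[l], dims[l + 1])
    pos <- pos + nw
    b[[l]] <- model$params[pos + 1:dims[l + 1]]
    pos <- pos + dims[l + 1]
  }
  out <- numeric(nrow(X))
  for (r in seq_len(nrow(X))) {
    a <- (X[r, ] - model$x_center) / model$x_scale
    for (l in 1:L) {
      z <- numeric(dims[l + 1])
      for (j in seq_len(dims[l + 1])) {
        z[j] <- sum(a * W[[l]][, j]) + b[[l]][j]
      }
      a <- if (l < L) pmax(z, 0) else z
    }
    out[r] <- a * model$y_scale + model$y_center
  }
  out
}

# Small deterministic synthetic session shared across tests.
tiny_session <- function(seed = 5L, duration_s = 3, noise_sd = 0.02) {
  prof <- make_gait_profile("normal", seed)
  echo <- make_echo_model(prof, seed, noise_sd = noise_sd)
  simulate_trial(prof, echo, duration_s = duration_s, seed = seed)
}
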