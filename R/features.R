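# Frame-level feature reduction: one 997-sample A-mode frame is offset,
# rectified, enveloped with a 77-point moving average over depth, trimmed by
# 37 samples at the deep end and collapsed into 48 windowed means of 20
# samples each (one feature per ~0.08 cm of depth).

#' Feature-geometry defaults for a 997-sample frame
#'
#' @param frame_samples Samples per raw frame.
#' @param envelope_window Moving-average window (odd), in samples.
#' @param trim Samples dropped from the deep end before windowing.
#' @param n_windows Number of feature windows.
#' @param window_len Samples per window.
#' @return A list of class `feature_geometry`.
#' @export
feature_geometry <- function(frame_samples = 997L, envelope_window = 77L,
                             trim = 37L, n_windows = 48L, window_len = 20L) {
  g <- list(
    frame_samples = as.integer(frame_samples),
    envelope_window = as.integer(envelope_window),
    trim = as.integer(trim),
    n_windows = as.integer(n_windows),
    window_len = as.integer(window_len)
  )
  if (g$trim + g$n_windows * g$window_len != g$frame_samples) {
    stop_sonokin(
      "inconsistent geometry: trim + n_windows * window_len must equal frame_samples",
      "config_error"
    )
  }
  structure(g, class = "feature_geometry")
}

#' Offset and rectify one raw frame
#'
#' Removes the frame's DC component and rectifies: `|x - offset|`. The
#' offset is the frame mean by default; a fixed value or no offset can be
#' configured.
#'
#' @param samples Numeric vector of raw frame samples (length 997 by
#'   default geometry).
#' @param offset `"mean"` (default), `"none"`, or a single numeric value.
#' @param frame_samples Expected length.
#' @return Non-negative numeric vector, same length.
#' @export
preprocess_frame <- function(samples, offset = "mean",
                             frame_samples = US_FRAME_SAMPLES) {
  if (length(samples) != frame_samples) {
    stop_sonokin(
      sprintf("frame has %d samples, expected %d", length(samples), frame_samples),
      "shape_error"
    )
  }
  if (!all(is.finite(samples))) {
    stop_sonokin("frame contains non-finite samples", "value_error")
  }
  off <- if (identical(offset, "mean")) {
    mean(samples)
  } else if (identical(offset, "none")) {
    0
  } else if (is.numeric(offset) && length(offset) == 1) {
    offset
  } else {
    stop_sonokin("offset must be 'mean', 'none', or a single number",
      "config_error")
  }
  abs(samples - off)
}

#' Moving-average envelope over depth
#'
#' Centered moving average with an odd window. At the edges the window is
#' truncated to the available samples and the mean is taken over the
#' truncated window, so a constant input stays exactly constant
#' (`edge = "truncate"`); `edge = "zero"` zero-pads instead.
#'
#' @param x Numeric vector (rectified frame).
#' @param window Odd window length, at most `length(x)`.
#' @param edge `"truncate"` (default) or `"zero"`.
#' @return Numeric vector, same length as `x`.
#' @export
envelope <- function(x, window = 77L, edge = c("truncate", "zero")) {
  edge <- match.arg(edge)
  n <- length(x)
  if (window %% 2 == 0 || window > n) {
    stop_sonokin("envelope window must be odd and no longer than the signal",
      "config_error")
  }
  half <- (window - 1) %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  sums <- cs[hi + 1] - cs[lo]
  if (edge == "truncate") sums / (hi - lo + 1) else sums / window
}

#' Trim the deep end and average 20-sample windows
#'
#' Drops the last `trim` samples (the deepest end of the frame), partitions
#' the remaining samples into `n_windows` contiguous non-overlapping windows
#' of `window_len` samples in depth order, and returns the mean of each.
#'
#' @param env Envelope vector (length `trim + n_windows * window_len`).
#' @param geometry A [feature_geometry()].
#' @return Numeric vector of `n_windows` features.
#' @export
trim_and_window <- function(env, geometry = feature_geometry()) {
  g <- geometry
  if (length(env) != g$frame_samples) {
    stop_sonokin(
      sprintf("envelope has %d samples, expected %d", length(env), g$frame_samples),
      "shape_error"
    )
  }
  kept <- env[seq_len(g$frame_samples - g$trim)]
  colMeans(matrix(kept, nrow = g$window_len))
}

#' Reduce one raw frame to its 48 features
#'
#' Composition of [preprocess_frame()], [envelope()] and
#' [trim_and_window()]: offset removal, rectification, 77-point
#' moving-average envelope, 37-sample deep-end trim, then 48 window means of
#' 20 samples. Each feature spans roughly 0.08 cm of tissue depth.
#'
#' @param samples Raw frame (numeric vector of 997 samples).
#' @param channel,tick Optional provenance carried into the result.
#' @param geometry A [feature_geometry()].
#' @param offset,edge Passed to the stages.
#' @return A tibble with one row: `tick`, `channel`, `f01`..`f48`.
#' @export
extract_channel_features <- function(samples, channel = NA_integer_,
                                     tick = NA_integer_,
                                     geometry = feature_geometry(),
                                     offset = "mean", edge = "truncate") {
  feats <- channel_feature_values(samples, geometry, offset, edge)
  out <- tibble(tick = as.integer(tick), channel = as.integer(channel))
  out[feature_names(geometry$n_windows)] <- as.list(feats)
  out
}

# Bare numeric pipeline (no tibble wrapper).
channel_feature_values <- function(samples, geometry = feature_geometry(),
                                   offset = "mean", edge = "truncate") {
  rect <- preprocess_frame(samples, offset, geometry$frame_samples)
  env <- envelope(rect, geometry$envelope_window, edge)
  trim_and_window(env, geometry)
}

feature_names <- function(n = 48L) sprintf("f%02d", seq_len(n))

#' Extract per-frame features for a whole trial
#'
#' Applies the frame reduction to every tick of a [simulate_trial()]
#' recording (or any trial with a `frames` matrix and `channel` vector).
#'
#' @param trial A `trial_recording`.
#' @param geometry A [feature_geometry()].
#' @param offset,edge Passed to the frame stages.
#' @return A tibble with columns `tick`, `channel`, `f01`..`f48`, one row
#'   per tick in tick order.
#' @export
extract_trial_features <- function(trial, geometry = feature_geometry(),
                                   offset = "mean", edge = "truncate") {
  stopifnot(inherits(trial, "trial_recording"))
  m <- trial$frames
  feats <- t(apply(m, 1, channel_feature_values,
    geometry = geometry, offset = offset, edge = edge
  ))
  colnames(feats) <- feature_names(geometry$n_windows)
  bind_cols(
    tibble(tick = trial$kinematics$tick, channel = trial$channel),
    as_tibble(feats)
  )
}
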