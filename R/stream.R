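# Round-robin stream assembly: at each 80 Hz tick exactly one channel's 48
# features refresh, and the model input is the 192-element concatenation of
# the most recent features of all four channels (channel 1 in positions
# 1-48, ..., channel 4 in 145-192).

#' Create an empty 192-element feature vector
#'
#' @param n_features Features per channel (default 48).
#' @return A `feature_vector` object with zeroed values at tick -1.
#' @export
new_feature_vector <- function(n_features = 48L) {
  structure(
    list(
      values = rep(0, US_N_CHANNELS * n_features),
      tick = -1L,
      updated_channel = NA_integer_,
      n_features = as.integer(n_features)
    ),
    class = "feature_vector"
  )
}

#' Fold one channel update into the running feature vector
#'
#' Overwrites the 48-element block of the updated channel, leaving the other
#' three blocks (the most recent readings of their channels) untouched.
#' Ticks must advance by exactly one.
#'
#' @param prev A `feature_vector`.
#' @param feats One-row tibble from [extract_channel_features()] (columns
#'   `tick`, `channel`, `f01`..`f48`), or a list with `tick`, `channel`,
#'   `values`.
#' @return The updated `feature_vector`.
#' @export
update_feature_vector <- function(prev, feats) {
  stopifnot(inherits(prev, "feature_vector"))
  if (is_tibble(feats) || is.data.frame(feats)) {
    feats <- list(
      tick = feats$tick[1],
      channel = feats$channel[1],
      values = as.numeric(feats[1, feature_names(prev$n_features)])
    )
  }
  if (!isTRUE(feats$tick == prev$tick + 1L)) {
    stop_sonokin(
      sprintf("tick discontinuity: previous %d, update %d", prev$tick, feats$tick),
      "sequencing_error"
    )
  }
  if (length(feats$values) != prev$n_features) {
    stop_sonokin("channel update has the wrong number of features", "shape_error")
  }
  k <- prev$n_features
  block <- ((feats$channel - 1L) * k + 1L):(feats$channel * k)
  out <- prev
  out$values[block] <- feats$values
  out$tick <- as.integer(feats$tick)
  out$updated_channel <- as.integer(feats$channel)
  out
}

#' Assemble the supervised dataset for one trial and joint variable
#'
#' Folds [update_feature_vector()] over the trial's per-tick channel
#' features. Emission starts at the first tick at which all four channels
#' have been observed (tick 3, 0-based), so every emitted row contains real
#' readings for every channel; earlier ticks are discarded rather than
#' zero-filled. The label of row `t` is the named joint variable at the same
#' tick (concurrent kinematics, no lead or lag).
#'
#' @param trial A `trial_recording`.
#' @param variable_name One of `"knee_pos"`, `"knee_vel"`, `"ankle_pos"`,
#'   `"ankle_vel"`.
#' @param features Optional precomputed [extract_trial_features()] table
#'   (saves recomputation when building datasets for all four variables).
#' @param geometry A [feature_geometry()].
#' @return A tibble with columns `tick`, `role`, `variable`, `label`,
#'   `x001`..`x192`, in tick order.
#' @export
build_supervised_dataset <- function(trial, variable_name,
                                     features = NULL,
                                     geometry = feature_geometry()) {
  stopifnot(inherits(trial, "trial_recording"))
  if (!variable_name %in% KIN_VARIABLES) {
    stop_sonokin(
      paste0("unknown joint variable '", variable_name, "'"),
      "config_error"
    )
  }
  if (is.null(features)) {
    features <- extract_trial_features(trial, geometry)
  }
  k <- geometry$n_windows
  fmat <- as.matrix(features[, feature_names(k)])
  channel <- features$channel
  ticks <- features$tick
  n <- nrow(fmat)
  warmup <- US_N_CHANNELS - 1L
  if (n <= warmup) {
    stop_sonokin("trial too short: all four channels must be observed",
      "sequencing_error")
  }

  # Row for tick t uses, per channel, the latest frame at a tick <= t.
  # With the round-robin law channel = (t mod 4) + 1 this is
  # t - ((t - (c - 1)) mod 4).
  emit <- (warmup + 1L):n
  X <- matrix(0, nrow = length(emit), ncol = US_N_CHANNELS * k)
  for (c in seq_len(US_N_CHANNELS)) {
    src <- emit - ((ticks[emit] - (c - 1L)) %% US_N_CHANNELS)
    stopifnot(all(channel[src] == c))
    X[, ((c - 1L) * k + 1L):(c * k)] <- fmat[src, ]
  }
  colnames(X) <- sprintf("x%03d", seq_len(ncol(X)))

  labels <- trial$kinematics[[variable_name]][emit]
  bind_cols(
    tibble(
      tick = ticks[emit],
      role = trial$trial_role,
      variable = variable_name,
      label = labels
    ),
    as_tibble(X)
  )
}

#' Partition four trials into the train/test split
#'
#' The two comfortable-speed training trials train the regressors; the
#' remaining comfortable-speed and fast-speed trials are held out as two
#' distinct testing sets. The split is driven by each trial's role, not by
#' input order, and no rows ever cross trials.
#'
#' @param trials A list of exactly four `trial_recording`s with roles
#'   `train1`, `train2`, `normal_test`, `fast_test` (each exactly once).
#' @return A list with elements `train` (list of 2), `normal_test`,
#'   `fast_test`.
#' @export
split_trials <- function(trials) {
  if (length(trials) != 4) {
    stop_sonokin("expected exactly four trials", "config_error")
  }
  roles <- purrr::map_chr(trials, "trial_role")
  expected <- c("train1", "train2", "normal_test", "fast_test")
  if (!setequal(roles, expected) || anyDuplicated(roles)) {
    stop_sonokin(
      paste0(
        "trial roles must be exactly {train1, train2, normal_test, fast_test}, got {",
        paste(roles, collapse = ", "), "}"
      ),
      "config_error"
    )
  }
  list(
    train = list(trials[[which(roles == "train1")]],
                 trials[[which(roles == "train2")]]),
    normal_test = trials[[which(roles == "normal_test")]],
    fast_test = trials[[which(roles == "fast_test")]]
  )
}
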