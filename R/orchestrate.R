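# One-command synthetic experiment plus trial/config persistence. The
# protocol mirrors the four-trial recording session: two comfortable-speed
# training trials, one comfortable-speed test trial, one fast test trial;
# four per-variable regressors trained on the pooled training trials and
# evaluated on both held-out sets with the same models.

#' Default experiment configuration
#'
#' Collects every tunable of the pipeline in one nested list: synthetic
#' profile and echo parameters, feature geometry, regressor settings and
#' filter specification. Constants of the acquisition chain (80 Hz, 4
#' channels, 997 samples, 3.94 cm) are fixed in the package.
#'
#' @param seed Global integer seed; fanned out deterministically to
#'   per-trial and per-model substreams.
#' @param duration_s Trial duration in seconds (default 8, so the two
#'   training trials pool ~1280 frames).
#' @param knee_rom,ankle_rom Normal-speed ranges of motion (deg).
#' @param rom_scale Fast-speed ROM multiplier.
#' @param noise_sd Raw-sample noise standard deviation.
#' @param max_iterations Regressor L-BFGS iteration cap.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L, duration_s = 8,
                              knee_rom = 65, ankle_rom = 20,
                              rom_scale = 1.15,
                              noise_sd = 0.02,
                              max_iterations = 1000L) {
  structure(
    list(
      seed = as.integer(seed),
      synth = list(
        duration_s = duration_s,
        knee_rom = knee_rom,
        ankle_rom = ankle_rom,
        rom_scale = rom_scale,
        n_harmonics = 4L,
        n_reflectors = 3L,
        mod_amp_cm = 0.25,
        pulse_sigma = 15,
        noise_sd = noise_sd
      ),
      geometry = unclass(feature_geometry()),
      regressor = unclass(regressor_config(
        max_iterations = max_iterations, seed = seed
      )),
      filter = unclass(filter_spec())
    ),
    class = "experiment_config"
  )
}

validate_config <- function(config) {
  g <- do.call(feature_geometry, config$geometry) # re-checks geometry law
  stopifnot(config$synth$duration_s > 0)
  invisible(g)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> seed=%d, trials %gs, knee/ankle ROM %g/%g deg, noise sd %g\n",
    x$seed, x$synth$duration_s, x$synth$knee_rom, x$synth$ankle_rom,
    x$synth$noise_sd
  ))
  invisible(x)
}

# Render double columns as round-trip-exact decimal strings for CSV output.
format_doubles <- function(df) {
  dplyr::mutate(df, across(
    dplyr::where(is.double),
    ~ sprintf("%.17g", .x)
  ))
}

# Deterministic seed fan-out, kept below 2^31.
sub_seed <- function(seed, k) (as.integer(seed) * 1009L + as.integer(k)) %% 2147483647L

#' Simulate the four-trial walking session
#'
#' @param config An [experiment_config()].
#' @return Named list of four `trial_recording`s (`train1`, `train2`,
#'   `normal_test`, `fast_test`).
#' @export
simulate_session <- function(config = experiment_config()) {
  validate_config(config)
  s <- config$synth
  prof_n <- make_gait_profile("normal", config$seed,
    n_harmonics = s$n_harmonics, knee_rom = s$knee_rom,
    ankle_rom = s$ankle_rom, rom_scale = s$rom_scale)
  prof_f <- make_gait_profile("fast", config$seed,
    n_harmonics = s$n_harmonics, knee_rom = s$knee_rom,
    ankle_rom = s$ankle_rom, rom_scale = s$rom_scale)
  echo <- make_echo_model(prof_n, config$seed,
    n_reflectors = s$n_reflectors, mod_amp_cm = s$mod_amp_cm,
    pulse_sigma = s$pulse_sigma, noise_sd = s$noise_sd)

  roles <- c("train1", "train2", "normal_test", "fast_test")
  profs <- list(prof_n, prof_n, prof_n, prof_f)
  out <- purrr::map2(roles, seq_along(roles), function(role, k) {
    simulate_trial(profs[[k]], echo, s$duration_s, role,
      seed = sub_seed(config$seed, k))
  })
  names(out) <- roles
  out
}

#' Run the full synthetic experiment end to end
#'
#' Simulates the four trials, extracts features, assembles the per-variable
#' supervised datasets, trains the four regressors on the pooled training
#' trials, and scores both testing sets. Fully deterministic given
#' `config$seed`.
#'
#' @param config An [experiment_config()].
#' @param variables Joint variables to model (default all four).
#' @return A `us_eval_report` (see [evaluate_experiment()]); the trained
#'   models, trials and config are attached as attributes `models`,
#'   `trials`, `config`.
#' @export
run_experiment <- function(config = experiment_config(),
                           variables = KIN_VARIABLES) {
  validate_config(config)
  trials <- simulate_session(config)
  split <- split_trials(trials)
  geometry <- do.call(feature_geometry, config$geometry)

  train_feats <- purrr::map(split$train, extract_trial_features,
    geometry = geometry)

  models <- purrr::map(set_names_chr(variables), function(v) {
    ds <- bind_rows(purrr::map2(
      split$train, train_feats,
      ~ build_supervised_dataset(.x, v, features = .y, geometry = geometry)
    ))
    cfg <- do.call(regressor_config, config$regressor)
    cfg$seed <- sub_seed(config$seed, 100L + match(v, KIN_VARIABLES))
    train_regressor(ds, cfg)
  })

  report <- evaluate_experiment(
    models,
    list(normal_test = split$normal_test, fast_test = split$fast_test),
    spec = do.call(filter_spec, config$filter),
    geometry = geometry
  )
  attr(report, "models") <- models
  attr(report, "trials") <- trials
  attr(report, "config") <- config
  report
}

set_names_chr <- function(x) stats::setNames(x, x)

#' Write / read a trial recording
#'
#' A trial is stored as a directory of plain-text files: `frames.csv`
#' (tick, channel, s0001..s0997), `kinematics.csv` (tick + four joint
#' variables + phase) and `meta.yaml` (role, sample rate, stride events and
#' stride times). The round trip is lossless (doubles are written with
#' shortest round-trip precision).
#'
#' @param trial A `trial_recording`.
#' @param path Directory to write into (created if needed).
#' @return `write_trial()` returns `path` invisibly; `read_trial()` returns
#'   the reconstructed `trial_recording`.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fr <- as_tibble(trial$frames, .name_repair = ~ sprintf("s%04d", seq_along(.x)))
  fr <- bind_cols(
    tibble(tick = trial$kinematics$tick, channel = trial$channel), fr
  )
  # doubles are serialized with 17 significant digits so the decimal ->
  # binary round trip is exact
  readr::write_csv(format_doubles(fr), file.path(path, "frames.csv"))
  readr::write_csv(format_doubles(trial$kinematics),
    file.path(path, "kinematics.csv"))
  yaml::write_yaml(
    list(
      trial_role = trial$trial_role,
      sample_rate = trial$sample_rate,
      stride_events = as.list(trial$stride_events),
      stride_times = as.list(sprintf("%.17g", trial$stride_times)),
      seed = trial$seed
    ),
    file.path(path, "meta.yaml")
  )
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  fr_path <- file.path(path, "frames.csv")
  kin_path <- file.path(path, "kinematics.csv")
  meta_path <- file.path(path, "meta.yaml")
  for (p in c(fr_path, kin_path, meta_path)) {
    if (!file.exists(p)) {
      stop_sonokin(paste0("missing trial file: ", p), "parse_error")
    }
  }
  # Parse all cells as text and convert with base R's strtod, which is
  # correctly rounded (vroom's fast float path can be 1 ulp off).
  chr <- readr::cols(.default = readr::col_character())
  fr <- readr::read_csv(fr_path, col_types = chr, progress = FALSE)
  kin <- readr::read_csv(kin_path, col_types = chr, progress = FALSE)
  meta <- yaml::read_yaml(meta_path)
  fr <- dplyr::mutate(fr, across(!c("tick", "channel"), as.numeric))
  kin <- dplyr::mutate(kin, across(!"tick", as.numeric))
  fr$tick <- as.integer(fr$tick)
  fr$channel <- as.integer(fr$channel)
  kin$tick <- as.integer(kin$tick)

  if (!identical(fr$tick, kin$tick)) {
    missing <- setdiff(fr$tick, kin$tick)
    extra <- setdiff(kin$tick, fr$tick)
    stop_sonokin(
      sprintf(
        "frames and kinematics tick mismatch (missing kinematics tick%s: %s)",
        if (length(missing) == 1) "" else "s",
        paste(c(missing, extra), collapse = ", ")
      ),
      "parse_error"
    )
  }
  expected <- seq_len(nrow(kin)) - 1L
  if (!identical(as.integer(kin$tick), expected)) {
    gap <- setdiff(expected, kin$tick)
    stop_sonokin(
      paste0("missing kinematics tick: ", paste(gap, collapse = ", ")),
      "parse_error"
    )
  }

  structure(
    list(
      frames = unname(as.matrix(fr[, grep("^s\\d+$", names(fr))])),
      channel = as.integer(fr$channel),
      kinematics = kin,
      stride_events = as.integer(unlist(meta$stride_events)),
      stride_times = as.numeric(unlist(meta$stride_times)),
      trial_role = meta$trial_role,
      sample_rate = meta$sample_rate,
      seed = meta$seed
    ),
    class = "trial_recording"
  )
}

#' Write / read an experiment configuration as YAML
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the `experiment_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- experiment_config(seed = raw$seed)
  for (sec in c("synth", "geometry", "regressor", "filter")) {
    for (nm in names(raw[[sec]])) cfg[[sec]][[nm]] <- raw[[sec]][[nm]]
  }
  validate_config(cfg)
  cfg
}

#' Acquisition timing of the round-robin ultrasound system
#'
#' Derives the timing facts of the sequential 4-channel acquisition from a
#' simulated trial: the per-tick channel update interval, the time for a
#' full refresh of all four channels, and the effective sampling rate of
#' each muscle group (two channels per group: anterior channels 1 and 3,
#' posterior channels 2 and 4).
#'
#' @param trial Optional `trial_recording`; a short synthetic trial is
#'   generated if omitted.
#' @return One-row tibble: `channel_update_ms`, `full_refresh_ms`,
#'   `muscle_group_rate_hz`.
#' @export
acquisition_timing <- function(trial = NULL) {
  if (is.null(trial)) {
    prof <- make_gait_profile("normal", 1L)
    echo <- make_echo_model(prof, 1L, noise_sd = 0)
    trial <- simulate_trial(prof, echo, duration_s = 1, seed = 1L)
  }
  tick_ms <- 1000 / trial$sample_rate
  # Ticks between successive polls of the same channel.
  refresh_ticks <- unique(diff(which(trial$channel == 1L)))
  stopifnot(length(refresh_ticks) == 1)
  # Each muscle group is covered by two interleaved channels.
  anterior <- which(trial$channel %in% c(1L, 3L))
  group_interval_ticks <- unique(diff(anterior))
  tibble(
    channel_update_ms = tick_ms,
    full_refresh_ms = refresh_ticks * tick_ms,
    muscle_group_rate_hz = trial$sample_rate / mean(group_interval_ticks)
  )
}
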