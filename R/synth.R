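# Synthetic trial generation: periodic gait kinematics plus A-mode echo
# trains whose reflector depths deform with gait phase. Stands in for the
# human-subject recordings, which were never deposited.

KIN_VARIABLES <- c("knee_pos", "knee_vel", "ankle_pos", "ankle_vel")

# Stride-time distributions by self-selected speed class (seconds).
STRIDE_PARAMS <- list(
  normal = list(mean = 1.2, sd = 0.1),
  fast   = list(mean = 1.0, sd = 0.2)
)

#' Create a gait profile for one synthetic subject
#'
#' A gait profile defines periodic knee/ankle position trajectories as
#' truncated Fourier series in normalized gait phase (heel strike = phase 0),
#' together with the stride-time distribution of a speed class. Velocities
#' are always the exact analytic phase-derivative of the positions scaled by
#' the instantaneous stride rate, so position and velocity streams are
#' mutually consistent by construction.
#'
#' The harmonic *shapes* are drawn from a substream keyed only to `seed`, so
#' the `normal` and `fast` profiles of the same seed describe the same
#' subject walking at two speeds. Faster walking uses a larger range of
#' motion (`rom_scale`), reflecting the larger joint excursions commonly
#' recorded at faster speeds.
#'
#' @param speed_class `"normal"` (stride time 1.2 +/- 0.1 s) or `"fast"`
#'   (1.0 +/- 0.2 s).
#' @param seed Integer seed; identical seeds give identical profiles.
#' @param n_harmonics Number of Fourier harmonics per joint (default 4).
#' @param knee_rom,ankle_rom Peak-to-peak range of motion targets in degrees
#'   for the normal-speed profile.
#' @param rom_scale Multiplier applied to both ROMs for the fast class.
#' @return An object of class `gait_profile`.
#' @export
make_gait_profile <- function(speed_class = c("normal", "fast"), seed,
                              n_harmonics = 4,
                              knee_rom = 65, ankle_rom = 20,
                              rom_scale = 1.15) {
  if (length(speed_class) == 1 && !speed_class %in% names(STRIDE_PARAMS)) {
    stop_sonokin(
      paste0("unknown speed_class '", speed_class, "'"),
      "config_error"
    )
  }
  speed_class <- match.arg(speed_class)
  stride <- STRIDE_PARAMS[[speed_class]]
  scale <- if (speed_class == "fast") rom_scale else 1

  # Shape substream depends on the seed only, not on the speed class.
  coeffs <- withr_seed(as.integer(seed), {
    purrr::map(
      c(knee_pos = "knee_pos", ankle_pos = "ankle_pos"),
      function(v) {
        h <- seq_len(n_harmonics)
        amp <- runif(n_harmonics, 0.5, 1) / h^1.3
        ph <- runif(n_harmonics, 0, 2 * pi)
        tibble(harmonic = h, amplitude = amp, phase = ph)
      }
    )
  })

  rom_target <- c(knee_pos = knee_rom * scale, ankle_pos = ankle_rom * scale)
  baseline <- c(knee_pos = 30, ankle_pos = 0)

  # Rescale drawn amplitudes so the realized peak-to-peak range matches the
  # ROM target (evaluated on a fine phase grid).
  grid <- seq(0, 1, length.out = 2048)
  for (v in names(coeffs)) {
    pos <- fourier_eval(coeffs[[v]], grid)$pos
    coeffs[[v]]$amplitude <- coeffs[[v]]$amplitude *
      rom_target[[v]] / diff(range(pos))
  }

  structure(
    list(
      speed_class = speed_class,
      stride_time_mean = stride$mean,
      stride_time_sd = stride$sd,
      fourier = coeffs,
      baseline = baseline,
      n_harmonics = n_harmonics,
      seed = as.integer(seed)
    ),
    class = "gait_profile"
  )
}

# Evaluate a Fourier coefficient table at phases; returns position and its
# analytic derivative with respect to phase.
fourier_eval <- function(coef_tbl, phase) {
  pos <- rep(0, length(phase))
  dpos <- rep(0, length(phase))
  for (i in seq_len(nrow(coef_tbl))) {
    h <- coef_tbl$harmonic[i]
    a <- coef_tbl$amplitude[i]
    p <- coef_tbl$phase[i]
    pos <- pos + a * sin(2 * pi * h * phase + p)
    dpos <- dpos + a * 2 * pi * h * cos(2 * pi * h * phase + p)
  }
  list(pos = pos, dpos = dpos)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Sample stride times from a gait profile
#'
#' Draws from the profile's normal stride-time distribution, truncated to
#' positive values by rejection.
#'
#' @param profile A `gait_profile`.
#' @param n Number of strides.
#' @return Numeric vector of stride durations in seconds.
#' @export
sample_stride_times <- function(profile, n) {
  out <- rnorm(n, profile$stride_time_mean, profile$stride_time_sd)
  bad <- out <= 0
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), profile$stride_time_mean, profile$stride_time_sd)
    bad <- out <= 0
  }
  out
}

#' Evaluate joint kinematics at a gait phase
#'
#' Positions come from the profile's truncated Fourier series; velocities are
#' the analytic phase-derivative multiplied by the instantaneous stride rate
#' `1 / stride_time`. Phase is wrapped modulo 1, so the trajectories are
#' periodic.
#'
#' @param profile A `gait_profile`.
#' @param phase Gait phase(s); wrapped into `[0, 1)`.
#' @param stride_time Instantaneous stride duration in seconds (defaults to
#'   the profile mean).
#' @return A tibble with columns `phase`, `knee_pos`, `knee_vel`,
#'   `ankle_pos`, `ankle_vel` (degrees and degrees/second).
#' @export
kinematics_at <- function(profile, phase, stride_time = profile$stride_time_mean) {
  phase <- phase %% 1
  knee <- fourier_eval(profile$fourier$knee_pos, phase)
  ankle <- fourier_eval(profile$fourier$ankle_pos, phase)
  tibble(
    phase = phase,
    knee_pos = profile$baseline[["knee_pos"]] + knee$pos,
    knee_vel = knee$dpos / stride_time,
    ankle_pos = profile$baseline[["ankle_pos"]] + ankle$pos,
    ankle_vel = ankle$dpos / stride_time
  )
}

#' Build an echo model tied to a reference gait profile
#'
#' Each of the 4 channels carries `n_reflectors` Gaussian echo pulses. The
#' depth of each reflector is modulated around its baseline by a coupling
#' function of gait phase: the instantaneous value of one joint variable,
#' normalized to `[-1, 1]` by the reference profile's range over a cycle and
#' clamped. Anterior/posterior placement is emulated by cycling the coupled
#' variable across the channel x reflector grid so that every joint variable
#' drives some reflectors. Echo amplitude decays exponentially with depth.
#'
#' @param profile Reference `gait_profile` used to normalize the couplings
#'   (the subject's normal-speed profile).
#' @param seed Integer seed for reflector layout draws.
#' @param n_reflectors Reflectors per channel (default 3).
#' @param mod_amp_cm Depth-modulation amplitude in cm (default 0.25).
#' @param pulse_sigma Gaussian pulse width (standard deviation) in samples.
#' @param atten_coef Exponential depth-attenuation coefficient (1/cm).
#' @param dc_offset Constant offset added to every sample.
#' @param noise_sd Standard deviation of additive Gaussian sample noise.
#' @return An object of class `echo_model`.
#' @export
make_echo_model <- function(profile, seed,
                            n_reflectors = 3,
                            mod_amp_cm = 0.25,
                            pulse_sigma = 15,
                            atten_coef = 0.3,
                            dc_offset = 0.35,
                            noise_sd = 0.02) {
  stopifnot(inherits(profile, "gait_profile"))
  margin <- 0.05
  lo <- mod_amp_cm + margin
  hi <- US_MAX_DEPTH_CM - mod_amp_cm - margin

  reflectors <- withr_seed(as.integer(seed) + 7L, {
    grid <- tidyr::expand_grid(
      channel = seq_len(US_N_CHANNELS),
      reflector = seq_len(n_reflectors)
    )
    k <- nrow(grid)
    grid %>%
      mutate(
        amplitude = runif(k, 0.6, 1.4),
        variable = KIN_VARIABLES[((channel - 1) * n_reflectors +
          (reflector - 1)) %% 4 + 1],
        coupling_sign = sample(c(-1, 1), k, replace = TRUE)
      ) %>%
      group_by(channel) %>%
      mutate(depth_cm = sort(runif(n(), lo, hi))) %>%
      ungroup()
  })

  bad <- reflectors$depth_cm - mod_amp_cm < 0 |
    reflectors$depth_cm + mod_amp_cm > US_MAX_DEPTH_CM
  if (any(bad)) {
    stop_sonokin("modulated reflector depth outside the 0-3.94 cm span",
      "config_error")
  }

  # Normalization of each coupled variable over one reference cycle.
  ref <- kinematics_at(profile, seq(0, 1, length.out = 1024))
  norms <- purrr::map(KIN_VARIABLES, function(v) {
    x <- ref[[v]]
    list(center = (max(x) + min(x)) / 2, halfrange = diff(range(x)) / 2)
  })
  names(norms) <- KIN_VARIABLES

  structure(
    list(
      reflectors = reflectors,
      mod_amp_cm = mod_amp_cm,
      pulse_sigma = pulse_sigma,
      atten_coef = atten_coef,
      dc_offset = dc_offset,
      noise_sd = noise_sd,
      norms = norms,
      n_samples = US_FRAME_SAMPLES,
      max_depth_cm = US_MAX_DEPTH_CM,
      seed = as.integer(seed)
    ),
    class = "echo_model"
  )
}

# Normalized coupling value in [-1, 1] for one joint variable at a phase.
coupling_value <- function(echo_model, profile, variable, phase, stride_time) {
  kin <- kinematics_at(profile, phase, stride_time)
  nm <- echo_model$norms[[variable]]
  pmin(1, pmax(-1, (kin[[variable]] - nm$center) / nm$halfrange))
}

#' Synthesize one raw A-mode frame
#'
#' Builds the 997-sample echo train of one channel at one gait phase:
#' DC offset plus Gaussian pulses centered at each reflector's modulated
#' depth, attenuated exponentially with depth, plus Gaussian noise drawn
#' from the current RNG stream.
#'
#' @param echo_model An `echo_model`.
#' @param channel Channel index 1..4.
#' @param phase Gait phase (wrapped modulo 1).
#' @param profile The `gait_profile` driving the couplings.
#' @param stride_time Instantaneous stride time in seconds.
#' @return Numeric vector of 997 samples.
#' @export
synth_raw_frame <- function(echo_model, channel, phase, profile,
                            stride_time = profile$stride_time_mean) {
  stopifnot(channel %in% seq_len(US_N_CHANNELS))
  n <- echo_model$n_samples
  cm_per_sample <- echo_model$max_depth_cm / n
  idx <- seq_len(n)
  refl <- echo_model$reflectors[echo_model$reflectors$channel == channel, ]
  x <- rep(echo_model$dc_offset, n)
  for (i in seq_len(nrow(refl))) {
    f <- coupling_value(echo_model, profile, refl$variable[i], phase, stride_time)
    d <- refl$depth_cm[i] + echo_model$mod_amp_cm * refl$coupling_sign[i] * f
    center <- d / cm_per_sample
    x <- x + refl$amplitude[i] * exp(-echo_model$atten_coef * d) *
      exp(-(idx - center)^2 / (2 * echo_model$pulse_sigma^2))
  }
  if (echo_model$noise_sd > 0) {
    x <- x + rnorm(n, 0, echo_model$noise_sd)
  }
  x
}

#' Simulate one walking trial
#'
#' Generates `floor(duration_s * 80)` ticks. At tick `t` (0-based) the
#' channel `(t mod 4) + 1` is polled, so a full refresh of all four channels
#' spans 4 ticks = 50 ms. Stride times are drawn per stride from the
#' profile's distribution; gait phase advances piecewise-linearly within each
#' stride and stride events are recorded at the phase-wrap ticks (the
#' synthetic stand-in for heel strikes). Kinematics are sampled every tick.
#'
#' @param profile A `gait_profile`.
#' @param echo_model An `echo_model`.
#' @param duration_s Trial duration in seconds (> 0).
#' @param trial_role One of `"train1"`, `"train2"`, `"normal_test"`,
#'   `"fast_test"`.
#' @param seed Integer seed; same seed reproduces the trial exactly.
#' @return An object of class `trial_recording` with elements `frames`
#'   (ticks x 997 matrix), `channel` (per-tick channel), `kinematics`
#'   (tibble: tick, phase, knee_pos, knee_vel, ankle_pos, ankle_vel),
#'   `stride_events` (0-based tick indices), `stride_times`, `trial_role`,
#'   `sample_rate`.
#' @export
simulate_trial <- function(profile, echo_model, duration_s = 8,
                           trial_role = c("train1", "train2",
                                          "normal_test", "fast_test"),
                           seed = 1L) {
  trial_role <- match.arg(trial_role)
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_sonokin("duration_s must be positive", "config_error")
  }
  n_ticks <- floor(duration_s * US_SAMPLE_RATE_HZ)

  withr_seed(as.integer(seed), {
    # Draw strides until they cover the trial.
    stride_times <- numeric(0)
    while (sum(stride_times) < duration_s) {
      stride_times <- c(stride_times, sample_stride_times(profile, 4))
    }
    starts <- cumsum(c(0, stride_times))
    t_sec <- (seq_len(n_ticks) - 1) / US_SAMPLE_RATE_HZ
    stride_idx <- findInterval(t_sec, starts)
    phase <- (t_sec - starts[stride_idx]) / stride_times[stride_idx]
    inst_stride <- stride_times[stride_idx]

    tick <- seq_len(n_ticks) - 1L
    channel <- (tick %% US_N_CHANNELS) + 1L
    stride_events <- tick[c(TRUE, diff(stride_idx) > 0)]

    kin <- kinematics_at(profile, phase, inst_stride)
    kin <- bind_cols(tibble(tick = tick), kin)

    frames <- matrix(0, nrow = n_ticks, ncol = US_FRAME_SAMPLES)
    for (t in seq_len(n_ticks)) {
      frames[t, ] <- synth_raw_frame(
        echo_model, channel[t], phase[t], profile, inst_stride[t]
      )
    }

    structure(
      list(
        frames = frames,
        channel = channel,
        kinematics = kin,
        stride_events = stride_events,
        stride_times = stride_times[seq_len(max(stride_idx))],
        trial_role = trial_role,
        sample_rate = US_SAMPLE_RATE_HZ,
        profile = profile,
        seed = as.integer(seed)
      ),
      class = "trial_recording"
    )
  })
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(
    "<gait_profile> %s speed: stride %.2f +/- %.2f s, %d harmonics\n",
    x$speed_class, x$stride_time_mean, x$stride_time_sd, x$n_harmonics
  ))
  invisible(x)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> role=%s: %d ticks at %d Hz, %d strides\n",
    x$trial_role, nrow(x$frames), x$sample_rate, length(x$stride_events)
  ))
  invisible(x)
}
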