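# Scoring suite: RMSE / range-normalized RMSE on unfiltered predictions,
# causal 2nd-order Butterworth smoothing of predictions, cross-correlation
# delay estimation, stride-normalized gait-cycle averaging, peak-timing
# conversion to milliseconds, and range/peak-shortfall metrics.

#' Causal low-pass filter specification
#'
#' Defaults match the smoothing applied to kinematic predictions: 2nd-order
#' Butterworth, 7 Hz cutoff (within the optimal band for walking), 80 Hz
#' sampling, applied forward-only so it could run online.
#'
#' @param order Filter order.
#' @param cutoff_hz Cutoff frequency in Hz (must be below Nyquist).
#' @param sample_rate_hz Sampling rate in Hz.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(order = 2L, cutoff_hz = 7, sample_rate_hz = 80) {
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate_hz / 2) {
    stop_sonokin("cutoff must lie strictly between 0 and Nyquist", "config_error")
  }
  structure(
    list(
      order = as.integer(order),
      cutoff_hz = cutoff_hz,
      sample_rate_hz = sample_rate_hz
    ),
    class = "filter_spec"
  )
}

#' RMSE and range-normalized RMSE
#'
#' `nrmse = 100 * rmse / (max(actual) - min(actual))` over the evaluated
#' segment (range normalization is the default; `"sd"` and `"mean"`
#' denominators are available).
#'
#' @param pred,actual Equal-length numeric vectors (length >= 2).
#' @param normalization `"range"` (default), `"sd"` or `"mean"`.
#' @return A one-row tibble with `rmse` and `nrmse` (percent).
#' @export
rmse_nrmse <- function(pred, actual, normalization = c("range", "sd", "mean")) {
  normalization <- match.arg(normalization)
  if (length(pred) != length(actual) || length(actual) < 2) {
    stop_sonokin("pred and actual must have equal length >= 2", "shape_error")
  }
  rmse <- sqrt(mean((pred - actual)^2))
  denom <- switch(normalization,
    range = diff(range(actual)),
    sd = sd(actual),
    mean = abs(mean(actual))
  )
  if (denom <= 0) {
    stop_sonokin("nRMSE undefined: constant (or zero-denominator) actual signal",
      "value_error")
  }
  tibble(rmse = rmse, nrmse = 100 * rmse / denom)
}

#' Apply the causal Butterworth filter
#'
#' Designs the low-pass Butterworth by bilinear transform and applies it
#' forward-only (one-way), incurring phase lag as an online filter would.
#' The filter state is initialized to the steady-state response for the
#' first sample value, so a constant input passes through exactly and
#' startup transients are suppressed.
#'
#' @param x Finite numeric vector.
#' @param spec A [filter_spec()].
#' @return Filtered vector, same length.
#' @export
causal_butterworth <- function(x, spec = filter_spec()) {
  if (!all(is.finite(x))) {
    stop_sonokin("input contains non-finite values", "value_error")
  }
  bf <- signal::butter(spec$order, spec$cutoff_hz / (spec$sample_rate_hz / 2),
    type = "low")
  # Unit DC gain means the steady-state response to x[1] is x[1] itself:
  # filter the deviation from x[1] with zero state and add x[1] back.
  as.numeric(signal::filter(bf, x - x[1])) + x[1]
}

#' Estimate the prediction delay by cross-correlation
#'
#' Finds the lag maximizing the normalized cross-correlation (both signals
#' mean-removed) within `±max_lag_s`, and converts it to milliseconds at the
#' sampling rate (12.5 ms per sample at 80 Hz). Positive delays mean the
#' prediction lags the recorded signal. If the peak correlation falls below
#' `min_correlation` the estimate is flagged unreliable (as happens for
#' high-error fast-speed predictions).
#'
#' @param pred_filtered,actual Equal-length numeric vectors.
#' @param max_lag_s Search half-window in seconds.
#' @param sample_rate_hz Sampling rate.
#' @param min_correlation Reliability floor on the peak correlation.
#' @return One-row tibble: `delay_ms`, `peak_correlation`, `reliable`.
#' @export
estimate_delay <- function(pred_filtered, actual, max_lag_s = 0.25,
                           sample_rate_hz = 80, min_correlation = 0.5) {
  if (length(pred_filtered) != length(actual)) {
    stop_sonokin("signals must have equal length", "shape_error")
  }
  p <- pred_filtered - mean(pred_filtered)
  a <- actual - mean(actual)
  n <- length(p)
  max_lag <- min(floor(max_lag_s * sample_rate_hz), n - 2)
  lags <- -max_lag:max_lag
  r <- purrr::map_dbl(lags, function(L) {
    if (L >= 0) {
      pi_ <- p[(1 + L):n]
      ai_ <- a[1:(n - L)]
    } else {
      pi_ <- p[1:(n + L)]
      ai_ <- a[(1 - L):n]
    }
    su <- sqrt(sum(pi_^2) * sum(ai_^2))
    if (su == 0) 0 else sum(pi_ * ai_) / su
  })
  best <- which.max(r)
  tibble(
    delay_ms = lags[best] * 1000 / sample_rate_hz,
    peak_correlation = r[best],
    reliable = r[best] >= min_correlation
  )
}

#' Average a signal over the gait cycle
#'
#' Segments the signal at stride events (heel strikes), linearly resamples
#' each stride onto a common 0-100% gait grid, and averages pointwise across
#' strides.
#'
#' @param x Numeric signal sampled at the trial ticks.
#' @param stride_events Strictly increasing 0-based tick indices of heel
#'   strikes (at least 2); strides extending past the signal are dropped.
#' @param n_points Grid resolution (default 101: 0,1,...,100%).
#' @param first_tick Tick index of `x[1]` (0-based), for signals that start
#'   after trial onset (e.g. post warm-up predictions).
#' @return A tibble with `gait_pct` and `value` (`n_points` rows).
#' @export
average_gait_cycle <- function(x, stride_events, n_points = 101L,
                               first_tick = 0L) {
  ev <- stride_events - first_tick + 1 # 1-based indices into x
  ev <- ev[ev >= 1 & ev <= length(x)]
  if (length(ev) < 2) {
    stop_sonokin("need at least two stride events inside the signal",
      "value_error")
  }
  grid <- seq(0, 100, length.out = n_points)
  cycles <- purrr::map(seq_len(length(ev) - 1), function(j) {
    seg <- x[ev[j]:ev[j + 1]]
    approx(seq(0, 100, length.out = length(seg)), seg, xout = grid)$y
  })
  tibble(gait_pct = grid, value = rowMeans(do.call(cbind, cycles)))
}

#' Convert a gait-percent peak-timing difference to milliseconds
#'
#' `round((pct_predicted - pct_recorded) / 100 * stride_time_s * 1000)` to
#' the nearest integer millisecond. Positive values mean the predicted peak
#' lags the recorded one.
#'
#' @param pct_predicted,pct_recorded Peak timings as percent of gait
#'   (0-100).
#' @param stride_time_s Mean stride time in seconds.
#' @return Integer milliseconds (vectorized).
#' @export
peak_delay_ms <- function(pct_predicted, pct_recorded, stride_time_s) {
  stopifnot(
    all(pct_predicted >= 0 & pct_predicted <= 100),
    all(pct_recorded >= 0 & pct_recorded <= 100)
  )
  as.integer(round((pct_predicted - pct_recorded) / 100 * stride_time_s * 1000))
}

#' Range and peak-shortfall metrics on mean gait cycles
#'
#' `range_ratio` is the predicted cycle's peak-to-peak range as a percent of
#' the recorded one. `peak_shortfall` is `100 * (actual_peak - pred_peak) /
#' actual_peak` for a named extremum of the cycle (`"max"` or `"min"`), so a
#' prediction that undershoots the recorded peak gives a positive
#' shortfall.
#'
#' @param pred_cycle,actual_cycle Mean-cycle values on the same gait grid
#'   (numeric vectors or `average_gait_cycle()` tibbles).
#' @param extremum `"max"` (default) or `"min"`.
#' @return One-row tibble: `range_ratio`, `peak_shortfall` (both percent).
#' @export
range_metrics <- function(pred_cycle, actual_cycle,
                          extremum = c("max", "min")) {
  extremum <- match.arg(extremum)
  pv <- if (is.data.frame(pred_cycle)) pred_cycle$value else pred_cycle
  av <- if (is.data.frame(actual_cycle)) actual_cycle$value else actual_cycle
  if (length(pv) != length(av)) {
    stop_sonokin("cycles must share the same gait grid", "shape_error")
  }
  a_range <- diff(range(av))
  ext_fun <- if (extremum == "max") max else min
  a_peak <- ext_fun(av)
  if (a_range == 0 || a_peak == 0) {
    stop_sonokin("zero actual range or peak", "value_error")
  }
  tibble(
    range_ratio = 100 * diff(range(pv)) / a_range,
    peak_shortfall = 100 * (a_peak - ext_fun(pv)) / a_peak
  )
}

# Gait-percent location of an extremum of a mean cycle.
peak_location <- function(cycle, extremum = "max") {
  i <- if (extremum == "max") which.max(cycle$value) else which.min(cycle$value)
  cycle$gait_pct[i]
}

#' Evaluate four trained regressors on the two testing sets
#'
#' Reproduces the full results structure: per joint variable and test set,
#' unfiltered predictions are scored with RMSE / range-normalized RMSE (the
#' unfiltered prediction has no filter delay, so it is the accuracy
#' benchmark), while the causally filtered predictions are used for delay
#' estimation, gait-cycle peak timing and range metrics. The
#' cross-correlation delay is reported only for the normal-speed set; on the
#' fast set the larger prediction error makes the correlation unreliable.
#'
#' @param models Named list of `us_regressor`s, one per joint variable
#'   (`knee_pos`, `knee_vel`, `ankle_pos`, `ankle_vel`).
#' @param test_trials List with `normal_test` and `fast_test`
#'   `trial_recording`s.
#' @param spec A [filter_spec()].
#' @param geometry A [feature_geometry()].
#' @return An object of class `us_eval_report` with tibbles `metrics`,
#'   `peaks`, `ranges`, `cycles` and per-set stride-time means.
#' @export
evaluate_experiment <- function(models, test_trials, spec = filter_spec(),
                                geometry = feature_geometry()) {
  stopifnot(setequal(names(models), KIN_VARIABLES))
  sets <- c("normal_test", "fast_test")
  stopifnot(all(sets %in% names(test_trials)))

  metrics <- list()
  peaks <- list()
  ranges <- list()
  cycles <- list()
  stride_means <- purrr::map_dbl(
    test_trials[sets], ~ mean(.x$stride_times)
  )

  for (set in sets) {
    trial <- test_trials[[set]]
    feats <- extract_trial_features(trial, geometry)
    for (v in KIN_VARIABLES) {
      ds <- build_supervised_dataset(trial, v, features = feats,
        geometry = geometry)
      pred <- predict(models[[v]], ds)
      actual <- ds$label
      pred_f <- causal_butterworth(pred, spec)

      m_raw <- rmse_nrmse(pred, actual)
      m_flt <- rmse_nrmse(pred_f, actual)
      dly <- if (set == "normal_test") {
        estimate_delay(pred_f, actual, sample_rate_hz = trial$sample_rate)
      } else {
        tibble(delay_ms = NA_real_, peak_correlation = NA_real_,
          reliable = NA)
      }

      first_tick <- ds$tick[1]
      cyc_a <- average_gait_cycle(actual, trial$stride_events,
        first_tick = first_tick)
      cyc_p <- average_gait_cycle(pred_f, trial$stride_events,
        first_tick = first_tick)

      metrics[[paste(set, v)]] <- tibble(
        test_set = set, variable = v,
        rmse = m_raw$rmse, nrmse = m_raw$nrmse,
        rmse_filtered = m_flt$rmse, nrmse_filtered = m_flt$nrmse,
        delay_ms = dly$delay_ms, peak_correlation = dly$peak_correlation,
        delay_reliable = dly$reliable
      )

      st <- stride_means[[set]]
      peaks[[paste(set, v)]] <- purrr::map_dfr(c("max", "min"), function(e) {
        pr <- peak_location(cyc_a, e)
        pp <- peak_location(cyc_p, e)
        tibble(
          test_set = set, variable = v, extremum = e,
          pct_recorded = pr, pct_predicted = pp,
          delay_ms = peak_delay_ms(pp, pr, st)
        )
      })

      ranges[[paste(set, v)]] <- purrr::map_dfr(c("max", "min"), function(e) {
        bind_cols(
          tibble(test_set = set, variable = v, extremum = e),
          range_metrics(cyc_p, cyc_a, e)
        )
      })

      cycles[[paste(set, v)]] <- tibble(
        test_set = set, variable = v,
        gait_pct = cyc_a$gait_pct,
        recorded = cyc_a$value, predicted = cyc_p$value
      )
    }
  }

  structure(
    list(
      metrics = bind_rows(metrics),
      peaks = bind_rows(peaks),
      ranges = bind_rows(ranges),
      cycles = bind_rows(cycles),
      stride_time_means = stride_means,
      filter = spec
    ),
    class = "us_eval_report"
  )
}

#' @export
print.us_eval_report <- function(x, ...) {
  cat("<us_eval_report>\n")
  cat(sprintf(
    "  stride time means: normal %.3f s, fast %.3f s\n",
    x$stride_time_means[["normal_test"]], x$stride_time_means[["fast_test"]]
  ))
  print(as.data.frame(
    x$metrics[, c("test_set", "variable", "rmse", "nrmse", "nrmse_filtered",
      "delay_ms")]
  ), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `us_eval_report`.
#' @param ... Unused.
#' @return The per-variable, per-test-set metrics tibble.
#' @export
tidy.us_eval_report <- function(x, ...) x$metrics

#' One-row evaluation summary
#'
#' @param x A `us_eval_report`.
#' @param ... Unused.
#' @return Tibble with mean nRMSE per test set and the mean reliable delay.
#' @export
glance.us_eval_report <- function(x, ...) {
  m <- x$metrics
  tibble(
    mean_nrmse_normal = mean(m$nrmse[m$test_set == "normal_test"]),
    mean_nrmse_fast = mean(m$nrmse[m$test_set == "fast_test"]),
    mean_delay_ms = mean(m$delay_ms[m$delay_reliable %in% TRUE]),
    n_variables = length(unique(m$variable))
  )
}

#' Plot recorded vs predicted mean gait cycles
#'
#' @param object A `us_eval_report`.
#' @param ... Unused.
#' @return A ggplot: one panel per joint variable x test set, recorded and
#'   filtered-predicted mean cycles over 0-100% gait.
#' @export
autoplot.us_eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$cycles, c("recorded", "predicted"),
    names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$gait_pct, y = .data$value, colour = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(variable ~ test_set, scales = "free_y") +
    ggplot2::labs(
      x = "Gait cycle (%)", y = "Joint angle (deg) / velocity (deg/s)",
      colour = NULL,
      title = "Mean recorded vs predicted gait cycles"
    )
}
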