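# Voltage-waveform feature extraction.
#
# The 50 Hz potential-difference channel shows millivolt-scale spikes tied
# to mechanical events (preload, preconditioning cycles, unloading and
# re-stretching) that decay over roughly 90 s, and occasional abrupt drops
# during the relaxation hold despite the specimen not moving. Reported
# amplitudes are magnitudes relative to the baseline; the signed value is
# kept in a raw field.

#' Baseline voltage of a record
#'
#' Median over the first `window_s` seconds.
#'
#' @param voltage data frame `time_s`, `voltage_mV`.
#' @param window_s baseline window, s (default 2).
#' @return baseline, mV.
#' @export
voltage_baseline <- function(voltage, window_s = 2) {
  idx <- voltage$time_s <= voltage$time_s[1] + window_s
  if (!any(idx)) stop("empty baseline window")
  stats::median(voltage$voltage_mV[idx])
}

#' Maximum voltage excursion over a stage
#'
#' Largest absolute deviation from baseline within the interval; the
#' magnitude convention covers spikes of either polarity.
#'
#' @param voltage data frame `time_s`, `voltage_mV`.
#' @param interval list with `t_start`, `t_end`.
#' @param baseline baseline voltage, mV; default [voltage_baseline()].
#' @return magnitude, mV.
#' @export
stage_max_voltage <- function(voltage, interval,
                              baseline = voltage_baseline(voltage)) {
  idx <- voltage$time_s >= interval$t_start - 1e-9 &
    voltage$time_s <= interval$t_end + 1e-9
  if (!any(idx)) stop("interval contains no samples")
  max(abs(voltage$voltage_mV[idx] - baseline))
}

#' Detect voltage spikes
#'
#' Local maxima of `|V - baseline|` above `threshold_mv`, thinned greedily
#' (largest first) so reported peaks are at least `min_separation_s` apart,
#' each annotated with the protocol phase it falls in when intervals are
#' supplied.
#'
#' @param voltage data frame `time_s`, `voltage_mV`.
#' @param threshold_mv detection threshold, mV; default 5x the noise sd
#'   estimated from the baseline window.
#' @param min_separation_s minimum peak separation, s.
#' @param intervals optional phase interval table ([stage_intervals()]).
#' @param baseline baseline voltage, mV.
#' @return data frame `t_peak_s`, `amplitude_mV` (magnitude), `value_mV`
#'   (signed), `phase`.
#' @export
detect_spikes <- function(voltage, threshold_mv = NULL, min_separation_s = 5,
                          intervals = NULL,
                          baseline = voltage_baseline(voltage)) {
  v <- voltage$voltage_mV - baseline
  t <- voltage$time_s
  if (is.null(threshold_mv)) {
    idx0 <- t <= t[1] + 2
    threshold_mv <- 5 * max(stats::sd(v[idx0]), 1e-6)
  }
  mag <- abs(v)
  n <- length(mag)
  is_peak <- mag >= threshold_mv &
    mag >= c(-Inf, mag[-n]) & mag >= c(mag[-1], -Inf)
  cand <- which(is_peak)
  cand <- cand[order(mag[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(t[i] - t[kept]) >= min_separation_s)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  phase <- rep(NA_character_, length(kept))
  if (!is.null(intervals) && length(kept)) {
    for (j in seq_along(kept)) {
      hit <- which(intervals$t_start - 1e-9 <= t[kept[j]] &
                   t[kept[j]] < intervals$t_end + 1e-9)
      if (length(hit)) phase[j] <- as.character(intervals$phase[hit[1]])
    }
  }
  data.frame(t_peak_s = t[kept], amplitude_mV = mag[kept],
             value_mV = v[kept] + baseline, phase = phase,
             stringsAsFactors = FALSE)
}

#' Fit the exponential decay constant after a spike
#'
#' Log-linear least squares on `|V - baseline|` (floored at the noise sd)
#' over `window_s` after the peak. Returns `NA` when fewer than 20 samples
#' rise above the floor — a flat signal has no decay to fit.
#'
#' @param voltage data frame `time_s`, `voltage_mV`.
#' @param t_peak peak time, s.
#' @param window_s fit window after the peak, s (default 90, the scale over
#'   which observed spikes die away).
#' @param baseline baseline voltage, mV.
#' @param noise_floor_mv amplitude floor; default the baseline-window
#'   noise sd.
#' @return decay time constant tau in s, or `NA_real_`.
#' @export
fit_decay <- function(voltage, t_peak, window_s = 90,
                      baseline = voltage_baseline(voltage),
                      noise_floor_mv = NULL) {
  t <- voltage$time_s
  v <- abs(voltage$voltage_mV - baseline)
  if (is.null(noise_floor_mv)) {
    noise_floor_mv <- max(stats::sd(voltage$voltage_mV[t <= t[1] + 2]), 1e-9)
  }
  idx <- which(t >= t_peak & t <= t_peak + window_s & v > 3 * noise_floor_mv)
  if (length(idx) < 20L) return(NA_real_)
  fit <- stats::lm(log(v[idx]) ~ t[idx])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  -1 / slope
}

#' Detect step drops during a hold phase
#'
#' Difference of 1 s leading and trailing medians at each sample; reports
#' the locations where the level decreases by at least `magnitude_mv`,
#' clustered so each event is reported once at its steepest point.
#'
#' @param voltage data frame `time_s`, `voltage_mV`.
#' @param hold_interval list with `t_start`, `t_end`.
#' @param magnitude_mv minimum drop magnitude, mV.
#' @param window_s median window on each side, s.
#' @return data frame `t_s`, `magnitude_mV`.
#' @export
detect_hold_drops <- function(voltage, hold_interval, magnitude_mv,
                              window_s = 1) {
  idx <- voltage$time_s >= hold_interval$t_start &
    voltage$time_s <= hold_interval$t_end
  t <- voltage$time_s[idx]
  v <- voltage$voltage_mV[idx]
  n <- length(v)
  if (n < 4L) return(data.frame(t_s = numeric(0), magnitude_mV = numeric(0)))
  dt <- grid_step(t)
  k <- max(1L, round(window_s / dt))
  lead_med <- trail_med <- rep(NA_real_, n)
  med_run <- stats::runmed(v, 2L * (k %/% 2L) + 1L, endrule = "median")
  # leading median at i: median of v[i .. i+k-1]; trailing: v[i-k .. i-1]
  for (i in seq_len(n)) {
    lo <- i
    hi <- min(n, i + k - 1L)
    lead_med[i] <- med_run[min(n, lo + (hi - lo) %/% 2L)]
    lo2 <- max(1L, i - k)
    hi2 <- i - 1L
    trail_med[i] <- if (hi2 >= 1L) med_run[max(1L, lo2 + (hi2 - lo2) %/% 2L)] else NA_real_
  }
  step <- lead_med - trail_med
  hits <- which(!is.na(step) & step <= -magnitude_mv)
  if (length(hits) == 0L) {
    return(data.frame(t_s = numeric(0), magnitude_mV = numeric(0)))
  }
  gaps <- c(0, diff(hits))
  cluster <- cumsum(gaps > k)
  out <- do.call(rbind, lapply(split(hits, cluster), function(h) {
    best <- h[which.min(step[h])]
    data.frame(t_s = t[best], magnitude_mV = -step[best])
  }))
  rownames(out) <- NULL
  out
}

#' Extract all voltage features for one record
#'
#' @param record a `test_record` (or supply `voltage` and `intervals`
#'   directly).
#' @param spike_threshold_mv spike threshold; default 5x baseline noise sd.
#' @param drop_threshold_mv hold-drop threshold, mV.
#' @return object of class `voltage_features`: `baseline_mV`,
#'   `max_voltage_s1`, `max_voltage_s5` (mV, magnitudes), `spikes`,
#'   `decay_tau_s` (fit on the largest spike, `NA` if absent),
#'   `hold_drops`.
#' @export
voltage_features <- function(record, spike_threshold_mv = NULL,
                             drop_threshold_mv = 5) {
  volt <- record$voltage
  iv <- stage_intervals(record$protocol)
  base <- voltage_baseline(volt)
  ivrow <- function(ph) as.list(iv[iv$phase == ph, ])
  spikes <- detect_spikes(volt, threshold_mv = spike_threshold_mv,
                          intervals = iv, baseline = base)
  tau <- NA_real_
  if (nrow(spikes) > 0) {
    main <- spikes[which.max(spikes$amplitude_mV), ]
    tau <- fit_decay(volt, main$t_peak_s, baseline = base)
  }
  structure(
    list(
      baseline_mV = base,
      max_voltage_s1 = stage_max_voltage(volt, ivrow("s1"), base),
      max_voltage_s5 = stage_max_voltage(volt, ivrow("s5"), base),
      spikes = spikes,
      decay_tau_s = tau,
      hold_drops = detect_hold_drops(volt, ivrow("s2"), drop_threshold_mv)
    ),
    class = "voltage_features"
  )
}

#' @export
print.voltage_features <- function(x, ...) {
  cat(sprintf(
    "<voltage_features> baseline %.2f mV; max |V| s1 %.1f mV, s5 %.1f mV; %d spikes; decay tau %s s; %d hold drops\n",
    x$baseline_mV, x$max_voltage_s1, x$max_voltage_s5, nrow(x$spikes),
    ifelse(is.na(x$decay_tau_s), "NA", sprintf("%.1f", x$decay_tau_s)),
    nrow(x$hold_drops)
  ))
  invisible(x)
}
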