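# Elastic and viscoelastic metrics from one test record.
#
# Strain is grip-to-grip (displacement / 50 mm gauge); stress is force
# divided by the mean CSA from the slice profile. From the six-stage record
# we extract: Ef and Es, the slopes of lines fitted to the stage-1 and
# stage-5 loading curves; their normalized percent drop
# dE = (Ef - Es)/Ef * 100; peak stresses sigma_f (stage 1) and sigma_s
# (stage 5) and their drop dsigma = (sigma_f - sigma_s)/sigma_f * 100;
# hysteresis H as the normalized inner area between the stage-1 loading and
# stage-3 unloading curves by the trapezoid rule (loading area = 100%); and
# the percent stress-relaxation drop over the stage-2 hold.

#' Convert a test record to a stress-strain series
#'
#' @param record a `test_record` (simulated or assembled from measured CSVs).
#' @param mean_csa mean cross-sectional area, mm^2 (from [csa_profile()]).
#' @param gauge_length grip-to-grip gauge length, mm.
#' @return object of class `stress_strain`: data frame `time_s`, `strain`,
#'   `stress_MPa` (force clock, displacement linearly resampled onto it),
#'   with the protocol attached when available.
#' @export
to_stress_strain <- function(record, mean_csa, gauge_length = 50) {
  if (mean_csa <= 0) stop("mean_csa must be positive")
  if (gauge_length <= 0) stop("gauge_length must be positive")
  f <- record$force
  disp <- if (!is.null(f$displacement_mm)) {
    f$displacement_mm
  } else {
    resample_linear(record$displacement$time_s,
                    record$displacement$displacement_mm, f$time_s)
  }
  out <- data.frame(
    time_s = f$time_s,
    strain = disp / gauge_length,
    stress_MPa = f$force_N / mean_csa
  )
  structure(out, class = c("stress_strain", "data.frame"),
            protocol = record$protocol, gauge_length = gauge_length,
            mean_csa = mean_csa)
}

#' Locate the six protocol stages in a stress-strain series
#'
#' With a protocol waveform the stage labels are copied by time alignment.
#' Without one, stages are inferred from the strain derivative: samples are
#' classified as ramp-up / hold / ramp-down against a threshold of 10% of
#' the ramp rate, runs shorter than 0.5 s are merged, and the trailing
#' up-hold-down-hold-up-down pattern is reported.
#'
#' @param series a [to_stress_strain()] result.
#' @param protocol optional [build_protocol()] waveform.
#' @return data frame `phase` (`"s1"`..`"s6"`), `t_start`, `t_end`.
#' @export
segment_stages <- function(series, protocol = attr(series, "protocol")) {
  time <- series$time_s
  if (!is_uniform_grid(time)) stop("segment_stages requires a uniform time grid")
  if (!is.null(protocol)) {
    iv <- stage_intervals(protocol)
    iv <- iv[grepl("^s[1-6]$", iv$phase), c("phase", "t_start", "t_end")]
    rownames(iv) <- NULL
    return(iv)
  }
  dt <- grid_step(time)
  rate <- diff(series$strain) / dt
  ramp_rate <- stats::quantile(abs(rate), 0.98, names = FALSE)
  if (ramp_rate <= 0) stop("segmentation error: strain never moves")
  thr <- 0.10 * ramp_rate
  state <- ifelse(rate > thr, 1L, ifelse(rate < -thr, -1L, 0L))
  r <- rle(state)
  # merge runs shorter than 0.5 s into their predecessor
  min_len <- max(1L, round(0.5 / dt))
  keep_states <- integer(0)
  keep_lens <- integer(0)
  for (i in seq_along(r$lengths)) {
    if (length(keep_lens) > 0 &&
        (r$lengths[i] < min_len || r$values[i] == keep_states[length(keep_states)])) {
      keep_lens[length(keep_lens)] <- keep_lens[length(keep_lens)] + r$lengths[i]
    } else if (r$lengths[i] < min_len && length(keep_lens) == 0) {
      keep_states <- c(keep_states, r$values[i])
      keep_lens <- c(keep_lens, r$lengths[i])
    } else {
      keep_states <- c(keep_states, r$values[i])
      keep_lens <- c(keep_lens, r$lengths[i])
    }
  }
  # collapse adjacent equal states created by merging
  rr <- rle(rep(keep_states, keep_lens))
  states <- rr$values
  ends_idx <- cumsum(rr$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1) + 1L)
  pattern <- c(1L, 0L, -1L, 0L, 1L, -1L)
  found <- NULL
  if (length(states) >= 6L) {
    for (i in seq(length(states) - 5L, 1L)) {
      if (all(states[i:(i + 5L)] == pattern)) {
        found <- i
        break
      }
    }
  }
  if (is.null(found)) {
    stop("segmentation error: could not locate the six-stage pattern; runs found: ",
         paste(sprintf("%+d(%.1fs)", states, rr$lengths * dt), collapse = " "))
  }
  idx <- found:(found + 5L)
  data.frame(
    phase = c("s1", "s2", "s3", "s4", "s5", "s6"),
    t_start = time[starts_idx[idx]],
    t_end = time[pmin(ends_idx[idx] + 1L, length(time))],
    stringsAsFactors = FALSE
  )
}

slice_interval <- function(series, interval) {
  series[series$time_s >= interval$t_start - 1e-9 &
         series$time_s <= interval$t_end + 1e-9, , drop = FALSE]
}

#' Fit the elastic modulus on a loading interval
#'
#' Least-squares straight line `stress = a * strain + b` through the samples
#' of the loading interval restricted to the strain window; the slope `a`
#' is the elastic modulus.
#'
#' @param series a [to_stress_strain()] result.
#' @param interval one row of [segment_stages()] output (or any list with
#'   `t_start`, `t_end`).
#' @param window strain range used for the fit; default the full ramp.
#' @return object of class `modulus_fit`: `slope_a` (MPa), `intercept_b`
#'   (MPa), `r_squared`, `fit_window`, `n`.
#' @export
fit_modulus <- function(series, interval, window = c(0, Inf)) {
  seg <- slice_interval(series, interval)
  seg <- seg[seg$strain >= window[1] - 1e-12 & seg$strain <= window[2] + 1e-12, ]
  if (nrow(seg) < 10L) {
    stop("insufficient points for modulus fit (", nrow(seg), " < 10)")
  }
  fit <- stats::lm(stress_MPa ~ strain, data = seg)
  sst <- sum((seg$stress_MPa - mean(seg$stress_MPa))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(
    list(slope_a = unname(stats::coef(fit)[2]),
         intercept_b = unname(stats::coef(fit)[1]),
         r_squared = r2, fit_window = window, n = nrow(seg)),
    class = "modulus_fit"
  )
}

#' Normalized percent modulus drop between the two stretches
#'
#' `(Ef - Es) / Ef * 100`. Negative values (stiffening) are allowed.
#'
#' @param Ef stage-1 modulus, MPa; must be positive.
#' @param Es stage-5 modulus, MPa.
#' @return percent.
#' @export
delta_modulus <- function(Ef, Es) {
  if (Ef <= 0) stop("Ef must be positive")
  (Ef - Es) / Ef * 100
}

#' Peak stress over an interval
#'
#' @param series a [to_stress_strain()] result.
#' @param interval list with `t_start`, `t_end`.
#' @return maximum stress, MPa.
#' @export
peak_stress <- function(series, interval) {
  seg <- slice_interval(series, interval)
  if (nrow(seg) == 0L) stop("interval contains no samples")
  max(seg$stress_MPa)
}

#' Normalized percent stress drop between the two peaks
#'
#' `(sigma_f - sigma_s) / sigma_f * 100`.
#'
#' @param sigma_f stage-1 peak stress, MPa; must be positive.
#' @param sigma_s stage-5 peak stress, MPa.
#' @return percent.
#' @export
delta_stress <- function(sigma_f, sigma_s) {
  if (sigma_f <= 0) stop("sigma_f must be positive")
  (sigma_f - sigma_s) / sigma_f * 100
}

#' Hysteresis between a loading and an unloading curve
#'
#' Trapezoid-rule areas under stress(strain) for the loading interval and
#' the unloading interval (reversed to ascending strain first);
#' `H = (A_load - A_unload) / A_load * 100`, i.e. the loading area is the
#' 100% reference. In the six-stage protocol the loading curve is stage 1
#' and the unloading curve stage 3 — note the 600 s relaxation hold sits
#' between them, which inflates H relative to an uninterrupted cycle.
#'
#' @param series a [to_stress_strain()] result.
#' @param load_interval,unload_interval lists with `t_start`, `t_end`.
#' @return percent.
#' @export
hysteresis <- function(series, load_interval, unload_interval) {
  load <- slice_interval(series, load_interval)
  unload <- slice_interval(series, unload_interval)
  if (nrow(load) < 2L || nrow(unload) < 2L) stop("intervals too short")
  a_load <- pracma::trapz(load$strain, load$stress_MPa)
  if (a_load <= 0) stop("loading-curve area must be positive")
  o <- order(unload$strain)
  a_unload <- pracma::trapz(unload$strain[o], unload$stress_MPa[o])
  (a_load - a_unload) / a_load * 100
}

#' Percent stress drop over a relaxation hold
#'
#' `(sigma_start - sigma_end) / sigma_start * 100`, where the endpoints are
#' medians over the first and last 1 s of the hold to resist channel noise.
#'
#' @param series a [to_stress_strain()] result.
#' @param hold_interval list with `t_start`, `t_end`.
#' @param endpoint_window endpoint median window, s.
#' @return percent.
#' @export
relaxation_drop <- function(series, hold_interval, endpoint_window = 1) {
  seg <- slice_interval(series, hold_interval)
  if (nrow(seg) < 2L) stop("hold must contain at least 2 samples")
  t0 <- seg$time_s[1]
  t1 <- seg$time_s[nrow(seg)]
  w <- min(endpoint_window, (t1 - t0) / 2)
  s_start <- stats::median(seg$stress_MPa[seg$time_s <= t0 + w])
  s_end <- stats::median(seg$stress_MPa[seg$time_s >= t1 - w])
  if (s_start <= 0) stop("stress at hold start must be positive")
  (s_start - s_end) / s_start * 100
}

#' Compute all mechanics metrics for one record
#'
#' Ef and sigma_f come from stage 1, Es and sigma_s from stage 5, H from
#' stages 1/3, and the relaxation drop from stage 2.
#'
#' @param record a `test_record`.
#' @param mean_csa mean CSA, mm^2.
#' @param gauge_length gauge length, mm.
#' @param fit_window strain window for the modulus fits (default full ramp).
#' @return object of class `mechanics_metrics` with fields `Ef`, `Es`,
#'   `delta_E`, `sigma_f`, `sigma_s`, `delta_sigma`, `hysteresis_H`,
#'   `relaxation_drop` plus the two [fit_modulus()] objects.
#' @export
compute_metrics <- function(record, mean_csa, gauge_length = 50,
                            fit_window = c(0, Inf)) {
  series <- to_stress_strain(record, mean_csa, gauge_length)
  stages <- segment_stages(series)
  iv <- function(ph) as.list(stages[stages$phase == ph, ])
  fit_f <- fit_modulus(series, iv("s1"), window = fit_window)
  fit_s <- fit_modulus(series, iv("s5"), window = fit_window)
  sigma_f <- peak_stress(series, iv("s1"))
  sigma_s <- peak_stress(series, iv("s5"))
  structure(
    list(
      Ef = fit_f$slope_a, Es = fit_s$slope_a,
      delta_E = delta_modulus(fit_f$slope_a, fit_s$slope_a),
      sigma_f = sigma_f, sigma_s = sigma_s,
      delta_sigma = delta_stress(sigma_f, sigma_s),
      hysteresis_H = hysteresis(series, iv("s1"), iv("s3")),
      relaxation_drop = relaxation_drop(series, iv("s2")),
      fit_first = fit_f, fit_second = fit_s
    ),
    class = "mechanics_metrics"
  )
}

#' @export
print.mechanics_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<mechanics_metrics> Ef %.1f MPa, Es %.1f MPa (dE %.1f%%); ",
           "sigma_f %.2f MPa, sigma_s %.2f MPa (dsigma %.1f%%); ",
           "H %.1f%%, relaxation drop %.1f%%\n"),
    x$Ef, x$Es, x$delta_E, x$sigma_f, x$sigma_s, x$delta_sigma,
    x$hysteresis_H, x$relaxation_drop
  ))
  invisible(x)
}
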