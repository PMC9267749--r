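# Strain-controlled testing protocol.
#
# The test runs: preload to a target force, five +/-1 mm preconditioning
# cycles at 1 Hz, then six strain-controlled stages — stretch to 6% strain
# at 1 mm/s (s1), 10 min relaxation hold (s2), unload to 0% (s3), 2 s rest
# (s4), stretch to 6% again (s5) and immediate unload (s6). The waveform is
# sampled on a uniform command clock (100 Hz default). Strain is
# grip-to-grip: displacement / gauge length, with the strain datum (0%) at
# the grip-to-grip length reached after preload.

PROTOCOL_PHASES <- c("preload", "precondition", "s1", "s2", "s3", "s4", "s5", "s6")

#' Protocol configuration
#'
#' @param gauge_length grip-to-grip gauge length, mm.
#' @param preload_force preload target, N (force-controlled; see Details).
#' @param preload_dur placeholder duration of the preload phase, s.
#' @param precond_cycles number of preconditioning cycles.
#' @param precond_freq preconditioning frequency, Hz.
#' @param precond_amplitude preconditioning displacement amplitude about the
#'   strain datum, mm (i.e. +/- this value).
#' @param max_strain peak strain of stages 1 and 5, as a fraction.
#' @param ramp_speed loading/unloading crosshead speed, mm/s.
#' @param relax_hold stage-2 relaxation hold, s.
#' @param rest_hold stage-4 rest, s.
#' @param sample_rate command-clock rate, Hz.
#'
#' @details The preload cannot be expressed as a strain target: it is force
#'   controlled, so its waveform entry is a zero-displacement placeholder
#'   flagged `force_controlled`; the realised preload displacement comes from
#'   the simulator or the hardware log.
#' @return object of class `protocol_config`.
#' @export
protocol_config <- function(gauge_length = 50, preload_force = 1,
                            preload_dur = 2, precond_cycles = 5L,
                            precond_freq = 1, precond_amplitude = 1,
                            max_strain = 0.06, ramp_speed = 1,
                            relax_hold = 600, rest_hold = 2,
                            sample_rate = 100) {
  cfg <- list(
    gauge_length = gauge_length, preload_force = preload_force,
    preload_dur = preload_dur, precond_cycles = as.integer(precond_cycles),
    precond_freq = precond_freq, precond_amplitude = precond_amplitude,
    max_strain = max_strain, ramp_speed = ramp_speed,
    relax_hold = relax_hold, rest_hold = rest_hold, sample_rate = sample_rate
  )
  pos <- c("gauge_length", "preload_force", "preload_dur", "precond_freq",
           "precond_amplitude", "ramp_speed", "relax_hold", "rest_hold",
           "sample_rate")
  for (nm in pos) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) stop(nm, " must be positive")
  }
  if (cfg$precond_cycles < 0L) stop("precond_cycles must be >= 0")
  if (cfg$max_strain < 0) stop("max_strain must be >= 0")
  ramp_dur <- cfg$max_strain * cfg$gauge_length / cfg$ramp_speed
  if (!is.finite(ramp_dur)) stop("ramp duration is not finite")
  structure(cfg, class = "protocol_config")
}

#' Build the six-stage protocol waveform
#'
#' Phases in order: `preload` (placeholder, force-controlled),
#' `precondition` (sinusoidal displacement about the datum), then stages
#' `s1`..`s6`. Ramps are piecewise linear at exactly `ramp_speed`; holds are
#' constant. Phase durations are rounded up to the command clock so phase
#' boundaries land on grid samples.
#'
#' @param config a [protocol_config()].
#' @return object of class `protocol_waveform`: data frame columns `time_s`,
#'   `strain`, `displacement_mm`, `phase` plus attributes `config` and
#'   `intervals`.
#' @export
build_protocol <- function(config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  dt <- 1 / config$sample_rate
  snap <- function(x) ceiling(x / dt - 1e-9) * dt
  ramp_dur <- snap(config$max_strain * config$gauge_length / config$ramp_speed)
  precond_dur <- snap(config$precond_cycles / config$precond_freq)
  durs <- c(
    preload = snap(config$preload_dur),
    precondition = precond_dur,
    s1 = ramp_dur, s2 = snap(config$relax_hold), s3 = ramp_dur,
    s4 = snap(config$rest_hold), s5 = ramp_dur, s6 = ramp_dur
  )
  starts <- cumsum(c(0, durs[-length(durs)]))
  names(starts) <- names(durs)
  ends <- starts + durs
  total <- ends[length(ends)]
  n <- round(total / dt)
  time <- (0:n) * dt
  max_disp <- config$max_strain * config$gauge_length

  disp <- numeric(length(time))
  phase <- character(length(time))
  for (ph in PROTOCOL_PHASES) {
    idx <- which(time >= starts[ph] - 1e-9 &
                 (time < ends[ph] - 1e-9 | ph == "s6"))
    phase[idx] <- ph
    trel <- time[idx] - starts[ph]
    disp[idx] <- switch(ph,
      preload = 0,
      precondition = config$precond_amplitude *
        sin(2 * pi * config$precond_freq * trel),
      s1 = config$ramp_speed * trel,
      s2 = max_disp,
      s3 = max_disp - config$ramp_speed * trel,
      s4 = 0,
      s5 = config$ramp_speed * trel,
      s6 = max_disp - config$ramp_speed * trel
    )
  }
  # ramp targets are exact at stage ends even if rounding nudged durations
  disp <- pmin(pmax(disp, -config$precond_amplitude - max_disp), max_disp)
  wf <- data.frame(
    time_s = time,
    strain = disp / config$gauge_length,
    displacement_mm = disp,
    phase = factor(phase, levels = PROTOCOL_PHASES),
    stringsAsFactors = FALSE
  )
  intervals <- data.frame(
    phase = PROTOCOL_PHASES,
    t_start = as.numeric(starts),
    t_end = as.numeric(ends),
    force_controlled = PROTOCOL_PHASES == "preload",
    stringsAsFactors = FALSE
  )
  structure(wf, class = c("protocol_waveform", "data.frame"),
            config = config, intervals = intervals)
}

#' Labeled stage intervals of a protocol waveform
#'
#' @param waveform a [build_protocol()] result.
#' @return data frame with `phase`, `t_start`, `t_end`, `force_controlled`;
#'   the 8 rows are contiguous and cover the full time axis.
#' @export
stage_intervals <- function(waveform) {
  iv <- attr(waveform, "intervals")
  if (is.null(iv)) stop("waveform carries no interval table")
  iv
}

#' Emit a protocol waveform as g-code
#'
#' Dialect: `G21` (mm units), `G90` (absolute positioning), `G1 X<mm>
#' F<mm/min>` linear moves, `G4 S<s>` dwells. Ramps become single moves at
#' the equivalent feed rate; holds become dwells; the preconditioning
#' sinusoid is emitted sample by sample at the command clock; the
#' force-controlled preload is a commented dwell.
#'
#' @param waveform a [build_protocol()] result.
#' @param steps_per_mm motion resolution recorded in the header comment.
#' @return character vector of g-code lines.
#' @export
emit_gcode <- function(waveform, steps_per_mm = 200L) {
  time <- waveform$time_s
  if (is.unsorted(time, strictly = TRUE)) stop("waveform time must be strictly increasing")
  disp <- waveform$displacement_mm
  iv <- stage_intervals(waveform)
  out <- c(
    sprintf("; tendonmech protocol (%d steps/mm)", steps_per_mm),
    "G21 ; millimetre units",
    "G90 ; absolute positioning"
  )
  for (r in seq_len(nrow(iv))) {
    ph <- iv$phase[r]
    idx <- which(waveform$phase == ph)
    if (length(idx) == 0L) next
    # include the first sample of the next phase so each ramp ends exactly
    # on its target value
    if (idx[length(idx)] < length(time)) idx <- c(idx, idx[length(idx)] + 1L)
    t0 <- time[idx[1]]
    t1 <- time[idx[length(idx)]]
    d0 <- disp[idx[1]]
    d1 <- disp[idx[length(idx)]]
    dur <- t1 - t0
    out <- c(out, sprintf("; phase %s", ph))
    if (iv$force_controlled[r]) {
      out <- c(out, sprintf("G4 S%.3f ; preload placeholder (force-controlled)", dur))
    } else if (ph == "precondition") {
      tt <- time[idx]
      dd <- disp[idx]
      for (k in seq_along(idx)[-1]) {
        step <- abs(dd[k] - dd[k - 1])
        dtk <- tt[k] - tt[k - 1]
        if (step > 1e-9) {
          out <- c(out, sprintf("G1 X%.6f F%.6f", dd[k], step / dtk * 60))
        } else {
          out <- c(out, sprintf("G4 S%.6f", dtk))
        }
      }
    } else if (abs(d1 - d0) > 1e-9) {
      feed <- abs(d1 - d0) / dur * 60
      out <- c(out, sprintf("G1 X%.6f F%.6f", d1, feed))
    } else {
      out <- c(out, sprintf("G4 S%.3f", dur))
    }
  }
  out
}

#' Parse tendonmech g-code back into a displacement profile
#'
#' Round-trip companion of [emit_gcode()]; used to verify that the emitted
#' commands reproduce the commanded motion.
#'
#' @param lines character vector of g-code.
#' @return data frame `time_s`, `displacement_mm` of motion breakpoints.
#' @export
parse_gcode <- function(lines) {
  t <- 0
  x <- 0
  times <- 0
  pos <- 0
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^G1\\b", ln)) {
      xm <- regmatches(ln, regexec("X(-?[0-9.]+)", ln))[[1]]
      fm <- regmatches(ln, regexec("F(-?[0-9.]+)", ln))[[1]]
      if (length(xm) < 2 || length(fm) < 2) stop("malformed G1: ", ln)
      target <- as.numeric(xm[2])
      feed <- as.numeric(fm[2]) / 60  # mm/s
      dur <- abs(target - x) / feed
      t <- t + dur
      x <- target
      times <- c(times, t)
      pos <- c(pos, x)
    } else if (grepl("^G4\\b", ln)) {
      sm <- regmatches(ln, regexec("S(-?[0-9.]+)", ln))[[1]]
      if (length(sm) < 2) stop("malformed G4: ", ln)
      t <- t + as.numeric(sm[2])
      times <- c(times, t)
      pos <- c(pos, x)
    }
  }
  data.frame(time_s = times, displacement_mm = pos)
}

#' Write a protocol waveform as CSV
#'
#' @param waveform a [build_protocol()] result.
#' @param path output CSV path (columns `time_s`, `strain`,
#'   `displacement_mm`, `phase`).
#' @return `path`, invisibly.
#' @export
write_protocol_csv <- function(waveform, path) {
  df <- as.data.frame(waveform)
  df$phase <- as.character(df$phase)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
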