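# Plumbing: channel CSV readers/writers with a fixed dialect, run
# configuration, and the end-to-end pipeline (simulate or load -> CSA ->
# stress-strain metrics + voltage features -> group statistics -> report).
#
# CSV dialect everywhere: comma separator, dot decimal, one header row,
# UTF-8, time column `time_s`.

#' Read a sampled-channel CSV
#'
#' @param path CSV with a `time_s` column plus numeric value column(s).
#' @param expected_rate_hz declared sampling rate; a measured rate deviating
#'   by more than 1% raises a warning, a non-uniform grid is an error.
#' @return data frame as stored.
#' @export
read_channel_csv <- function(path, expected_rate_hz = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) stop("channel CSV must have a time_s column: ", path)
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))))[1]
      stop(sprintf("non-numeric value in column '%s' of '%s' at data line %d",
                   nm, path, bad))
    }
  }
  if (nrow(df) >= 3L && !is_uniform_grid(df$time_s, rel_tol = 1e-3)) {
    stop("non-uniform time grid in '", path, "'")
  }
  if (!is.null(expected_rate_hz) && nrow(df) >= 2L) {
    rate <- 1 / grid_step(df$time_s)
    if (abs(rate - expected_rate_hz) > 0.01 * expected_rate_hz) {
      warning(sprintf("'%s': measured rate %.3f Hz differs from expected %g Hz",
                      path, rate, expected_rate_hz))
    }
  }
  df
}

#' Write a sampled-channel CSV
#'
#' Numeric fields are written with 12 significant digits so repeated runs of
#' the same configuration are byte-identical.
#'
#' @param df data frame with a `time_s` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param protocol a [protocol_config()].
#' @param groups list of [group_spec()]s to simulate (ignored when records
#'   are supplied to [run_pipeline()] directly).
#' @param seed master seed.
#' @param fit_window strain window for modulus fits.
#' @param spike_threshold_mv spike threshold (NULL = 5x noise sd).
#' @param drop_threshold_mv hold-drop threshold, mV.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(protocol = protocol_config(),
                       groups = list(group_spec("G3"), group_spec("G5"),
                                     group_spec("G7")),
                       seed = 42L, fit_window = c(0, Inf),
                       spike_threshold_mv = NULL, drop_threshold_mv = 5,
                       out_dir = tempfile("tendonmech_run_")) {
  structure(
    list(protocol = protocol, groups = groups, seed = as.integer(seed),
         fit_window = fit_window, spike_threshold_mv = spike_threshold_mv,
         drop_threshold_mv = drop_threshold_mv, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full validation pipeline
#'
#' For each specimen: CSA profile from its mesh (or true CSA when no mesh is
#' attached), stress-strain conversion, mechanics metrics and voltage
#' features; then group summaries, ANOVA and pairwise tests over every
#' metric. A failure in one specimen is logged and skipped; the run
#' continues.
#'
#' @param config a [run_config()].
#' @param records optional list of `test_record`s; when `NULL` the
#'   configured groups are simulated (with meshes).
#' @param write write the report files (per-specimen CSV, stats JSON, log)
#'   into `config$out_dir`?
#' @return list with `metrics` (wide per-specimen data frame), `stats`
#'   (from [group_stats_report()]), `errors` (named character vector) and,
#'   when written, `paths`.
#' @export
run_pipeline <- function(config = run_config(), records = NULL,
                         write = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  if (is.null(records)) {
    protocol <- build_protocol(config$protocol)
    seeds <- split_seed(config$seed, length(config$groups))
    records <- list()
    for (gi in seq_along(config$groups)) {
      gs <- config$groups[[gi]]
      note("simulating group %s (n = %d, seed %d)", gs$group_id, gs$n, seeds[gi])
      records <- c(records, simulate_group(gs, seeds[gi], protocol = protocol,
                                           mesh = TRUE))
    }
  }
  rows <- list()
  errors <- character(0)
  for (rec in records) {
    sid <- rec$provenance$specimen_id %||% sprintf("spec-%02d", length(rows) + 1L)
    gid <- rec$provenance$group_id %||% "NA"
    row <- tryCatch({
      mean_csa <- if (!is.null(rec$mesh)) {
        csa_profile(rec$mesh)$mean
      } else if (!is.null(rec$provenance$params)) {
        rec$provenance$params$csa_true
      } else {
        stop("record has neither mesh nor true CSA")
      }
      gauge <- attr(rec$protocol, "config")$gauge_length
      mm <- compute_metrics(rec, mean_csa, gauge_length = gauge,
                            fit_window = config$fit_window)
      vf <- voltage_features(rec,
                             spike_threshold_mv = config$spike_threshold_mv,
                             drop_threshold_mv = config$drop_threshold_mv)
      data.frame(
        specimen_id = sid, group_id = gid, csa_mm2 = mean_csa,
        Ef_MPa = mm$Ef, Es_MPa = mm$Es, dE_pct = mm$delta_E,
        sigma_f_MPa = mm$sigma_f, sigma_s_MPa = mm$sigma_s,
        dSigma_pct = mm$delta_sigma, H_pct = mm$hysteresis_H,
        drop_pct = mm$relaxation_drop,
        max_V_s1_mV = vf$max_voltage_s1, max_V_s5_mV = vf$max_voltage_s5,
        n_spikes = nrow(vf$spikes), decay_tau_s = vf$decay_tau_s,
        n_hold_drops = nrow(vf$hold_drops),
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      errors[[sid]] <<- conditionMessage(e)
      note("specimen %s failed: %s", sid, conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  metrics <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame()
  }
  stats_rep <- if (nrow(metrics) > 0 &&
                   length(unique(metrics$group_id)) >= 2L) {
    stat_cols <- c("specimen_id", "group_id", "csa_mm2", "Ef_MPa", "Es_MPa",
                   "dE_pct", "sigma_f_MPa", "sigma_s_MPa", "dSigma_pct",
                   "H_pct", "drop_pct", "max_V_s1_mV", "max_V_s5_mV")
    group_stats_report(metrics[, stat_cols])
  } else {
    NULL
  }
  result <- list(metrics = metrics, stats = stats_rep, errors = errors)
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      metrics = file.path(config$out_dir, "metrics.csv"),
      stats = file.path(config$out_dir, "stats.json"),
      log = file.path(config$out_dir, "run.log")
    )
    mfmt <- metrics
    for (nm in names(mfmt)) {
      if (is.numeric(mfmt[[nm]])) mfmt[[nm]] <- fmt_num(mfmt[[nm]])
    }
    utils::write.csv(mfmt, paths["metrics"], row.names = FALSE, quote = FALSE)
    jsonlite::write_json(stats_rep, paths["stats"], auto_unbox = TRUE,
                         digits = NA, force = TRUE, dataframe = "rows")
    cfg_digest <- sum(utf8ToInt(paste(utils::capture.output(utils::str(config)),
                                      collapse = "")))
    writeLines(c(sprintf("tendonmech run; config checksum %d; seed %d",
                         cfg_digest, config$seed), log_lines), paths["log"])
    result$paths <- paths
  }
  result
}
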