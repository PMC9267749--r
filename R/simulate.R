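# Seeded synthetic specimen records.
#
# The simulator emulates one tensile test end to end: a surface-scan mesh
# with known mean CSA, a 20 Hz force/displacement log and a 50 Hz voltage
# log, all driven by the protocol waveform. Mechanics follow quasi-linear
# viscoelasticity (QLV): an instantaneous toe-then-linear elastic response
# passed through a hereditary convolution with a Prony-series reduced
# relaxation function G(t) = g_inf + sum_i g_i exp(-t / tau_i). The voltage
# channel is a strain-rate-driven spike generator with first-order decay,
# plus optional step drops during holds. Every specimen carries its
# ground-truth parameters so downstream estimators can be checked against
# truth.

#' Ground-truth parameters of one synthetic specimen
#'
#' @param modulus_E linear-region elastic modulus, MPa.
#' @param toe_strain strain extent of the quadratic toe region (fraction).
#' @param prony_g Prony weights `g_i` (unitless); `g_inf = 1 - sum(g_i)`
#'   must lie in (0, 1].
#' @param prony_tau Prony time constants `tau_i`, s (same length as
#'   `prony_g`).
#' @param csa_true true mean cross-sectional area, mm^2.
#' @param piezo_gain voltage gain k, mV per unit strain rate (1/s).
#' @param piezo_decay voltage decay time constant tau_v, s.
#' @param drop_rate rate of spontaneous voltage step drops during hold
#'   phases, events/s.
#' @param drop_mag_mv typical magnitude of a hold drop, mV.
#' @param noise_sd_force force channel noise sd, N.
#' @param noise_sd_voltage voltage channel noise sd, mV.
#' @param seed integer seed for this specimen's noise and drop events.
#' @return object of class `specimen_params`.
#' @export
specimen_params <- function(modulus_E = 100, toe_strain = 0.015,
                            prony_g = c(0.30, 0.25),
                            prony_tau = c(10, 120),
                            csa_true = 15, piezo_gain = 6000,
                            piezo_decay = 30, drop_rate = 0,
                            drop_mag_mv = 10,
                            noise_sd_force = 0.05,
                            noise_sd_voltage = 1, seed = 1L) {
  if (modulus_E <= 0) stop("modulus_E must be positive")
  if (toe_strain < 0) stop("toe_strain must be >= 0")
  if (length(prony_g) != length(prony_tau)) {
    stop("prony_g and prony_tau must have equal length")
  }
  g_inf <- 1 - sum(prony_g)
  if (g_inf <= 0 || g_inf > 1) stop("g_inf = 1 - sum(g_i) must lie in (0, 1]")
  if (length(prony_tau) && any(prony_tau <= 0)) stop("prony_tau must be positive")
  if (piezo_decay <= 0) stop("piezo_decay must be positive")
  if (csa_true <= 0) stop("csa_true must be positive")
  structure(
    list(modulus_E = modulus_E, toe_strain = toe_strain,
         prony_g = prony_g, prony_tau = prony_tau, g_inf = g_inf,
         csa_true = csa_true, piezo_gain = piezo_gain,
         piezo_decay = piezo_decay, drop_rate = drop_rate,
         drop_mag_mv = drop_mag_mv, noise_sd_force = noise_sd_force,
         noise_sd_voltage = noise_sd_voltage, seed = as.integer(seed)),
    class = "specimen_params"
  )
}

#' Instantaneous elastic stress
#'
#' Toe-then-linear response, the standard shape for tendon: a quadratic toe
#' for `strain < toe_strain` joining a linear region of slope `modulus_E`
#' with continuous value and slope. Negative strains (slack specimen) carry
#' zero stress.
#'
#' @param strain strain value(s), fraction.
#' @param params a [specimen_params()].
#' @return stress in MPa.
#' @export
elastic_stress <- function(strain, params) {
  E <- params$modulus_E
  et <- params$toe_strain
  s <- numeric(length(strain))
  pos <- strain > 0
  if (et <= 0) {
    s[pos] <- E * strain[pos]
  } else {
    toe <- pos & strain < et
    lin <- strain >= et
    s[toe] <- E * strain[toe]^2 / (2 * et)
    s[lin] <- E * (strain[lin] - et / 2)
  }
  s
}

#' Quasi-linear viscoelastic stress response
#'
#' Discrete hereditary convolution of the instantaneous elastic stress
#' increments with the reduced relaxation function
#' `G(t) = g_inf + sum_i g_i exp(-t/tau_i)`:
#' `sigma(t_n) = sum_{j<=n} G(t_n - t_j) * delta_sigma_e(t_j)`,
#' evaluated with one exact exponential recursion per Prony term. With all
#' `g_i = 0` the output equals [elastic_stress()] pointwise.
#'
#' @param strain strain series on a uniform time grid.
#' @param params a [specimen_params()].
#' @param dt grid step, s.
#' @param time optional explicit time vector (checked for uniformity).
#' @return stress series, MPa.
#' @export
qlv_stress <- function(strain, params, dt = NULL, time = NULL) {
  if (!is.null(time)) {
    if (!is_uniform_grid(time)) stop("qlv_stress requires a uniform time grid")
    dt <- grid_step(time)
  }
  if (is.null(dt) || dt <= 0) stop("dt must be positive (or supply time)")
  se <- elastic_stress(strain, params)
  dse <- diff(c(0, se))
  sigma <- params$g_inf * cumsum(dse)
  for (i in seq_along(params$prony_g)) {
    a <- exp(-dt / params$prony_tau[i])
    sigma <- sigma + params$prony_g[i] *
      as.numeric(stats::filter(dse, a, method = "recursive"))
  }
  sigma
}

#' Piezoelectric voltage channel
#'
#' Drives a first-order decay element (time constant `piezo_decay`) with the
#' absolute strain rate scaled by `piezo_gain`, resamples to 50 Hz, and adds
#' Gaussian noise plus Poisson-placed persistent step drops during hold
#' phases. Deterministic given the seed.
#'
#' @param strain strain series on a uniform grid covering the protocol.
#' @param time time vector of the strain series, s.
#' @param params a [specimen_params()].
#' @param hold_intervals optional data frame with `t_start`/`t_end` rows of
#'   hold phases eligible for drop events.
#' @param seed seed; defaults to `params$seed`.
#' @param rate_hz output sampling rate (50 Hz per the acquisition device).
#' @return data frame `time_s`, `voltage_mV`; the injected drop events are
#'   attached as attribute `drop_events` (`t_s`, `magnitude_mV`).
#' @export
piezo_voltage <- function(strain, time, params, hold_intervals = NULL,
                          seed = params$seed, rate_hz = 50) {
  if (!is_uniform_grid(time)) stop("piezo_voltage requires a uniform time grid")
  dt <- grid_step(time)
  drive <- params$piezo_gain * c(0, abs(diff(strain)) / dt)
  v <- exp_smooth(drive, dt, params$piezo_decay)
  t_out <- seq(0, time[length(time)] + 1e-12, by = 1 / rate_hz)
  v_out <- resample_linear(time, v, t_out)
  events <- data.frame(t_s = numeric(0), magnitude_mV = numeric(0))
  out <- with_seed(seed, {
    v_out <- v_out + stats::rnorm(length(v_out), 0, params$noise_sd_voltage)
    if (!is.null(hold_intervals) && params$drop_rate > 0) {
      for (r in seq_len(nrow(hold_intervals))) {
        t0 <- hold_intervals$t_start[r]
        t1 <- hold_intervals$t_end[r]
        n_ev <- stats::rpois(1, params$drop_rate * (t1 - t0))
        if (n_ev > 0) {
          t_ev <- sort(stats::runif(n_ev, t0, t1))
          mag <- params$drop_mag_mv * stats::runif(n_ev, 0.5, 1.5)
          for (j in seq_len(n_ev)) {
            v_out[t_out >= t_ev[j]] <- v_out[t_out >= t_ev[j]] - mag[j]
          }
          events <- rbind(events,
                          data.frame(t_s = t_ev, magnitude_mV = mag))
        }
      }
    }
    data.frame(time_s = t_out, voltage_mV = v_out)
  })
  attr(out, "drop_events") <- events
  out
}

#' Synthetic specimen mesh with known mean cross-sectional area
#'
#' Extrudes a radially perturbed ellipse along z. Each ring polygon is
#' rescaled so its shoelace area matches the target axial area profile,
#' whose mean over the central slicing window equals `csa_true`; end caps
#' close the surface, so the mesh is watertight.
#'
#' @param csa_true target mean cross-sectional area, mm^2.
#' @param length_mm specimen length, mm (dissected samples are >= 70 mm).
#' @param irregularity relative amplitude of the radial/axial perturbation
#'   (0 gives a perfect elliptic cylinder).
#' @param seed integer seed for the perturbation.
#' @param n_theta circumferential resolution.
#' @param ring_spacing axial ring spacing, mm.
#' @param aspect ellipse major/minor aspect ratio.
#' @param window_mm central window over which the mean area is normalised
#'   (the default matches the 300 x 0.1 mm slicing window).
#' @return a [triangle_mesh()].
#' @export
make_mesh <- function(csa_true, length_mm = 70, irregularity = 0.05,
                      seed = 1L, n_theta = 64L, ring_spacing = 1,
                      aspect = 1.3, window_mm = 30) {
  if (csa_true <= 0) stop("csa_true must be positive")
  n_z <- max(8L, ceiling(length_mm / ring_spacing)) + 1L
  z <- seq(0, length_mm, length.out = n_z)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  a <- sqrt(csa_true / pi * aspect)
  b <- csa_true / (pi * a)
  with_seed(seed, {
    # smooth low-order perturbations in theta and z
    c_th <- stats::rnorm(3, 0, 1)
    s_th <- stats::rnorm(3, 0, 1)
    c_z <- stats::rnorm(2, 0, 1)
    ph_z <- stats::runif(2, 0, 2 * pi)
    NULL
  })
  radial_mod <- 1 + irregularity * (
    c_th[1] * cos(theta) + s_th[1] * sin(theta) +
      0.5 * (c_th[2] * cos(2 * theta) + s_th[2] * sin(2 * theta)) +
      0.25 * (c_th[3] * cos(3 * theta) + s_th[3] * sin(3 * theta))
  ) / 2
  axial_mod <- 1 + irregularity * (
    c_z[1] * sin(2 * pi * z / length_mm + ph_z[1]) +
      0.5 * c_z[2] * sin(4 * pi * z / length_mm + ph_z[2])
  ) / 2
  # normalise the axial profile so the mean target area over the central
  # window equals csa_true
  zc <- mean(range(z))
  in_win <- abs(z - zc) <= window_mm / 2
  axial_mod <- axial_mod / mean(axial_mod[if (any(in_win)) in_win else TRUE])
  target_area <- csa_true * axial_mod

  rings <- vector("list", n_z)
  for (iz in seq_len(n_z)) {
    x <- a * cos(theta) * radial_mod
    y <- b * sin(theta) * radial_mod
    area0 <- shoelace_area(cbind(x, y))
    s <- sqrt(target_area[iz] / area0)
    rings[[iz]] <- cbind(x * s, y * s, z[iz])
  }
  verts <- do.call(rbind, rings)
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, length_mm))
  bot <- nrow(verts) - 1L
  top <- nrow(verts)
  faces <- list()
  for (iz in seq_len(n_z - 1L)) {
    o1 <- (iz - 1L) * n_theta
    o2 <- iz * n_theta
    j <- seq_len(n_theta)
    jn <- c(seq_len(n_theta)[-1], 1L)
    faces[[length(faces) + 1L]] <- cbind(o1 + j, o1 + jn, o2 + j)
    faces[[length(faces) + 1L]] <- cbind(o1 + jn, o2 + jn, o2 + j)
  }
  j <- seq_len(n_theta)
  jn <- c(seq_len(n_theta)[-1], 1L)
  faces[[length(faces) + 1L]] <- cbind(j, bot, jn)                 # bottom cap
  o <- (n_z - 1L) * n_theta
  faces[[length(faces) + 1L]] <- cbind(o + j, o + jn, top)         # top cap
  triangle_mesh(verts, do.call(rbind, faces), source_format = "generated")
}

#' Simulate one complete specimen test record
#'
#' Realises the protocol on the specimen: the force-controlled preload phase
#' becomes a short crosshead ramp ending at the strain datum where the
#' recorded force equals the preload target; from there the strain-control
#' waveform is followed exactly. Stress is the QLV response; force =
#' stress x true CSA + preload offset, floored at zero (slack specimen
#' carries no load) and sampled at 20 Hz with Gaussian noise. Voltage comes
#' from [piezo_voltage()] at 50 Hz.
#'
#' @param protocol a [build_protocol()] waveform.
#' @param params a [specimen_params()].
#' @param mesh logical: also generate the specimen mesh via [make_mesh()]?
#' @return object of class `test_record`: list with `force` (data frame
#'   `time_s`, `force_N`, `displacement_mm` at 20 Hz), `voltage` (50 Hz),
#'   `protocol`, optional `mesh`, and `provenance` (list with `type =
#'   "simulated"` and the ground-truth `params`).
#' @export
simulate_specimen <- function(protocol, params, mesh = FALSE) {
  stopifnot(inherits(protocol, "protocol_waveform"))
  stopifnot(inherits(params, "specimen_params"))
  cfg <- attr(protocol, "config")
  time <- protocol$time_s
  dt <- grid_step(time)
  iv <- stage_intervals(protocol)

  # realised displacement: preload phase ramps from slack (-1 mm) up to the
  # datum; everything else follows the strain-control targets
  disp <- protocol$displacement_mm
  pre <- which(protocol$phase == "preload")
  if (length(pre) > 1L) {
    t0 <- time[pre[1]]
    t1 <- iv$t_end[iv$phase == "preload"]
    disp[pre] <- -1 + (time[pre] - t0) / (t1 - t0)
  }
  strain <- disp / cfg$gauge_length
  sigma <- qlv_stress(strain, params, dt = dt)
  end_preload <- max(pre %||% 1L)
  offset <- cfg$preload_force - sigma[end_preload] * params$csa_true
  force <- pmax(sigma * params$csa_true + offset, 0)

  t20 <- seq(0, time[length(time)] + 1e-12, by = 0.05)
  seeds <- split_seed(params$seed, 2L)
  force20 <- resample_linear(time, force, t20)
  force20 <- with_seed(seeds[1],
    force20 + stats::rnorm(length(t20), 0, params$noise_sd_force))
  disp20 <- resample_linear(time, disp, t20)

  holds <- iv[iv$phase %in% c("s2", "s4"), c("t_start", "t_end")]
  volt <- piezo_voltage(strain, time, params, hold_intervals = holds,
                        seed = seeds[2])

  structure(
    list(
      force = data.frame(time_s = t20, force_N = force20,
                         displacement_mm = disp20),
      voltage = volt,
      protocol = protocol,
      mesh = if (mesh) make_mesh(params$csa_true, seed = params$seed) else NULL,
      provenance = list(type = "simulated", params = params,
                        stress_true = sigma, strain_true = strain,
                        force_offset = offset,
                        drop_events = attr(volt, "drop_events"))
    ),
    class = "test_record"
  )
}

#' @export
print.test_record <- function(x, ...) {
  cat(sprintf(
    "<test_record> %s; force %d samples @20 Hz, voltage %d samples @50 Hz\n",
    x$provenance$type, nrow(x$force), nrow(x$voltage)
  ))
  invisible(x)
}

#' Group-level simulation settings
#'
#' Default parameter distributions for the three validation groups:
#' G3 porcine common digital extensor (positional tendon, stiffer, smallest
#' CSA), G5 bovine superficial digital flexor, G7 deer superficial digital
#' flexor (largest, most variable CSA). CSA distributions follow the
#' group-level means and spreads observed on real fascicle bundles
#' (about 11, 17 and 23 mm^2); voltage gains are drawn identically across
#' groups. Parameter draws are normal, truncated at two standard
#' deviations.
#'
#' @param group_id one of `"G3"`, `"G5"`, `"G7"`.
#' @param n specimens per group (default 9).
#' @param overrides named list overriding distribution entries; each entry
#'   is `c(mean, sd)`.
#' @return object of class `group_spec`.
#' @export
group_spec <- function(group_id = c("G3", "G5", "G7"), n = 9L,
                       overrides = list()) {
  group_id <- match.arg(group_id)
  if (n < 2L) stop("n must be >= 2")
  base <- switch(group_id,
    G3 = list(modulus_E = c(160, 25), csa_true = c(11.1, 2.0)),
    G5 = list(modulus_E = c(110, 18), csa_true = c(16.8, 4.0)),
    G7 = list(modulus_E = c(100, 22), csa_true = c(22.8, 6.0))
  )
  dist <- utils::modifyList(list(
    modulus_E = base$modulus_E,
    toe_strain = c(0.015, 0.004),
    g1 = c(0.30, 0.04),
    g2 = c(0.25, 0.04),
    tau1 = c(10, 2),
    tau2 = c(120, 20),
    csa_true = base$csa_true,
    piezo_gain = c(6000, 1200),
    piezo_decay = c(30, 4),
    drop_rate = c(0.005, 0.002),
    noise_sd_force = c(0.05, 0),
    noise_sd_voltage = c(1, 0)
  ), overrides)
  structure(list(group_id = group_id, n = as.integer(n), dist = dist),
            class = "group_spec")
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  lo <- max(lower, mean - 2 * sd)
  hi <- min(upper, mean + 2 * sd)
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate a full specimen group
#'
#' Draws `spec$n` parameter sets from the group distributions (normal,
#' truncated at +/- 2 sd and at physical bounds) and simulates each
#' specimen. All randomness flows from `seed` through one deterministic
#' splitting rule.
#'
#' @param spec a [group_spec()].
#' @param seed master seed for the group.
#' @param protocol protocol waveform; default [build_protocol()] with
#'   default [protocol_config()].
#' @param mesh generate meshes too?
#' @return list of [simulate_specimen()] records, with specimen ids
#'   `"<group>-01"` etc. in `provenance$specimen_id`.
#' @export
simulate_group <- function(spec, seed, protocol = NULL, mesh = FALSE) {
  stopifnot(inherits(spec, "group_spec"))
  if (spec$n < 2L) stop("group must have n >= 2 specimens")
  if (is.null(protocol)) protocol <- build_protocol(protocol_config())
  d <- spec$dist
  draws <- with_seed(seed, {
    list(
      modulus_E = rnorm_trunc(spec$n, d$modulus_E[1], d$modulus_E[2], lower = 10),
      toe_strain = rnorm_trunc(spec$n, d$toe_strain[1], d$toe_strain[2],
                               lower = 0, upper = 0.04),
      g1 = rnorm_trunc(spec$n, d$g1[1], d$g1[2], lower = 0.05, upper = 0.45),
      g2 = rnorm_trunc(spec$n, d$g2[1], d$g2[2], lower = 0.05, upper = 0.45),
      tau1 = rnorm_trunc(spec$n, d$tau1[1], d$tau1[2], lower = 1),
      tau2 = rnorm_trunc(spec$n, d$tau2[1], d$tau2[2], lower = 20),
      csa_true = rnorm_trunc(spec$n, d$csa_true[1], d$csa_true[2], lower = 3),
      piezo_gain = rnorm_trunc(spec$n, d$piezo_gain[1], d$piezo_gain[2], lower = 500),
      piezo_decay = rnorm_trunc(spec$n, d$piezo_decay[1], d$piezo_decay[2], lower = 5),
      drop_rate = rnorm_trunc(spec$n, d$drop_rate[1], d$drop_rate[2], lower = 0)
    )
  })
  seeds <- split_seed(seed, spec$n)
  records <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    p <- specimen_params(
      modulus_E = draws$modulus_E[i], toe_strain = draws$toe_strain[i],
      prony_g = c(draws$g1[i], draws$g2[i]),
      prony_tau = c(draws$tau1[i], draws$tau2[i]),
      csa_true = draws$csa_true[i], piezo_gain = draws$piezo_gain[i],
      piezo_decay = draws$piezo_decay[i], drop_rate = draws$drop_rate[i],
      noise_sd_force = d$noise_sd_force[1],
      noise_sd_voltage = d$noise_sd_voltage[1],
      seed = seeds[i]
    )
    rec <- simulate_specimen(protocol, p, mesh = mesh)
    rec$provenance$specimen_id <- sprintf("%s-%02d", spec$group_id, i)
    rec$provenance$group_id <- spec$group_id
    records[[i]] <- rec
  }
  records
}

#' Write a simulated record to disk
#'
#' Emits the per-specimen artifact set: binary STL (if a mesh is attached),
#' force CSV (`time_s`, `force_N`, `displacement_mm`), voltage CSV
#' (`time_s`, `voltage_mV`) and a ground-truth JSON.
#'
#' @param record a [simulate_specimen()] result.
#' @param prefix output path prefix.
#' @return named character vector of written paths, invisibly.
#' @export
write_record <- function(record, prefix) {
  stopifnot(inherits(record, "test_record"))
  paths <- c(force = paste0(prefix, "_force.csv"),
             voltage = paste0(prefix, "_voltage.csv"),
             truth = paste0(prefix, "_truth.json"))
  write_channel_csv(record$force, paths["force"])
  write_channel_csv(record$voltage, paths["voltage"])
  p <- record$provenance$params
  jsonlite::write_json(
    list(type = record$provenance$type,
         specimen_id = record$provenance$specimen_id %||% NA,
         group_id = record$provenance$group_id %||% NA,
         params = p[setdiff(names(p), character(0))]),
    paths["truth"], auto_unbox = TRUE, digits = NA, force = TRUE
  )
  if (!is.null(record$mesh)) {
    paths["stl"] <- paste0(prefix, ".stl")
    write_stl_binary(record$mesh, paths["stl"])
  }
  invisible(paths)
}
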