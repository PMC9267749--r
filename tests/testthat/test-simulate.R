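test_that("elastic stress is toe-then-linear and C1 at the junction", {
  p0 <- specimen_params(toe_strain = 0, modulus_E = 100)
  expect_equal(elastic_stress(0, p0), 0)
  expect_equal(elastic_stress(0.06, p0), 6)
  expect_equal(elastic_stress(-0.02, p0), 0)

  p <- specimen_params(toe_strain = 0.02, modulus_E = 100)
  # closed form above the toe: E * (eps - toe/2)
  expect_equal(elastic_stress(0.06, p), 100 * (0.06 - 0.01))
  # slope at 0.06 equals E (finite-difference oracle)
  h <- 1e-6
  slope <- (elastic_stress(0.06 + h, p) - elastic_stress(0.06 - h, p)) / (2 * h)
  expect_equal(slope, 100, tolerance = 1e-6)
  # continuity of value and slope at the junction
  expect_equal(elastic_stress(0.02 - 1e-9, p), elastic_stress(0.02 + 1e-9, p),
               tolerance = 1e-6)
  sl_lo <- (elastic_stress(0.02, p) - elastic_stress(0.02 - h, p)) / h
  expect_equal(sl_lo, 100, tolerance = 1e-3)
})

test_that("QLV reduces to the elastic response when all g_i are zero", {
  p <- specimen_params(prony_g = numeric(0), prony_tau = numeric(0),
                       toe_strain = 0.01)
  tt <- seq(0, 10, by = 0.01)
  eps <- 0.06 * pmin(tt / 3, 1)
  expect_equal(qlv_stress(eps, p, dt = 0.01), elastic_stress(eps, p),
               tolerance = 1e-12)
})

test_that("QLV matches the closed form under step strain and is monotone in tau", {
  p <- specimen_params(modulus_E = 100, toe_strain = 0,
                       prony_g = 0.4, prony_tau = 300)
  tt <- seq(0, 600, by = 0.05)
  s <- qlv_stress(rep(0.06, length(tt)), p, dt = 0.05)
  cf <- 6 * (0.6 + 0.4 * exp(-tt / 300))
  expect_lt(max(abs(s - cf) / cf), 1e-3)

  drop_for_tau <- function(tau) {
    pp <- specimen_params(modulus_E = 100, toe_strain = 0,
                          prony_g = 0.3, prony_tau = tau)
    ss <- qlv_stress(rep(0.06, length(tt)), pp, dt = 0.05)
    (ss[1] - ss[length(ss)]) / ss[1]
  }
  drops <- vapply(c(50, 100, 200, 400), drop_for_tau, 1)
  expect_true(all(diff(drops) < 0))
})

test_that("QLV rejects a non-uniform time grid", {
  p <- specimen_params()
  expect_error(qlv_stress(c(0, 0.01, 0.02), p, time = c(0, 1, 3)), "uniform")
})

test_that("piezo voltage is zero without motion and linear in the gain", {
  tt <- seq(0, 100, by = 0.01)
  p <- specimen_params(noise_sd_voltage = 0, drop_rate = 0)
  v0 <- piezo_voltage(rep(0.03, length(tt)), tt, p)
  expect_true(all(v0$voltage_mV == 0))

  eps <- 0.06 * pmin(tt / 3, 1)
  v1 <- piezo_voltage(eps, tt, p)
  p2 <- specimen_params(piezo_gain = 2 * p$piezo_gain, noise_sd_voltage = 0,
                        drop_rate = 0)
  v2 <- piezo_voltage(eps, tt, p2)
  expect_equal(max(v2$voltage_mV), 2 * max(v1$voltage_mV), tolerance = 1e-9)
  expect_equal(diff(v1$time_s[1:2]), 0.02)  # 50 Hz channel
})

test_that("post-ramp voltage decay recovers the time constant", {
  tt <- seq(0, 200, by = 0.01)
  eps <- 0.06 * pmin(tt / 3, 1)
  p <- specimen_params(piezo_decay = 30, noise_sd_voltage = 0, drop_rate = 0)
  v <- piezo_voltage(eps, tt, p)
  tau <- fit_decay(v, t_peak = 3, window_s = 90, baseline = 0,
                   noise_floor_mv = 0.01)
  expect_equal(tau, 30, tolerance = 0.05 * 30)
})

test_that("simulated records honour channel rates, preload and determinism", {
  wf <- short_protocol()
  p <- specimen_params(seed = 11L)
  rec <- simulate_specimen(wf, p)
  expect_equal(diff(rec$force$time_s[1:2]), 0.05)     # 20 Hz
  expect_equal(diff(rec$voltage$time_s[1:2]), 0.02)   # 50 Hz
  span_f <- range(rec$force$time_s)
  span_v <- range(rec$voltage$time_s)
  expect_lt(abs(span_f[2] - span_v[2]), 0.05 + 1e-9)

  # force at the end of the force-controlled preload equals the 1 N target
  iv <- stage_intervals(wf)
  t_pre <- iv$t_end[iv$phase == "preload"]
  f_pre <- rec$force$force_N[abs(rec$force$time_s - t_pre) < 0.026]
  expect_equal(mean(f_pre), 1, tolerance = 5 * p$noise_sd_force)

  # byte-identical CSV output on re-simulation with the same seed
  rec2 <- simulate_specimen(wf, p)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_channel_csv(rec$force, f1)
  write_channel_csv(rec2$force, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(rec$voltage$voltage_mV, rec2$voltage$voltage_mV)
})

test_that("downstream modulus fit recovers the simulated modulus", {
  wf <- short_protocol()
  p <- specimen_params(modulus_E = 80, toe_strain = 0,
                       prony_g = numeric(0), prony_tau = numeric(0),
                       noise_sd_force = 0, csa_true = 15)
  rec <- simulate_specimen(wf, p)
  mm <- compute_metrics(rec, p$csa_true)
  expect_equal(mm$Ef, 80, tolerance = 0.01 * 80)
})

test_that("generated meshes hit the target mean CSA and scale correctly", {
  m0 <- make_mesh(12, irregularity = 0, seed = 1)
  prof0 <- csa_profile(m0)
  expect_lt(max(abs(prof0$areas - 12)) / 12, 1e-3)

  m1 <- make_mesh(11.079, irregularity = 0.05, seed = 3)
  prof1 <- csa_profile(m1)
  expect_equal(prof1$mean, 11.079, tolerance = 0.005 * 11.079)

  # scaling the section by sqrt(2) in radius doubles the recovered area
  m2 <- triangle_mesh(cbind(m1$vertices[, 1:2] * sqrt(2), m1$vertices[, 3]),
                      m1$faces)
  prof2 <- csa_profile(m2)
  expect_equal(prof2$mean, 2 * prof1$mean, tolerance = 0.005 * 2 * prof1$mean)
})

test_that("group simulation is deterministic and respects n", {
  gs <- group_spec("G5", n = 3)
  wf <- short_protocol()
  recs <- simulate_group(gs, seed = 5, protocol = wf)
  expect_length(recs, 3L)
  expect_equal(vapply(recs, function(r) r$provenance$specimen_id, ""),
               c("G5-01", "G5-02", "G5-03"))
  recs2 <- simulate_group(gs, seed = 5, protocol = wf)
  e1 <- vapply(recs, function(r) r$provenance$params$modulus_E, 1)
  e2 <- vapply(recs2, function(r) r$provenance$params$modulus_E, 1)
  expect_identical(e1, e2)
  expect_gt(stats::sd(e1), 0)  # distinct specimens
  expect_error(group_spec("G5", n = 1), ">= 2")
})

test_that("specimen parameter validation enforces the Prony constraints", {
  expect_error(specimen_params(prony_g = c(0.6, 0.5)), "g_inf")
  expect_error(specimen_params(prony_g = 0.3, prony_tau = -1), "positive")
  expect_error(specimen_params(modulus_E = 0), "positive")
  p <- specimen_params(prony_g = c(0.3, 0.2))
  expect_equal(p$g_inf, 0.5)
})

test_that("written records include channels and ground truth", {
  wf <- short_protocol()
  rec <- simulate_specimen(wf, specimen_params(seed = 2), mesh = TRUE)
  prefix <- file.path(withr::local_tempdir(), "spec01")
  paths <- write_record(rec, prefix)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$params$modulus_E, rec$provenance$params$modulus_E)
  back <- read_channel_csv(paths[["force"]], expected_rate_hz = 20)
  expect_equal(nrow(back), nrow(rec$force))
  stl <- load_stl(paths[["stl"]])
  expect_gt(nrow(stl$faces), 1000)
})
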