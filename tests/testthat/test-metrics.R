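# Helper: wrap explicit vectors as a stress-strain series.
ss_series <- function(time, strain, stress, protocol = NULL) {
  structure(
    data.frame(time_s = time, strain = strain, stress_MPa = stress),
    class = c("stress_strain", "data.frame"), protocol = protocol
  )
}

test_that("stress and strain use the CSA and gauge-length conventions", {
  rec <- list(force = data.frame(time_s = seq(0, 1, 0.05),
                                 force_N = 12,
                                 displacement_mm = 3))
  ser <- to_stress_strain(rec, mean_csa = 12, gauge_length = 50)
  expect_true(all(ser$stress_MPa == 1))     # 12 N / 12 mm^2
  expect_true(all(ser$strain == 0.06))      # 3 mm / 50 mm
  expect_error(to_stress_strain(rec, mean_csa = 0), "positive")
})

test_that("simulated stress matches the ground-truth stress within noise", {
  wf <- short_protocol()
  p <- specimen_params(noise_sd_force = 0.02, seed = 4, csa_true = 15)
  rec <- simulate_specimen(wf, p)
  ser <- to_stress_strain(rec, p$csa_true)
  truth <- stats::approx(wf$time_s,
                         rec$provenance$stress_true +
                           rec$provenance$force_offset / p$csa_true,
                         xout = ser$time_s, rule = 2)$y
  resid <- ser$stress_MPa - pmax(truth, 0)
  expect_lt(stats::sd(resid), 3 * p$noise_sd_force / p$csa_true)
})

test_that("stage segmentation recovers the six stages with and without the protocol", {
  wf <- short_protocol()
  rec <- simulate_specimen(wf, specimen_params(seed = 9))
  ser <- to_stress_strain(rec, 15)
  seg_p <- segment_stages(ser)
  expect_equal(seg_p$phase, paste0("s", 1:6))
  iv <- stage_intervals(wf)
  expect_equal(seg_p$t_start, iv$t_start[match(seg_p$phase, iv$phase)])

  # inference from the strain derivative alone
  attr(ser, "protocol") <- NULL
  seg_i <- segment_stages(ser, protocol = NULL)
  expect_equal(seg_i$phase, paste0("s", 1:6))
  truth_s2 <- iv[iv$phase == "s2", ]
  got_s2 <- seg_i[seg_i$phase == "s2", ]
  expect_lt(abs(got_s2$t_start - truth_s2$t_start), 0.25)
  expect_lt(abs(got_s2$t_end - truth_s2$t_end), 0.25)

  # a monotone single ramp has no six-stage structure
  mono <- ss_series(seq(0, 10, 0.05), seq(0, 0.06, length.out = 201),
                    seq(0, 6, length.out = 201))
  expect_error(segment_stages(mono, protocol = NULL), "segmentation error")
})

test_that("modulus fit recovers exact lines and ignores stress offsets", {
  tt <- seq(0, 3, 0.05)
  strain <- 0.02 * tt
  ser <- ss_series(tt, strain, 100 * strain)
  fit <- fit_modulus(ser, list(t_start = 0, t_end = 3))
  expect_equal(fit$slope_a, 100, tolerance = 1e-9)
  expect_equal(fit$intercept_b, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  ser2 <- ss_series(tt, strain, 100 * strain + 0.5)
  fit2 <- fit_modulus(ser2, list(t_start = 0, t_end = 3))
  expect_equal(fit2$slope_a, 100, tolerance = 1e-9)
  expect_equal(fit2$intercept_b, 0.5, tolerance = 1e-9)

  expect_error(
    fit_modulus(ser, list(t_start = 0, t_end = 3), window = c(0.059, 0.06)),
    "insufficient"
  )
})

test_that("the modulus and stress drop formulas follow their definitions", {
  expect_equal(delta_modulus(100, 50), 50)
  expect_equal(delta_modulus(80, 80), 0)
  expect_equal(delta_modulus(80, 100), -25)
  expect_error(delta_modulus(0, 10), "positive")
  expect_equal(delta_stress(10, 7.5), 25)
  expect_equal(delta_stress(3, 3), 0)
  expect_error(delta_stress(-1, 0), "positive")
})

test_that("peak stress is the interval maximum", {
  tt <- seq(0, 3, 0.01)
  ser <- ss_series(tt, 0.02 * tt, 2 * tt / 3)
  expect_equal(peak_stress(ser, list(t_start = 0, t_end = 3)), 2)
  set.seed(1)
  noisy <- ss_series(tt, 0.02 * tt, 2 + stats::rnorm(length(tt), 0, 0.01))
  pk <- peak_stress(noisy, list(t_start = 0, t_end = 3))
  expect_gte(pk, 2)
  expect_lte(pk, 2.05)
})

test_that("hysteresis handles identity, total loss and an analytic loop", {
  n <- 1001
  e <- seq(0, 1, length.out = n)
  t_load <- seq(0, 10, length.out = n)
  t_unload <- seq(10.01, 20, length.out = n)
  li <- list(t_start = 0, t_end = 10)
  ui <- list(t_start = 10.01, t_end = 20)

  same <- ss_series(c(t_load, t_unload), c(e, rev(e)), c(e, rev(e)))
  expect_equal(hysteresis(same, li, ui), 0, tolerance = 1e-9)

  lost <- ss_series(c(t_load, t_unload), c(e, rev(e)), c(e, rep(0, n)))
  expect_equal(hysteresis(lost, li, ui), 100)

  # loading eps, unloading eps^2: H = (1/2 - 1/3) / (1/2) = 33.33%
  loop <- ss_series(c(t_load, t_unload), c(e, rev(e)), c(e, rev(e)^2))
  expect_equal(hysteresis(loop, li, ui), 100 / 3, tolerance = 0.01)

  expect_error(hysteresis(lost, ui, li), "positive")
})

test_that("hysteresis is invariant to time reparameterization", {
  n <- 501
  e <- seq(0, 0.06, length.out = n)
  stress_l <- 100 * e
  stress_u <- 100 * e^1.5 / 0.06^0.5
  t1 <- c(seq(0, 3, length.out = n), seq(3.01, 6, length.out = n))
  t2 <- c(seq(0, 30, length.out = n), seq(30.1, 33, length.out = n))
  s1 <- ss_series(t1, c(e, rev(e)), c(stress_l, rev(stress_u)))
  s2 <- ss_series(t2, c(e, rev(e)), c(stress_l, rev(stress_u)))
  h1 <- hysteresis(s1, list(t_start = 0, t_end = 3),
                   list(t_start = 3.01, t_end = 6))
  h2 <- hysteresis(s2, list(t_start = 0, t_end = 30),
                   list(t_start = 30.1, t_end = 33))
  expect_equal(h1, h2, tolerance = 1e-9)
})

test_that("trapezoid areas agree with a fine Simpson oracle on smooth curves", {
  e <- seq(0, 0.06, length.out = 1201)
  stress <- 120 * e^2 / 0.06 + 10 * e
  a_trapz <- pracma::trapz(e, stress)
  f <- function(x) 120 * x^2 / 0.06 + 10 * x
  a_simpson <- stats::integrate(f, 0, 0.06, rel.tol = 1e-12)$value
  expect_equal(a_trapz, a_simpson, tolerance = 1e-3 * a_simpson)
})

test_that("relaxation drop matches the single-Prony closed form", {
  tt <- seq(0, 600, 0.05)
  ser_const <- ss_series(tt, 0.06, rep(2, length(tt)))
  expect_equal(relaxation_drop(ser_const, list(t_start = 0, t_end = 600)), 0)

  g1 <- 0.4
  tau <- 300
  stress <- 6 * (0.6 + g1 * exp(-tt / tau))
  ser <- ss_series(tt, 0.06, stress)
  drop <- relaxation_drop(ser, list(t_start = 0, t_end = 600))
  cf <- (1 - (0.6 + g1 * exp(-600 / tau)) / (0.6 + g1)) * 100
  expect_equal(drop, cf, tolerance = 0.01 * cf)

  # larger g1 gives a larger drop
  stress2 <- 6 * (0.4 + 0.6 * exp(-tt / tau))
  expect_gt(relaxation_drop(ss_series(tt, 0.06, stress2),
                            list(t_start = 0, t_end = 600)), drop)
  expect_error(relaxation_drop(ss_series(tt, 0, rep(-1, length(tt))),
                               list(t_start = 0, t_end = 600)), "positive")
})

test_that("compute_metrics satisfies its identities and sign structure", {
  wf <- short_protocol()
  elastic <- specimen_params(modulus_E = 90, toe_strain = 0,
                             prony_g = numeric(0), prony_tau = numeric(0),
                             noise_sd_force = 0, csa_true = 15)
  mm0 <- compute_metrics(simulate_specimen(wf, elastic), 15)
  expect_equal(mm0$delta_E, 0, tolerance = 0.1)
  expect_equal(mm0$delta_sigma, 0, tolerance = 0.1)
  expect_equal(mm0$hysteresis_H, 0, tolerance = 0.1)
  expect_equal(mm0$relaxation_drop, 0, tolerance = 0.1)

  visc <- specimen_params(modulus_E = 90, seed = 8, noise_sd_force = 0)
  rec <- simulate_specimen(wf, visc)
  mm <- compute_metrics(rec, visc$csa_true)
  expect_gt(mm$delta_E, 0)
  expect_gt(mm$delta_sigma, 0)
  expect_gt(mm$hysteresis_H, 0)
  expect_gt(mm$relaxation_drop, 0)
  # Eq-style identities hold exactly on pipeline output
  expect_identical(mm$delta_E, (mm$Ef - mm$Es) / mm$Ef * 100)
  expect_identical(mm$delta_sigma,
                   (mm$sigma_f - mm$sigma_s) / mm$sigma_f * 100)
  # determinism
  mm2 <- compute_metrics(rec, visc$csa_true)
  expect_identical(unclass(mm)[1:8], unclass(mm2)[1:8])
})

test_that("metrics rise monotonically with total Prony weight", {
  wf <- short_protocol()
  levels <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  vals <- t(vapply(levels, function(gsum) {
    p <- specimen_params(modulus_E = 100,
                         prony_g = gsum * c(0.55, 0.45),
                         prony_tau = c(10, 120),
                         noise_sd_force = 0, csa_true = 15)
    mm <- compute_metrics(simulate_specimen(wf, p), 15)
    c(mm$hysteresis_H, mm$delta_E, mm$delta_sigma, mm$relaxation_drop)
  }, numeric(4)))
  for (j in 1:4) {
    expect_equal(stats::cor(vals[, j], seq_along(levels), method = "spearman"),
                 1, info = paste("metric column", j))
  }
})
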