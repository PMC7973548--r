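test_that("burst detector finds injected bursts and nothing else", {
  # constant envelope: no bursts, no error
  expect_identical(nrow(detect_bursts(rep(2, 5000), 1000, band = band_hfo_kx())), 0L)

  # envelope with a known noise floor and 10 strong bumps
  set.seed(17)
  fs <- 1000
  env <- abs(rnorm(60 * fs, mean = 1, sd = 0.05))
  floor_sd <- mad(env)
  truth <- seq(3, 57, by = 6)
  for (pk in truth) {
    idx <- round((pk - 0.05) * fs):round((pk + 0.05) * fs)
    env[idx] <- env[idx] + 6 * floor_sd * cos(pi * ((idx / fs) - pk) / 0.1)^2
  }
  ev <- detect_bursts(env, fs, band = band_hfo_kx(), min_duration_s = 0.02)
  expect_equal(nrow(ev), 10L)
  # cosine-squared bumps have a flat top, so the noise floor can move the
  # argmax by a few samples; sharp-peak timing is checked on generator bursts
  expect_lte(max(abs(ev$peak_s - truth)), 0.02)

  # bumps peaking at 2 SD stay below the 3 SD criterion: sporadic noise
  # crossings are too short to count (gap merging off isolates them)
  env2 <- abs(rnorm(60 * fs, mean = 1, sd = 0.05))
  for (pk in truth) {
    idx <- round((pk - 0.05) * fs):round((pk + 0.05) * fs)
    env2[idx] <- env2[idx] + 2 * floor_sd * cos(pi * ((idx / fs) - pk) / 0.1)^2
  }
  expect_equal(nrow(detect_bursts(env2, fs, min_duration_s = 0.02,
                                  merge_gap_s = 0)), 0L)
  expect_error(detect_bursts(env, fs, band = band_hfo_kx(), threshold_sd = -1),
               "threshold")
})

test_that("burst detector recovers generator events with high precision/recall", {
  sim <- fixture_sim()
  gt <- sim$ground_truth
  env <- analytic_envelope_phase(bandpass(ref_channel_trace(sim),
                                          band_hfo_kx()))$envelope
  ev <- detect_bursts(env, gt$fs, band = band_hfo_kx())
  m <- match_events(ev$peak_s, sim$bursts$peak_s, tol_s = 0.05)
  expect_gte(m$precision, 0.9)
  expect_gte(m$recall, 0.9)
  # envelope peak timing: within 5 ms of the true burst peak at this SNR
  err <- vapply(sim$bursts$peak_s, function(s) min(abs(ev$peak_s - s)),
                numeric(1))
  expect_lt(median(err), 0.005)
})

test_that("burst delta phase follows the time-rescaling definition", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  delta <- cos(2 * pi * 1.5 * t)   # peaks at multiples of 2/3 s
  mk <- function(pk) data.frame(onset_s = pk - 0.05, offset_s = pk + 0.05,
                                peak_s = pk, peak_env = 1, channel = 1L)
  # burst exactly at a delta peak -> phase 0
  ps0 <- burst_delta_phase(mk(4 / 1.5), delta, fs = fs)
  expect_lt(abs(ps0$phases), 0.02)
  # quarter cycle after the peak (mid-descent) -> pi/2
  ps1 <- burst_delta_phase(mk(4 / 1.5 + 1 / 6), delta, fs = fs)
  expect_lt(abs(ps1$phases - pi / 2), 0.02)
  # hilbert mode agrees on a pure sinusoid
  ps2 <- burst_delta_phase(mk(4 / 1.5 + 1 / 6), delta, fs = fs, mode = "hilbert")
  expect_lt(circ_dist(ps2$phases, pi / 2), 0.02)

  # recovery of the configured lock phase from a seeded simulation
  sim <- fixture_sim()
  gt <- sim$ground_truth
  x <- ref_channel_trace(sim)
  env <- analytic_envelope_phase(bandpass(x, band_hfo_kx()))$envelope
  ev <- detect_bursts(env, gt$fs, band = band_hfo_kx())
  ps <- burst_delta_phase(ev, bandpass(x, band_delta()))
  expect_lt(circ_dist(circ_mean(ps$phases), gt$lock_phase), 0.2)
})

test_that("ITPC matches its analytic values", {
  expect_equal(itpc(rep(1.2, 50)), 1.0, tolerance = 1e-15)
  expect_equal(itpc(c(0, 2 * pi / 3, 4 * pi / 3)), 0, tolerance = 1e-15)
  set.seed(99)
  expect_lt(itpc(runif(10000, -pi, pi)), 0.03)
  # rotation invariance at machine precision
  set.seed(100)
  ph <- runif(500, -pi, pi)
  expect_equal(itpc(ph), itpc(ph + 1.234), tolerance = 1e-12)
  expect_error(itpc(numeric(0)), "empty")
})

test_that("envelope correlation behaves at its analytic anchors", {
  set.seed(41)
  x <- rnorm(5000)
  expect_equal(envelope_correlation(2 * x + 3, x), 1, tolerance = 1e-12)
  expect_lt(abs(envelope_correlation(rnorm(1e5), rnorm(1e5))), 0.02)
  expect_error(envelope_correlation(rep(1, 100), rnorm(100)), "variance")

  # resampling to a common rate: decimation path
  fs_hi <- 2000; fs_lo <- 500
  th <- seq(0, 10 - 1 / fs_hi, by = 1 / fs_hi)
  tl <- seq(0, 10 - 1 / fs_lo, by = 1 / fs_lo)
  r <- envelope_correlation(sin(2 * pi * 3 * th), sin(2 * pi * 3 * tl),
                            fs_x = fs_hi, fs_y = fs_lo)
  expect_gt(r, 0.99)

  # coupling strength increases delta/HFO-envelope correlation (matched seeds)
  mk <- function(kappa) {
    gt <- ground_truth(seed = 5L, fs = 1000, duration = 60,
                       coupling_kappa = kappa, mua_rate = 0)
    sim <- generate_laminar_recording(gt, probe_geometry(4, 800, 200))
    x <- ref_channel_trace(sim)
    d <- bandpass(x, band_delta())$samples[1, ]
    e <- analytic_envelope_phase(bandpass(x, band_hfo_kx()))$envelope
    abs(envelope_correlation(d, e))
  }
  expect_gt(mk(8), mk(0))
})

test_that("Tort MI equals the brute-force oracle and its analytic anchors", {
  set.seed(12)
  th <- runif(20000, -pi, pi)
  expect_identical(tort_mi(th, rep(3, length(th))), 0)
  onebin <- as.numeric(th > -pi + 2 * pi * 4 / 18 & th <= -pi + 2 * pi * 5 / 18)
  expect_equal(tort_mi(th, onebin), 1, tolerance = 1e-15)

  # dense uniform phase sampling of amplitude = 1 + cos(phase): closed-form
  # binned distribution evaluated independently
  thd <- seq(-pi, pi - 1e-6, length.out = 100000)
  amp <- 1 + cos(thd)
  expect_equal(tort_mi(thd, amp), tort_mi_oracle(thd, amp), tolerance = 1e-12)

  # 100 random inputs: exact agreement with the oracle
  for (i in 1:100) {
    n <- sample(200:2000, 1)
    ph <- runif(n, -pi, pi)
    am <- rexp(n)
    expect_equal(tort_mi(ph, am), tort_mi_oracle(ph, am), tolerance = 1e-12)
  }
  expect_error(tort_mi(runif(10), rexp(9)), "length")
})

test_that("comodulogram localises the configured coupling cell", {
  sim <- fixture_sim()
  gt <- sim$ground_truth
  x <- sim$lfp$samples[sim$reference_channel, ]
  cm <- comodulogram(x, band_grid(c(0.75, 1.5, 2.5, 3.5), 1),
                     band_grid(c(65, 85, 105, 125), 20), fs = gt$fs)
  am <- comodulogram_argmax(cm)
  expect_equal(am$phase_freq, 1.5)
  expect_equal(am$amp_freq, 105)
  # deterministic
  cm2 <- comodulogram(x, band_grid(c(0.75, 1.5, 2.5, 3.5), 1),
                      band_grid(c(65, 85, 105, 125), 20), fs = gt$fs)
  expect_identical(cm$mi, cm2$mi)
  # overlapping bands flagged invalid, not computed
  cmo <- comodulogram(x[1:20000], band_grid(2, 2), band_grid(c(3, 50), 4),
                      fs = gt$fs)
  expect_true(is.na(cmo$mi[1, 1]))
  expect_false(is.na(cmo$mi[1, 2]))
})

test_that("white-noise comodulogram stays within its surrogate null", {
  set.seed(23)
  fs <- 250
  x <- rnorm(40 * fs)
  pb <- band_grid(c(1.5, 3), 1)
  ab <- band_grid(c(40, 70), 20)
  cm <- comodulogram(x, pb, ab, fs = fs)
  # surrogate null: circularly shift the amplitude stream against the phases
  ph <- lapply(1:2, function(i)
    analytic_envelope_phase(bandpass(x, band_spec(pb$lo[i], pb$hi[i]),
                                     fs = fs))$phase)
  env <- lapply(1:2, function(j)
    analytic_envelope_phase(bandpass(x, band_spec(ab$lo[j], ab$hi[j]),
                                     fs = fs))$envelope)
  null_q <- sapply(1:2, function(i) sapply(1:2, function(j) {
    nulls <- replicate(200, {
      s <- sample(length(x), 1)
      tort_mi(ph[[i]], c(env[[j]][(s + 1):length(x)], env[[j]][1:s]))
    })
    quantile(nulls, 0.99)
  }))
  expect_true(all(cm$mi < t(null_q)))
})

test_that("MI resampling test is calibrated, sensitive and reproducible", {
  set.seed(61)
  mats <- replicate(8, matrix(runif(12, 0.01, 0.05), 3, 4), simplify = FALSE)
  # identical groups: nothing significant
  res_id <- mi_resampling_test(mats, mats, n_draws = 10000, seed = 4)
  expect_gte(min(res_id$p), 0.01)

  # a single-cell shift of 5 pooled SDs is detected there and only there
  pooled_sd <- sd(sapply(mats, function(m) m[2, 2]))
  mats_b <- lapply(mats, function(m) { m[2, 2] <- m[2, 2] + 5 * pooled_sd; m })
  res <- mi_resampling_test(mats, mats_b, n_draws = 10000, seed = 4)
  expect_lt(res$p[2, 2], 0.01)
  expect_gt(min(res$p[-5]), 0.05)   # cell [2,2] is index 5 column-major

  # bit-exact reproducibility per seed
  res2 <- mi_resampling_test(mats, mats_b, n_draws = 10000, seed = 4)
  expect_identical(res$p, res2$p)
  expect_error(mi_resampling_test(mats[1:1], mats, n_draws = 100, seed = 1),
               "2 matrices")
  expect_error(mi_resampling_test(mats, replicate(3, matrix(1, 2, 2),
                                                  simplify = FALSE),
                                  n_draws = 100, seed = 1), "grids")
})
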