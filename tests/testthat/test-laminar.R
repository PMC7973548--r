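test_that("depth power profile localises the HFO dipole", {
  # fine probe (50 um) so the channel grid resolves the inter-lobe minimum
  gt <- ground_truth(seed = 13L, fs = 1000, duration = 20, coupling_kappa = 4,
                     delta_dipole_depth = 2000, mua_rate = 0)
  geom <- probe_geometry(36, 50, 700)
  sim <- generate_laminar_recording(gt, geom)
  prof <- depth_power_profile(sim$lfp, band_hfo_kx(), window_s = 5)
  # expected lobe depths from the dipole profile itself (fine grid)
  zf <- seq(700, 2450, by = 1)
  wf <- obhfo:::dipole_weight(zf, gt$hfo_dipole_depth, gt$hfo_dipole_halfwidth)
  lobe_depths <- c(zf[which.max(wf)], zf[which.min(wf)])
  max_d <- prof$depth_um[which.max(prof$value)]
  expect_lte(min(abs(max_d - lobe_depths)), 2 * geom$spacing_um)
  # local minimum between the lobes within one channel of the dipole centre
  near <- which(prof$depth_um > lobe_depths[1] & prof$depth_um < lobe_depths[2])
  min_d <- prof$depth_um[near][which.min(prof$value[near])]
  expect_lte(abs(min_d - gt$hfo_dipole_depth), geom$spacing_um)

  # uniform common-mode signal: flat profile
  t <- seq(0, 20 - 1e-3, by = 1e-3)
  cmn <- recording(matrix(rep(0.1 * sin(2 * pi * 100 * t), 8), nrow = 8,
                          byrow = TRUE), 1000, geometry = probe_geometry(8, 100, 50))
  pf <- depth_power_profile(cmn, band_hfo_kx(), window_s = 5)
  expect_lt(max(pf$value) / min(pf$value), 1.2)

  # zero signal: all-zero profile
  z <- recording(matrix(0, 8, 5000), 1000, geometry = probe_geometry(8, 100, 50))
  expect_identical(max(depth_power_profile(z, band_hfo_kx(), window_s = 5)$value), 0)
  expect_error(depth_power_profile(recording(matrix(0, 4, 100), 1000),
                                   band_gamma()), "depths")
})

test_that("interchannel phase shift shows the dipole phase reversal", {
  sim <- fixture_sim()
  gt <- sim$ground_truth
  geom <- sim$lfp$geometry
  env <- analytic_envelope_phase(bandpass(ref_channel_trace(sim),
                                          band_hfo_kx()))$envelope
  ev <- detect_bursts(env, gt$fs, band = band_hfo_kx())
  prof <- interchannel_phase_shift(sim$lfp, band_hfo_kx(),
                                   sim$reference_channel, ev)
  # reference channel: exactly zero
  expect_identical(prof$value[sim$reference_channel], 0)
  # same side as reference: near 0; other side: near 180
  same <- geom$depths_um < gt$hfo_dipole_depth
  ref_side <- geom$depths_um[sim$reference_channel] < gt$hfo_dipole_depth
  if (!ref_side) same <- !same
  strong <- abs(sim$weights$hfo) > 0.3
  expect_lt(max(circ_dist(prof$value[same & strong] * pi / 180, 0)), pi / 4)
  expect_lt(max(circ_dist(prof$value[!same & strong] * pi / 180, pi)), pi / 4)
  # reversal within one electrode spacing of the dipole centre
  expect_lte(abs(reversal_depth(prof) - gt$hfo_dipole_depth), geom$spacing_um)

  # explicit anti-phase construction at the band centre: exactly 180 degrees
  # (the lag-to-degrees conversion uses the band-centre period, so the tone
  # sits at the centre of an 80-120 Hz band and fs is a multiple of it)
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  base <- sin(2 * pi * 100 * t)
  rec2 <- recording(rbind(base, -base), 1000,
                    geometry = probe_geometry(2, 100, 50))
  ev2 <- data.frame(onset_s = c(2, 5), offset_s = c(2.2, 5.2),
                    peak_s = c(2.1, 5.1), peak_env = 1, channel = 1L)
  p2 <- interchannel_phase_shift(rec2, band_spec(80, 120), 1L, ev2)
  expect_identical(p2$value[1], 0)
  expect_lt(circ_dist(p2$value[2] * pi / 180, pi), 1e-6)
})

test_that("kCSD inverts its own forward model", {
  geom <- probe_geometry(32, 20, 1000)
  x <- geom$depths_um

  # zero potentials -> zero CSD
  z <- kcsd_reconstruct(recording(matrix(0, 32, 3), 1000, geometry = geom))
  expect_identical(max(abs(z$csd)), 0)

  # single Gaussian source, noise-free: r > 0.95, peak within one spacing
  src_c <- 1310; src_w <- 60
  phi <- obhfo:::kcsd_forward_phi(x, src_c, src_w, 500)
  m <- kcsd_reconstruct(recording(matrix(phi, ncol = 1), 1000, geometry = geom))
  truth <- exp(-(m$depths_um - src_c)^2 / (2 * src_w^2))
  expect_gt(cor(m$csd[, 1], truth), 0.95)
  expect_lte(abs(m$depths_um[which.max(m$csd[, 1])] - src_c), geom$spacing_um)

  # linearity at fixed lambda, machine precision
  phi2 <- obhfo:::kcsd_forward_phi(x, 1500, 80, 500)
  rec_of <- function(v) recording(matrix(v, ncol = 1), 1000, geometry = geom)
  m1 <- kcsd_reconstruct(rec_of(phi), lambda_grid = 1e-4)
  m2 <- kcsd_reconstruct(rec_of(phi2), lambda_grid = 1e-4)
  mb <- kcsd_reconstruct(rec_of(2 * phi - 0.5 * phi2), lambda_grid = 1e-4)
  expect_equal(mb$csd, 2 * m1$csd - 0.5 * m2$csd, tolerance = 1e-10)

  # two opposite sources 200 um apart: exactly one sign change between them
  c1 <- 1300; c2 <- 1500
  phi_d <- obhfo:::kcsd_forward_phi(x, c1, 60, 500) -
           obhfo:::kcsd_forward_phi(x, c2, 60, 500)
  md <- kcsd_reconstruct(rec_of(phi_d))
  between <- md$depths_um > c1 & md$depths_um < c2
  signs <- sign(md$csd[between, 1])
  expect_equal(sum(diff(signs[signs != 0]) != 0), 1)

  # depth-uniform potential offset: CSD ~ 0 compared with the naive second
  # difference of a real source profile
  mc <- kcsd_reconstruct(rec_of(rep(0.5, 32)), lambda_grid = 1e-4)
  ratio <- sqrt(mean(mc$csd^2)) / sqrt(mean(m1$csd^2))
  expect_lt(ratio, 0.05)

  # deterministic cross-validation
  expect_identical(kcsd_reconstruct(rec_of(phi))$lambda,
                   kcsd_reconstruct(rec_of(phi))$lambda)
  expect_error(kcsd_reconstruct(recording(matrix(0, 3, 2), 1000,
                                          geometry = probe_geometry(3, 20, 0))),
               ">= 4 channels")
})

test_that("band-filtered CSD separates the delta and HFO dipoles", {
  sim <- fixture_sim()
  gt <- sim$ground_truth
  geom <- sim$lfp$geometry
  # 12 s window so the delta band has enough cycles
  idx <- seq(round(20 * gt$fs), round(32 * gt$fs))
  snap <- recording(sim$lfp$samples[, idx], gt$fs, geometry = geom)
  csd <- kcsd_reconstruct(snap, lambda_grid = 1e-4)

  # full-band filtering is near-identity away from the edges
  full <- band_filtered_csd(csd, band_spec(0.1, gt$fs / 2 * 0.98))
  mid <- seq(round(0.2 * ncol(csd$csd)), round(0.8 * ncol(csd$csd)))
  expect_gt(cor(as.numeric(csd$csd[, mid]), as.numeric(full$csd[, mid])), 0.99)

  # zero map stays zero
  zmap <- csd; zmap$csd[] <- 0
  expect_identical(max(abs(band_filtered_csd(zmap, band_delta())$csd)), 0)

  d_csd <- band_filtered_csd(csd, band_delta())
  h_csd <- band_filtered_csd(csd, band_hfo_kx())
  row_rms <- function(m) apply(m$csd[, mid], 1, function(v) sqrt(mean(v^2)))
  d_peak <- d_csd$depths_um[which.max(row_rms(d_csd))]
  h_peak <- h_csd$depths_um[which.max(row_rms(h_csd))]
  expect_lt(abs(d_peak - gt$delta_dipole_depth), 2 * gt$delta_dipole_halfwidth)
  expect_lt(abs(h_peak - gt$hfo_dipole_depth), 2 * gt$hfo_dipole_halfwidth)

  # HFO-filtered CSD sign change sits at the dipole centre
  expect_lte(abs(csd_sign_change_depth(h_csd) - gt$hfo_dipole_depth),
             geom$spacing_um)
})

test_that("kCSD agrees with the second-difference oracle on smooth profiles", {
  geom <- probe_geometry(32, 20, 1000)
  x <- geom$depths_um
  phi <- obhfo:::kcsd_forward_phi(x, 1310, 80, 500)
  snap <- recording(matrix(phi, ncol = 1), 1000, geometry = geom)
  k <- kcsd_reconstruct(snap)
  naive <- csd_second_difference(snap)
  # compare on the electrode grid (interior channels)
  k_on_el <- approx(k$depths_um, k$csd[, 1], xout = x[2:31])$y
  expect_gt(cor(k_on_el, naive[, 1]), 0.9)
})

test_that("MUA detector has Gaussian-bounded false positives and high recall", {
  # spike-free LFP-band signal: detections below the Rice upcrossing bound
  set.seed(3)
  fs <- 10000
  dur <- 20
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  lfp_only <- 0.3 * sin(2 * pi * 2 * t) + 0.05 * sin(2 * pi * 100 * t) +
    0.01 * rnorm(length(t))
  rec <- recording(matrix(lfp_only, 1), fs)
  det <- detect_mua(rec, threshold_sd = 3)[[1]]
  # Rice bound for the high-passed Gaussian floor at 3 SD:
  # rate = f_eff * exp(-9/2), f_eff^2 = int f^2 S df / int S df over the band
  f_eff <- sqrt(((fs / 2)^3 - 500^3) / (3 * (fs / 2 - 500)))
  rice_rate <- f_eff * exp(-9 / 2)
  expect_lt(length(det) / dur, rice_rate)

  # zero signal: nothing
  expect_identical(detect_mua(recording(matrix(0, 1, fs * 2), fs))[[1]],
                   numeric(0))
  expect_error(detect_mua(recording(matrix(0, 1, 1000), 1000)), "fs")

  # generator ground truth: recall >= 0.9, timing < 1 ms
  sim <- fixture_sim_mua()
  ref <- sim$reference_channel
  spk <- detect_mua(sim$lfp)[[ref]]
  m <- match_events(spk, sim$spikes[[ref]], tol_s = 1e-3)
  expect_gte(m$recall, 0.9)
  err <- vapply(sim$spikes[[ref]], function(s) min(abs(spk - s)), numeric(1))
  expect_lt(median(err), 1e-3)
})

test_that("MUA-HFO correlation reports trough locking", {
  # spikes exactly at the minima of a pure cosine: r = -1 on the binned grid
  fs <- 10000
  f0 <- 100
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  wave <- recording(matrix(cos(2 * pi * f0 * t), 1), fs)
  pk <- seq(1, 29, by = 1)            # "burst" peaks at cosine peaks
  ev <- data.frame(onset_s = pk - 0.05, offset_s = pk + 0.05, peak_s = pk,
                   peak_env = 1, channel = 1L)
  troughs <- as.numeric(sapply(pk, function(p) p + ((-10:9) + 0.5) / f0))
  # half-period bins with a bin centred on the peak: the binned waveform is
  # exactly two-valued and alternating, so trough spikes give r = -1 exactly
  mh <- mua_hfo_correlation(list(troughs), ev, wave,
                            histogram_bin_s = 1 / (2 * f0), window_s = 0.1025)
  expect_equal(mh$r[1], -1, tolerance = 1e-3)

  # uniformly timed spikes: negligible correlation with >= 200 events
  set.seed(77)
  pk2 <- seq(0.6, 29.4, length.out = 220)
  ev2 <- data.frame(onset_s = pk2 - 0.05, offset_s = pk2 + 0.05, peak_s = pk2,
                    peak_env = 1, channel = 1L)
  unif <- sort(runif(5000, 0, 30))
  mh2 <- mua_hfo_correlation(list(unif), ev2, wave, histogram_bin_s = 1e-3)
  expect_lt(abs(mh2$r[1]), 0.1)

  # generator: trough-locked spiking anti-correlates with the HFO waveform
  sim <- fixture_sim_mua()
  ref <- sim$reference_channel
  spikes <- detect_mua(sim$lfp)
  hfo <- bandpass(sim$lfp, band_hfo_kx())
  mh3 <- mua_hfo_correlation(spikes, sim$bursts, hfo)
  expect_lt(mh3$r[ref], 0)
  expect_gt(abs(mh3$r[ref]), 0.5)
  expect_error(mua_hfo_correlation(list(numeric(0)), ev2[1:3, ], wave), "bursts")
})
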