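fs <- 500
tt_s <- (0:549) / fs

test_that("a pure tone localizes at its own frequency at every valid time", {
  tone <- matrix(sin(2 * pi * 10 * tt_s), 1)
  tf <- morlet_power(tone, fs, t0 = -300)
  ti <- which(tf$times >= 100 & tf$times < 300)
  for (s in ti) {
    ok <- tf$valid[, s]
    pk <- tf$freqs[ok][which.max(tf$power[1, ok, s])]
    expect_lt(abs(pk - 10), 0.55)
  }
})

test_that("power scales quadratically with amplitude", {
  tone <- matrix(sin(2 * pi * 10 * tt_s), 1)
  tf1 <- morlet_power(tone, fs, t0 = -300)
  tf2 <- morlet_power(2 * tone, fs, t0 = -300)
  s <- 275  # epoch center
  ratio <- max(tf2$power[1, , s]) / max(tf1$power[1, , s])
  expect_equal(ratio, 4, tolerance = 0.01)
})

test_that("two-tone mixtures produce two independent ridges", {
  t10 <- matrix(sin(2 * pi * 10 * tt_s), 1)
  t20 <- matrix(sin(2 * pi * 20 * tt_s), 1)
  both <- t10 + t20
  s <- 275
  p10 <- morlet_power(t10, fs, t0 = -300)$power[1, , s]
  p20 <- morlet_power(t20, fs, t0 = -300)$power[1, , s]
  pb <- morlet_power(both, fs, t0 = -300)$power[1, , s]
  grid <- seq(0.1, 30, 0.5)
  i10 <- which.min(abs(grid - 10)); i20 <- which.min(abs(grid - 20))
  expect_lt(abs(pb[i10] - p10[i10]) / p10[i10], 0.05)
  expect_lt(abs(pb[i20] - p20[i20]) / p20[i20], 0.05)
})

test_that("peak-frequency error is at most one grid step from 4 to 15 Hz", {
  s <- 275
  for (f0 in 4:15) {
    tf <- morlet_power(matrix(sin(2 * pi * f0 * tt_s), 1), fs, t0 = -300)
    ok <- tf$valid[, s]
    pk <- tf$freqs[ok][which.max(tf$power[1, ok, s])]
    expect_lte(abs(pk - f0), 0.5)
  }
})

test_that("evoked power is the transform of the trial average", {
  cfg <- tiny_sim(n_channels = 2, n_trials = 4, seed = 12L)
  ep <- gen_epoch_set(cfg, "s1", "control", "self")
  # identical trials: evoked equals single-trial morlet power
  ep$data <- ep$data[, , c(1, 1, 1, 1)]
  tf <- evoked_power(ep)
  tf1 <- morlet_power(ep$data[, , 1], ep$fs, t0 = ep$t0,
                      channel_labels = ep$channel_labels)
  expect_equal(tf$power, tf1$power, tolerance = 1e-12)

  # zero signal maps to zero power
  ep0 <- ep
  ep0$data[] <- 0
  expect_true(all(evoked_power(ep0)$power == 0))

  # single trial warns
  ep1 <- ep
  ep1$data <- ep1$data[, , 1, drop = FALSE]
  expect_warning(evoked_power(ep1), "single trial")
})

test_that("trial-phase jitter cancels evoked power (roughly 1/N)", {
  spec <- wavelet_spec(freqs = seq(8.1, 12.6, 0.5))
  locked <- sim_config(n_channels = 2, n_trials = 70, noise_sd = 0,
                       subject_amp_cv = 0, burst_phase_jitter = 0,
                       coupled_edges = matrix(integer(0), 0, 2), seed = 2L)
  jit <- locked
  jit$burst_phase_jitter <- pi
  p_locked <- band_window_mean(evoked_power(
    gen_epoch_set(locked, "s1", "control", "self"), spec),
    c(8, 13), c(100, 300))
  p_jit <- band_window_mean(evoked_power(
    gen_epoch_set(jit, "s1", "control", "self"), spec),
    c(8, 13), c(100, 300))
  expect_lt(p_jit / p_locked, 0.10)
})

test_that("evoked power rises monotonically as phase jitter falls", {
  spec <- wavelet_spec(freqs = seq(8.1, 12.6, 0.5))
  pw <- vapply(c(pi, pi / 2, pi / 4, 0), function(j) {
    cfg <- sim_config(n_channels = 2, n_trials = 70, noise_sd = 0,
                      subject_amp_cv = 0, burst_phase_jitter = j,
                      coupled_edges = matrix(integer(0), 0, 2), seed = 6L)
    band_window_mean(evoked_power(
      gen_epoch_set(cfg, "s1", "control", "self"), spec),
      c(8, 13), c(100, 300))
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("band/window averaging is exact arithmetic over unmasked cells", {
  tf <- morlet_power(matrix(rnorm(550), 1), fs, t0 = -300)
  # uniform map returns the constant
  tf$power[] <- 0.7
  expect_equal(band_window_mean(tf, c(8, 13), c(0, 200)), 0.7)

  # hand-summed two-cell toy selection
  tf$power[] <- 0
  grid <- tf$freqs
  i1 <- which.min(abs(grid - 10)); s1 <- which(tf$times == 100)
  tf$power[1, i1, s1] <- 2; tf$power[1, i1 + 1, s1] <- 4
  got <- band_window_mean(tf, c(grid[i1], grid[i1 + 1]),
                          c(100, 100 + 1000 / fs))
  expect_equal(got, 3)

  # masked selections error
  expect_error(band_window_mean(tf, c(0.1, 0.2), c(-300, -200)), "masked")
  expect_error(band_window_mean(tf, c(8, 13), c(900, 1000)), "no grid cells")
})

test_that("a burst is localized in its window, not the prestimulus one", {
  cfg <- sim_config(n_channels = 2, n_trials = 20, noise_sd = 0,
                    subject_amp_cv = 0,
                    coupled_edges = matrix(integer(0), 0, 2), seed = 3L)
  tf <- evoked_power(gen_epoch_set(cfg, "s1", "control", "self"))
  expect_gt(band_window_mean(tf, c(8, 13), c(100, 300)),
            band_window_mean(tf, c(8, 13), c(-200, 0)))
})

test_that("low-frequency cells with wavelet support beyond the epoch are masked", {
  tf <- morlet_power(matrix(rnorm(550), 1), fs, t0 = -300)
  # f0 = 0.1 Hz: sigma_t ~ 11 s >> 1.1 s epoch => fully masked row
  expect_false(any(tf$valid[1, ]))
  # 10 Hz: masked within 2 sigma_t (~223 ms) of the edges only
  i10 <- which.min(abs(tf$freqs - 10.1))
  expect_true(tf$valid[i10, 275])
  expect_false(tf$valid[i10, 5])
  # stationary tone: window choice among unmasked windows is immaterial
  tone <- matrix(sin(2 * pi * 10 * tt_s), 1)
  tfs <- morlet_power(tone, fs, t0 = -300)
  m1 <- band_window_mean(tfs, c(9, 11), c(0, 200))
  m2 <- band_window_mean(tfs, c(9, 11), c(200, 400))
  expect_lt(abs(m1 - m2) / m1, 0.05)
})

test_that("electrode p-maps behave under null, shift and permutation", {
  set.seed(21)
  # equal samples: t = 0, p = 1
  a <- matrix(rnorm(40), 10, 4)
  pm <- electrode_p_map(a, a)
  expect_equal(pm$t, rep(0, 4))
  expect_equal(pm$p, rep(1, 4))
  expect_equal(pm$df, rep(18, 4))

  # a planted 3-pooled-SD shift at one electrode survives Bonferroni
  hits <- vapply(1:40, function(r) {
    ga <- matrix(rnorm(18 * 4), 18, 4)
    gb <- matrix(rnorm(18 * 4), 18, 4)
    gb[, 2] <- gb[, 2] + 3
    pm <- electrode_p_map(ga, gb)
    pm$p_bonferroni[2] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # permuted labels reject at about the nominal rate
  x <- matrix(rnorm(36 * 4), 36, 4)
  rej <- vapply(1:150, function(r) {
    idx <- sample(36, 18)
    pm <- electrode_p_map(x[idx, , drop = FALSE], x[-idx, , drop = FALSE])
    pm$p < 0.05
  }, logical(4))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)

  # zero variance in both groups is flagged
  za <- matrix(1, 3, 2); zb <- matrix(1, 3, 2)
  zb[, 2] <- rnorm(3)
  pm0 <- electrode_p_map(za, zb)
  expect_true(pm0$flagged[1])
  expect_true(is.na(pm0$p[1]))
  expect_false(pm0$flagged[2])
})
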