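test_that("same config and seed regenerate bit-identical data", {
  cfg <- tiny_sim(seed = 42L)
  a <- gen_epoch_set(cfg, "c01", "control", "self")
  b <- gen_epoch_set(cfg, "c01", "control", "self")
  expect_identical(a$data, b$data)
  ba <- gen_behavior(cfg, "c01", "control")
  bb <- gen_behavior(cfg, "c01", "control")
  expect_identical(ba$hits, bb$hits)
  expect_identical(ba$false_alarms, bb$false_alarms)

  # different subjects / conditions / seeds give different streams
  expect_false(identical(
    a$data, gen_epoch_set(cfg, "c02", "control", "self")$data))
  expect_false(identical(
    a$data, gen_epoch_set(cfg, "c01", "control", "other")$data))
  cfg2 <- tiny_sim(seed = 43L)
  expect_false(identical(
    a$data, gen_epoch_set(cfg2, "c01", "control", "self")$data))
})

test_that("cohort has n_per_group x 2 subjects x 3 conditions", {
  cfg <- tiny_sim(n_per_group = 2, n_channels = 3, n_trials = 4)
  coh <- gen_cohort(cfg)
  expect_equal(nrow(coh$subjects), 4L)
  expect_length(coh$epoch_sets, 4L)
  expect_true(all(vapply(coh$epoch_sets, length, 1L) == 3L))
  expect_equal(nrow(coh$behavior), 12L)
  # regeneration is bit-identical
  coh2 <- gen_cohort(cfg)
  expect_identical(coh$epoch_sets[["pat01"]][["other"]]$data,
                   coh2$epoch_sets[["pat01"]][["other"]]$data)
  # ground truth records the planted structure
  expect_named(coh$ground_truth,
               c("burst_amp", "evoked_power_ratio", "coupling_consistency",
                 "expected_coupled_pli", "coupled_edges",
                 "expected_recognition", "expected_srm_bias",
                 "network_contrast"))
  expect_equal(coh$ground_truth$expected_srm_bias[["control"]], 0.14)
})

test_that("epoch dimensions follow fs and window", {
  cfg <- tiny_sim(n_channels = 5, n_trials = 7)
  ep <- gen_epoch_set(cfg, "s1", "control", "physical")
  expect_equal(dim(ep$data), c(5L, 550L, 7L))
  expect_equal(epoch_times(ep)[1], -300)
  expect_equal(epoch_times(ep)[151], 0)   # onset on-grid at 500 Hz
})

test_that("zero burst amplitude leaves no evoked alpha above the noise floor", {
  # active-window alpha power should be statistically indistinguishable
  # from the prestimulus window when nothing is planted
  cfg <- sim_config(n_channels = 2, n_trials = 20,
                    burst_amp = gc_matrix(control = c(0, 0, 0),
                                          patient = c(0, 0, 0)),
                    coupled_edges = matrix(integer(0), 0, 2), seed = 1L)
  spec <- wavelet_spec(freqs = seq(8.1, 12.6, 0.5))
  ratio <- vapply(1:24, function(s) {
    cfg$seed <- s
    ep <- gen_epoch_set(cfg, "s1", "control", "self")
    tf <- evoked_power(ep, spec)
    band_window_mean(tf, c(8, 13), c(100, 300)) /
      band_window_mean(tf, c(8, 13), c(-250, -50))
  }, numeric(1))
  tt <- stats::t.test(log(ratio))
  expect_gt(tt$p.value, 0.01)
})

test_that("behavioral counts are binomial with the configured rates", {
  # control cell: p_hit(self) = 0.8, p_hit(other) = 0.65, p_fa = 0.3
  # both => expected SRM bias 0.15, recovered within 3 SE over seeds
  cfg <- tiny_sim(behavior = behavior_params(
    p_hit = gc_matrix(control = c(0.8, 0.65, 0.65),
                      patient = c(0.8, 0.65, 0.65)),
    p_fa = gc_matrix(control = rep(0.3, 3), patient = rep(0.3, 3))))
  bias <- vapply(1:1000, function(s) {
    cfg$seed <- s
    rec <- score_behavior(gen_behavior(cfg, "s1", "control"))
    rec$per_subject$srm_bias
  }, numeric(1))
  se <- sd(bias) / sqrt(length(bias))
  expect_lt(abs(mean(bias) - 0.15), 3 * se)

  # degenerate rates give exact scores
  cfg2 <- tiny_sim(behavior = behavior_params(
    p_hit = gc_matrix(control = rep(1, 3), patient = rep(1, 3)),
    p_fa = gc_matrix(control = rep(0, 3), patient = rep(0, 3))))
  rec <- score_behavior(gen_behavior(cfg2, "s1", "control"))
  expect_equal(rec$per_condition$recognition, rep(1, 3))
})

test_that("background noise has a 1/f spectrum", {
  cfg <- sim_config(n_channels = 2, n_trials = 60,
                    burst_amp = gc_matrix(control = c(0, 0, 0),
                                          patient = c(0, 0, 0)),
                    coupled_edges = matrix(integer(0), 0, 2), seed = 9L)
  ep <- gen_epoch_set(cfg, "s1", "control", "self")
  n <- dim(ep$data)[2]
  spec <- rowMeans(Mod(mvfft(ep$data[1, , ]))^2)[2:(n %/% 2)]
  f <- (1:(n %/% 2 - 1)) * ep$fs / n
  sel <- f >= 1 & f <= 100
  slope <- coef(lm(log(spec[sel]) ~ log(f[sel])))[2]
  expect_lt(abs(slope - (-1)), 0.15)
  # and the configured RMS is respected
  expect_lt(abs(sd(ep$data) - cfg$noise_sd) / cfg$noise_sd, 0.1)
})

test_that("increasing burst amplitude strictly increases evoked alpha power", {
  spec <- wavelet_spec(freqs = seq(8.1, 12.6, 0.5))
  pw <- vapply(c(0.5, 1, 2, 4), function(a) {
    cfg <- sim_config(n_channels = 2, n_trials = 10, noise_sd = 0,
                      subject_amp_cv = 0,
                      burst_amp = gc_matrix(control = rep(a, 3),
                                            patient = rep(a, 3)),
                      coupled_edges = matrix(integer(0), 0, 2), seed = 3L)
    band_window_mean(evoked_power(
      gen_epoch_set(cfg, "s1", "control", "self"), spec),
      c(8, 13), c(100, 300))
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
  # noise-free: quadratic in amplitude
  expect_equal(pw[3] / pw[2], 4, tolerance = 1e-6)
})

test_that("increasing coupling consistency increases coupled-edge PLI", {
  est <- vapply(c(0.6, 0.75, 0.9, 1.0), function(p) {
    cfg <- coupling_only_sim(p, n_trials = 40, seed = 11L)
    ep <- gen_epoch_set(cfg, "s1", "control", "self")
    ph <- band_analytic_phase(ep)
    window_pli(pli_timeseries(ph), c(100, 300))$m[1, 2]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("plain-text epoch container round-trips", {
  cfg <- tiny_sim(n_channels = 3, n_trials = 2)
  ep <- gen_epoch_set(cfg, "s1", "patient", "other")
  stem <- tempfile("s1_other")
  write_epochs(ep, stem)
  back <- read_epochs(stem)
  expect_equal(back$data, ep$data, tolerance = 1e-12)
  expect_identical(back$channel_labels, ep$channel_labels)
  expect_identical(back$condition, "other")
  expect_identical(back$group, "patient")
  expect_equal(back$fs, ep$fs)
})

test_that("configuration invariants are enforced", {
  expect_error(tiny_sim(coupling_consistency =
    gc_matrix(control = rep(0.4, 3), patient = rep(0.9, 3))),
    "coupling_consistency")
  expect_error(tiny_sim(behavior = behavior_params(
    p_hit = gc_matrix(control = rep(1.2, 3), patient = rep(0.5, 3)))),
    "probabilities")
  expect_error(tiny_sim(burst_window = c(700, 900)), "span")
  expect_error(tiny_sim(epoch_window = c(-300.7, 800)), "integer sample")
  expect_error(gen_epoch_set(tiny_sim(), "s1", "control", "bogus"))
  expect_error(gen_epoch_set(tiny_sim(), "s1", "dog", "self"))
})

test_that("correlated score generator plants the requested correlation", {
  r <- vapply(1:200, function(s)
    cor(gen_correlated_scores(n = 200, rho = 0.6, seed = s)$alpha_power,
        gen_correlated_scores(n = 200, rho = 0.6, seed = s)$srm_bias),
    numeric(1))
  expect_lt(abs(mean(r) - 0.6), 0.02)
})
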