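fs <- 500
tt_s <- (0:549) / fs

test_that("analytic phase of a tone advances at 2*pi*f rad/s", {
  tone <- sin(2 * pi * 10 * tt_s)
  ep <- make_epochs(array(tone, c(1, 550, 2)), channel_labels = "Cz")
  ph <- analytic_phase(ep, check_narrowband = FALSE)
  v <- which(ph$valid)
  slope <- mean(diff(unwrap_phase(ph$phase[1, v, 1]))) * fs
  expect_lt(abs(slope - 2 * pi * 10) / (2 * pi * 10), 0.01)
  # the trim removes exactly 100 ms (50 samples) per edge
  expect_equal(sum(!ph$valid), 100L)
  expect_false(any(ph$valid[1:50]))
  expect_false(any(ph$valid[501:550]))
})

test_that("phase differences reflect known delays", {
  tone <- sin(2 * pi * 10 * tt_s)
  # identical channels: delta phi = 0 everywhere
  ep <- make_epochs(array(rep(tone, 2), c(550, 2, 1)) |>
                      aperm(c(2, 1, 3)), channel_labels = c("a", "b"))
  ph <- analytic_phase(ep, check_narrowband = FALSE)
  v <- which(ph$valid)
  expect_equal(max(abs(ph$phase[1, v, 1] - ph$phase[2, v, 1])), 0)

  # 25 ms delay at 10 Hz = quarter cycle => delta phi ~ pi/2
  v <- 51:500
  delayed <- sin(2 * pi * 10 * (tt_s - 0.025))
  ep2 <- make_epochs(aperm(array(c(tone, delayed), c(550, 2, 1)),
                           c(2, 1, 3)), channel_labels = c("a", "b"))
  ph2 <- analytic_phase(ep2, check_narrowband = FALSE)
  d <- ph2$phase[1, v, 1] - ph2$phase[2, v, 1]
  d <- atan2(sin(d), cos(d))
  expect_lt(max(abs(d - pi / 2)), 0.02)

  # broadband input triggers the narrow-band warning
  set.seed(4)
  epw <- make_epochs(array(rnorm(550 * 2), c(1, 550, 2)),
                     channel_labels = "Cz")
  expect_warning(analytic_phase(epw), "narrow-band")
})

test_that("PLI follows the sign-consistency formula", {
  # all-positive lags: PLI = 1 at every valid sample
  ph <- array(0, c(2, 550, 4))
  set.seed(1)
  ph[1, , ] <- runif(550 * 4, -pi, pi)
  ph[2, , ] <- ph[1, , ] - 0.5
  pt <- make_phase_tensor(ph)
  ser <- pli_timeseries(pt)
  expect_true(all(ser$pli[1, ser$valid] == 1))

  # sign pattern (+, +, -, +) across four trials: PLI = 0.5
  ph2 <- array(0, c(2, 550, 4))
  ph2[1, , ] <- runif(550 * 4, -pi, pi)
  off <- c(0.5, 0.5, -0.5, 0.5)
  for (tr in 1:4) ph2[2, , tr] <- ph2[1, , tr] - off[tr]
  ser2 <- pli_timeseries(make_phase_tensor(ph2))
  expect_true(all(abs(ser2$pli[1, ser2$valid] - 0.5) < 1e-12))
})

test_that("zero-lag (volume-conduction-like) copies give PLI exactly 0", {
  set.seed(7)
  x <- matrix(rnorm(550 * 6), 550, 6)
  ep <- make_epochs(aperm(array(c(x, 0.5 * x), c(550, 6, 2)), c(3, 1, 2)),
                    channel_labels = c("a", "b"))
  # second channel is an exactly scaled copy: analytic signals share
  # their argument, sign(0) = 0 at every sample and trial
  ph <- analytic_phase(ep, check_narrowband = FALSE)
  ser <- pli_timeseries(ph)
  expect_true(all(ser$pli[1, ser$valid] == 0))
})

test_that("vectorized PLI equals the naive per-trial loop", {
  set.seed(33)
  for (r in 1:25) {
    n_ch <- sample(2:4, 1); n_s <- sample(10:25, 1); n_tr <- sample(2:8, 1)
    ph <- array(runif(n_ch * n_s * n_tr, -pi, pi), c(n_ch, n_s, n_tr))
    pt <- make_phase_tensor(ph, valid = rep(TRUE, n_s))
    got <- pli_timeseries(pt)
    want <- naive_pli(ph)
    expect_equal(got$pli, want, tolerance = 1e-15)
  }
})

test_that("PLI is bounded and invariant to channel-order swap", {
  set.seed(9)
  for (r in 1:20) {
    ph <- array(runif(3 * 30 * 6, -pi, pi), c(3, 30, 6))
    ser <- pli_timeseries(make_phase_tensor(ph, valid = rep(TRUE, 30)))
    expect_true(all(ser$pli >= 0 & ser$pli <= 1))
    # swapping the two channels of a pair leaves PLI unchanged
    ph_sw <- ph[c(2, 1, 3), , ]
    ser_sw <- pli_timeseries(make_phase_tensor(ph_sw,
                                               valid = rep(TRUE, 30)))
    expect_equal(ser$pli[1, ], ser_sw$pli[1, ])
  }
})

test_that("window averaging of PLI series is exact and guarded", {
  ph <- array(runif(2 * 550 * 4, -pi, pi), c(2, 550, 4))
  pt <- make_phase_tensor(ph)
  ser <- pli_timeseries(pt)
  # constant series: every off-diagonal entry equals the constant
  ser$pli[1, ] <- 0.3
  m <- window_pli(ser, c(100, 300))
  expect_equal(m$m[1, 2], 0.3)
  expect_equal(m$m, t(m$m))
  expect_equal(diag(m$m), c(Ch01 = 0, Ch02 = 0))

  # hand-averaged three-sample toy window
  ser$pli[1, ] <- NA
  ser$valid[] <- FALSE
  idx <- 201:203   # times 100, 102, 104 ms
  ser$valid[idx] <- TRUE
  ser$pli[1, idx] <- c(0.2, 0.4, 0.9)
  expect_equal(window_pli(ser, c(100, 106))$m[1, 2], mean(c(0.2, 0.4, 0.9)))

  # a window fully inside the trimmed edges errors
  trimmed <- make_phase_tensor(ph, valid = c(rep(FALSE, 50),
                                             rep(TRUE, 450),
                                             rep(FALSE, 50)))
  ser2 <- pli_timeseries(trimmed)
  expect_error(window_pli(ser2, c(-300, -250)), "valid")
})

test_that("mean strength is the upper-triangle average", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.2
  m[1, 3] <- m[3, 1] <- 0.4
  m[2, 3] <- m[3, 2] <- 0.6
  expect_equal(mean_strength(m), 0.4)
  expect_equal(mean_strength(matrix(0.3, 4, 4) - diag(0.3, 4)), 0.3)
})

test_that("edgewise maps: null, planted shift and permutation behave", {
  set.seed(15)
  mk <- function(vals) {
    m <- matrix(0, 4, 4)
    m[upper.tri(m)] <- vals
    structure(list(m = m + t(m), window = c(100, 300),
                   channel_labels = sprintf("Ch%02d", 1:4)),
              class = "pli_matrix")
  }
  base_vals <- replicate(10, runif(6, 0.1, 0.3), simplify = FALSE)
  act_null <- lapply(base_vals, mk)
  base <- lapply(base_vals, mk)
  em <- edge_significance(act_null, base)
  expect_true(all(!em$sig))

  # planted strong shift on edges 1-3 detected at p < 0.001
  act_shift <- lapply(base_vals, function(v) mk(v + c(1, 1, 1, 0, 0, 0)
                                                + rnorm(6, 0, 0.02)))
  base_j <- lapply(base_vals, function(v) mk(v + rnorm(6, 0, 0.02)))
  em2 <- edge_significance(act_shift, base_j)
  expect_true(all(em2$sig[1:3]))
  expect_true(em2$p_bonferroni[1] < 0.05)

  # paired variant runs and is at least as sensitive here
  em3 <- edge_significance(act_shift, base_j, paired = TRUE)
  expect_true(all(em3$sig[1:3]))

  # permutation of subject labels keeps the family-wise rate nominal
  pool <- lapply(1:20, function(i) mk(runif(6, 0.1, 0.3)))
  rej <- vapply(1:100, function(r) {
    idx <- sample(20, 10)
    em <- edge_significance(pool[idx], pool[-idx])
    mean(em$p < 0.05)
  }, numeric(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("fused band+phase path matches the composed operators", {
  cfg <- tiny_sim(n_channels = 3, n_trials = 6, seed = 19L)
  ep <- gen_epoch_set(cfg, "s1", "control", "self")
  fused <- band_analytic_phase(ep, 8, 13)
  composed <- analytic_phase(bandpass(ep, 8, 13), check_narrowband = FALSE)
  v <- which(composed$valid)
  amp <- Mod(composed$analytic[, v, ])
  d <- abs(Arg(exp(1i * (fused$phase[, v, ] - composed$phase[, v, ]))))
  # phases agree except where the narrow-band amplitude is negligible
  # (phase is ill-conditioned near amplitude zeros)
  strong <- amp > stats::median(amp)
  expect_lt(stats::quantile(d[strong], 0.99), 0.1)
  # ~0.05 rad (3 degrees) is far below anything that could move a
  # sign-based PLI; residual differences come from padding strategy
  expect_lt(stats::median(d), 0.05)
  # and the resulting connectivity matrices are interchangeable
  m_f <- window_pli(pli_timeseries(fused), c(100, 300))$m
  m_c <- window_pli(pli_timeseries(composed), c(100, 300))$m
  expect_lt(max(abs(m_f - m_c)), 0.05)
})

test_that("estimated PLI tracks the binomial expectation of planted lags", {
  for (p in c(0.6, 0.9)) {
    est <- vapply(1:40, function(s) {
      cfg <- coupling_only_sim(p, n_trials = 30, seed = s)
      ep <- gen_epoch_set(cfg, "s1", "control", "self")
      window_pli(pli_timeseries(band_analytic_phase(ep)), c(100, 300))$m[1, 2]
    }, numeric(1))
    want <- binom_abs_mean(p, 30)
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - want), 3 * se + 1e-3)
  }
})
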