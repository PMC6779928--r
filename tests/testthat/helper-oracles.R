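# Independent oracles the implementation is checked against.
# Everything here is deliberately brute-force and shares no code with R/.

# Floyd-Warshall all-pairs shortest paths on a binary adjacency matrix
fw_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a != 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# graph metrics recomputed from Floyd-Warshall distances
fw_metrics <- function(a) {
  d <- fw_distances(a)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  off <- d[row(d) != col(d)]
  list(e_global = sum(inv) / (n * (n - 1)),
       char_path_length = mean(off[is.finite(off)]),
       e_nodal = rowSums(inv) / (n - 1))
}

# Erdos-Renyi-style random binary graph (possibly disconnected)
random_graph <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p)
  a + t(a)
}

# naive PLI: explicit per-trial, per-pair, per-sample loop with
# atan2-wrapped phase differences
naive_pli <- function(phase) {
  d <- dim(phase)
  n_ch <- d[1]; n_s <- d[2]; n_tr <- d[3]
  pairs <- which(upper.tri(diag(n_ch)), arr.ind = TRUE)
  pli <- matrix(NA_real_, nrow(pairs), n_s)
  for (e in seq_len(nrow(pairs))) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    for (t in seq_len(n_s)) {
      s <- 0
      for (tr in seq_len(n_tr)) {
        dphi <- phase[i, t, tr] - phase[j, t, tr]
        wrapped <- atan2(sin(dphi), cos(dphi))
        s <- s + sign(wrapped)
      }
      pli[e, t] <- abs(s) / n_tr
    }
  }
  pli
}

# classical split-plot sums-of-squares, written out longhand
anova_ss_oracle <- function(values, group) {
  G <- length(unique(group))
  C <- ncol(values)
  n <- nrow(values) / G
  grand <- mean(values)
  subj_means <- rowMeans(values)
  grp_means <- tapply(subj_means, group, mean)[unique(group)]
  cond_means <- colMeans(values)
  ss_between_subj <- C * sum((subj_means - grand)^2)
  ss_group <- n * C * sum((grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_cond <- n * G * sum((cond_means - grand)^2)
  gc_means <- matrix(NA_real_, G, C)
  for (g in seq_len(G)) for (c in seq_len(C))
    gc_means[g, c] <- mean(values[group == unique(group)[g], c])
  ss_gc <- n * sum((gc_means -
                      outer(grp_means, rep(1, C)) -
                      outer(rep(1, G), cond_means) + grand)^2)
  ss_total <- sum((values - grand)^2)
  ss_err_within <- ss_total - ss_between_subj - ss_cond - ss_gc
  f_group <- (ss_group / (G - 1)) / (ss_subj_within / (G * (n - 1)))
  f_cond <- (ss_cond / (C - 1)) / (ss_err_within / ((C - 1) * G * (n - 1)))
  f_gc <- (ss_gc / ((G - 1) * (C - 1))) /
    (ss_err_within / ((C - 1) * G * (n - 1)))
  list(F_group = f_group, F_cond = f_cond, F_interaction = f_gc)
}

# exact expectation of |2 * Binomial(n, p) / n - 1| by enumeration
binom_abs_mean <- function(p, n) {
  b <- 0:n
  sum(stats::dbinom(b, n, p) * abs(2 * b / n - 1))
}

# cumulative phase unwrapping
unwrap_phase <- function(p) {
  d <- diff(p)
  cumsum(c(p[1], atan2(sin(d), cos(d))))
}

# build a phase tensor object directly (bypassing any signal path)
make_phase_tensor <- function(phase, fs = 500, t0 = -300,
                              valid = rep(TRUE, dim(phase)[2])) {
  structure(list(phase = phase, valid = valid, fs = fs, t0 = t0,
                 channel_labels = sprintf("Ch%02d", seq_len(dim(phase)[1])),
                 analytic = NULL),
            class = "phase_tensor")
}

# small epoch-set builder around a channel x sample x trial array
make_epochs <- function(data, fs = 500, t0 = -300, ...) {
  eeg_epochs(data, fs = fs, t0 = t0, ...)
}

# minimal fast simulation configs for repeated draws
tiny_sim <- function(..., n_channels = 4, n_trials = 8, n_per_group = 3,
                     seed = 1L) {
  sim_config(n_channels = n_channels, n_trials = n_trials,
             n_per_group = n_per_group, seed = seed, ...)
}

# coupling-isolation config: no burst, no noise -- the regime in which
# PLI sign recovery is exact and matches the binomial closed form
coupling_only_sim <- function(p, n_trials = 70, seed = 1L, lag_ms = 8,
                              n_channels = 2,
                              edges = cbind(1L, 2L)) {
  sim_config(n_channels = n_channels, n_trials = n_trials, seed = seed,
             burst_amp = gc_matrix(control = c(0, 0, 0),
                                   patient = c(0, 0, 0)),
             noise_sd = 0,
             coupled_edges = edges, lag_ms = lag_ms,
             coupling_consistency = gc_matrix(control = rep(p, 3),
                                              patient = rep(p, 3)))
}
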