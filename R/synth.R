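#' Simulation configuration for a synthetic SRM-task EEG cohort
#'
#' Defines the full generative model for a two-group (control /
#' patient), three-condition (self / other / physical) event-related
#' EEG study with behavioral recognition counts. Each trial is 1/f
#' ("pink") background noise plus a Gaussian-windowed alpha burst whose
#' phase is fixed within subject (so it survives trial averaging, i.e.
#' it is *evoked*) and whose amplitude depends on group x condition.
#' Inter-channel coupling is planted on a configured edge set: all
#' channels of a coupled component share a narrow-band alpha source
#' (random phase per trial, so it contributes nothing to evoked power)
#' injected with channel-specific time lags whose common sign is
#' positive in a `coupling_consistency` fraction of trials and flipped
#' in the remainder -- exactly the sign-consistency the phase lag index
#' estimates.
#'
#' @param n_per_group subjects per group (default 18).
#' @param n_channels electrode count (default 59, the replica montage).
#' @param fs sampling rate, Hz (default 500).
#' @param epoch_window epoch extent in ms relative to stimulus onset,
#'   half-open `[pre, post)` (default `c(-300, 800)`, 550 samples).
#' @param n_trials trials per condition (default 70).
#' @param alpha_freq burst/coupling carrier frequency, Hz (default 10).
#' @param burst_window ms window holding the evoked burst (default
#'   `c(100, 300)`; the Gaussian envelope is centered in it with
#'   sd = width/4).
#' @param burst_amp 2 x 3 matrix (group x condition) of burst
#'   amplitudes, microvolts. Default: 2.0 everywhere except a 30%
#'   patient deficit in the self condition (1.4).
#' @param burst_phase_jitter half-width (radians) of the uniform
#'   per-trial phase jitter; 0 = perfectly phase-locked, `pi` = fully
#'   jittered (evoked power cancels ~ 1/N).
#' @param subject_amp_cv log-sd of the per-subject multiplicative
#'   amplitude factor (between-subject variability; default 0.2).
#' @param coupling_consistency 2 x 3 matrix of the per-trial
#'   probability (>= 0.5) that the lag sign on coupled edges is
#'   positive. Default 0.9 everywhere except 0.55 for patients in the
#'   self condition (near-abolished lag consistency).
#' @param coupled_edges 2-column integer matrix of channel pairs
#'   (i < j) carrying the planted coupling; default: all 6 pairs of
#'   the posterior cluster (P3/P4/O1/O2 on the 59-channel montage,
#'   last 4 channels otherwise).
#' @param coupling_amp amplitude (microvolts) of the shared coupled
#'   source (default 4, dominating the alpha-band noise floor).
#' @param lag_ms channel-to-channel lag step of the coupled source
#'   (default 8 ms; ranks within a coupled component are spaced by one
#'   step, and the largest spacing must stay under half an alpha cycle).
#' @param zero_lag_edges optional 2-column matrix of channel pairs that
#'   receive a common source at exactly zero lag -- the
#'   volume-conduction fixture PLI must be insensitive to.
#' @param zero_lag_amp amplitude of the zero-lag common source.
#' @param noise_exponent spectral slope of the 1/f^a background
#'   (default 1).
#' @param noise_sd RMS of the background noise, microvolts (default 5).
#' @param behavior list with `n_old`, `n_new` item counts and 2 x 3
#'   matrices `p_hit`, `p_fa` plus per-condition `rt_mean`, `rt_sd`
#'   (ms). Defaults plant a self-referential memory advantage in
#'   controls only, with hit rates chosen so expected recognition
#'   scores mirror a 0.49 / 0.35 (control self/other) vs 0.36 / 0.33
#'   (patient) regime at a common 0.30 false-alarm rate.
#' @param seed master integer seed; all per-subject streams derive
#'   from it deterministically.
#' @return a validated object of class `"sim_config"`.
#' @seealso [gen_epoch_set], [gen_behavior], [gen_cohort]
#' @export
sim_config <- function(n_per_group = 18L,
                       n_channels = 59L,
                       fs = 500,
                       epoch_window = c(-300, 800),
                       n_trials = 70L,
                       alpha_freq = 10,
                       burst_window = c(100, 300),
                       burst_amp = gc_matrix(control = c(2, 2, 2),
                                             patient = c(1.4, 2, 2)),
                       burst_phase_jitter = 0,
                       subject_amp_cv = 0.2,
                       coupling_consistency = gc_matrix(
                         control = c(0.9, 0.9, 0.9),
                         patient = c(0.55, 0.9, 0.9)),
                       coupled_edges = NULL,
                       coupling_amp = 4,
                       lag_ms = 8,
                       zero_lag_edges = NULL,
                       zero_lag_amp = 0,
                       noise_exponent = 1,
                       noise_sd = 5,
                       behavior = behavior_params(),
                       seed = 1L) {
  labels <- default_montage(n_channels)
  if (is.null(coupled_edges)) {
    post <- posterior_channels(labels)
    coupled_edges <- t(utils::combn(sort(post), 2L))
  }
  cfg <- structure(
    list(n_per_group = as.integer(n_per_group),
         n_channels = as.integer(n_channels), fs = fs,
         epoch_window = epoch_window, n_trials = as.integer(n_trials),
         alpha_freq = alpha_freq, burst_window = burst_window,
         burst_amp = burst_amp, burst_phase_jitter = burst_phase_jitter,
         subject_amp_cv = subject_amp_cv,
         coupling_consistency = coupling_consistency,
         coupled_edges = coupled_edges, coupling_amp = coupling_amp,
         lag_ms = lag_ms, zero_lag_edges = zero_lag_edges,
         zero_lag_amp = zero_lag_amp, noise_exponent = noise_exponent,
         noise_sd = noise_sd, behavior = behavior,
         channel_labels = labels, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Build a group x condition parameter matrix
#'
#' @param control,patient numeric length-3 vectors ordered
#'   (self, other, physical).
#' @return 2 x 3 matrix with dimnames group x condition.
#' @export
gc_matrix <- function(control, patient) {
  m <- rbind(control = control, patient = patient)
  colnames(m) <- c("self", "other", "physical")
  m
}

#' @rdname sim_config
#' @param n_old,n_new old/new item counts of the recognition test.
#' @param p_hit,p_fa 2 x 3 hit and false-alarm probability matrices.
#' @param rt_mean,rt_sd per-condition reaction-time mean/sd (ms),
#'   ordered (self, other, physical).
#' @export
behavior_params <- function(n_old = 70L, n_new = 30L,
                            p_hit = gc_matrix(control = c(0.79, 0.65, 0.65),
                                              patient = c(0.66, 0.63, 0.65)),
                            p_fa = gc_matrix(control = c(0.3, 0.3, 0.3),
                                             patient = c(0.3, 0.3, 0.3)),
                            rt_mean = c(self = 999.4, other = 1032.9,
                                        physical = 630.5),
                            rt_sd = c(self = 159, other = 195.9,
                                      physical = 101.4)) {
  list(n_old = as.integer(n_old), n_new = as.integer(n_new),
       p_hit = p_hit, p_fa = p_fa, rt_mean = rt_mean, rt_sd = rt_sd)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_per_group >= 1L, cfg$n_channels >= 2L, cfg$fs > 0,
            cfg$n_trials >= 1L)
  if (any(cfg$behavior$p_hit < 0 | cfg$behavior$p_hit > 1) ||
      any(cfg$behavior$p_fa < 0 | cfg$behavior$p_fa > 1))
    stop("behavior probabilities must lie in [0, 1]")
  if (any(cfg$coupling_consistency < 0.5 | cfg$coupling_consistency > 1))
    stop("coupling_consistency must lie in [0.5, 1]")
  if (cfg$behavior$n_old <= 0L || cfg$behavior$n_new <= 0L)
    stop("n_old and n_new must be positive")
  w <- cfg$epoch_window
  if (!(w[1] <= cfg$burst_window[1] && cfg$burst_window[2] <= w[2]))
    stop("epoch_window must span burst_window")
  n_samp <- (w[2] - w[1]) * cfg$fs / 1000
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("fs x epoch length must be an integer sample count")
  if (!is.null(cfg$coupled_edges) && nrow(cfg$coupled_edges) > 0) {
    ce <- cfg$coupled_edges
    stopifnot(is.matrix(ce), ncol(ce) == 2L)
    if (any(ce < 1L | ce > cfg$n_channels) || any(ce[, 1L] >= ce[, 2L]))
      stop("coupled_edges must be pairs i < j within the montage")
    comp <- edge_components(ce, cfg$n_channels)
    max_rank <- max(vapply(comp, length, 1L)) - 1L
    if (max_rank * cfg$lag_ms * cfg$alpha_freq / 1000 >= 0.5)
      warning("largest coupled-component lag spread reaches half an ",
              "alpha cycle; pairwise lag signs may alias")
  }
  invisible(cfg)
}

# connected components of the coupled-edge graph; each component is a
# sorted vector of channel indices whose position (minus 1) is the lag rank
edge_components <- function(edges, n_channels) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_channels - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  used <- sort(unique(as.vector(edges)))
  comps <- split(used, memb[used])
  lapply(unname(comps), sort)
}

#' Generate one subject-by-condition epoch set
#'
#' Draws `n_trials` epochs of `n_channels x samples` according to the
#' generative model of [sim_config]. The per-subject amplitude factor
#' and burst phase come from a subject-level seed stream (shared across
#' conditions, giving a subject random effect); noise, trial jitter and
#' coupling signs come from a subject-by-condition stream, all derived
#' deterministically from `config$seed`.
#'
#' @param config a [sim_config] object.
#' @param subject_id subject identifier string.
#' @param group `"control"` or `"patient"`.
#' @param condition `"self"`, `"other"` or `"physical"`.
#' @param seed optional explicit seed overriding the derived stream.
#' @return an [eeg_epochs] object.
#' @examples
#' cfg <- sim_config(n_channels = 4, n_trials = 5, seed = 7)
#' ep <- gen_epoch_set(cfg, "c01", "control", "self")
#' dim(ep$data)
#' @export
gen_epoch_set <- function(config, subject_id, group,
                          condition = c("self", "other", "physical"),
                          seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  group <- match.arg(group, c("control", "patient"))
  n_ch <- config$n_channels
  fs <- config$fs
  n_samp <- round((config$epoch_window[2] - config$epoch_window[1]) *
                    fs / 1000)
  n_tr <- config$n_trials
  t_ms <- config$epoch_window[1] + (seq_len(n_samp) - 1L) * 1000 / fs

  # subject-level quantities (identical for all conditions of a subject)
  subj <- with_seed(mix_seed(config$seed, subject_id), list(
    amp_factor = exp(stats::rnorm(1L, 0, config$subject_amp_cv)),
    burst_phase = stats::runif(1L, 0, 2 * pi)))

  if (is.null(seed)) seed <- mix_seed(config$seed, subject_id,
                                      cond_index(condition))
  with_seed(seed, {
    data <- if (config$noise_sd > 0)
      config$noise_sd * pink_noise(n_samp, n_ch * n_tr,
                                   config$noise_exponent)
    else matrix(0, n_samp, n_ch * n_tr)
    dim(data) <- c(n_samp, n_ch, n_tr)

    amp <- config$burst_amp[group, condition] * subj$amp_factor
    bw <- config$burst_window
    center <- mean(bw)
    cenv <- exp(-(t_ms - center)^2 / (2 * ((bw[2] - bw[1]) / 2)^2))
    if (amp != 0) {
      env <- exp(-(t_ms - center)^2 / (2 * ((bw[2] - bw[1]) / 4)^2))
      jit <- if (config$burst_phase_jitter > 0)
        stats::runif(n_tr, -config$burst_phase_jitter,
                     config$burst_phase_jitter) else numeric(n_tr)
      ph <- outer(2 * pi * config$alpha_freq * (t_ms - center) / 1000,
                  subj$burst_phase + jit, "+")
      burst <- (amp * env) * cos(ph)              # samples x trials
      data <- data + aperm(array(burst, c(n_samp, n_tr, n_ch)),
                           c(1L, 3L, 2L))
    }

    # planted lag-consistent coupling
    if (!is.null(config$coupled_edges) && nrow(config$coupled_edges) > 0 &&
        config$coupling_amp != 0) {
      p <- config$coupling_consistency[group, condition]
      comps <- edge_components(config$coupled_edges, n_ch)
      omega <- 2 * pi * config$alpha_freq / 1000   # rad per ms
      for (comp in comps) {
        psi <- stats::runif(n_tr, 0, 2 * pi)
        s <- ifelse(stats::runif(n_tr) < p, 1, -1)
        for (r in seq_along(comp)) {
          lag <- (r - 1L) * config$lag_ms
          ph <- outer(omega * t_ms, psi, "+") -
            rep(omega * lag * s, each = n_samp)
          data[, comp[r], ] <- data[, comp[r], ] +
            config$coupling_amp * cenv * cos(ph)
        }
      }
    }

    # zero-lag common source (volume-conduction fixture)
    if (!is.null(config$zero_lag_edges) && config$zero_lag_amp != 0) {
      comps <- edge_components(config$zero_lag_edges, n_ch)
      omega <- 2 * pi * config$alpha_freq / 1000
      for (comp in comps) {
        psi <- stats::runif(n_tr, 0, 2 * pi)
        src <- config$zero_lag_amp * cenv * cos(outer(omega * t_ms, psi, "+"))
        for (ch in comp) data[, ch, ] <- data[, ch, ] + src
      }
    }

    eeg_epochs(aperm(data, c(2L, 1L, 3L)), fs = fs,
               t0 = config$epoch_window[1],
               channel_labels = config$channel_labels,
               condition = condition, subject_id = subject_id,
               group = group)
  })
}

# Pink (1/f^a) noise, samples x series, unit variance per series in
# expectation. Synthesized directly in the frequency domain with
# Hermitian symmetry (one inverse FFT).
pink_noise <- function(n, m, exponent = 1) {
  k_pos <- seq_len((n - 1L) %/% 2L)             # positive-freq bins
  has_nyq <- n %% 2L == 0L
  w_pos <- k_pos^(-exponent / 2)
  w_nyq <- if (has_nyq) (n / 2)^(-exponent / 2) else numeric(0)
  # normalization so Var(x_t) = 1
  tot <- 2 * sum(w_pos^2) + sum(w_nyq^2)
  scl <- n / sqrt(tot)
  f <- matrix(0 + 0i, n, m)
  np <- length(k_pos)
  re <- matrix(stats::rnorm(np * m), np, m)
  im <- matrix(stats::rnorm(np * m), np, m)
  f[k_pos + 1L, ] <- (w_pos * scl / sqrt(2)) * complex(real = re,
                                                       imaginary = im)
  if (has_nyq)
    f[n %/% 2L + 1L, ] <- (w_nyq * scl) * stats::rnorm(m)
  f[n + 1L - k_pos, ] <- Conj(f[k_pos + 1L, , drop = FALSE])
  Re(mvfft(f, inverse = TRUE)) / n
}

#' Generate behavioral recognition counts for one subject
#'
#' Per condition, hits ~ Binomial(`n_old`, `p_hit[group, condition]`)
#' and false alarms ~ Binomial(`n_new`, `p_fa[group, condition]`);
#' reaction time is the per-subject mean RT over correct responses,
#' drawn as Normal(`rt_mean`, `rt_sd` / sqrt(n_old)). Recognition and
#' SRM bias scores are *not* computed here -- see [score_behavior].
#'
#' @inheritParams gen_epoch_set
#' @return a `data.frame` (class `"behavioral_record"`) with one row
#'   per condition: counts, `n_old`, `n_new`, `mean_rt`, plus subject
#'   metadata.
#' @export
gen_behavior <- function(config, subject_id, group, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  group <- match.arg(group, c("control", "patient"))
  b <- config$behavior
  if (is.null(seed)) seed <- mix_seed(config$seed, subject_id, 97L)
  conds <- c("self", "other", "physical")
  with_seed(seed, {
    hits <- stats::rbinom(3L, b$n_old, b$p_hit[group, conds])
    fas <- stats::rbinom(3L, b$n_new, b$p_fa[group, conds])
    rt <- stats::rnorm(3L, b$rt_mean[conds], b$rt_sd[conds] / sqrt(b$n_old))
    out <- data.frame(subject_id = subject_id, group = group,
                      condition = conds, n_old = b$n_old, n_new = b$n_new,
                      hits = hits, false_alarms = fas, mean_rt = rt,
                      stringsAsFactors = FALSE)
    class(out) <- c("behavioral_record", "data.frame")
    out
  })
}

#' Generate a full synthetic cohort
#'
#' `n_per_group` subjects per group, three conditions each, with all
#' per-subject seeds derived deterministically from `config$seed`
#' (regeneration with the same config is bit-identical). The returned
#' ground truth records every planted contrast, so downstream tests
#' know what the data contain.
#'
#' With the replica montage (59 channels, 70 trials) a materialized
#' cohort is large; `materialize_epochs = FALSE` returns only subjects,
#' behavior and ground truth, and callers regenerate epoch sets on
#' demand via [gen_epoch_set] (bit-identical by seed derivation).
#'
#' @param config a [sim_config] object.
#' @param materialize_epochs keep all epoch sets in memory?
#' @return list of class `"synthetic_cohort"` with elements `subjects`
#'   (data.frame id/group), `epoch_sets` (nested list subject ->
#'   condition, if materialized), `behavior` (row-bound
#'   behavioral records) and `ground_truth`.
#' @export
gen_cohort <- function(config, materialize_epochs = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- data.frame(
    subject_id = c(sprintf("ctrl%02d", seq_len(config$n_per_group)),
                   sprintf("pat%02d", seq_len(config$n_per_group))),
    group = rep(c("control", "patient"), each = config$n_per_group),
    stringsAsFactors = FALSE)
  behavior <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i)
    gen_behavior(config, subjects$subject_id[i], subjects$group[i])))
  epoch_sets <- NULL
  if (materialize_epochs) {
    epoch_sets <- lapply(seq_len(nrow(subjects)), function(i) {
      sets <- lapply(c("self", "other", "physical"), function(cond)
        gen_epoch_set(config, subjects$subject_id[i], subjects$group[i],
                      cond))
      names(sets) <- c("self", "other", "physical")
      sets
    })
    names(epoch_sets) <- subjects$subject_id
  }
  gt <- cohort_ground_truth(config)
  structure(list(subjects = subjects, epoch_sets = epoch_sets,
                 behavior = behavior, ground_truth = gt, config = config),
            class = "synthetic_cohort")
}

# Planted-effect summary fully determining downstream expectations.
cohort_ground_truth <- function(config) {
  b <- config$behavior
  rec <- b$p_hit - array(b$p_fa, dim(b$p_hit), dimnames(b$p_hit))
  cc <- config$coupling_consistency
  epli <- cc
  epli[] <- vapply(as.vector(cc), expected_pli, numeric(1),
                   n_trials = config$n_trials)
  # Patients with weaker lag consistency on the clustered posterior
  # edge set lose those edges from the top of the PLI ranking; at fixed
  # sparsity their binary networks spread the same edge budget over
  # more dispersed (noise-ranked) pairs instead of a redundant clique,
  # which raises global efficiency. Sign convention: +1 means
  # patient > control in the self condition.
  net_sign <- if (cc["patient", "self"] < cc["control", "self"]) 1 else 0
  list(burst_amp = config$burst_amp,
       evoked_power_ratio = (config$burst_amp / config$burst_amp[1, 1])^2,
       coupling_consistency = cc,
       expected_coupled_pli = epli,
       coupled_edges = config$coupled_edges,
       expected_recognition = rec,
       expected_srm_bias = rec[, "self"] - rec[, "other"],
       network_contrast = list(metric = "e_global_auc",
                               condition = "self", sign = net_sign))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects x 3 conditions (seed %d)\n",
              nrow(x$subjects), x$config$seed))
  cat(sprintf("  epochs %s | %d channels, %d trials/condition\n",
              if (is.null(x$epoch_sets)) "not materialized" else "materialized",
              x$config$n_channels, x$config$n_trials))
  invisible(x)
}

#' Expected PLI for a planted sign-consistency
#'
#' For `n_trials` trials whose lag sign is positive with probability
#' `p`, the number of positive signs is `B ~ Binomial(n, p)` and the
#' phase lag index is `|2B/n - 1|`. This evaluates its exact
#' expectation by enumeration -- the closed-form oracle the estimator
#' is checked against.
#'
#' @param p sign-consistency probability.
#' @param n_trials number of trials.
#' @return expected PLI in `[0, 1]`.
#' @examples
#' expected_pli(1, 70)    # 1
#' expected_pli(0.5, 70)  # the finite-N noise floor, ~0.095
#' @export
expected_pli <- function(p, n_trials) {
  b <- 0:n_trials
  sum(stats::dbinom(b, n_trials, p) * abs(2 * b / n_trials - 1))
}

#' Subject-level scores with a planted power-bias correlation
#'
#' Generates per-subject (evoked alpha power, SRM bias) pairs from a
#' bivariate normal with correlation `rho` -- the subject-summary-level
#' regime used to study how well Pearson/regression recover a planted
#' brain-behavior association at small n.
#'
#' @param n subjects (default 18).
#' @param rho planted correlation (default 0.6).
#' @param power_mean,power_sd evoked alpha power scale (microvolt^2).
#' @param bias_mean,bias_sd SRM bias scale.
#' @param seed integer seed.
#' @return data.frame with columns `alpha_power`, `srm_bias`.
#' @export
gen_correlated_scores <- function(n = 18L, rho = 0.6, power_mean = 1,
                                  power_sd = 0.3, bias_mean = 0.03,
                                  bias_sd = 0.08, seed = 1L) {
  stopifnot(abs(rho) <= 1, n >= 3L)
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    data.frame(
      alpha_power = power_mean + power_sd * z1,
      srm_bias = bias_mean + bias_sd * (rho * z1 + sqrt(1 - rho^2) * z2))
  })
}
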