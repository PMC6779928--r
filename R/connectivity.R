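#' Instantaneous phase via the Hilbert analytic signal
#'
#' Computes the analytic signal of every channel x trial series with
#' the standard FFT construction and returns its argument as the
#' instantaneous phase in (-pi, pi]. Because the transform is unstable
#' near the series ends, the first and last 100 ms are flagged invalid
#' (50 samples per edge at 500 Hz) and excluded from all downstream
#' PLI aggregates.
#'
#' The input must already be narrow-band (alpha, 8-13 Hz) for the
#' phase to be meaningful; a spectral-spread check warns otherwise.
#'
#' @param epochs an [eeg_epochs] object, alpha-band filtered.
#' @param trim_ms edge trim per side in ms (default 100).
#' @param check_narrowband warn when the signal does not look
#'   narrow-band?
#' @return object of class `"phase_tensor"`: list with `phase`
#'   (channel x sample x trial, radians), `valid` (per-sample logical),
#'   `fs`, `t0`, `channel_labels`, and the complex `analytic` tensor.
#' @export
analytic_phase <- function(epochs, trim_ms = 100, check_narrowband = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  n <- d[2L]
  m <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), n, d[1L] * d[3L])
  if (check_narrowband && !is_narrowband(m, epochs$fs))
    warning("input does not look narrow-band; Hilbert phase may be ",
            "uninterpretable (band-pass to 8-13 Hz first)")
  z <- analytic_columns(m)
  analytic <- aperm(array(z, c(n, d[1L], d[3L])), c(2L, 1L, 3L))
  phase <- Arg(analytic)
  n_trim <- round(trim_ms * epochs$fs / 1000)
  valid <- rep(TRUE, n)
  if (n_trim > 0) {
    valid[seq_len(min(n_trim, n))] <- FALSE
    valid[seq.int(max(1L, n - n_trim + 1L), n)] <- FALSE
  }
  if (!any(valid)) stop("edge trimming removed every sample")
  structure(list(phase = phase, valid = valid, fs = epochs$fs,
                 t0 = epochs$t0, channel_labels = epochs$channel_labels,
                 analytic = analytic),
            class = "phase_tensor")
}

# analytic signal of each column via FFT (h-weights construction)
analytic_columns <- function(m) {
  n <- nrow(m)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n %/% 2L + 1L] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) %/% 2L)] <- 2
  }
  mvfft(mvfft(m) * h, inverse = TRUE) / n
}

# crude narrow-band check: fraction of spectral power inside the
# dominant third-octave neighbourhood of the peak frequency
is_narrowband <- function(m, fs, min_fraction = 0.6) {
  n <- nrow(m)
  spec <- rowSums(Mod(mvfft(m))^2)[seq_len(n %/% 2L + 1L)]
  spec[1L] <- 0
  f <- (seq_along(spec) - 1L) * fs / n
  pk <- f[which.max(spec)]
  if (pk == 0) return(FALSE)
  inb <- f >= pk / 1.6 & f <= pk * 1.6
  sum(spec[inb]) / sum(spec) >= min_fraction
}

#' Across-trial PLI time series for every channel pair
#'
#' For each pair (i < j) and valid sample t, the phase lag index is
#' `PLI_ij(t) = | mean_n sign(delta_phi_ij(t, n)) |` with the phase
#' difference wrapped to (-pi, pi] before the sign and `sign(0) = 0`.
#' The sign convention makes exactly zero-lag coupling -- the signature
#' of volume conduction -- contribute nothing.
#'
#' @param phases a `"phase_tensor"` from [analytic_phase].
#' @param samples optional integer subset of sample indices to compute
#'   (intersected with the valid mask); default: all valid samples.
#' @return object of class `"pli_series"`: `pli` (pair x sample matrix,
#'   entries in \[0, 1\], `NA` at uncomputed samples), `pairs`
#'   (2-column index matrix), `valid`, `fs`, `t0`, `channel_labels`.
#' @export
pli_timeseries <- function(phases, samples = NULL) {
  stopifnot(inherits(phases, "phase_tensor"))
  d <- dim(phases$phase)
  n_ch <- d[1L]; n_s <- d[2L]; n_tr <- d[3L]
  if (n_tr < 2L) stop("PLI needs at least 2 trials")
  keep <- if (is.null(samples)) which(phases$valid)
          else intersect(samples, which(phases$valid))
  if (length(keep) == 0L) stop("no valid samples selected")
  pr <- which(upper.tri(diag(n_ch)), arr.ind = TRUE)  # canonical order
  ip <- pr[, "row"]
  jp <- pr[, "col"]
  # sign(wrapped phase diff) == sign(Im(z_i conj(z_j))) for unit (or any
  # positive-modulus) phasors -- computed vectorized over pairs
  z <- if (!is.null(phases$analytic)) phases$analytic
       else exp(1i * phases$phase)
  z <- z[, keep, , drop = FALSE]
  zm <- matrix(z, n_ch, length(keep) * n_tr)
  sgn <- sign(Im(zm[ip, , drop = FALSE] * Conj(zm[jp, , drop = FALSE])))
  dim(sgn) <- c(length(ip) * length(keep), n_tr)
  pli_keep <- abs(sgn %*% rep(1 / n_tr, n_tr))
  pli <- matrix(NA_real_, length(ip), n_s)
  pli[, keep] <- pli_keep
  valid <- logical(n_s)
  valid[keep] <- TRUE
  structure(list(pli = pli, pairs = cbind(i = ip, j = jp), valid = valid,
                 fs = phases$fs, t0 = phases$t0,
                 channel_labels = phases$channel_labels),
            class = "pli_series")
}

#' Window-averaged PLI connectivity matrix
#'
#' Averages each pair's PLI over the valid samples of a ms window and
#' symmetrizes into a channel x channel matrix (zero diagonal).
#'
#' @param series a `"pli_series"`.
#' @param window length-2 ms window, half-open `[start, end)`.
#' @return object of class `"pli_matrix"`: symmetric matrix `m` with
#'   entries in \[0, 1\], plus the `window` tag and channel labels.
#' @export
window_pli <- function(series, window) {
  stopifnot(inherits(series, "pli_series"))
  n_s <- ncol(series$pli)
  times <- series$t0 + (seq_len(n_s) - 1L) * 1000 / series$fs
  ti <- intersect(window_samples(times, window), which(series$valid))
  if (length(ti) == 0L)
    stop("window contains no valid samples (check edge trimming)")
  v <- rowMeans(series$pli[, ti, drop = FALSE])
  n_ch <- length(series$channel_labels)
  m <- matrix(0, n_ch, n_ch,
              dimnames = list(series$channel_labels, series$channel_labels))
  m[series$pairs] <- v
  m <- m + t(m)
  structure(list(m = m, window = window,
                 channel_labels = series$channel_labels),
            class = "pli_matrix")
}

#' Mean PLI connectivity strength
#'
#' Mean of the upper-triangle entries of a PLI matrix -- the scalar
#' connectivity strength summarized per subject and window.
#'
#' @param x a `"pli_matrix"` (or a plain symmetric matrix).
#' @return scalar in \[0, 1\].
#' @export
mean_strength <- function(x) {
  m <- if (inherits(x, "pli_matrix")) x$m else x
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  mean(m[upper.tri(m)])
}

#' Edgewise active-vs-baseline significance map
#'
#' Per edge, a two-sample t-test (independent by default, following
#' the active-vs-baseline comparison as reported; `paired = TRUE`
#' gives the statistically more natural paired variant) between
#' per-subject PLI values in the active and baseline windows. Returns
#' raw p, Bonferroni-adjusted p (factor = number of edges), and the
#' display mask at the uncorrected threshold.
#'
#' @param active,baseline lists of `"pli_matrix"` objects, one per
#'   subject, in matching order.
#' @param threshold uncorrected display threshold (default 0.001).
#' @param paired use a paired t-test across subjects?
#' @return data.frame with one row per edge: `i`, `j`, `t`, `df`, `p`,
#'   `p_bonferroni`, `sig`.
#' @export
edge_significance <- function(active, baseline, threshold = 0.001,
                              paired = FALSE) {
  stopifnot(length(active) == length(baseline), length(active) >= 2L)
  amat <- vapply(active, function(x) x$m[upper.tri(x$m)],
                 numeric(sum(upper.tri(active[[1L]]$m))))
  bmat <- vapply(baseline, function(x) x$m[upper.tri(x$m)],
                 numeric(nrow(amat)))
  n_ch <- nrow(active[[1L]]$m)
  idx <- which(upper.tri(diag(n_ch)), arr.ind = TRUE)
  res <- lapply(seq_len(nrow(amat)), function(e) {
    a <- amat[e, ]; b <- bmat[e, ]
    tt <- if (paired) {
      d <- a - b
      if (stats::var(d) == 0)
        return(data.frame(t = NA_real_, df = length(d) - 1L, p = NA_real_))
      ht <- stats::t.test(d)
      data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
    } else {
      if (stats::var(a) == 0 && stats::var(b) == 0)
        return(data.frame(t = NA_real_, df = length(a) + length(b) - 2L,
                          p = NA_real_))
      st <- ttest_ind(a, b)
      data.frame(t = st$statistic, df = st$df, p = st$p)
    }
    tt
  })
  out <- cbind(data.frame(i = idx[, "row"], j = idx[, "col"]),
               do.call(rbind, res))
  out$p_bonferroni <- bonferroni(out$p)
  out$sig <- !is.na(out$p) & out$p < threshold
  out
}

#' Band-limited instantaneous phase in one pass
#'
#' Fuses the alpha band-pass and the Hilbert analytic signal into a
#' single padded FFT round: the Butterworth band gain and the
#' analytic-signal weights are applied together. Equivalent to
#' [bandpass] followed by [analytic_phase] away from the (trimmed)
#' epoch edges -- the equivalence is unit-tested -- at half the
#' transform cost, which matters when cohorts are re-simulated many
#' times.
#'
#' @param epochs an [eeg_epochs] object (broadband).
#' @param lo,hi band edges in Hz (default alpha, 8-13).
#' @param trim_ms edge trim per side in ms (default 100).
#' @param prefilter optional broadband band (Hz pair, e.g.
#'   `c(0.1, 30)`) whose zero-phase gain is composed with the alpha
#'   band gain -- equivalent to running [bandpass] with that band
#'   first.
#' @return a `"phase_tensor"` (see [analytic_phase]).
#' @export
band_analytic_phase <- function(epochs, lo = 8, hi = 13, trim_ms = 100,
                                prefilter = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  n <- d[2L]
  fs <- epochs$fs
  m <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), n, d[1L] * d[3L])
  pad <- min(n - 1L, 128L)
  mp <- rbind(m[(pad + 1L):2L, , drop = FALSE], m,
              m[(n - 1L):(n - pad), , drop = FALSE])
  np <- nrow(mp)
  f <- c(0:(np %/% 2L), -((np - np %/% 2L - 1L):1L)) * fs / np
  g <- butter_gain(lo, hi)(abs(f))
  if (!is.null(prefilter))
    g <- g * butter_gain(prefilter[1], prefilter[2])(abs(f))
  h <- numeric(np)
  if (np %% 2L == 0L) { h[1L] <- 1; h[np %/% 2L + 1L] <- 1; h[2:(np %/% 2L)] <- 2 }
  else { h[1L] <- 1; h[2:((np + 1L) %/% 2L)] <- 2 }
  z <- mvfft(mvfft(mp) * (g * h), inverse = TRUE) / np
  z <- z[(pad + 1L):(pad + n), , drop = FALSE]
  analytic <- aperm(array(z, c(n, d[1L], d[3L])), c(2L, 1L, 3L))
  n_trim <- round(trim_ms * fs / 1000)
  valid <- rep(TRUE, n)
  if (n_trim > 0) {
    valid[seq_len(min(n_trim, n))] <- FALSE
    valid[seq.int(max(1L, n - n_trim + 1L), n)] <- FALSE
  }
  structure(list(phase = Arg(analytic), valid = valid, fs = fs,
                 t0 = epochs$t0, channel_labels = epochs$channel_labels,
                 analytic = analytic),
            class = "phase_tensor")
}
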