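#' Complex Morlet wavelet specification
#'
#' The wavelet family is parameterized by the ratio `f0 / sigma_f = 7`:
#' at center frequency `f0` the spectral bandwidth is
#' `sigma_f = f0 / ratio` and the temporal envelope sd is
#' `sigma_t = 1 / (2 pi sigma_f)`. Wavelets are L2 (unit-energy)
#' normalized, which makes power scale exactly quadratically with
#' signal amplitude.
#'
#' @param ratio dimensionless `f0 / sigma_f` (default 7).
#' @param freqs center-frequency grid in Hz; default 0.1-30 Hz in
#'   0.5 Hz steps.
#' @return an object of class `"wavelet_spec"`.
#' @export
wavelet_spec <- function(ratio = 7, freqs = seq(0.1, 30, by = 0.5)) {
  stopifnot(ratio > 0, all(freqs > 0), !is.unsorted(freqs, strictly = TRUE))
  structure(list(ratio = ratio, freqs = freqs), class = "wavelet_spec")
}

#' Morlet wavelet time-frequency power of a multichannel signal
#'
#' Convolves each channel with unit-energy complex Morlet wavelets on
#' the frequency grid and returns squared magnitudes. Cells whose time
#' point lies within `2 sigma_t` of either epoch edge are flagged in a
#' validity mask (the wavelet support exceeds the available data there)
#' and are excluded from every aggregate; very low frequencies, whose
#' `sigma_t` exceeds the whole epoch, are fully masked but still
#' computed.
#'
#' @param signal numeric matrix, channel x sample.
#' @param fs sampling rate, Hz (must exceed twice the top grid
#'   frequency).
#' @param spec a [wavelet_spec].
#' @param t0 time of the first sample, ms.
#' @param channel_labels optional channel names.
#' @return object of class `"timefreq_map"`: list with `power`
#'   (channel x frequency x time, microvolt^2), `freqs`, `times` (ms)
#'   and `valid` (frequency x time logical mask).
#' @export
morlet_power <- function(signal, fs, spec = wavelet_spec(), t0 = -300,
                         channel_labels = NULL) {
  stopifnot(is.matrix(signal), all(is.finite(signal)))
  if (fs <= 2 * max(spec$freqs))
    stop("grid frequency at or above Nyquist")
  n_ch <- nrow(signal)
  n_s <- ncol(signal)
  times <- t0 + (seq_len(n_s) - 1L) * 1000 / fs
  n_f <- length(spec$freqs)

  sigma_t <- spec$ratio / (2 * pi * spec$freqs)      # seconds
  half_len <- pmin(ceiling(4 * sigma_t * fs), n_s)   # truncate huge kernels
  max_len <- 2L * max(half_len) + 1L
  nfft <- stats::nextn(n_s + max_len - 1L, c(2L, 3L, 5L))
  sig_f <- mvfft(rbind(t(signal), matrix(0, nfft - n_s, n_ch)))

  power <- array(NA_real_, c(n_ch, n_f, n_s))
  for (k in seq_len(n_f)) {
    hl <- half_len[k]
    tt <- (-hl:hl) / fs
    w <- exp(-tt^2 / (2 * sigma_t[k]^2)) *
      exp(1i * 2 * pi * spec$freqs[k] * tt)
    w <- w / sqrt(sum(Mod(w)^2) / fs)                # unit energy
    wf <- stats::fft(c(w, rep(0 + 0i, nfft - length(w))))
    conv <- mvfft(sig_f * wf, inverse = TRUE) / nfft
    power[, k, ] <- t(Mod(conv[(hl + 1L):(hl + n_s), , drop = FALSE])^2)
  }

  margin_ms <- 2 * sigma_t * 1000
  valid <- outer(seq_len(n_f), seq_len(n_s), function(k, s)
    times[s] - times[1L] >= margin_ms[k] &
      times[n_s] - times[s] >= margin_ms[k])
  if (is.null(channel_labels)) channel_labels <- default_montage(n_ch)
  structure(list(power = power, freqs = spec$freqs, times = times,
                 valid = valid, channel_labels = channel_labels),
            class = "timefreq_map")
}

#' @export
print.timefreq_map <- function(x, ...) {
  cat(sprintf(
    "<timefreq_map> %d ch x %d freqs (%g-%g Hz) x %d times [%g, %g] ms\n",
    dim(x$power)[1L], dim(x$power)[2L], min(x$freqs), max(x$freqs),
    dim(x$power)[3L], min(x$times), max(x$times)))
  cat(sprintf("  %.0f%% of (f, t) cells valid\n", 100 * mean(x$valid)))
  invisible(x)
}

#' Evoked (phase-locked) time-frequency power
#'
#' Averages trials first, then transforms: the resulting power reflects
#' only activity both time-locked and phase-locked to stimulus onset.
#' Non-phase-locked activity cancels in the average (by roughly 1/N in
#' power for fully random phase).
#'
#' @param epochs an [eeg_epochs] object with at least 2 trials.
#' @param spec a [wavelet_spec].
#' @return a `"timefreq_map"` (see [morlet_power]).
#' @export
evoked_power <- function(epochs, spec = wavelet_spec()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n_tr <- dim(epochs$data)[3L]
  if (n_tr < 2L)
    warning("single trial: evoked power equals total power")
  avg <- rowMeans(epochs$data, dims = 2L)
  morlet_power(avg, epochs$fs, spec, t0 = epochs$t0,
               channel_labels = epochs$channel_labels)
}

#' Mean power in a frequency band x time window
#'
#' Averages power over the unmasked cells of `band` (Hz, inclusive) by
#' `window` (ms, half-open `[start, end)`), over the selected channels.
#'
#' @param tf a `"timefreq_map"`.
#' @param band length-2 Hz band (inclusive bounds on the grid).
#' @param window length-2 ms window, half-open.
#' @param channels channel label subset (default all).
#' @return scalar mean power.
#' @export
band_window_mean <- function(tf, band = c(8, 13), window = c(100, 300),
                             channels = NULL) {
  stopifnot(inherits(tf, "timefreq_map"))
  fi <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  ti <- window_samples(tf$times, window)
  if (length(fi) == 0L || length(ti) == 0L)
    stop("band/window selects no grid cells")
  ci <- if (is.null(channels)) seq_along(tf$channel_labels)
        else match(channels, tf$channel_labels)
  if (any(is.na(ci))) stop("unknown channel label")
  v <- tf$valid[fi, ti, drop = FALSE]
  if (!any(v)) stop("selection is fully masked (wavelet support exceeds epoch)")
  p <- tf$power[ci, fi, ti, drop = FALSE]
  vmask <- aperm(array(v, c(length(fi), length(ti), length(ci))),
                 c(3L, 1L, 2L))
  mean(p[vmask])
}

#' Per-electrode group comparison p-map
#'
#' Independent two-sample (pooled-variance, two-tailed) t-test per
#' electrode between two groups of per-subject scalars, with
#' Bonferroni adjustment over electrodes. Electrodes with zero
#' variance in both groups are flagged (`p = NA`, `flagged = TRUE`).
#'
#' @param group_a,group_b numeric matrices, subject x electrode, with
#'   matching electrode columns.
#' @return data.frame with one row per electrode: `electrode`, `t`,
#'   `df`, `p`, `p_bonferroni`, `flagged`.
#' @export
electrode_p_map <- function(group_a, group_b) {
  stopifnot(is.matrix(group_a), is.matrix(group_b),
            ncol(group_a) == ncol(group_b),
            nrow(group_a) >= 2L, nrow(group_b) >= 2L)
  n_e <- ncol(group_a)
  labs <- colnames(group_a)
  if (is.null(labs)) labs <- sprintf("E%02d", seq_len(n_e))
  res <- lapply(seq_len(n_e), function(e) {
    a <- group_a[, e]; b <- group_b[, e]
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(data.frame(electrode = labs[e], t = NA_real_,
                        df = length(a) + length(b) - 2L, p = NA_real_,
                        flagged = TRUE))
    tt <- ttest_ind(a, b)
    data.frame(electrode = labs[e], t = tt$statistic, df = tt$df,
               p = tt$p, flagged = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- bonferroni(out$p)
  out[, c("electrode", "t", "df", "p", "p_bonferroni", "flagged")]
}
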