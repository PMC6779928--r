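#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel and trial with an order-4 Butterworth band-pass
#' applied with exactly zero phase: the squared-magnitude response
#' |H(f)|^2 of the analog order-4 prototype (the response a
#' forward-backward Butterworth pass realizes) is applied in the
#' frequency domain on reflection-padded signals. Zero phase matters
#' downstream because Hilbert instantaneous phase must not be biased by
#' filter delay.
#'
#' @param epochs an [eeg_epochs] object.
#' @param lo,hi band edges in Hz, `0 <= lo < hi < fs/2`.
#' @return an [eeg_epochs] object of identical shape.
#' @examples
#' x <- eeg_epochs(array(rnorm(2 * 550 * 3), c(2, 550, 3)), fs = 500)
#' y <- bandpass(x, 8, 13)
#' dim(y$data)
#' @export
bandpass <- function(epochs, lo, hi) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$fs
  if (!(lo >= 0 && lo < hi && hi < fs / 2))
    stop("band must satisfy 0 <= lo < hi < fs/2")
  d <- dim(epochs$data)
  n <- d[2L]
  if (hi - lo < fs / n)
    stop("band narrower than the spectral resolution of one epoch")
  m <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), n, d[1L] * d[3L])
  out <- fft_zero_phase(m, fs, butter_gain(lo, hi))
  epochs$data <- aperm(array(out, c(n, d[1L], d[3L])), c(2L, 1L, 3L))
  epochs
}

# Squared-magnitude response of the analog order-4 Butterworth band-pass:
# |H(f)|^2 = 1 / (1 + X^8),  X = (f^2 - lo*hi) / (f * (hi - lo)).
# Returns a gain function of frequency (Hz).
butter_gain <- function(lo, hi, order = 4L) {
  force(lo); force(hi); force(order)
  function(f) {
    x <- ifelse(f == 0,
                if (lo == 0) 0 else Inf,
                (f^2 - lo * hi) / (f * (hi - lo)))
    ifelse(is.infinite(x), 0, 1 / (1 + x^(2L * order)))
  }
}

# Apply a real zero-phase gain(f) to the columns of `m` (samples x series)
# using even reflection padding at both ends to suppress edge transients.
fft_zero_phase <- function(m, fs, gain) {
  n <- nrow(m)
  pad <- min(n - 1L, 256L)
  mp <- rbind(m[(pad + 1L):2L, , drop = FALSE],
              m,
              m[(n - 1L):(n - pad), , drop = FALSE])
  np <- nrow(mp)
  f <- c(0:(np %/% 2L), -((np - np %/% 2L - 1L):1L)) * fs / np
  g <- gain(abs(f))
  y <- Re(mvfft(mvfft(mp) * g, inverse = TRUE)) / np
  y[(pad + 1L):(pad + n), , drop = FALSE]
}

#' Re-reference epochs
#'
#' `averaged_mastoid` subtracts the mean of the two mastoid channels
#' from every channel and then drops the mastoids from the analysis
#' set (the offline re-reference applied to recordings referenced to
#' one mastoid online). `none` is the identity.
#'
#' @param epochs an [eeg_epochs] object.
#' @param scheme `"averaged_mastoid"` or `"none"`.
#' @param mastoid_labels the two mastoid channel names.
#' @return an [eeg_epochs] object (mastoids removed under
#'   `averaged_mastoid`).
#' @export
rereference <- function(epochs, scheme = c("averaged_mastoid", "none"),
                        mastoid_labels = c("M1", "M2")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  scheme <- match.arg(scheme)
  if (scheme == "none") return(epochs)
  idx <- match(mastoid_labels, epochs$channel_labels)
  if (any(is.na(idx)))
    stop("mastoid channels ", paste(mastoid_labels, collapse = ", "),
         " not present")
  ref <- (epochs$data[idx[1L], , , drop = FALSE] +
            epochs$data[idx[2L], , , drop = FALSE]) / 2
  keep <- setdiff(seq_len(dim(epochs$data)[1L]), idx)
  data <- epochs$data[keep, , , drop = FALSE] -
    ref[rep(1L, length(keep)), , , drop = FALSE]
  epochs$data <- data
  epochs$channel_labels <- epochs$channel_labels[keep]
  epochs
}

#' Segment continuous data into event-locked epochs
#'
#' Cuts one trial per event onset, spanning `[-pre_ms, post_ms)` around
#' the onset sample (the onset sample itself is t = 0). Onsets whose
#' window would exceed the recording bounds are rejected; the count of
#' rejected events is attached as attribute `"n_rejected"` and reported
#' via a message.
#'
#' @param continuous numeric matrix, channel x sample.
#' @param event_onsets 1-based sample indices of stimulus onsets.
#' @param pre_ms,post_ms window extent in ms before/after onset.
#' @param fs sampling rate in Hz.
#' @param ... passed to [eeg_epochs] (labels, condition, subject, group).
#' @return an [eeg_epochs] object with `t0 = -pre_ms`.
#' @examples
#' cont <- matrix(rnorm(2 * 5000), 2)
#' ep <- segment(cont, c(500, 1500, 2500), 300, 800, fs = 500)
#' dim(ep$data)  # 2 x 550 x 3
#' @export
segment <- function(continuous, event_onsets, pre_ms, post_ms, fs, ...) {
  stopifnot(is.matrix(continuous), fs > 0, !anyNA(event_onsets))
  n_pre <- round(pre_ms * fs / 1000)
  n_post <- round(post_ms * fs / 1000)
  n <- ncol(continuous)
  ok <- event_onsets - n_pre >= 1L & event_onsets + n_post - 1L <= n
  n_rej <- sum(!ok)
  if (n_rej > 0)
    message(n_rej, " event(s) rejected: epoch window exceeds recording bounds")
  onsets <- event_onsets[ok]
  if (length(onsets) == 0L) stop("zero usable events after bounds check")
  len <- n_pre + n_post
  data <- vapply(onsets, function(o)
    continuous[, (o - n_pre):(o + n_post - 1L), drop = FALSE],
    matrix(0, nrow(continuous), len))
  out <- eeg_epochs(data, fs = fs, t0 = -pre_ms, ...)
  attr(out, "n_rejected") <- n_rej
  out
}

#' Spectral distortion between raw and reconstructed epochs
#'
#' Quantifies how much an artifact-removal reconstruction (e.g. ICA
#' back-projection) distorts the signal spectrum: per channel,
#' `|delta P| = sum_f |P_recon(f) - P_raw(f)|` over the 0.1-30 Hz grid,
#' where `P` is the trial-averaged periodogram power spectral density.
#' A faithful reconstruction yields values near zero; the metric is
#' symmetric in its arguments and exactly zero for identical spectra.
#' The decomposition itself is not performed here: any (raw,
#' reconstructed) pair of equal shape can be assessed.
#'
#' @param raw,reconstructed [eeg_epochs] of identical shape, fs, labels.
#' @param f_lo,f_hi frequency bounds (Hz) of the summation grid.
#' @return numeric vector of nonnegative per-channel distortions, named
#'   by channel.
#' @export
spectral_distortion <- function(raw, reconstructed, f_lo = 0.1, f_hi = 30) {
  stopifnot(inherits(raw, "eeg_epochs"), inherits(reconstructed, "eeg_epochs"))
  if (!identical(dim(raw$data), dim(reconstructed$data)) ||
      raw$fs != reconstructed$fs ||
      !identical(raw$channel_labels, reconstructed$channel_labels))
    stop("raw and reconstructed epochs must share shape, fs and labels")
  p_raw <- trial_psd(raw)
  p_rec <- trial_psd(reconstructed)
  f <- attr(p_raw, "freqs")
  sel <- f >= f_lo & f <= f_hi
  dp <- rowSums(abs(p_rec[, sel, drop = FALSE] - p_raw[, sel, drop = FALSE]))
  names(dp) <- raw$channel_labels
  dp
}

# Trial-averaged one-sided periodogram PSD, channel x frequency.
trial_psd <- function(epochs) {
  d <- dim(epochs$data)
  n <- d[2L]
  m <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), n, d[1L] * d[3L])
  spec <- Mod(mvfft(m))^2 / (n * epochs$fs)
  nf <- n %/% 2L + 1L
  spec <- spec[seq_len(nf), , drop = FALSE]
  spec[2:(nf - 1L), ] <- 2 * spec[2:(nf - 1L), ]
  p <- array(spec, c(nf, d[1L], d[3L]))
  out <- t(apply(p, c(1L, 2L), mean))
  attr(out, "freqs") <- (seq_len(nf) - 1L) * epochs$fs / n
  out
}
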