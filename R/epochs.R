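#' Event-locked multi-trial EEG epochs
#'
#' `eeg_epochs()` constructs the container every pipeline stage consumes:
#' a channel x sample x trial tensor of event-locked EEG (microvolts),
#' with sampling and timing metadata, per-trial condition label and
#' per-subject group label.
#'
#' Timing convention: the first sample sits at `t0` ms relative to
#' stimulus onset (default -300), samples advance by `1000/fs` ms, and
#' windows elsewhere in the package are half-open `[start, end)` in ms.
#' At the default 500 Hz and `t0 = -300`, sample 151 (1-based) is
#' stimulus onset and a -300..800 ms epoch holds exactly 550 samples.
#'
#' @param data numeric array, channel x sample x trial (microvolts).
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in ms relative to stimulus onset.
#' @param channel_labels character vector of electrode names (10-20
#'   system for the 59-channel replica montage).
#' @param condition one of `"self"`, `"other"`, `"physical"`.
#' @param subject_id subject identifier string.
#' @param group one of `"control"`, `"patient"`.
#' @return an object of class `"eeg_epochs"`.
#' @examples
#' x <- eeg_epochs(array(rnorm(4 * 550 * 3), c(4, 550, 3)), fs = 500,
#'                 t0 = -300, condition = "self", group = "control")
#' epoch_times(x)[1:3]
#' @export
eeg_epochs <- function(data, fs, t0 = -300, channel_labels = NULL,
                       condition = c("self", "other", "physical"),
                       subject_id = "s01",
                       group = c("control", "patient")) {
  condition <- match.arg(condition)
  group <- match.arg(group)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (channel x sample x trial)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz")
  if (any(!is.finite(data)))
    stop("`data` contains NaN/Inf")
  n_ch <- dim(data)[1L]
  if (is.null(channel_labels)) channel_labels <- default_montage(n_ch)
  if (length(channel_labels) != n_ch)
    stop("channel_labels length does not match channel count")
  dur_ms <- dim(data)[2L] * 1000 / fs
  if (!(t0 <= 0 && 0 < t0 + dur_ms))
    stop("stimulus onset (0 ms) must lie inside the epoch window")
  structure(
    list(data = data, fs = fs, t0 = t0, channel_labels = channel_labels,
         condition = condition, subject_id = subject_id, group = group),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d ch x %d samples x %d trials | fs = %g Hz | %s\n",
    d[1L], d[2L], d[3L],
    x$fs, paste0("[", x$t0, ", ", x$t0 + d[2L] * 1000 / x$fs, ") ms")))
  cat(sprintf("  subject %s (%s), condition %s\n",
              x$subject_id, x$group, x$condition))
  invisible(x)
}

#' Sample times of an epoch set
#'
#' @param epochs an [eeg_epochs] object.
#' @return numeric vector of sample times in ms relative to stimulus onset.
#' @export
epoch_times <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  epochs$t0 + (seq_len(dim(epochs$data)[2L]) - 1L) * 1000 / epochs$fs
}

#' Default electrode montage
#'
#' Returns the 59-channel 10-20/10-10 label set used for the replica
#' configuration (64 recorded channels minus reference, mastoids and
#' EOG), or generic `ChNN` labels for other channel counts used in
#' reduced simulations.
#'
#' @param n number of channels.
#' @return character vector of `n` labels.
#' @export
default_montage <- function(n = 59) {
  labels59 <- c(
    "Fp1", "Fp2", "AF3", "AF4", "AF7", "AF8", "Fz", "F1", "F2", "F3",
    "F4", "F5", "F6", "F7", "F8", "FCz", "FC1", "FC2", "FC3", "FC4",
    "FC5", "FC6", "FT7", "FT8", "Cz", "C1", "C2", "C3", "C4", "C5",
    "C6", "T7", "T8", "CPz", "CP1", "CP2", "CP3", "CP4", "CP5", "CP6",
    "TP7", "TP8", "Pz", "P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8",
    "POz", "PO3", "PO4", "PO7", "PO8", "O1", "Oz", "O2")
  if (n == 59L) return(labels59)
  sprintf("Ch%02d", seq_len(n))
}

#' Posterior electrodes of a montage
#'
#' The default coupled-edge set of the synthetic generator lives on a
#' posterior (parieto-occipital) cluster, mirroring where alpha-band
#' connectivity effects are expected. For the 59-channel montage these
#' are P3/P4/O1/O2; for generic reduced montages, the last four channels.
#'
#' @param channel_labels montage labels.
#' @return integer indices of the posterior cluster.
#' @export
posterior_channels <- function(channel_labels) {
  want <- c("P3", "P4", "O1", "O2")
  if (all(want %in% channel_labels)) return(match(want, channel_labels))
  n <- length(channel_labels)
  seq.int(max(1L, n - 3L), n)
}

#' Write / read the plain-text epoch container
#'
#' Fixtures are stored as a documented two-file plain-text container:
#' `<stem>.tsv` holds the tensor flattened to (channel * trial) rows by
#' sample columns (channel varying fastest), and `<stem>.json` is a
#' sidecar with dimensions, sampling metadata and labels. The format is
#' lossless for the double-precision data (17 significant digits).
#'
#' @param epochs an [eeg_epochs] object.
#' @param stem path stem (without extension).
#' @return `write_epochs()` returns `stem` invisibly; `read_epochs()`
#'   returns the reconstructed [eeg_epochs] object.
#' @export
write_epochs <- function(epochs, stem) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  m <- matrix(aperm(epochs$data, c(1L, 3L, 2L)), d[1L] * d[3L], d[2L])
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(n_channels = d[1L], n_samples = d[2L], n_trials = d[3L],
               fs = epochs$fs, t0 = epochs$t0,
               channel_labels = epochs$channel_labels,
               condition = epochs$condition,
               subject_id = epochs$subject_id, group = epochs$group,
               layout = "rows = channel x trial (channel fastest), cols = samples",
               units = "microvolt")
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(paste0(stem, ".tsv"), sep = "\t",
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  a <- aperm(array(m, c(meta$n_channels, meta$n_trials, meta$n_samples)),
             c(1L, 3L, 2L))
  eeg_epochs(a, fs = meta$fs, t0 = meta$t0,
             channel_labels = meta$channel_labels,
             condition = meta$condition, subject_id = meta$subject_id,
             group = meta$group)
}

## ---- internal utilities ----------------------------------------------------

# Deterministic 31-bit seed stream: mixes integer tokens with a
# Lehmer-style recurrence kept exact in doubles (multiplier chosen so
# h * mult stays below 2^53).
mix_seed <- function(...) {
  tokens <- list(...)
  h <- 0
  mod <- 2147483563
  for (t in tokens) {
    if (is.character(t)) {
      for (b in utf8ToInt(t)) h <- (h * 131 + b + 1) %% mod
    } else {
      h <- (h * 69069 + (as.numeric(t) %% mod) + 1) %% mod
    }
  }
  # avalanche rounds: tokens differing in one unit must not yield
  # adjacent seeds (first draws after set.seed(k), set.seed(k + 1) are
  # weakly correlated)
  for (i in 1:3) h <- (h * 48271 + 11) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# index of condition in the fixed design order
cond_index <- function(condition) {
  match(condition, c("self", "other", "physical"))
}

# samples (1-based indices) whose time lies in [start, end) ms
window_samples <- function(times, window) {
  which(times >= window[1] & times < window[2])
}

# Rolling polynomial hash of a canonical character representation, as a
# hex string; used only to tag pipeline outputs with their configuration.
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "niceNames", "showAttributes")),
             collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  # h * 8191 stays below 2^53 for h < 2^40, and h is kept < 2^31
  for (b in bytes) h <- (h * 8191 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}
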