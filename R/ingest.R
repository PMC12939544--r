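#' Construct an EEG epoch object
#'
#' @param data channels x samples numeric matrix (rows named by channel).
#' @param fs sampling rate in Hz.
#' @param channel_names ordered channel labels; defaults to rownames.
#' @param validate check basic consistency.
#' @return An `eeg_epoch`.
#' @export
new_epoch <- function(data, fs, channel_names = rownames(data),
                      validate = TRUE) {
  if (validate) {
    if (!is.matrix(data) || !is.numeric(data)) stopf("data must be a numeric matrix")
    if (is.null(channel_names) || length(channel_names) != nrow(data))
      stopf("channel_names must match the number of rows")
    if (!all(is.finite(data))) stopf("epoch contains non-finite samples")
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "eeg_epoch")
}

#' Check the standardized-epoch invariant
#'
#' A standardized epoch has exactly the 8 canonical channels in order
#' (Fp1, Fp2, F3, F4, F7, F8, C3, C4), 960 samples, and fs = 128 Hz.
#'
#' @param epoch an `eeg_epoch`.
#' @return `TRUE`/`FALSE`.
#' @export
is_standard_epoch <- function(epoch) {
  inherits(epoch, "eeg_epoch") &&
    identical(epoch$channel_names, EEG_CHANNELS) &&
    ncol(epoch$data) == 960L && isTRUE(all.equal(epoch$fs, 128))
}

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth applied forward and backward (`signal::filtfilt`),
#' giving zero phase distortion and an effective 8th-order magnitude
#' response. Default band is the 4-45 Hz analysis band.
#'
#' @param x numeric vector, or channels x samples matrix (filtered row-wise).
#' @param fs sampling rate in Hz; must exceed `2 * hi`.
#' @param lo,hi band edges in Hz.
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, fs, lo = 4, hi = 45) {
  if (fs <= 2 * hi)
    stopf("parameter error: fs (%g) must exceed twice the upper edge (%g)", fs, hi)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  ff <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.matrix(x)) t(apply(x, 1, ff)) else ff(x)
}

#' Downsample a signal to a target rate
#'
#' Polyphase anti-aliased resampling (`signal::resample`). Upsampling is
#' refused: recordings are only ever brought down to the 128 Hz analysis
#' rate.
#'
#' @param x numeric vector or channels x samples matrix.
#' @param fs_in input sampling rate (>= `fs_out`).
#' @param fs_out output sampling rate, default 128 Hz.
#' @return Resampled signal; length `round(n * fs_out / fs_in)` per channel.
#' @export
resample_to <- function(x, fs_in, fs_out = 128) {
  if (fs_in < fs_out)
    stopf("parameter error: upsampling refused (fs_in %g < fs_out %g)", fs_in, fs_out)
  if (fs_in == fs_out) return(x)
  rs <- function(v) as.numeric(signal::resample(v, fs_out, fs_in))
  if (is.matrix(x)) {
    out <- t(apply(x, 1, rs))
    rownames(out) <- rownames(x)
    out
  } else rs(x)
}

#' Screen a rated trial for severe negative emotion
#'
#' Keeps trials with low valence and low arousal; both inequalities are
#' strict, so a trial at exactly the valence threshold is excluded.
#'
#' @param trial a `rated_trial`.
#' @param valence_max,arousal_max screening thresholds (defaults 2.5 and 5
#'   on the 1-9 SAM scale).
#' @return `TRUE` iff `valence < valence_max` and `arousal < arousal_max`.
#' @export
screen_trial <- function(trial, valence_max = 2.5, arousal_max = 5) {
  if (trial$valence < 1 || trial$valence > 9 ||
      trial$arousal < 1 || trial$arousal > 9)
    stopf("ratings must lie in [1, 9]")
  trial$valence < valence_max && trial$arousal < arousal_max
}

#' Crop the steady-state window of a trial
#'
#' Returns the `[start, end)` window measured from stimulus onset, i.e.
#' skipping the trial's pre-stimulus baseline (3 s for DEAP-style trials).
#' The default 15-60 s window at 128 Hz yields 5760 samples.
#'
#' @param trial a `rated_trial` (or list with `signal`, `fs`, optional
#'   `baseline_s`).
#' @param start,end window edges in seconds relative to stimulus onset.
#' @return Channels x samples matrix.
#' @export
crop_steady_state <- function(trial, start = 15, end = 60) {
  if (start >= end) stopf("empty-window error: start (%g) >= end (%g)", start, end)
  fs <- trial$fs
  base <- trial$baseline_s %||% 0
  i0 <- round((base + start) * fs)
  i1 <- round((base + end) * fs)
  if (i1 > ncol(trial$signal))
    stopf("bounds error: trial too short (%d samples, need %d)",
          ncol(trial$signal), i1)
  trial$signal[, (i0 + 1):i1, drop = FALSE]
}

#' Segment a continuous signal into fixed-length epochs
#'
#' Non-overlapping consecutive windows; a trailing remainder shorter than
#' one window is discarded. A signal shorter than one window yields an
#' empty list.
#'
#' @param x channels x samples matrix (or numeric vector, treated as one
#'   channel).
#' @param fs sampling rate, default 128 Hz.
#' @param win_s window length in seconds, default 7.5 (960 samples).
#' @param overlap fraction of window overlap in `[0, 1)`, default 0.
#' @return List of `eeg_epoch`s.
#' @export
segment_epochs <- function(x, fs = 128, win_s = 7.5, overlap = 0) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list("ch1", NULL))
  win <- as.integer(round(win_s * fs))
  if (overlap < 0 || overlap >= 1) stopf("overlap must lie in [0, 1)")
  step <- max(1L, as.integer(round(win * (1 - overlap))))
  n <- ncol(x)
  starts <- seq.int(1L, by = step, length.out = max(0L, (n - win) %/% step + 1L))
  if (n < win) starts <- integer(0)
  lapply(starts, function(s)
    new_epoch(x[, s:(s + win - 1L), drop = FALSE], fs = fs,
              channel_names = rownames(x)))
}

#' Select and reorder the canonical analysis channels
#'
#' Extracts the requested channels from a larger montage and returns them
#' in canonical order regardless of source order.
#'
#' @param x an `eeg_epoch`, or a channels x samples matrix with rownames.
#' @param names channels to keep, default [EEG_CHANNELS].
#' @return Same type as the input, restricted/reordered to `names`.
#' @export
select_channels <- function(x, names = EEG_CHANNELS) {
  mat <- if (inherits(x, "eeg_epoch")) x$data else x
  have <- rownames(mat)
  missing <- setdiff(names, have)
  if (length(missing))
    stopf("channel error: missing channel(s) %s", paste(missing, collapse = ", "))
  out <- mat[names, , drop = FALSE]
  if (inherits(x, "eeg_epoch"))
    new_epoch(out, fs = x$fs, channel_names = names)
  else out
}

#' Down-sample the majority class to a 1:1 balanced cohort
#'
#' Majority-class samples are removed by seeded sampling without
#' replacement until both classes have the minority-class count; minority
#' membership and within-class order are preserved.
#'
#' @param cohort an `eeg_cohort` (list of samples with `$label`).
#' @param seed integer seed.
#' @return A balanced `eeg_cohort`.
#' @export
balance_cohort <- function(cohort, seed = 1L) {
  labels <- vapply(cohort, function(s) s$label, numeric(1))
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) stopf("cohort error: both classes must be present")
  n_min <- min(tab)
  set.seed(derive_seed(seed, 0L))
  keep <- unlist(lapply(c(0, 1), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
  }))
  structure(cohort[sort(keep)], class = "eeg_cohort")
}

#' Build negative-emotion epochs from rated trials
#'
#' Applies the full selection pipeline to DEAP-style trials: screen on
#' valence/arousal, crop the 15-60 s steady-state window, select the 8
#' canonical channels, and segment into 7.5 s epochs (6 per trial).
#'
#' @param trials list of `rated_trial`s.
#' @param valence_max,arousal_max screening thresholds.
#' @param source provenance tag for the resulting samples.
#' @return An `eeg_cohort` of label-0 (negative emotion) samples; the
#'   attribute `n_trials_kept` records how many trials passed screening.
#' @export
trials_to_cohort <- function(trials, valence_max = 2.5, arousal_max = 5,
                             source = "deap-style") {
  kept <- Filter(function(tr) screen_trial(tr, valence_max, arousal_max), trials)
  samples <- list()
  for (tr in kept) {
    sig <- crop_steady_state(tr)
    sig <- select_channels(sig)
    eps <- segment_epochs(sig, fs = tr$fs)
    samples <- c(samples, lapply(eps, function(ep)
      list(epoch = ep, label = 0L, source = source)))
  }
  structure(samples, class = "eeg_cohort",
            n_trials_kept = length(kept))
}
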