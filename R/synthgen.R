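#' Specification of a synthetic EEG epoch class
#'
#' Describes the class-conditional structure of a synthetic 8-channel EEG
#' epoch: per-band oscillator amplitudes, the left/right alpha amplitude
#' imbalance, and the temporal regularity of the background process. The
#' generator realises each band as a sum of random-phase sinusoids whose
#' frequencies are drawn inside the band (with a small guard margin so that
#' band power stays attributable to the band), plus an AR(1) background
#' whose lag-1 coefficient equals `regularity` -- one knob that drives
#' sample entropy down without touching the band structure.
#'
#' @param class_label `"depression"` or `"negative_emotion"`.
#' @param band_amplitudes named numeric vector of per-band oscillator RMS
#'   amplitudes (unitless); names among `delta`, `theta`, `alpha`, `beta`,
#'   `gamma`. Missing bands default to 0.
#' @param asymmetry_coeff number in `[-1, 1]`; alpha-band amplitude on left
#'   channels is scaled by `1 + asymmetry_coeff`, on right channels by
#'   `1 - asymmetry_coeff`.
#' @param regularity number in `[0, 1]`; AR(1) coefficient of the
#'   background process (0 = white noise, near 1 = strongly autocorrelated,
#'   lowering sample entropy).
#' @param noise_sd standard deviation of the background process.
#' @param fs sampling rate in Hz.
#' @param duration_s epoch duration in seconds; `fs * duration_s` must be a
#'   whole number of samples.
#' @param n_channels number of channels (the canonical montage has 8).
#' @return An object of class `signal_spec`.
#' @seealso [preset_spec()], [generate_epoch()]
#' @export
signal_spec <- function(class_label = c("depression", "negative_emotion"),
                        band_amplitudes = c(alpha = 1, beta = 1),
                        asymmetry_coeff = 0,
                        regularity = 0,
                        noise_sd = 1,
                        fs = 128,
                        duration_s = 7.5,
                        n_channels = 8) {
  class_label <- match.arg(class_label)
  amps <- stats::setNames(numeric(nrow(EEG_BANDS)), EEG_BANDS$band)
  if (length(band_amplitudes)) {
    if (is.null(names(band_amplitudes)) ||
        !all(names(band_amplitudes) %in% EEG_BANDS$band))
      stopf("band_amplitudes must be named with bands among: %s",
            paste(EEG_BANDS$band, collapse = ", "))
    if (!all(is.finite(band_amplitudes)) || any(band_amplitudes < 0))
      stopf("band amplitudes must be finite and >= 0")
    amps[names(band_amplitudes)] <- band_amplitudes
  }
  check_finite_scalar(asymmetry_coeff, "asymmetry_coeff")
  check_finite_scalar(regularity, "regularity")
  check_finite_scalar(noise_sd, "noise_sd")
  check_finite_scalar(fs, "fs")
  check_finite_scalar(duration_s, "duration_s")
  if (asymmetry_coeff < -1 || asymmetry_coeff > 1)
    stopf("asymmetry_coeff must lie in [-1, 1]")
  if (regularity < 0 || regularity > 1)
    stopf("regularity must lie in [0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  n <- fs * duration_s
  if (abs(n - round(n)) > 1e-9)
    stopf("fs * duration_s must be an integer number of samples (got %g)", n)
  structure(list(class_label = class_label,
                 band_amplitudes = amps,
                 asymmetry_coeff = asymmetry_coeff,
                 regularity = regularity,
                 noise_sd = noise_sd,
                 fs = fs, duration_s = duration_s,
                 n_samples = as.integer(round(n)),
                 n_channels = as.integer(n_channels)),
            class = "signal_spec")
}

#' Default class presets for the synthetic cohort
#'
#' The shipped study conditions: the negative-emotion preset has an
#' alpha/beta amplitude ratio 1.5 times the depression preset's (so its
#' alpha/beta PSD ratio is higher), a weakly negative alpha asymmetry and a
#' weakly autocorrelated background (regularity 0.2, high sample entropy);
#' the depression preset has a positive left-alpha asymmetry and a strongly
#' autocorrelated background (regularity 0.8, low sample entropy). The
#' `"null"` preset is the class midpoint, used for chance-level controls:
#' both classes drawn from it are statistically identical.
#'
#' @param class_label `"depression"`, `"negative_emotion"` or `"null"`.
#' @return A [signal_spec()].
#' @export
preset_spec <- function(class_label = c("depression", "negative_emotion", "null")) {
  class_label <- match.arg(class_label)
  common <- c(theta = 0.8, gamma = 0.5)
  switch(class_label,
    depression = signal_spec("depression",
      band_amplitudes = c(common, alpha = 2.0, beta = 2.0),
      asymmetry_coeff = 0.15, regularity = 0.8, noise_sd = 1.5),
    negative_emotion = signal_spec("negative_emotion",
      band_amplitudes = c(common, alpha = 3.0, beta = 2.0),
      asymmetry_coeff = -0.05, regularity = 0.2, noise_sd = 1.5),
    null = signal_spec("negative_emotion",
      band_amplitudes = c(common, alpha = 2.5, beta = 2.0),
      asymmetry_coeff = 0.05, regularity = 0.5, noise_sd = 1.5))
}

# Realise one channel's band oscillators + AR(1) background.
# Oscillator frequencies keep a guard margin from the band edges (up to
# 2 Hz, capped at a quarter of the band width) so that windowed-spectrum
# leakage out of the nominal band stays negligible: a Hann analysis
# window spreads a tone over roughly +/- 2 of its 1 Hz bins.
synth_channel <- function(spec, alpha_scale, n_sin = 8L) {
  n <- spec$n_samples
  t <- (seq_len(n) - 1) / spec$fs
  x <- numeric(n)
  for (b in seq_len(nrow(EEG_BANDS))) {
    amp <- spec$band_amplitudes[[EEG_BANDS$band[b]]]
    if (EEG_BANDS$band[b] == "alpha") amp <- amp * alpha_scale
    if (amp <= 0) { # keep the RNG stream aligned across specs
      next
    }
    lo <- EEG_BANDS$lo[b]; hi <- EEG_BANDS$hi[b]
    margin <- min(2, (hi - lo) / 4)
    freqs <- runif(n_sin, lo + margin, hi - margin)
    phases <- runif(n_sin, 0, 2 * pi)
    comp <- sqrt(2 / n_sin) * colSums(matrix(
      sin(outer(freqs, t, function(f, tt) 2 * pi * f * tt) +
            phases), nrow = n_sin))
    x <- x + amp * comp
  }
  if (spec$noise_sd > 0) {
    rho <- min(spec$regularity, 0.999)
    innov <- rnorm(n, sd = spec$noise_sd * sqrt(1 - rho^2))
    bg <- if (rho > 0)
      as.numeric(stats::filter(innov, rho, method = "recursive"))
    else innov
    x <- x + bg
  }
  x
}

#' Generate one synthetic EEG epoch
#'
#' Each channel is a sum of band-limited random-phase oscillators (one per
#' band with non-zero amplitude) plus an AR(1) background process. The
#' alpha-band amplitude is scaled by `1 + asymmetry_coeff` on the left
#' channels (Fp1, F3, F7, C3) and `1 - asymmetry_coeff` on the right
#' channels, which downstream surfaces as a frontal alpha asymmetry.
#' The same `(spec, seed)` pair always yields a bit-identical epoch.
#'
#' @param spec a [signal_spec()].
#' @param seed integer seed.
#' @return An `eeg_epoch`: list with `data` (channels x samples matrix,
#'   rows named), `fs`, `channel_names`.
#' @export
generate_epoch <- function(spec, seed) {
  if (!inherits(spec, "signal_spec")) stopf("spec must be a signal_spec")
  check_finite_scalar(seed, "seed")
  set.seed(as.integer(seed))
  chans <- if (spec$n_channels == 8) EEG_CHANNELS
           else paste0("ch", seq_len(spec$n_channels))
  data <- matrix(0, nrow = spec$n_channels, ncol = spec$n_samples,
                 dimnames = list(chans, NULL))
  for (i in seq_len(spec$n_channels)) {
    scale <- if (chans[i] %in% LEFT_CHANNELS) 1 + spec$asymmetry_coeff
             else if (chans[i] %in% RIGHT_CHANNELS) 1 - spec$asymmetry_coeff
             else 1
    data[i, ] <- synth_channel(spec, alpha_scale = scale)
  }
  new_epoch(data, fs = spec$fs, channel_names = chans, validate = FALSE)
}

#' Generate a balanced labelled synthetic cohort
#'
#' Draws `n_per_class` epochs from each class specification, attaching the
#' binary label (depression = 1, negative emotion = 0), the provenance tag
#' `"synthetic"` and the per-sample seed (derived deterministically from
#' the master seed, so the whole cohort is reproducible).
#'
#' @param n_per_class samples per class (>= 1).
#' @param spec_depr,spec_neg [signal_spec()]s for the two classes.
#' @param seed master integer seed.
#' @return A list of cohort samples (class `eeg_cohort`); each element has
#'   `epoch`, `label`, `source`, `seed`.
#' @export
generate_cohort <- function(n_per_class,
                            spec_depr = preset_spec("depression"),
                            spec_neg = preset_spec("negative_emotion"),
                            seed = 1L) {
  if (!is.numeric(n_per_class) || n_per_class < 1)
    stopf("n_per_class must be >= 1")
  n_per_class <- as.integer(n_per_class)
  samples <- vector("list", 2L * n_per_class)
  k <- 0L
  for (cls in list(list(spec = spec_depr, label = 1L),
                   list(spec = spec_neg, label = 0L))) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      s <- derive_seed(seed, k)
      samples[[k]] <- list(epoch = generate_epoch(cls$spec, s),
                           label = cls$label, source = "synthetic",
                           seed = s)
    }
  }
  structure(samples, class = "eeg_cohort")
}

resolve_rating_dist <- function(dist, name) {
  if (is.function(dist)) return(dist)
  if (is.numeric(dist) && length(dist) == 1L) {
    if (dist < 1 || dist > 9) stopf("%s must lie in [1, 9]", name)
    v <- dist
    return(function(n) rep(v, n))
  }
  if (is.numeric(dist) && length(dist) == 2L) {
    if (any(dist < 1) || any(dist > 9) || dist[1] > dist[2])
      stopf("%s uniform bounds must satisfy 1 <= lo <= hi <= 9", name)
    return(function(n) runif(n, dist[1], dist[2]))
  }
  stopf("%s must be a constant, a c(lo, hi) uniform range, or a function(n)", name)
}

#' Generate rating-annotated synthetic trials
#'
#' Produces DEAP-style trials: a 3 s pre-stimulus baseline plus 60 s of
#' stimulus signal (8064 samples at 128 Hz) with per-trial valence and
#' arousal self-assessment ratings on the 1-9 SAM scale. Trial signals are
#' drawn from the `"null"` preset; the ratings, not the signals, carry the
#' screening structure.
#'
#' @param n number of trials (>= 1).
#' @param valence_dist,arousal_dist rating distributions: a constant in
#'   `[1, 9]`, a `c(lo, hi)` uniform range, or a `function(n)`.
#' @param seed integer seed.
#' @param spec optional [signal_spec()] for the signal content.
#' @return List of `rated_trial`s, each with `signal` (channels x samples),
#'   `fs`, `channel_names`, `baseline_s`, `valence`, `arousal`.
#' @export
generate_rated_trials <- function(n, valence_dist = c(1, 9),
                                  arousal_dist = c(1, 9), seed = 1L,
                                  spec = NULL) {
  if (!is.numeric(n) || n < 1) stopf("n must be >= 1")
  n <- as.integer(n)
  vfun <- resolve_rating_dist(valence_dist, "valence_dist")
  afun <- resolve_rating_dist(arousal_dist, "arousal_dist")
  spec <- spec %||% preset_spec("null")
  tspec <- signal_spec(spec$class_label,
                       band_amplitudes = spec$band_amplitudes[spec$band_amplitudes > 0],
                       asymmetry_coeff = spec$asymmetry_coeff,
                       regularity = spec$regularity, noise_sd = spec$noise_sd,
                       fs = 128, duration_s = 63, n_channels = spec$n_channels)
  set.seed(derive_seed(seed, 0L))
  val <- vfun(n); aro <- afun(n)
  if (any(!is.finite(val)) || any(val < 1) || any(val > 9) ||
      any(!is.finite(aro)) || any(aro < 1) || any(aro > 9))
    stopf("sampled ratings must lie in [1, 9]")
  lapply(seq_len(n), function(i) {
    ep <- generate_epoch(tspec, derive_seed(seed, i))
    structure(list(signal = ep$data, fs = ep$fs,
                   channel_names = ep$channel_names, baseline_s = 3,
                   valence = val[i], arousal = aro[i]),
              class = "rated_trial")
  })
}

#' Write a cohort to disk as EDF files plus a CSV manifest
#'
#' One EDF file per sample (`sample_0001.edf`, ...) and a `manifest.csv`
#' with columns `sample_id`, `file`, `label`, `seed`, `source`. The pair
#' round-trips through [read_cohort_edf()] up to EDF 16-bit quantisation.
#'
#' @param cohort an `eeg_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort_edf <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(cohort)
  files <- sprintf("sample_%04d.edf", seq_len(n))
  for (i in seq_len(n))
    write_edf(cohort[[i]]$epoch, file.path(dir, files[i]))
  manifest <- data.frame(
    sample_id = seq_len(n), file = files,
    label = vapply(cohort, function(s) s$label, integer(1)),
    seed = vapply(cohort, function(s) s$seed %||% NA_integer_, integer(1)),
    source = vapply(cohort, function(s) s$source, character(1)),
    stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort_edf()]
#'
#' @param dir directory containing `manifest.csv` and the EDF files.
#' @return An `eeg_cohort`.
#' @export
read_cohort_edf <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stopf("no manifest.csv in %s", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_edf(file.path(dir, manifest$file[i]))
    list(epoch = new_epoch(rec$data, rec$fs, rec$channel_names),
         label = manifest$label[i], source = manifest$source[i],
         seed = manifest$seed[i])
  })
  structure(samples, class = "eeg_cohort")
}
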