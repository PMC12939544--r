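#' Welch power spectral density estimate
#'
#' Mean modified periodogram over Hann-windowed segments (defaults: 128
#' samples = 1 s at the analysis rate, 50% overlap), one-sided and scaled
#' so that `sum(psd) * df` equals the signal mean square (Parseval).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples.
#' @param overlap fractional segment overlap.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs = 128, nperseg = 128, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  w <- 0.5 * (1 - cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1)))
  scale <- fs * sum(w^2)
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  nfreq <- nperseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    sp <- abs(fft(seg)[1:nfreq])^2 / scale
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC and Nyquist
  if (nperseg %% 2 == 0) psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)]
  else psd[2:nfreq] <- 2 * psd[2:nfreq]
  list(freq = (0:(nfreq - 1)) * fs / nperseg, psd = psd)
}

band_row <- function(band) {
  if (is.list(band) && !is.null(band$lo)) return(band)
  i <- match(band, EEG_BANDS$band)
  if (is.na(i)) stopf("unknown band '%s'", band)
  list(name = EEG_BANDS$band[i], lo = EEG_BANDS$lo[i], hi = EEG_BANDS$hi[i])
}

#' Band power via WPD reconstruction and Welch integration
#'
#' The WPD leaves overlapping `[lo, hi)` are reconstructed to a band
#' signal, its Welch PSD is estimated, and the PSD is integrated over
#' exactly `[lo, hi)`. Reconstructing the overlapping leaves first (rather
#' than summing leaf energies) resolves the mismatch between the band
#' edges (e.g. alpha ends at 13 Hz) and the 4 Hz leaf grid without
#' redefining the band.
#'
#' Because the short Daubechies analysis filters have finite transition
#' bands, part of a component's energy leaks into the leaves adjacent to
#' its own; one `guard` leaf on each side of the selection recovers that
#' leakage (the Welch integral still runs over the exact band, so content
#' genuinely outside the band is not counted).
#'
#' @param x numeric vector at `fs` Hz.
#' @param band band name from [EEG_BANDS] or `list(lo=, hi=)` in Hz.
#' @param fs sampling rate.
#' @param wavelet mother wavelet for the WPD.
#' @param level WPD depth.
#' @param guard extra leaves kept on each side of the overlapping set.
#' @return Band power (signal units squared, e.g. uV^2).
#' @export
band_power <- function(x, band = "alpha", fs = 128, wavelet = "db4",
                       level = 4, guard = 1L) {
  b <- band_row(band)
  if (b$lo >= fs / 2) stopf("parameter error: band above Nyquist (%g Hz)", fs / 2)
  wp <- wpd_decompose(x, level = level, wavelet = wavelet, fs = fs)
  sel <- which(wp$freq_lo < b$hi & wp$freq_hi > b$lo)
  sel <- max(1L, min(sel) - guard):min(length(wp$leaves), max(sel) + guard)
  rec <- wpd_reconstruct(wp, sel)
  ps <- welch_psd(rec, fs = fs)
  inb <- ps$freq >= b$lo & ps$freq < b$hi
  df <- ps$freq[2] - ps$freq[1]
  sum(ps$psd[inb]) * df
}

# Per-channel alpha and beta band powers of one epoch (single WPD +
# reconstruction pass per channel, shared by the F1 and F2 features).
epoch_band_powers <- function(epoch, wavelet = "db4") {
  ch <- epoch$channel_names
  out <- matrix(0, nrow = length(ch), ncol = 2,
                dimnames = list(ch, c("alpha", "beta")))
  for (i in seq_along(ch)) {
    out[i, "alpha"] <- band_power(epoch$data[i, ], "alpha", fs = epoch$fs,
                                  wavelet = wavelet)
    out[i, "beta"] <- band_power(epoch$data[i, ], "beta", fs = epoch$fs,
                                 wavelet = wavelet)
  }
  out
}

#' Per-channel alpha/beta PSD ratio (feature family F1)
#'
#' Ratio of alpha-band to beta-band power for each channel; scale-free
#' (invariant to positive rescaling of the channel). A lower ratio marks a
#' more aroused/negative state; in the shipped presets the depression
#' class has the lower ratio.
#'
#' @param epoch an `eeg_epoch`.
#' @param wavelet mother wavelet.
#' @param cap value substituted (with a warning) if beta power is exactly 0.
#' @return Named numeric vector, one ratio per channel.
#' @export
psd_ratio <- function(epoch, wavelet = "db4", cap = 1e6) {
  bp <- epoch_band_powers(epoch, wavelet)
  r <- bp[, "alpha"] / bp[, "beta"]
  if (any(bp[, "beta"] == 0)) {
    warning("beta power is zero on some channel(s); ratio clamped to cap")
    r[bp[, "beta"] == 0] <- cap
  }
  r
}

#' Normalized alpha-power hemispheric asymmetry (feature family F2)
#'
#' For each channel `ch` with mirror electrode `m(ch)` on the opposite
#' hemisphere: `A(ch) = (P_a(ch) - P_a(m)) / (P_a(ch) + P_a(m))`, bounded
#' in `[-1, 1]` and antisymmetric between mirrored channels. Computed per
#' channel (not per pair), so the 8-channel montage yields 8 values with
#' built-in redundancy `A(left) = -A(right)`.
#'
#' @param epoch an `eeg_epoch` on the canonical montage.
#' @param wavelet mother wavelet.
#' @return Named numeric vector, one asymmetry per channel.
#' @export
alpha_asymmetry <- function(epoch, wavelet = "db4") {
  bp <- epoch_band_powers(epoch, wavelet)
  pa <- bp[, "alpha"]
  ch <- epoch$channel_names
  if (!all(ch %in% names(EEG_MIRROR)))
    stopf("alpha_asymmetry needs the canonical homologous montage")
  out <- stats::setNames(numeric(length(ch)), ch)
  for (c1 in ch) {
    c2 <- EEG_MIRROR[[c1]]
    denom <- pa[c1] + pa[c2]
    if (denom == 0) {
      warning(sprintf("alpha power zero on pair %s/%s; asymmetry set to 0", c1, c2))
      out[c1] <- 0
    } else out[c1] <- (pa[c1] - pa[c2]) / denom
  }
  out
}

#' Sample entropy (feature family F3)
#'
#' `SampEn(m, r, N) = -ln(A/B)`, where `B` counts template pairs of length
#' `m` within Chebyshev tolerance `r = r_factor * sd(x)` and `A` the same
#' for length `m + 1`; self-matches are excluded. Because `r` scales with
#' the series SD the measure is invariant to affine rescaling. A constant
#' series returns 0 (no variability means no complexity); if no
#' `(m+1)`-template pair matches (`A = 0`), the maximum estimable value
#' `-ln(1 / ((N - m) * (N - m - 1)))` is returned instead of infinity.
#' Both degenerate paths warn.
#'
#' @param x numeric vector, length in `[100, 5000]`.
#' @param m embedding dimension, default 2.
#' @param r_factor tolerance as a multiple of `sd(x)`, default 0.2.
#' @return Non-negative sample entropy value.
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2) {
  N <- length(x)
  if (N < 100 || N > 5000)
    stopf("series length must lie in [100, 5000] (got %d)", N)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    warning("constant series: sample entropy defined as 0")
    return(0)
  }
  cnt <- .sampen_counts_cpp(as.numeric(x), as.integer(m), r_factor * s)
  cap <- -log(1 / ((N - m) * (N - m - 1)))
  if (cnt[["B"]] == 0 || cnt[["A"]] == 0) {
    warning("no template matches at m+1; returning maximum estimable SampEn")
    return(cap)
  }
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Full 24-dimensional feature vector of one epoch
#'
#' Fixed order: 8 alpha/beta PSD ratios, then 8 alpha asymmetries, then 8
#' sample entropies, channels in canonical order within each block. Names
#' follow the `<family>_<channel>` convention (`ratio_F8`, `asym_Fp1`,
#' `sampen_Fp2`, ...).
#'
#' @param epoch a standardized `eeg_epoch`.
#' @param wavelet mother wavelet.
#' @param sampen_m,sampen_r sample-entropy parameters.
#' @return Named numeric vector of length 24.
#' @export
feature_vector <- function(epoch, wavelet = "db4", sampen_m = 2,
                           sampen_r = 0.2) {
  bp <- epoch_band_powers(epoch, wavelet)
  ch <- epoch$channel_names
  f1 <- bp[, "alpha"] / bp[, "beta"]
  pa <- bp[, "alpha"]
  f2 <- vapply(ch, function(c1) {
    c2 <- EEG_MIRROR[[c1]]
    d <- pa[c1] + pa[c2]
    if (d == 0) 0 else (pa[c1] - pa[c2]) / d
  }, numeric(1))
  f3 <- vapply(seq_along(ch), function(i)
    sample_entropy(epoch$data[i, ], m = sampen_m, r_factor = sampen_r),
    numeric(1))
  stats::setNames(c(f1, f2, f3),
                  c(paste0("ratio_", ch), paste0("asym_", ch),
                    paste0("sampen_", ch)))
}

#' Assemble the N x 24 feature matrix of a cohort
#'
#' One row per cohort sample in cohort order; rows with any non-finite
#' feature are rejected (with a warning naming them), never imputed.
#'
#' @param cohort an `eeg_cohort`.
#' @param wavelet mother wavelet.
#' @param sampen_m,sampen_r sample-entropy parameters.
#' @param progress print a dot every 100 samples.
#' @return List with `features` (N x 24 named matrix), `labels` (integer
#'   vector), `rejected` (indices of dropped samples), and `params` (the
#'   extraction settings, suitable for the JSON sidecar).
#' @export
build_feature_matrix <- function(cohort, wavelet = "db4", sampen_m = 2,
                                 sampen_r = 0.2, progress = FALSE) {
  n <- length(cohort)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ep <- cohort[[i]]$epoch
    if (!is_standard_epoch(ep))
      stopf("sample %d is not a standardized 8 x 960 epoch at 128 Hz", i)
    rows[[i]] <- feature_vector(ep, wavelet, sampen_m, sampen_r)
    if (progress && i %% 100 == 0) cat(".")
  }
  if (progress) cat("\n")
  mat <- do.call(rbind, rows)
  labels <- vapply(cohort, function(s) as.integer(s$label), integer(1))
  bad <- which(!apply(is.finite(mat), 1, all))
  if (length(bad)) {
    warning(sprintf("rejected %d sample(s) with non-finite features: %s",
                    length(bad), paste(head(bad, 10), collapse = ", ")))
    mat <- mat[-bad, , drop = FALSE]
    labels <- labels[-bad]
  }
  list(features = mat, labels = labels, rejected = bad,
       params = list(wavelet = wavelet,
                     welch = list(nperseg = 128, overlap = 0.5, window = "hann"),
                     sampen = list(m = sampen_m, r_factor = sampen_r),
                     bands = EEG_BANDS,
                     band_power = "total band power (integrated Welch PSD over the exact band)"))
}

#' Write a feature matrix with its parameter sidecar
#'
#' CSV with a header row plus a `label` column, and a `<stem>_params.json`
#' sidecar recording all extraction parameters.
#'
#' @param fm result of [build_feature_matrix()].
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$features)
  df$label <- fm$labels
  write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", "", path)
  jsonlite::write_json(fm$params, paste0(side, "_params.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
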