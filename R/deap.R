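# DEAP-style rated-trial archive: a single flat binary file with a
# documented byte layout (all integers int32 little-endian, all reals
# float64 little-endian):
#
#   bytes 0-7   magic "EEGFDEAP"
#   int32 x 4   n_trials, n_channels, n_samples, fs
#   per channel: int32 name length, then that many ASCII bytes
#   per trial:  float64 x 4 ratings (valence, arousal, dominance, liking)
#   per trial:  float64 x (n_channels * n_samples) samples, channel-major
#
# The canonical DEAP preprocessed geometry is 40 trials x (>= 32) channels
# x 8064 samples (63 s at 128 Hz: 3 s baseline + 60 s stimulus); the reader
# accepts any internally consistent archive but rejects truncated or
# inconsistent files with a format error quoting that expected layout.

#' Write rated trials to a DEAP-style archive
#'
#' @param trials list of `rated_trial`s (see [generate_rated_trials()]).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_deap_archive <- function(trials, path) {
  if (!length(trials)) stopf("no trials to write")
  nch <- nrow(trials[[1]]$signal); nsamp <- ncol(trials[[1]]$signal)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("EEGFDEAP"), con)
  writeBin(as.integer(c(length(trials), nch, nsamp, trials[[1]]$fs)), con,
           size = 4L, endian = "little")
  for (nm in trials[[1]]$channel_names) {
    writeBin(nchar(nm), con, size = 4L, endian = "little")
    writeBin(charToRaw(nm), con)
  }
  for (tr in trials)
    writeBin(as.numeric(c(tr$valence, tr$arousal, 5, 5)), con,
             endian = "little")
  for (tr in trials)
    writeBin(as.numeric(t(tr$signal)), con, endian = "little")
  invisible(path)
}

#' Read a DEAP-style rated-trial archive
#'
#' @param path archive file path.
#' @return List of `rated_trial`s with valence/arousal attached and channel
#'   names taken from the archive header.
#' @export
read_deap_archive <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (length(magic) < 8L || rawToChar(magic) != "EEGFDEAP")
    stopf("format error: %s is not a DEAP-style archive (expected 40 x (>=32) x 8064 trial layout)", path)
  dims <- readBin(con, "integer", 4L, size = 4L, endian = "little")
  if (length(dims) < 4L || any(dims < 1))
    stopf("format error: bad archive dimensions (expected 40 x (>=32) x 8064)")
  n_trials <- dims[1]; nch <- dims[2]; nsamp <- dims[3]; fs <- dims[4]
  chans <- character(nch)
  for (i in seq_len(nch)) {
    len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(len) || len < 1 || len > 64)
      stopf("format error: corrupt channel table (expected 40 x (>=32) x 8064)")
    chans[i] <- rawToChar(readBin(con, "raw", len))
  }
  ratings <- matrix(readBin(con, "numeric", 4L * n_trials, endian = "little"),
                    ncol = 4L, byrow = TRUE)
  if (nrow(ratings) < n_trials)
    stopf("format error: truncated ratings block (expected 40 x (>=32) x 8064)")
  if (any(ratings[, 1:2] < 1) || any(ratings[, 1:2] > 9))
    stopf("validation error: valence/arousal ratings outside [1, 9]")
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    vals <- readBin(con, "numeric", nch * nsamp, endian = "little")
    if (length(vals) < nch * nsamp)
      stopf("format error: truncated data block, trial %d (expected 40 x (>=32) x 8064)", i)
    sig <- matrix(vals, nrow = nch, byrow = TRUE,
                  dimnames = list(chans, NULL))
    trials[[i]] <- structure(
      list(signal = sig, fs = fs, channel_names = chans, baseline_s = 3,
           valence = ratings[i, 1], arousal = ratings[i, 2]),
      class = "rated_trial")
  }
  trials
}
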