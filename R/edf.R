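# Minimal EDF (European Data Format) writer/reader: one data record holding
# the whole signal, 16-bit samples, physical range fitted per channel.
# Covers exactly what the cohort round-trip needs; not a general EDF+ tool.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  sprintf(paste0("%-", width, "s"), x)
}

#' Write an epoch (or any channels x samples matrix) to an EDF file
#'
#' Samples are quantised to the EDF 16-bit digital range with a per-channel
#' physical min/max fitted to the data, so a write/read round trip is exact
#' up to quantisation (relative error ~ range / 65535).
#'
#' @param epoch an `eeg_epoch`, or a list with `data`, `fs`, `channel_names`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(epoch, path) {
  data <- epoch$data
  fs <- epoch$fs
  chans <- epoch$channel_names %||% rownames(data)
  ns <- nrow(data); nsamp <- ncol(data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic subject", 80),
    edf_pad("eegfuse synthetic recording", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(1, 8), edf_pad(format(nsamp / fs, digits = 8), 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  pmin <- apply(data, 1, min); pmax <- apply(data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  fld <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  fld(chans, 16); fld(rep("", ns), 80); fld(rep("uV", ns), 8)
  fld(formatC(pmin, digits = 7, width = 8), 8)
  fld(formatC(pmax, digits = 7, width = 8), 8)
  fld(rep("-32768", ns), 8); fld(rep("32767", ns), 8)
  fld(rep("BP:4-45Hz", ns), 80); fld(rep(nsamp, ns), 8); fld(rep("", ns), 32)
  for (i in seq_len(ns)) {
    dig <- round((data[i, ] - pmin[i]) / (pmax[i] - pmin[i]) * 65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the plain-EDF header and 16-bit samples, rescaling to physical
#' units. If `channels` is given, all requested channels must be present
#' (an error names any absentees) and the returned matrix contains exactly
#' those, in the requested order.
#'
#' @param path EDF file path.
#' @param channels optional character vector of required channel labels.
#' @return List with `data` (channels x samples), `fs`, `channel_names`.
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readBin(con, "raw", width)
    if (length(raw) < width) stopf("malformed EDF header in %s (truncated)", path)
    trimws(rawToChar(raw))
  }
  version <- rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8))); rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(hdr_bytes) || is.na(n_rec) || is.na(rec_dur) || is.na(ns) ||
      version != "0" || ns < 1)
    stopf("malformed EDF header in %s", path)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  nsamp <- as.integer(rdv(8)); rdv(32)
  data <- matrix(0, nrow = ns, ncol = nsamp[1] * n_rec,
                 dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", nsamp[i], size = 2L, endian = "little")
      if (length(dig) < nsamp[i]) stopf("malformed EDF data in %s", path)
      phys <- pmin[i] + (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      data[i, ((r - 1) * nsamp[i] + 1):(r * nsamp[i])] <- phys
    }
  }
  fs <- nsamp[1] / rec_dur
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing))
      stopf("channel error: missing channel(s) %s in %s",
            paste(missing, collapse = ", "), path)
    data <- data[channels, , drop = FALSE]
    labels <- channels
  }
  list(data = data, fs = fs, channel_names = labels)
}
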