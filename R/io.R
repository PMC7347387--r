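# Minimal file interfaces: RIFF/WAVE audio and attribute-preserving CSV
# matrices for spectrograms, responses and DSTRF series.

#' Read a WAV file
#'
#' Supports uncompressed PCM (8/16/32-bit integer) and IEEE float (32/64
#' bit) mono or multichannel RIFF/WAVE files; multichannel audio is
#' averaged to mono.
#'
#' @param path file path.
#' @return a [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little"),
        rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little"))
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV file")
  bytes <- fmt$bits / 8
  n <- length(data_raw) %/% bytes
  x <- if (fmt$audio_format == 3) {
    readBin(data_raw, "double", n, bytes, endian = "little")
  } else if (fmt$audio_format == 1) {
    if (fmt$bits == 8)
      (readBin(data_raw, "integer", n, 1, signed = FALSE) - 128) / 128
    else
      readBin(data_raw, "integer", n, bytes, endian = "little") /
        2^(fmt$bits - 1)
  } else stop("unsupported WAV encoding: format tag ", fmt$audio_format)
  if (fmt$channels > 1)
    x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
  waveform(x, fmt$rate)
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param wav a [waveform()] (samples clipped to `[-1, 1]`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wav, path) {
  x <- pmin(pmax(wav$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(wav$rate), con, size = 4, endian = "little")
  writeBin(as.integer(wav$rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Write / read a spectrogram as CSV with attribute header
#'
#' Plain-text round trip: attribute lines (`# key: value`) followed by the
#' frames x bands matrix.
#'
#' @param spec an `auditory_spectrogram`.
#' @param path file path.
#' @return `path` / the spectrogram.
#' @export
write_spectrogram_csv <- function(spec, path) {
  hdr <- c(sprintf("# frame_rate: %g", attr(spec, "frame_rate")),
           sprintf("# center_freqs: %s",
                   paste(signif(attr(spec, "center_freqs"), 8),
                         collapse = " ")))
  writeLines(hdr, path)
  utils::write.table(unclass(spec), path, append = TRUE, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrogram_csv
#' @export
read_spectrogram_csv <- function(path) {
  lines <- readLines(path, n = 10)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE))
  vals <- as.matrix(utils::read.csv(path, header = FALSE,
                                    comment.char = "#"))
  dimnames(vals) <- NULL
  new_spectrogram(vals, as.numeric(get("frame_rate")),
                  as.numeric(strsplit(get("center_freqs"), " ")[[1]]))
}
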