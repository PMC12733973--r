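# Audio I/O and time-frequency front end.

#' Write a mono waveform as 16-bit PCM WAV
#'
#' @param wave numeric vector in \[-1, 1\] (values are clipped)
#' @param path output file
#' @param sample_rate sampling rate in Hz
#' @return `path`, invisibly
#' @export
write_wav <- function(wave, path, sample_rate = 44100) {
  pcm <- as.integer(round(pmin(pmax(wave, -1), 1) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal RIFF reader for files produced by [write_wav()].
#' @param path WAV file path
#' @return list with `wave` (numeric in \[-1,1\]) and `sample_rate`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  readChar(con, 4) # WAVE
  sample_rate <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("malformed WAV: ", path)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8))
    } else if (id == "data") {
      pcm <- readBin(con, "integer", sz / 2, 2, endian = "little")
      return(list(wave = pcm / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}

# HTK mel scale
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_mels, n_fft, sample_rate, fmin = 50, fmax = sample_rate / 2) {
  mpts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  fpts <- mel_to_hz(mpts)
  bins <- floor((n_fft + 1) * fpts / sample_rate) + 1
  nb <- n_fft %/% 2 + 1
  fb <- matrix(0, n_mels, nb)
  for (m in seq_len(n_mels)) {
    l <- bins[m]; c <- bins[m + 1]; r <- bins[m + 2]
    if (c > l) fb[m, l:c] <- (seq(l, c) - l) / (c - l)
    if (r > c) fb[m, c:r] <- (r - seq(c, r)) / (r - c)
  }
  fb
}

#' Mel-spectrogram of a mono waveform
#'
#' STFT with a Hann window followed by an HTK-style mel filterbank and a
#' `log(1 + power)` compression, so all values are non-negative. Defaults are a
#' 25 ms window and 10 ms hop with 64 mel bins.
#'
#' @param wave numeric waveform
#' @param sample_rate sampling rate in Hz
#' @param n_mels number of mel bins (rows of the output)
#' @param win_ms,hop_ms analysis window and hop, in milliseconds
#' @param n_frames if given, the output is padded/truncated to this many columns
#' @param fmin lowest filterbank frequency in Hz
#' @return an `n_mels` x `n_frames` non-negative matrix
#' @export
melspectrogram <- function(wave, sample_rate = 44100, n_mels = 64, win_ms = 25,
                           hop_ms = 10, n_frames = NULL, fmin = 50) {
  win <- round(sample_rate * win_ms / 1000)
  hop <- round(sample_rate * hop_ms / 1000)
  n_fft <- 2^ceiling(log2(win))
  if (length(wave) < win) wave <- c(wave, numeric(win - length(wave)))
  starts <- seq(1, length(wave) - win + 1, by = hop)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  frames <- matrix(0, n_fft, length(starts))
  for (i in seq_along(starts)) frames[seq_len(win), i] <- wave[starts[i] + seq_len(win) - 1] * hann
  spec <- stats::mvfft(frames)
  pow <- Mod(spec[seq_len(n_fft %/% 2 + 1), , drop = FALSE])^2
  fb <- mel_filterbank(n_mels, n_fft, sample_rate, fmin = fmin)
  mel <- fb %*% pow
  out <- log1p(mel)
  if (!is.null(n_frames)) {
    if (ncol(out) >= n_frames) out <- out[, seq_len(n_frames), drop = FALSE]
    else out <- cbind(out, matrix(0, n_mels, n_frames - ncol(out)))
  }
  out
}
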