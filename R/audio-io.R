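#' Construct a PCG audio recording
#'
#' A lightweight container for a uniformly sampled mono heart-sound signal.
#' Amplitudes are dimensionless, nominally in \[-1, 1\]; times are seconds with
#' 0-based sample indexing (sample i covers time `[i/fs, (i+1)/fs)`).
#'
#' @param samples Numeric vector of finite amplitudes (length >= 1).
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param subject_id Opaque identifier string.
#' @param label Optional class label, `"normal"` or `"pathological"`.
#' @return An object of class `pcg_recording` with fields `samples`,
#'   `sample_rate_hz`, `subject_id`, `label`.
#' @export
pcg_recording <- function(samples, sample_rate_hz, subject_id = "anon",
                          label = NULL) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop_param("`samples` must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) stop_param("`samples` must all be finite")
  check_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  if (!is.null(label)) {
    label <- match.arg(label, c("normal", "pathological"))
  }
  structure(
    list(samples = as.numeric(samples),
         sample_rate_hz = as.numeric(sample_rate_hz),
         subject_id = as.character(subject_id),
         label = label),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> %s: %d samples @ %g Hz (%.2f s)%s\n",
              x$subject_id, length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz,
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

duration_s <- function(rec) length(rec$samples) / rec$sample_rate_hz

#' Read a WAV file as a PCG recording
#'
#' Accepts RIFF/WAVE files in PCM (8/16/24/32-bit integer) or IEEE float
#' (32/64-bit) encoding. Integer samples are scaled to \[-1, 1\]; multi-channel
#' audio is collapsed to mono by averaging channels.
#'
#' @param path Path to a WAV file.
#' @param subject_id Identifier stored on the recording; defaults to the file
#'   name without extension.
#' @return A [pcg_recording].
#' @export
read_wav <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop_param("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_param("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_param("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format   = sum(as.integer(body[1:2]) * c(1, 256)),
        channels = sum(as.integer(body[3:4]) * c(1, 256)),
        rate     = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits     = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_param("malformed WAV (missing fmt or data chunk): ", path)
  }
  if (fmt$format == 65534 && fmt$bits %in% c(32, 64)) fmt$format <- 3  # extensible float

  bytes <- fmt$bits / 8
  n_frames <- length(data_raw) %/% (bytes * fmt$channels)
  if (fmt$format == 1) {  # integer PCM
    if (fmt$bits == 8) {
      x <- (as.integer(data_raw) - 128) / 128
    } else if (fmt$bits == 16) {
      x <- readBin(data_raw, "integer", n_frames * fmt$channels, 2,
                   signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 24) {
      m <- matrix(as.integer(data_raw[seq_len(n_frames * fmt$channels * 3)]),
                  nrow = 3)
      v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
      v <- ifelse(v >= 8388608, v - 16777216, v)
      x <- v / 8388608
    } else if (fmt$bits == 32) {
      x <- readBin(data_raw, "integer", n_frames * fmt$channels, 4,
                   endian = "little") / 2147483648
    } else {
      stop_param("unsupported PCM bit depth: ", fmt$bits)
    }
  } else if (fmt$format == 3) {  # IEEE float
    x <- readBin(data_raw, "double", n_frames * fmt$channels, bytes,
                 endian = "little")
  } else {
    stop_param("unsupported WAV encoding (format tag ", fmt$format, ")")
  }

  if (fmt$channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pcg_recording(x, fmt$rate, subject_id = subject_id)
}

#' Write a PCG recording as 16-bit PCM WAV
#'
#' Amplitudes outside \[-1, 1\] are clipped with a warning. Roundtrip through
#' [read_wav()] reproduces samples within one 16-bit quantization step
#' (2^-15).
#'
#' @param recording A [pcg_recording].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path) {
  stopifnot(inherits(recording, "pcg_recording"))
  x <- recording$samples
  if (length(x) == 0) stop_param("cannot write empty recording")
  if (any(abs(x) > 1)) {
    warning("amplitudes outside [-1, 1] clipped on write", call. = FALSE)
    x <- pmin(1, pmax(-1, x))
  }
  q <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_param("cannot open for write: ", path))
  on.exit(close(con))
  n_bytes <- length(q) * 2L
  rate <- as.integer(round(recording$sample_rate_hz))

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")            # PCM
  writeBin(1L, con, 2, endian = "little")            # mono
  writeBin(rate, con, 4, endian = "little")
  writeBin(rate * 2L, con, 4, endian = "little")     # byte rate
  writeBin(2L, con, 2, endian = "little")            # block align
  writeBin(16L, con, 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(q, con, 2, endian = "little")
  invisible(path)
}

#' Resample a recording to a new rate
#'
#' Downsampling applies a zero-phase 8th-order Butterworth anti-alias low-pass
#' at 0.45 x target rate before cubic-spline interpolation onto the new time
#' grid; upsampling interpolates directly. Duration is preserved within one
#' sample period and in-band sinusoid amplitudes within 1%.
#'
#' @param recording A [pcg_recording].
#' @param target_rate_hz New sampling rate in Hz.
#' @return A [pcg_recording] at `target_rate_hz` with
#'   `round(n * target / source)` samples.
#' @export
resample_recording <- function(recording, target_rate_hz) {
  stopifnot(inherits(recording, "pcg_recording"))
  check_scalar(target_rate_hz, "target_rate_hz", positive = TRUE)
  fs <- recording$sample_rate_hz
  if (target_rate_hz == fs) return(recording)

  x <- recording$samples
  n_new <- round(length(x) * target_rate_hz / fs)
  if (target_rate_hz < fs) {
    bf <- signal::butter(8, 0.45 * target_rate_hz / (fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  t_old <- (seq_along(x) - 1) / fs
  t_new <- (seq_len(n_new) - 1) / target_rate_hz
  y <- spline(t_old, x, xout = t_new)$y
  pcg_recording(y, target_rate_hz, subject_id = recording$subject_id,
                label = recording$label)
}

#' Read or write a labels sidecar CSV
#'
#' The sidecar has columns `file` and `label` (`normal` | `pathological`).
#'
#' @param path CSV path.
#' @return For `read_labels`, a data.frame with columns `file`, `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_param("labels file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("file", "label") %in% names(df))) {
    stop_param("labels CSV must have columns `file` and `label`")
  }
  bad <- setdiff(unique(df$label), c("normal", "pathological"))
  if (length(bad)) stop_param("unknown labels: ", paste(bad, collapse = ", "))
  df[, c("file", "label")]
}

#' @rdname read_labels
#' @param labels Data.frame with columns `file`, `label`.
#' @export
write_labels <- function(labels, path) {
  write.csv(labels[, c("file", "label")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
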