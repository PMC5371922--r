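#' Complex Gaussian (Gabor) wavelet specification
#'
#' The mother wavelet is `psi(u) = C * exp(-i*omega*u) * exp(-u^2)` — a complex
#' carrier under a Gaussian envelope — applied after dilation `u = t / scale`.
#' Its passband centres at `omega / (2*pi*scale)` Hz; the defaults (omega =
#' 2*pi, scale = 0.02 s) centre it at 50 Hz, the midpoint of the 20-100 Hz
#' heart-sound band, with enough bandwidth to respond to both S1 (~40 Hz) and
#' S2 (~65 Hz) bursts while rejecting higher-frequency murmur noise.
#'
#' @param omega Carrier angular frequency of the mother wavelet (rad per unit
#'   of dimensionless time), > 0.
#' @param normalizing_constant The constant C, > 0. Output magnitudes are
#'   re-normalized to max 1 downstream, so C only matters for raw coefficient
#'   inspection.
#' @param scale Dilation in seconds, > 0.
#' @return A `gabor_wavelet_spec` object.
#' @export
gabor_wavelet_spec <- function(omega = 2 * pi, normalizing_constant = 1,
                               scale = 0.02) {
  check_scalar(omega, "omega", positive = TRUE)
  check_scalar(normalizing_constant, "normalizing_constant", positive = TRUE)
  check_scalar(scale, "scale", positive = TRUE)
  structure(list(omega = omega, normalizing_constant = normalizing_constant,
                 scale = scale),
            class = "gabor_wavelet_spec")
}

# The sampled (dilated) wavelet on a +-4*scale support grid.
gabor_kernel <- function(spec, sample_rate_hz) {
  half <- ceiling(4 * spec$scale * sample_rate_hz)
  u <- ((-half):half) / sample_rate_hz / spec$scale
  spec$normalizing_constant * exp(-1i * spec$omega * u) * exp(-u^2)
}

#' Gabor wavelet envelope of a recording
#'
#' Convolves the signal with the dilated complex Gaussian wavelet (FFT
#' convolution, kernel centred so the envelope is time-aligned) and returns
#' coefficient magnitudes normalized to a maximum of 1. An all-zero input
#' yields an all-zero envelope with a warning.
#'
#' @param recording A [pcg_recording] (band-pass filtered input recommended).
#' @param spec A [gabor_wavelet_spec].
#' @param normalize Rescale magnitudes to max 1 (default); set `FALSE` to get
#'   raw coefficient magnitudes, e.g. to compare responses across wavelet
#'   tunings.
#' @return Numeric vector of magnitudes, same length as the input, max 1 for
#'   non-zero input when `normalize = TRUE`.
#' @export
gabor_wavelet_transform <- function(recording, spec = gabor_wavelet_spec(),
                                    normalize = TRUE) {
  stopifnot(inherits(recording, "pcg_recording"))
  x <- recording$samples
  k <- gabor_kernel(spec, recording$sample_rate_hz)
  if (all(x == 0)) {
    warning("all-zero input: envelope not normalized", call. = FALSE)
    return(numeric(length(x)))
  }
  n <- length(x); m <- length(k)
  nfft <- stats::nextn(n + m - 1L, 2)
  conv <- fft(fft(c(x, rep(0, nfft - n))) * fft(c(k, rep(0, nfft - m))),
              inverse = TRUE) / nfft
  half <- (m - 1L) %/% 2L
  env <- Mod(conv[(half + 1L):(half + n)])
  if (normalize) env / max(env) else env
}

#' Detect envelope peaks above a threshold
#'
#' Peaks are local maxima of the (normalized) wavelet envelope, localized at
#' zero-crossings of the first difference, kept when their magnitude reaches
#' `threshold`. Peaks closer than `min_separation_s` are merged keeping the
#' larger (ties keep the earlier).
#'
#' @param coefficients Normalized magnitude series in `[0, 1]`.
#' @param sample_rate_hz Sampling rate of the series, Hz.
#' @param threshold Detection threshold on normalized magnitude; default 0.1.
#' @param min_separation_s Minimum peak spacing in seconds; the 0.06 s default
#'   is shorter than any plausible newborn systole and suppresses
#'   double-detections on split sounds.
#' @return Data frame with columns `time_s`, `magnitude`, ordered by time
#'   (possibly empty).
#' @export
detect_peaks <- function(coefficients, sample_rate_hz, threshold = 0.1,
                         min_separation_s = 0.06) {
  check_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  check_scalar(threshold, "threshold")
  x <- as.numeric(coefficients)
  empty <- data.frame(time_s = numeric(0), magnitude = numeric(0))
  if (length(x) < 3L) return(empty)

  d <- diff(x)
  # zero-crossing of the first difference: rising (or flat) then falling
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  idx <- idx[x[idx] >= threshold]
  if (length(idx) == 0) return(empty)

  # greedy non-maximum suppression within min_separation_s
  ord <- idx[order(-x[idx], idx)]
  min_gap <- min_separation_s * sample_rate_hz
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(time_s = (kept - 1) / sample_rate_hz, magnitude = x[kept])
}

#' Label peaks as S1/S2 by the interval rule
#'
#' Inter-peak intervals alternate between the shorter systole (S1 to S2) and
#' the longer diastole (S2 to next S1). Each adjacent interval pair whose
#' lengths differ by more than 5% votes for which parity is systolic; the
#' majority fixes the phase for the whole recording, the peak opening each
#' systolic interval is labeled S1 and the peak closing it S2.
#'
#' @param peaks Data frame from [detect_peaks()] (needs `time_s`; >= 3 rows).
#' @return Data frame with columns `time_s`, `kind` (`"S1"`/`"S2"`), kinds
#'   strictly alternating.
#' @export
label_events <- function(peaks) {
  if (!is.data.frame(peaks) || !"time_s" %in% names(peaks)) {
    stop_param("`peaks` must be a data frame with a `time_s` column")
  }
  tt <- sort(peaks$time_s)
  if (length(tt) < 3L) {
    stop_param("segmentation error: need at least 3 peaks, got ", length(tt))
  }
  d <- diff(tt)
  tol <- 0.05 * mean(d)
  votes <- c(odd = 0L, even = 0L)
  for (i in seq_len(length(d) - 1L)) {
    if (abs(d[i] - d[i + 1L]) <= tol) next
    shorter <- if (d[i] < d[i + 1L]) i else i + 1L
    if (shorter %% 2L == 1L) votes["odd"] <- votes["odd"] + 1L
    else votes["even"] <- votes["even"] + 1L
  }
  if (sum(votes) == 0L || votes["odd"] == votes["even"]) {
    stop_param("ambiguous segmentation: inter-peak intervals do not ",
               "alternate between short (systole) and long (diastole)")
  }
  systolic_parity <- if (votes["odd"] > votes["even"]) 1L else 0L
  kind <- ifelse(seq_along(tt) %% 2L == systolic_parity, "S1", "S2")
  data.frame(time_s = tt, kind = kind, stringsAsFactors = FALSE)
}

#' Cut a recording into cardiac cycles
#'
#' One cycle per consecutive S1 pair; any leading S2 is dropped and a trailing
#' partial cycle (after the last S1) is discarded. Intervals are half-open:
#' systole is `[S1, S2)`, diastole `[S2, next S1)`.
#'
#' @param recording A [pcg_recording].
#' @param events Data frame from [label_events()] (columns `time_s`, `kind`).
#' @return List of `cardiac_cycle` objects (fields `samples`,
#'   `sample_rate_hz`, `start_s`, `end_s`, `s2_offset_s`); empty with a
#'   warning when no complete S1-to-S1 span exists.
#' @export
extract_cycles <- function(recording, events) {
  stopifnot(inherits(recording, "pcg_recording"))
  ev <- events[order(events$time_s), ]
  first_s1 <- match("S1", ev$kind)
  if (!is.na(first_s1)) ev <- ev[first_s1:nrow(ev), ]
  s1_idx <- which(ev$kind == "S1")
  fs <- recording$sample_rate_hz
  out <- list()
  for (k in seq_len(length(s1_idx) - 1L)) {
    i <- s1_idx[k]; j <- s1_idx[k + 1L]
    if (j - i != 2L || ev$kind[i + 1L] != "S2") next  # exactly one S2 between
    start_s <- ev$time_s[i]; end_s <- ev$time_s[j]
    a <- floor(start_s * fs) + 1L
    b <- floor(end_s * fs)          # half-open [start, end)
    if (b > length(recording$samples) || b <= a) next
    out[[length(out) + 1L]] <- structure(
      list(samples = recording$samples[a:b],
           sample_rate_hz = fs,
           start_s = start_s, end_s = end_s,
           s2_offset_s = ev$time_s[i + 1L] - start_s),
      class = "cardiac_cycle")
  }
  if (length(out) == 0) {
    warning("no complete S1-to-S1 cycle found", call. = FALSE)
  }
  out
}

#' Segment a recording end to end
#'
#' Convenience wrapper: normalize, wavelet envelope, peak detection, interval
#' labeling and cycle cutting in one call. The input should already be
#' band-pass filtered.
#'
#' @param recording A filtered [pcg_recording].
#' @param wavelet A [gabor_wavelet_spec].
#' @param threshold Peak threshold on the normalized envelope.
#' @param min_separation_s Minimum peak spacing, seconds.
#' @return List with `events` (data frame) and `cycles` (list of
#'   `cardiac_cycle`).
#' @export
segment_recording <- function(recording, wavelet = gabor_wavelet_spec(),
                              threshold = 0.1, min_separation_s = 0.06) {
  rec <- normalize_amplitude(recording)
  env <- gabor_wavelet_transform(rec, wavelet)
  peaks <- detect_peaks(env, rec$sample_rate_hz, threshold, min_separation_s)
  events <- label_events(peaks)
  list(events = events, cycles = extract_cycles(rec, events))
}
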