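#' Band-pass filter specification
#'
#' Defaults follow the heart-sound analysis band: a 3rd-order Butterworth
#' band-pass with cutoffs at 20 and 100 Hz, which brackets the main spectral
#' content of S1 and S2.
#'
#' @param order Filter order (>= 1).
#' @param low_cutoff_hz,high_cutoff_hz Band edges in Hz, `0 < low < high`.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order = 3, low_cutoff_hz = 20, high_cutoff_hz = 100) {
  check_scalar(order, "order", positive = TRUE, integerish = TRUE)
  check_scalar(low_cutoff_hz, "low_cutoff_hz", positive = TRUE)
  check_scalar(high_cutoff_hz, "high_cutoff_hz", positive = TRUE)
  if (low_cutoff_hz >= high_cutoff_hz) {
    stop_param("`low_cutoff_hz` must be < `high_cutoff_hz`")
  }
  structure(list(order = as.integer(order),
                 low_cutoff_hz = low_cutoff_hz,
                 high_cutoff_hz = high_cutoff_hz),
            class = "filter_spec")
}

butter_design <- function(spec, sample_rate_hz) {
  nyq <- sample_rate_hz / 2
  if (spec$high_cutoff_hz >= nyq) {
    stop_param("`high_cutoff_hz` (", spec$high_cutoff_hz,
               " Hz) must be below the Nyquist frequency (", nyq, " Hz)")
  }
  signal::butter(spec$order,
                 c(spec$low_cutoff_hz, spec$high_cutoff_hz) / nyq,
                 type = "pass")
}

#' Band-pass de-noise a PCG recording
#'
#' Designs a Butterworth band-pass per `spec` at the recording's rate and
#' applies it forward-backward (zero phase), so S1/S2 event times are not
#' delayed by the filter. The effective magnitude response is the square of
#' the single-pass Butterworth response.
#'
#' @param recording A [pcg_recording].
#' @param spec A [filter_spec].
#' @return Filtered [pcg_recording] of equal length.
#' @export
bandpass_filter <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "pcg_recording"), inherits(spec, "filter_spec"))
  bf <- butter_design(spec, recording$sample_rate_hz)
  y <- signal::filtfilt(bf, recording$samples)
  pcg_recording(y, recording$sample_rate_hz, recording$subject_id,
                recording$label)
}

#' Single-pass magnitude response of the designed band-pass
#'
#' Evaluates the analytic frequency response of the Butterworth design at the
#' given frequencies (one forward pass; the zero-phase application in
#' [bandpass_filter()] squares this magnitude).
#'
#' @param spec A [filter_spec].
#' @param sample_rate_hz Rate the filter is designed at.
#' @param freqs_hz Frequencies to evaluate, in Hz.
#' @return Numeric vector of linear magnitudes.
#' @export
filter_response <- function(spec, sample_rate_hz, freqs_hz) {
  bf <- butter_design(spec, sample_rate_hz)
  w <- 2 * pi * freqs_hz / sample_rate_hz
  z <- exp(1i * w)
  num <- vapply(z, function(zi) sum(bf$b * zi^(-(seq_along(bf$b) - 1))),
                complex(1))
  den <- vapply(z, function(zi) sum(bf$a * zi^(-(seq_along(bf$a) - 1))),
                complex(1))
  Mod(num / den)
}

#' Short-time power spectrogram
#'
#' Hann-windowed short-time power spectrum, used for quality control of the
#' analysis band (heart-sound energy should sit below ~100 Hz).
#'
#' @param recording A [pcg_recording].
#' @param window_s Window length in seconds (must be shorter than the
#'   recording).
#' @param overlap_fraction Fractional window overlap in `[0, 1)`; default 0.5.
#' @return A `pcg_spectrogram`: list with `times_s` (frame centers), `freqs_hz`
#'   (bin centers) and `power` (time x frequency, non-negative).
#' @export
compute_spectrogram <- function(recording, window_s = 0.5,
                                overlap_fraction = 0.5) {
  stopifnot(inherits(recording, "pcg_recording"))
  check_scalar(window_s, "window_s", positive = TRUE)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_param("`overlap_fraction` must be in [0, 1)")
  }
  fs <- recording$sample_rate_hz
  nwin <- round(window_s * fs)
  if (nwin > length(recording$samples)) {
    stop_param("`window_s` is longer than the recording")
  }
  noverlap <- floor(nwin * overlap_fraction)
  sg <- signal::specgram(recording$samples, n = nwin, Fs = fs,
                         window = signal::hanning(nwin),
                         overlap = noverlap)
  structure(list(times_s = as.numeric(sg$t),
                 freqs_hz = as.numeric(sg$f),
                 power = t(Mod(sg$S)^2)),
            class = "pcg_spectrogram")
}

#' Normalize peak amplitude to 1
#'
#' Divides by `max(abs(samples))` so downstream dimensionless thresholds
#' (notably the 0.1 wavelet peak threshold) are scale-free. Sign is preserved.
#'
#' @param recording A [pcg_recording] with at least one non-zero sample.
#' @return Normalized [pcg_recording].
#' @export
normalize_amplitude <- function(recording) {
  stopifnot(inherits(recording, "pcg_recording"))
  m <- max(abs(recording$samples))
  if (m == 0) stop_param("cannot normalize an all-zero recording")
  pcg_recording(recording$samples / m, recording$sample_rate_hz,
                recording$subject_id, recording$label)
}
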