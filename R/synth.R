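#' Synthetic newborn PCG configuration
#'
#' Defaults describe a typical newborn phonocardiogram: heart rate 140 bpm,
#' systole occupying 40% of the cycle (shorter than diastole), S1 as a 40 Hz /
#' 80 ms Gaussian-windowed tone and S2 as a 65 Hz / 60 ms one — both inside
#' the 20-100 Hz analysis band. Murmurs are rendered as band-limited (60-150
#' Hz) noise bursts placed in systole or diastole; `innocent_systolic` murmurs
#' are soft (1/3 of the configured amplitude) and occupy only early systole,
#' while `pathological_*` murmurs are rendered at full amplitude across the
#' whole interval.
#'
#' @param duration_s Recording length in seconds.
#' @param sample_rate_hz Synthesis rate in Hz (must be >= twice the highest
#'   configured tone frequency).
#' @param heart_rate_bpm Mean heart rate, beats/min.
#' @param systole_fraction Fraction of the cycle from S1 to S2, in (0, 1).
#' @param s1_center_freq_hz,s2_center_freq_hz Tone centers of S1 and S2 (Hz).
#' @param s1_duration_s,s2_duration_s Effective burst durations (seconds).
#' @param murmur_kind One of `"none"`, `"innocent_systolic"`,
#'   `"pathological_systolic"`, `"pathological_diastolic"`.
#' @param murmur_relative_amplitude Murmur peak amplitude relative to S1 (>= 0).
#' @param noise_snr_db Additive-noise SNR in dB (`Inf` = noise-free).
#' @param hr_jitter_pct Cycle-to-cycle heart-rate jitter, percent of the cycle
#'   length.
#' @param seed Integer seed; the seed fully determines the waveform.
#' @return A `synth_config` object.
#' @export
synth_config <- function(duration_s = 6,
                         sample_rate_hz = 4000,
                         heart_rate_bpm = 140,
                         systole_fraction = 0.4,
                         s1_center_freq_hz = 40,
                         s2_center_freq_hz = 65,
                         s1_duration_s = 0.08,
                         s2_duration_s = 0.06,
                         murmur_kind = c("none", "innocent_systolic",
                                         "pathological_systolic",
                                         "pathological_diastolic"),
                         murmur_relative_amplitude = 0,
                         noise_snr_db = 20,
                         hr_jitter_pct = 2,
                         seed = 1L) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  check_scalar(heart_rate_bpm, "heart_rate_bpm", positive = TRUE)
  check_scalar(systole_fraction, "systole_fraction")
  if (systole_fraction <= 0 || systole_fraction >= 1) {
    stop_param("`systole_fraction` must be in (0, 1)")
  }
  check_scalar(s1_center_freq_hz, "s1_center_freq_hz", positive = TRUE)
  check_scalar(s2_center_freq_hz, "s2_center_freq_hz", positive = TRUE)
  check_scalar(s1_duration_s, "s1_duration_s", positive = TRUE)
  check_scalar(s2_duration_s, "s2_duration_s", positive = TRUE)
  murmur_kind <- match.arg(murmur_kind)
  if (!is.numeric(murmur_relative_amplitude) || murmur_relative_amplitude < 0) {
    stop_param("`murmur_relative_amplitude` must be >= 0")
  }
  if (!is.numeric(noise_snr_db) || length(noise_snr_db) != 1L ||
      is.na(noise_snr_db)) {
    stop_param("`noise_snr_db` must be a single number (Inf for noise-free)")
  }
  if (!is.numeric(hr_jitter_pct) || hr_jitter_pct < 0) {
    stop_param("`hr_jitter_pct` must be >= 0")
  }
  check_scalar(seed, "seed", integerish = TRUE)
  if (sample_rate_hz < 2 * max(s1_center_freq_hz, s2_center_freq_hz)) {
    stop_param("`sample_rate_hz` must be >= twice the highest tone frequency")
  }
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 heart_rate_bpm = heart_rate_bpm,
                 systole_fraction = systole_fraction,
                 s1_center_freq_hz = s1_center_freq_hz,
                 s2_center_freq_hz = s2_center_freq_hz,
                 s1_duration_s = s1_duration_s, s2_duration_s = s2_duration_s,
                 murmur_kind = murmur_kind,
                 murmur_relative_amplitude = murmur_relative_amplitude,
                 noise_snr_db = noise_snr_db, hr_jitter_pct = hr_jitter_pct,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Gaussian-windowed tone centred at `center_s`; sigma chosen so +-3 sigma
# spans the stated burst duration.
gauss_tone <- function(t, center_s, freq_hz, dur_s, amp) {
  sigma <- dur_s / 6
  amp * exp(-(t - center_s)^2 / (2 * sigma^2)) *
    sin(2 * pi * freq_hz * (t - center_s))
}

# Band-limited noise burst with a Hann taper over [from_s, to_s).
murmur_burst <- function(t, fs, from_s, to_s, amp) {
  if (amp <= 0 || to_s <= from_s) return(numeric(length(t)))
  i0 <- max(1L, floor(from_s * fs) + 1L)
  i1 <- min(length(t), ceiling(to_s * fs))
  if (i1 - i0 < 8L) return(numeric(length(t)))
  n <- i1 - i0 + 1L
  raw <- rnorm(n + 200L)  # pad so the band-pass transient is discarded
  hi <- min(150, 0.45 * fs)
  bf <- signal::butter(4, c(60, hi) / (fs / 2), type = "pass")
  band <- signal::filtfilt(bf, raw)[101:(100L + n)]
  band <- band / max(abs(band))
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  out <- numeric(length(t))
  out[i0:i1] <- amp * band * win
  out
}

#' Generate one synthetic PCG recording with ground truth
#'
#' Renders quasi-periodic S1/S2 bursts at the configured heart rate (with
#' cycle-length jitter), adds the configured murmur, normalizes the clean
#' signal to peak 1, then adds broadband plus low-frequency noise at the
#' requested SNR. Identical configs (including seed) give bit-identical
#' output.
#'
#' @param config A [synth_config].
#' @return A list with `recording` (a [pcg_recording]) and `truth` (list with
#'   `s1_times_s`, `s2_times_s`, `label`, `murmur_kind`). S1 and S2 times
#'   strictly interleave; `label` is `"pathological"` iff the murmur kind is
#'   pathological.
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    fs <- config$sample_rate_hz
    n <- round(config$duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    base_cycle <- 60 / config$heart_rate_bpm
    margin <- 0.1

    s1 <- numeric(0); s2 <- numeric(0); cycles <- numeric(0)
    tc <- margin
    repeat {
      cyc <- base_cycle *
        (1 + runif(1, -config$hr_jitter_pct, config$hr_jitter_pct) / 100)
      if (tc + cyc > config$duration_s - margin) break
      s1 <- c(s1, tc)
      s2 <- c(s2, tc + config$systole_fraction * cyc)
      cycles <- c(cycles, cyc)
      tc <- tc + cyc
    }
    if (length(s1) == 0) {
      stop_param("`duration_s` too short for even one cardiac cycle")
    }
    s1 <- c(s1, tc)  # closing S1 so the last full cycle is delimited

    x <- numeric(n)
    for (ts1 in s1) {
      x <- x + gauss_tone(t, ts1, config$s1_center_freq_hz,
                          config$s1_duration_s, 1.0)
    }
    for (ts2 in s2) {
      x <- x + gauss_tone(t, ts2, config$s2_center_freq_hz,
                          config$s2_duration_s, 0.8)
    }

    amp <- config$murmur_relative_amplitude
    if (config$murmur_kind != "none" && amp > 0) {
      for (k in seq_along(s2)) {
        sys_from <- s1[k] + config$s1_duration_s / 2
        sys_to <- s2[k] - config$s2_duration_s / 2
        dia_from <- s2[k] + config$s2_duration_s / 2
        dia_to <- s2[k] + 0.6 * (s1[k + 1] - s2[k])
        x <- x + switch(config$murmur_kind,
          innocent_systolic = murmur_burst(
            t, fs, sys_from, sys_from + 0.5 * (sys_to - sys_from), amp / 3),
          pathological_systolic = murmur_burst(t, fs, sys_from, sys_to, amp),
          pathological_diastolic = murmur_burst(t, fs, dia_from, dia_to, amp))
      }
    }

    x <- x / max(abs(x))  # peak 1 before noise

    if (is.finite(config$noise_snr_db)) {
      broadband <- rnorm(n)
      lf <- signal::filtfilt(signal::butter(2, 15 / (fs / 2), type = "low"),
                             rnorm(n))
      noise <- sqrt(0.7) * broadband / sd(broadband) +
               sqrt(0.3) * lf / sd(lf)
      p_sig <- mean(x^2)
      p_noise <- p_sig / 10^(config$noise_snr_db / 10)
      x <- x + noise * sqrt(p_noise) / sd(noise)
    }

    label <- if (startsWith(config$murmur_kind, "pathological")) {
      "pathological"
    } else "normal"
    list(recording = pcg_recording(x, fs, subject_id = "synthetic",
                                   label = label),
         truth = list(s1_times_s = s1, s2_times_s = s2, label = label,
                      murmur_kind = config$murmur_kind))
  })
}

#' Generate a labeled synthetic PCG dataset
#'
#' Per-recording seeds are derived deterministically from `seed`; heart rate
#' is drawn uniformly from 120-160 bpm and SNR jittered +-3 dB around the base
#' config. Normal recordings alternate between murmur-free and innocent
#' systolic murmurs; pathological ones alternate between systolic and
#' diastolic murmurs at the configured amplitude.
#'
#' @param n_normal,n_pathological Recording counts (>= 0).
#' @param base_config A [synth_config] giving the shared parameters.
#' @param seed Integer master seed.
#' @return A list of class `pcg_dataset`: elements as from
#'   [generate_recording()], normals first, each recording carrying its label
#'   and a unique `subject_id`.
#' @export
generate_dataset <- function(n_normal, n_pathological,
                             base_config = synth_config(), seed = 1L) {
  check_scalar(n_normal, "n_normal", integerish = TRUE)
  check_scalar(n_pathological, "n_pathological", integerish = TRUE)
  if (n_normal < 0 || n_pathological < 0) {
    stop_param("recording counts must be >= 0")
  }
  kinds <- c(rep(c("none", "innocent_systolic"), length.out = n_normal),
             rep(c("pathological_systolic", "pathological_diastolic"),
                 length.out = n_pathological))
  out <- vector("list", length(kinds))
  for (i in seq_along(kinds)) {
    child <- derive_seed(seed, i)
    draws <- with_seed(child, list(hr = runif(1, 120, 160),
                                   dsnr = runif(1, -3, 3)))
    cfg <- base_config
    cfg$heart_rate_bpm <- draws$hr
    cfg$noise_snr_db <- base_config$noise_snr_db + draws$dsnr
    cfg$murmur_kind <- kinds[i]
    cfg$seed <- derive_seed(child, 1L)
    rec <- generate_recording(cfg)
    rec$recording$subject_id <- sprintf("%s_%03d", rec$truth$label, i)
    out[[i]] <- rec
  }
  structure(out, class = "pcg_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes one 16-bit PCM WAV per recording, a per-recording ground-truth CSV
#' (`<id>_events.csv`: columns `time_s`, `event` in {S1, S2}) and a
#' `labels.csv` sidecar (columns `file`, `label`). Recordings whose additive
#' noise pushed the peak past full scale are rescaled to peak 1 rather than
#' clipped (the analysis pipeline renormalizes amplitude anyway).
#'
#' @param dataset A `pcg_dataset` from [generate_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0); labels <- character(0)
  for (item in dataset) {
    id <- item$recording$subject_id
    wav <- file.path(out_dir, paste0(id, ".wav"))
    rec <- item$recording
    peak <- max(abs(rec$samples))
    if (peak > 1) rec$samples <- rec$samples / peak
    write_wav(rec, wav)
    ev <- rbind(
      data.frame(time_s = item$truth$s1_times_s, event = "S1"),
      data.frame(time_s = item$truth$s2_times_s, event = "S2"))
    ev <- ev[order(ev$time_s), ]
    write.csv(ev, file.path(out_dir, paste0(id, "_events.csv")),
              row.names = FALSE, quote = FALSE)
    files <- c(files, basename(wav))
    labels <- c(labels, item$truth$label)
  }
  write_labels(data.frame(file = files, label = labels),
               file.path(out_dir, "labels.csv"))
  invisible(out_dir)
}
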