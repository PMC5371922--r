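cycle_samples <- function(cycle) {
  x <- if (inherits(cycle, "cardiac_cycle")) cycle$samples else as.numeric(cycle)
  if (length(x) == 0) stop_param("empty cycle")
  x
}

#' Time-domain features of a cardiac cycle
#'
#' @param cycle A `cardiac_cycle` or numeric vector.
#' @return Named numeric vector: `max_amplitude` (max of |x|),
#'   `sum_positive_area` (sum of positive samples) and `variance`
#'   (population variance).
#' @export
time_domain_features <- function(cycle) {
  x <- cycle_samples(cycle)
  c(max_amplitude = max(abs(x)),
    sum_positive_area = sum(x[x > 0]),
    variance = mean((x - mean(x))^2))
}

#' Shannon energy of a cycle
#'
#' `SE = -(1/N) * sum(x^2 * log(x^2))` with the `0 * log(0)` term taken as 0.
#' For amplitudes in \[-1, 1\] this is non-negative and emphasizes
#' medium-intensity components over both faint noise and full-scale peaks.
#'
#' @param cycle A `cardiac_cycle` or numeric vector with amplitudes in
#'   \[-1, 1\].
#' @return Non-negative scalar.
#' @export
shannon_energy <- function(cycle) {
  x <- cycle_samples(cycle)
  x2 <- x^2
  terms <- ifelse(x2 > 0, x2 * log(x2), 0)
  -mean(terms)
}

#' Direct (FFT-based) bispectrum estimate
#'
#' Splits the cycle into overlapping segments, takes the FFT of each and
#' averages the triple product `X(f1) * X(f2) * Conj(X(f1 + f2))` over
#' segments. Only the principal domain `f1, f2 >= 0`, `f1 + f2 <= fs/2` is
#' populated; entries outside it are zero with a logical `domain` mask. A
#' non-zero magnitude at (f1, f2) indicates quadratic phase coupling between
#' the two frequencies and their sum.
#'
#' @param cycle A `cardiac_cycle` or numeric vector.
#' @param segment_length Samples per segment (cycle must be at least this
#'   long).
#' @param overlap_fraction Fractional segment overlap in `[0, 1)`.
#' @return A `pcg_bispectrum`: `freqs_hz`, complex matrix `b` over
#'   (f1, f2), logical `domain` mask, `n_segments`.
#' @export
bispectrum <- function(cycle, segment_length = 256, overlap_fraction = 0.5) {
  x <- cycle_samples(cycle)
  fs <- if (inherits(cycle, "cardiac_cycle")) cycle$sample_rate_hz else 1
  check_scalar(segment_length, "segment_length", positive = TRUE,
               integerish = TRUE)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_param("`overlap_fraction` must be in [0, 1)")
  }
  n <- as.integer(segment_length)
  if (length(x) < n) {
    stop_param("cycle (", length(x), " samples) shorter than `segment_length` (",
               n, ")")
  }
  hop <- max(1L, as.integer(round(n * (1 - overlap_fraction))))
  starts <- seq(1L, length(x) - n + 1L, by = hop)

  K <- n %/% 2L
  idx <- 0:K
  sum_idx <- outer(idx, idx, "+")
  domain <- sum_idx <= K
  B <- matrix(0 + 0i, K + 1L, K + 1L)
  for (s in starts) {
    seg <- x[s:(s + n - 1L)]
    seg <- seg - mean(seg)
    X <- fft(seg)
    Xk <- X[idx + 1L]
    tri <- outer(Xk, Xk) * Conj(matrix(X[pmin(sum_idx, n - 1L) + 1L], K + 1L))
    tri[!domain] <- 0 + 0i
    B <- B + tri
  }
  B <- B / length(starts)
  structure(list(freqs_hz = idx * fs / n, b = B, domain = domain,
                 n_segments = length(starts)),
            class = "pcg_bispectrum")
}

# Analytic signal by the frequency-domain Hilbert method.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Diagonal slice of the (pseudo) Wigner bispectrum
#'
#' Third-order time-frequency map: for each frame centre t, the windowed
#' local third moment `x(t+tau1) * x(t+tau2) * Conj(x(t-tau1-tau2))` is
#' reduced over the combined lag `u = tau1 + tau2` and Fourier-transformed,
#' giving the diagonal slice W(t, f, f). The signal is made analytic first
#' (suppressing negative-frequency cross terms) and a Hann lag window keeps
#' the estimate stable (pseudo form). The combined lag doubles the apparent
#' frequency, so the frequency axis is halved: a steady tone at f Hz ridges
#' at f Hz on the returned axis.
#'
#' @param cycle A `cardiac_cycle` or numeric vector.
#' @param lag_window Half-width of the lag window in samples.
#' @param hop_samples Frame hop in samples.
#' @param nfft FFT length over the combined lag (>= 2 * lag_window + 1).
#' @return A `pcg_wigner`: `times_s` (frame centres), `freqs_hz`, complex
#'   matrix `w` (time x frequency).
#' @export
wigner_bispectrum <- function(cycle, lag_window = 127L, hop_samples = 8L,
                              nfft = 512L) {
  x <- if (inherits(cycle, "cardiac_cycle")) cycle$samples else cycle
  if (length(x) == 0) stop_param("empty cycle")
  fs <- if (inherits(cycle, "cardiac_cycle")) cycle$sample_rate_hz else 1
  L <- as.integer(lag_window)
  if (nfft < 2L * L + 1L) stop_param("`nfft` must be >= 2 * lag_window + 1")
  if (all(x == 0)) {
    centers <- seq(1L, length(x), by = as.integer(hop_samples))
    return(structure(list(times_s = (centers - 1) / fs,
                          freqs_hz = (0:(nfft / 2 - 1)) * fs / nfft / 2,
                          w = matrix(0 + 0i, length(centers), nfft / 2)),
                     class = "pcg_wigner"))
  }
  z <- if (is.complex(x)) x else analytic_signal(x)  # complex input taken
  n <- length(z)                                     # as already analytic
  zp <- c(rep(0 + 0i, 2L * L), z, rep(0 + 0i, 2L * L))  # edge padding
  win <- 0.5 + 0.5 * cos(pi * (-L:L) / L)               # Hann over lags
  centers <- seq(1L, n, by = as.integer(hop_samples))
  half <- nfft / 2
  W <- matrix(0 + 0i, length(centers), half)
  for (r in seq_along(centers)) {
    tc <- centers[r] + 2L * L                  # index into padded signal
    s <- win * zp[(tc - L):(tc + L)]           # w(tau) * x(t + tau)
    # autoconvolution over tau1 gives c(u), u = tau1 + tau2 in -2L..2L
    sp <- c(s, rep(0 + 0i, 2L * L))            # pad to full linear length
    cu_full <- fft(fft(sp)^2, inverse = TRUE) / length(sp)
    u <- -L:L
    cu <- cu_full[u + 2L * L + 1L]             # central lags only
    g <- cu * Conj(zp[tc - u]) * win
    spec <- fft(c(g[u >= 0], rep(0 + 0i, nfft - 2L * L - 1L), g[u < 0]))
    W[r, ] <- spec[seq_len(half)]
  }
  structure(list(times_s = (centers - 1) / fs,
                 freqs_hz = (0:(half - 1)) * fs / nfft / 2,
                 w = W),
            class = "pcg_wigner")
}

#' Summarize a polyspectrum into fixed scalars
#'
#' Reduces a bispectrum matrix or Wigner map to four scalars of its magnitude
#' values v: `mean(v)`, `max(v)`, the normalized entropy
#' `-(sum(p * log(p))) / log(K)` with `p = v / sum(v)`, and `sum(log1p(v))`.
#' An all-zero input gives all four as 0.
#'
#' @param x A `pcg_bispectrum`, `pcg_wigner`, or numeric/complex matrix.
#' @return Named numeric vector `(mean_mag, max_mag, entropy, log_sum)`.
#' @export
summarize_polyspectrum <- function(x) {
  v <- if (inherits(x, "pcg_bispectrum")) {
    Mod(x$b[x$domain])
  } else if (inherits(x, "pcg_wigner")) {
    as.vector(Mod(x$w))
  } else {
    as.vector(Mod(x))
  }
  if (!length(v) || !all(is.finite(v))) {
    stop_param("polyspectrum values must be finite and non-empty")
  }
  total <- sum(v)
  entropy <- 0
  if (total > 0 && length(v) > 1) {
    p <- v / total
    p <- p[p > 0]
    entropy <- -sum(p * log(p)) / log(length(v))
  }
  c(mean_mag = mean(v), max_mag = max(v), entropy = entropy,
    log_sum = sum(log1p(v)))
}

#' Per-recording feature vector from representative cycles
#'
#' Computes the full 12-dimensional descriptor on each representative cycle —
#' 3 time-domain features, Shannon energy, and 4 summary scalars for each of
#' the bispectrum and the Wigner bispectrum — then averages across
#' representatives weighted by the number of cycles each one covers.
#'
#' @param selection A `cycle_selection` from [select_representatives()].
#' @param cycles The list of `cardiac_cycle` objects the selection indexes.
#' @param segment_length Bispectrum segment length (capped at the cycle
#'   length).
#' @param overlap_fraction Bispectrum segment overlap.
#' @return Named numeric vector of length 12, fixed order: `max_amplitude`,
#'   `sum_positive_area`, `variance`, `shannon_energy`, `bisp_*`, `wig_*`.
#' @export
extract_features <- function(selection, cycles, segment_length = 256,
                             overlap_fraction = 0.5) {
  stopifnot(inherits(selection, "cycle_selection"))
  reps <- selection$representative_indices
  if (length(reps) == 0) stop_param("empty cycle selection")
  weights <- vapply(reps, function(r) sum(selection$assignment == r),
                    numeric(1))
  rows <- lapply(reps, function(r) {
    cyc <- cycles[[r]]
    seg <- min(segment_length, length(cycle_samples(cyc)))
    bs <- summarize_polyspectrum(bispectrum(cyc, seg, overlap_fraction))
    wb <- summarize_polyspectrum(wigner_bispectrum(cyc))
    c(time_domain_features(cyc),
      shannon_energy = shannon_energy(cyc),
      bisp = bs, wig = wb)
  })
  mat <- do.call(rbind, rows)
  out <- colSums(mat * (weights / sum(weights)))
  names(out) <- c("max_amplitude", "sum_positive_area", "variance",
                  "shannon_energy",
                  "bisp_mean", "bisp_max", "bisp_entropy", "bisp_logsum",
                  "wig_mean", "wig_max", "wig_entropy", "wig_logsum")
  out
}
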