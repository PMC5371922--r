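test_that("time-domain features match closed forms", {
  td <- time_domain_features(rep(0.5, 4))
  expect_equal(unname(td), c(0.5, 2.0, 0))
  td2 <- time_domain_features(c(-1, 1))
  expect_equal(unname(td2), c(1, 1, 1))
  set.seed(1)
  x <- rnorm(50)
  expect_equal(time_domain_features(x)[c("max_amplitude", "variance")],
               time_domain_features(-x)[c("max_amplitude", "variance")])
})

test_that("Shannon energy follows its defining formula", {
  expect_equal(shannon_energy(numeric(32)), 0)
  expect_equal(shannon_energy(c(1, -1, 1)), 0)
  expect_equal(shannon_energy(rep(exp(-0.5), 8)), exp(-1))
})

test_that("bispectrum is symmetric and vanishes on zero input", {
  z <- bispectrum(numeric(512), segment_length = 128)
  expect_true(all(Mod(z$b) == 0))

  set.seed(4)
  x <- rnorm(1024)
  bs <- bispectrum(x, segment_length = 128)
  asym <- max(Mod(bs$b - t(bs$b))) / max(Mod(bs$b))
  expect_lt(asym, 1e-10)
  expect_error(bispectrum(rnorm(64), segment_length = 128), "shorter")
})

test_that("bispectrum detects quadratic phase coupling", {
  fs <- 256
  t <- (0:(fs * 32 - 1)) / fs
  set.seed(7)
  noise <- rnorm(length(t), sd = 0.1)
  coupled <- cos(2 * pi * 30 * t) + cos(2 * pi * 40 * t) +
    cos(2 * pi * 70 * t) + noise
  cyc <- structure(list(samples = coupled, sample_rate_hz = fs),
                   class = "cardiac_cycle")
  bs <- bispectrum(cyc, segment_length = 256, overlap_fraction = 0.5)
  i30 <- which(bs$freqs_hz == 30); i40 <- which(bs$freqs_hz == 40)
  mag <- Mod(bs$b)
  peak <- mag[i30, i40]
  expect_gte(peak / median(mag[bs$domain & mag > 0]), 10)

  # randomizing the third tone's phase per segment destroys the coupling
  starts <- seq(1, length(t) - 255, by = 128)
  third <- numeric(length(t))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + 255)
    third[idx] <- cos(2 * pi * 70 * t[idx] + runif(1, 0, 2 * pi))
  }
  uncoupled <- cos(2 * pi * 30 * t) + cos(2 * pi * 40 * t) + third + noise
  cyc2 <- structure(list(samples = uncoupled, sample_rate_hz = fs),
                    class = "cardiac_cycle")
  peak2 <- Mod(bispectrum(cyc2, 256, 0.5)$b)[i30, i40]
  expect_lt(peak2, peak / 3)
})

test_that("Wigner bispectrum slice is shift-covariant and tracks a chirp", {
  fs <- 1000
  n <- 1500
  hop <- 50
  w0 <- wigner_bispectrum(numeric(n), hop_samples = hop)
  expect_true(all(Mod(w0$w) == 0))

  t <- (0:(n - 1)) / fs
  burst <- exp(-(t - 0.4)^2 / (2 * 0.03^2)) * sin(2 * pi * 50 * t)
  # a steady tone burst ridges at the tone frequency
  wt <- wigner_bispectrum(
    structure(list(samples = burst, sample_rate_hz = fs),
              class = "cardiac_cycle"), hop_samples = hop)
  peak_frame <- which.max(apply(Mod(wt$w), 1, max))
  expect_lt(abs(wt$freqs_hz[which.max(Mod(wt$w[peak_frame, ]))] - 50), 2)

  # shifting the signal by whole frames shifts the map by the same frames
  # (analytic input isolates the kernel's covariance from the Hilbert step)
  z <- pcgkit:::analytic_signal(burst)
  shift <- 4 * hop
  zshift <- c(rep(0 + 0i, shift), z[1:(n - shift)])
  wa <- wigner_bispectrum(z, hop_samples = hop)
  wb <- wigner_bispectrum(zshift, hop_samples = hop)
  inner <- 8:(nrow(wa$w) - 8)  # away from edge padding
  delta <- Mod(wb$w[inner, ]) - Mod(wa$w[inner - 4, ])
  expect_lt(max(abs(delta)) / max(Mod(wa$w)), 1e-6)

  chirp <- sin(2 * pi * (30 * t + 10 * t^2))  # 30 -> 60 Hz over 1.5 s
  wc <- wigner_bispectrum(
    structure(list(samples = chirp, sample_rate_hz = fs),
              class = "cardiac_cycle"), hop_samples = hop)
  band <- wc$freqs_hz >= 20 & wc$freqs_hz <= 100
  frames <- 5:(nrow(wc$w) - 5)
  ridge <- wc$freqs_hz[band][apply(Mod(wc$w[frames, band]), 1, which.max)]
  expect_true(all(diff(ridge) >= 0))
  expect_gt(ridge[length(ridge)], ridge[1])
})

test_that("polyspectrum summaries handle degenerate distributions", {
  expect_equal(unname(summarize_polyspectrum(matrix(0, 4, 4))), rep(0, 4))
  one <- matrix(0, 4, 4); one[2, 3] <- 5
  s <- summarize_polyspectrum(one)
  expect_equal(unname(s["entropy"]), 0)
  expect_equal(unname(s["max_mag"]), 5)
  expect_equal(unname(summarize_polyspectrum(matrix(2, 5, 5))["entropy"]), 1)
})

test_that("features scale as documented with input amplitude", {
  g <- generate_recording(synth_config(seed = 3, noise_snr_db = Inf))
  cyc <- segment_recording(bandpass_filter(g$recording))$cycles[[1]]
  scaled <- cyc; scaled$samples <- 2 * cyc$samples
  td1 <- time_domain_features(cyc); td2 <- time_domain_features(scaled)
  expect_equal(td2[["max_amplitude"]], 2 * td1[["max_amplitude"]],
               tolerance = 1e-6)
  expect_equal(td2[["variance"]], 4 * td1[["variance"]], tolerance = 1e-6)
  b1 <- summarize_polyspectrum(bispectrum(cyc, 256))
  b2 <- summarize_polyspectrum(bispectrum(scaled, 256))
  expect_equal(b2[["max_mag"]], 8 * b1[["max_mag"]], tolerance = 1e-6)
})

test_that("per-recording vectors are weighted means over representatives", {
  # no jitter and no noise: every cycle is identical, so one representative
  g <- generate_recording(synth_config(seed = 6, noise_snr_db = Inf,
                                       hr_jitter_pct = 0))
  cycles <- segment_recording(bandpass_filter(g$recording))$cycles
  sel <- select_representatives(cycles, threshold = 0.005)

  # single representative covering everything: vector equals its features
  expect_length(sel$representative_indices, 1)
  r <- sel$representative_indices
  fv <- extract_features(sel, cycles)
  expect_length(fv, 12)
  one <- extract_features(
    structure(list(representative_indices = 1L, assignment = 1L,
                   assigned_distance = 0, coverage_threshold = 0.005,
                   max_assigned_distance = 0),
              class = "cycle_selection"),
    cycles[r])
  expect_equal(unname(fv), unname(one))

  # two representatives covering 3 and 1 cycles -> (3a + b) / 4
  sel2 <- structure(list(representative_indices = c(1L, 4L),
                         assignment = c(1L, 1L, 1L, 4L),
                         assigned_distance = c(0, 1e-4, 1e-4, 0),
                         coverage_threshold = 0.005,
                         max_assigned_distance = 1e-4),
                    class = "cycle_selection")
  fv2 <- extract_features(sel2, cycles[1:4])
  a <- extract_features(structure(list(representative_indices = 1L,
                                       assignment = 1L, assigned_distance = 0,
                                       coverage_threshold = 0.005,
                                       max_assigned_distance = 0),
                                  class = "cycle_selection"), cycles[1])
  b <- extract_features(structure(list(representative_indices = 1L,
                                       assignment = 1L, assigned_distance = 0,
                                       coverage_threshold = 0.005,
                                       max_assigned_distance = 0),
                                  class = "cycle_selection"), cycles[4])
  expect_equal(fv2, (3 * a + b) / 4, tolerance = 1e-12)
})

test_that("feature vectors are finite, fixed-size and order-invariant", {
  g <- generate_recording(synth_config(seed = 8, noise_snr_db = 15,
                                       murmur_kind = "pathological_systolic",
                                       murmur_relative_amplitude = 0.6))
  cycles <- segment_recording(bandpass_filter(g$recording))$cycles
  fv <- extract_features(select_representatives(cycles), cycles)
  expect_length(fv, 12)
  expect_true(all(is.finite(fv)))

  perm <- rev(seq_along(cycles))
  fv_perm <- extract_features(select_representatives(cycles[perm]),
                              cycles[perm])
  expect_equal(fv, fv_perm, tolerance = 1e-10)
})

test_that("systolic Shannon energy separates classes with a large effect", {
  se_sys <- function(item) {
    r <- item$recording; tr <- item$truth; fs <- r$sample_rate_hz
    vals <- numeric(0)
    for (k in seq_along(tr$s2_times_s)) {
      a <- floor(tr$s1_times_s[k] * fs) + 1
      b <- floor(tr$s2_times_s[k] * fs)
      vals <- c(vals, r$samples[a:b])
    }
    shannon_energy(pmax(pmin(vals, 1), -1))
  }
  gen <- function(kind, seed) {
    generate_recording(synth_config(murmur_kind = kind,
                                    murmur_relative_amplitude = 0.5,
                                    noise_snr_db = 20, seed = seed))
  }
  normals <- vapply(1:25, function(i) {
    se_sys(gen(c("none", "innocent_systolic")[i %% 2 + 1], i))
  }, numeric(1))
  paths <- vapply(1:25, function(i) {
    se_sys(gen("pathological_systolic", 500 + i))
  }, numeric(1))
  d <- (mean(paths) - mean(normals)) /
    sqrt((var(paths) + var(normals)) / 2)
  expect_gt(abs(d), 1)
})
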