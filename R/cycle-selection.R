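#' Euclidean distance between equal-length series
#'
#' `sqrt(sum((x - y)^2))` — the local metric underlying the DTW alignment.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop_param("`x` and `y` must have equal length (", length(x), " vs ",
               length(y), ")")
  }
  sqrt(sum((x - y)^2))
}

#' DTW global path constraint
#'
#' @param kind `"none"`, `"sakoe_chiba"` (band around the diagonal) or
#'   `"itakura"` (parallelogram with slope bounds 1/2 and 2).
#' @param band_width Band half-width in index units (Sakoe-Chiba only,
#'   >= 1). When `NULL`, 10% of the longer series length is used at call
#'   time.
#' @return A `dtw_constraint` object.
#' @export
dtw_constraint <- function(kind = c("sakoe_chiba", "none", "itakura"),
                           band_width = NULL) {
  kind <- match.arg(kind)
  if (!is.null(band_width)) {
    check_scalar(band_width, "band_width", positive = TRUE)
    if (kind == "sakoe_chiba" && band_width < 1) {
      stop_param("`band_width` must be >= 1 index unit")
    }
  }
  structure(list(kind = kind, band_width = band_width),
            class = "dtw_constraint")
}

#' Dynamic time warping distance between two series
#'
#' Accumulated cost over monotone warping paths with steps (1,0), (0,1),
#' (1,1), local cost `|a_i - b_j|` (the one-dimensional Euclidean metric),
#' solved by dynamic programming on the m-by-n cost matrix. The reported
#' `distance` is the accumulated cost divided by the path length (per-step
#' normalization), so one absolute threshold is comparable across cycle
#' lengths.
#'
#' @param a,b Non-empty numeric vectors.
#' @param constraint A [dtw_constraint]; default unconstrained.
#' @return A `dtw_result`: `distance` (per-step), `cost` (accumulated),
#'   `path` (two-column index matrix from (1,1) to (m,n)), `path_length`.
#' @export
dtw_distance <- function(a, b, constraint = dtw_constraint("none")) {
  if (length(a) == 0 || length(b) == 0) {
    stop_param("DTW inputs must be non-empty")
  }
  stopifnot(inherits(constraint, "dtw_constraint"))
  ctype <- match(constraint$kind, c("none", "sakoe_chiba", "itakura")) - 1L
  band <- constraint$band_width
  if (ctype == 1L && is.null(band)) {
    band <- max(1, round(0.1 * max(length(a), length(b))))
  }
  res <- dtw_core(as.numeric(a), as.numeric(b), ctype,
                  if (is.null(band)) 0 else band)
  if (!is.finite(res$cost)) {
    stop_param("DTW constraint window is infeasible for lengths ",
               length(a), " and ", length(b))
  }
  path <- cbind(i = res$path_i, j = res$path_j)
  structure(list(distance = res$cost / nrow(path), cost = res$cost,
                 path = path, path_length = nrow(path)),
            class = "dtw_result")
}

# Resample a cycle's samples to a common length and normalize peak amplitude,
# so the absolute DTW threshold is scale- and length-comparable.
cycle_to_common <- function(cycle, n_points = 256L) {
  x <- if (inherits(cycle, "cardiac_cycle")) cycle$samples else as.numeric(cycle)
  if (length(x) < 2L) stop_param("cycle too short to resample")
  y <- approx(seq(0, 1, length.out = length(x)), x,
              xout = seq(0, 1, length.out = n_points))$y
  m <- max(abs(y))
  if (m > 0) y <- y / m
  y
}

#' Select representative cardiac cycles by DTW coverage
#'
#' Iterative data reduction: cycles are resampled to a common length (256
#' points) and peak-normalized, all pairwise per-step DTW distances are
#' computed, and a greedy cover is built — the cycle with minimal summed DTW
#' distance to the still-uncovered cycles (the "pattern cycle") is taken as a
#' representative, every uncovered cycle within `threshold` of it is assigned
#' to it, and the step repeats until all cycles are covered. Ties break
#' toward the lower cycle index.
#'
#' @param cycles List of `cardiac_cycle` objects (or numeric vectors), >= 1.
#' @param threshold Coverage threshold on the per-step DTW distance; default
#'   0.005.
#' @param constraint A [dtw_constraint]; default Sakoe-Chiba band of 10% of
#'   the common length.
#' @param n_points Common resampling length for comparison.
#' @return A `cycle_selection`: `representative_indices`, `assignment`
#'   (cycle index -> representative index), `assigned_distance`,
#'   `coverage_threshold`, `max_assigned_distance`, and the pairwise
#'   `distance_matrix`.
#' @export
select_representatives <- function(cycles, threshold = 0.005,
                                   constraint = dtw_constraint("sakoe_chiba"),
                                   n_points = 256L) {
  if (!is.list(cycles) || length(cycles) == 0) {
    stop_param("`cycles` must be a non-empty list")
  }
  if (threshold < 0) stop_param("`threshold` must be >= 0")
  n <- length(cycles)
  common <- lapply(cycles, cycle_to_common, n_points = n_points)

  D <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- dtw_distance(common[[i]], common[[j]],
                                           constraint)$distance
      }
    }
  }

  assignment <- rep(NA_integer_, n)
  assigned_distance <- rep(NA_real_, n)
  reps <- integer(0)
  uncovered <- seq_len(n)
  while (length(uncovered) > 0) {
    sums <- vapply(uncovered,
                   function(i) sum(D[i, uncovered]), numeric(1))
    medoid <- uncovered[which.min(sums)]  # which.min ties -> lower index
    covered <- uncovered[D[medoid, uncovered] < threshold |
                           uncovered == medoid]
    assignment[covered] <- medoid
    assigned_distance[covered] <- D[medoid, covered]
    reps <- c(reps, medoid)
    uncovered <- setdiff(uncovered, covered)
  }

  structure(list(representative_indices = sort(reps),
                 assignment = assignment,
                 assigned_distance = assigned_distance,
                 coverage_threshold = threshold,
                 max_assigned_distance = max(assigned_distance),
                 distance_matrix = D),
            class = "cycle_selection")
}
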