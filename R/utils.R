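# Internal validation helpers. All user-facing errors name the offending
# argument so CLI wrappers can surface them verbatim.

stop_param <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_scalar <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param("`", name, "` must be a single finite number")
  }
  if (positive && x <= 0) stop_param("`", name, "` must be > 0")
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_param("`", name, "` must be a whole number")
  }
  invisible(x)
}

# Run an expression under a temporary RNG state seeded from `seed`, restoring
# the caller's state afterwards so library code never clobbers user RNG streams.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed derived from a parent seed and an index, kept well
# inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 10007) %% 2147483629)
}
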