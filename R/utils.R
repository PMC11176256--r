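# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive an independent per-generator seed from one global seed, so adding a
# generator never perturbs another generator's stream. Kept below 2^31.
#' @keywords internal
#' @noRd
substream_seed <- function(seed, stream) {
  stop_if_not(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "`seed` must be a single finite number")
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 999983L
  as.integer((abs(as.integer(seed)) %% 999983L) * 2048L + h)
}

#' @keywords internal
#' @noRd
geomean <- function(x) {
  stop_if_not(all(is.finite(x)) && all(x > 0),
              "geometric mean requires finite positive values")
  exp(mean(log(x)))
}

# Multiplicative log-normal noise with unit mean and coefficient of
# variation `cv` on the linear scale.
#' @keywords internal
#' @noRd
rlnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
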