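#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# route their `seed` argument through this helper so that callers' RNG streams
# are never disturbed.
with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a child seed from a master seed and a stage tag
#'
#' Deterministic map from one master seed to per-stage seeds so a whole
#' pipeline run is reproducible from a single integer. Results stay below
#' 2^31 - 1 (a valid R integer seed).
#'
#' @param seed master integer seed (NULL passes through).
#' @param tag a short string naming the consumer.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

vec_norm <- function(v) sqrt(sum(v^2))

normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- NA_real_
  m / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
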