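#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulation helpers do not
#' disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash mixing, exact in double arithmetic
# (multiplier kept small enough that h * mult < 2^53).
hash_mix <- function(h, v) {
  ((h * 69069) %% 2147483647 + (v %% 2147483647)) %% 2147483647
}

#' Derive a per-site RNG key from a master seed and site coordinates
#'
#' Keys the pseudo-haploid caller's random base selection by
#' `(seed, chrom, pos)` so calls are order-independent and reproducible
#' under any processing order.
#'
#' @param seed Master integer seed.
#' @param chrom Chromosome label (coerced to character).
#' @param pos Physical position.
#' @return Integer key in `[1, 2^31 - 2]`, vectorized over sites.
#' @export
site_key <- function(seed, chrom, pos) {
  chrom <- as.character(chrom)
  ch <- vapply(chrom, function(s) {
    u <- utf8ToInt(s)
    h <- 7
    for (k in seq_along(u)) h <- hash_mix(h, u[k] * k)
    h
  }, numeric(1), USE.NAMES = FALSE)
  h <- hash_mix(abs(as.numeric(seed)) + 11, ch)
  h <- hash_mix(h, as.numeric(pos))
  h <- hash_mix(h, 2654435)
  as.integer(h %% 2147483645 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
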