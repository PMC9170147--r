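#' @keywords internal
"_PACKAGE"

# Seed plumbing ---------------------------------------------------------

#' Derive child seeds from a master seed
#'
#' All stochastic operations in the package take an explicit integer seed.
#' Pipelines that need several independent streams derive child seeds from a
#' single master seed with this helper: the master seed initialises R's RNG
#' once and `n` integers are drawn from it.  The scheme is deterministic and
#' keeps every derived seed below `.Machine$integer.max`.
#'
#' @param seed master integer seed.
#' @param n number of child seeds to derive.
#' @return integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# run `expr` under `seed` (NULL = current RNG state), restoring state after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Tiny FNV-1a fingerprint used in output-file headers (seed provenance only,
# not cryptographic).
fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gc <- function(...) stop(..., call. = FALSE)
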