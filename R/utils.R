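# Internal helpers shared across modules.

#' Evaluate code under a local RNG seed
#'
#' Restores the caller's RNG state on exit so seeded generators never perturb
#' the surrounding random stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named substream seed from a global seed
#'
#' Deterministic hash of (seed, label) into [0, 2^31 - 2]; each generator
#' component draws from its own substream so adding one generator does not
#' perturb the values produced by another.
#' @noRd
substream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * (seq_along(codes) %% 97 + 1))
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 131 + 17) %% 2147483647)
}

#' @noRd
stop_ <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
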