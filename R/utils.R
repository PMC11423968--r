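## Internal helpers shared across modules.

## Evaluate `code` under a temporary RNG state seeded with `seed`.
## A NULL seed leaves the caller's RNG stream untouched and in use, so calls
## nested inside a seeded pipeline still draw from one reproducible stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Derive a stream-specific sub-seed from one global seed so pipeline stages
## can be re-run independently. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + stream * 9973) %% 2147483629
}

stop_if_negative <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(what, " must be finite and nonnegative", call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
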