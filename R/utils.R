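# Internal helpers: seeded evaluation, seed derivation, validation.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a sub-seed from a base seed and a character tag so
# that every operation draws from its own named stream (kept below 2^31).
derive_seed <- function(seed, ...) {
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 + h) %% 2147480009) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == round(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
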