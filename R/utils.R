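# internal helpers shared across modules

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministically derive a 31-bit sub-seed from a master seed and a stream
# index, so every species / run / region gets its own named stream and the
# result does not depend on generation order.
mix_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  k <- (as.double(stream) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + k * 69621) %% 2147483647
  x <- (x * 16807) %% 2147483647
  as.integer(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != as.integer(x)) {
    stopf("`%s` must be a single positive integer, got %s", name, deparse(x))
  }
  as.integer(x)
}
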