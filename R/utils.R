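# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Generators take one explicit integer
# seed and never leak global RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a root seed; keeps every stream
# below 2^31 and decoupled from the others.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 48271 + as.integer(stream)) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 ||
      x != floor(x))
    stop(sprintf("'%s' must be a positive integer, got %s", name,
                 paste(format(x), collapse = ",")), call. = FALSE)
  invisible(as.integer(x))
}
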