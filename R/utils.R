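# Internal helpers: seeded evaluation, nested parameter-list arithmetic.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All generator/training determinism
# contracts rest on this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one parent seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Apply f elementwise over two parallel nested lists of numeric arrays.
nested_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) nested_map2(a[[i]], b[[i]], f))
    names(out) <- names(a)
    out
  } else f(a, b)
}

nested_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, nested_map, f = f)
    names(out) <- names(a)
    out
  } else f(a)
}

# Sum a function of leaves over a nested list.
nested_sum <- function(a, f = identity) {
  if (is.list(a)) sum(vapply(a, nested_sum, numeric(1), f = f)) else sum(f(a))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("`%s` must be a single non-negative integer", name), call. = FALSE)
}
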