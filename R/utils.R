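# Run expr with a locally seeded RNG, restoring global state afterward.
# All generator/permutation functions route their randomness through this
# so they are pure functions of (arguments, seed).
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Derive a child seed from a base seed and a stage label, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, salt) {
  s <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((as.numeric(seed) * 7919 + s * 104729) %% 2147483647)
}

check_positive_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("invalid parameter: `%s` must be a positive integer", name),
         call. = FALSE)
  as.integer(x)
}

check_positive_number <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (if (allow_zero) x < 0 else x <= 0))
    stop(sprintf("invalid parameter: `%s` must be %s", name,
                 if (allow_zero) "a non-negative number" else "a positive number"),
         call. = FALSE)
  as.numeric(x)
}
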