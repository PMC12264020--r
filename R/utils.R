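#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: every consumer of randomness draws its
# own stream from (seed, tag) so that e.g. train and test splits of one
# domain are independent and insensitive to call order.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}
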