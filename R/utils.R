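# internal helpers shared across modules

# coerce a sample set to a numeric matrix with points in rows
as_sample_matrix <- function(x, arg = "x") {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix (samples in rows)", arg), call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop(sprintf("'%s' must have at least one row and one column", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' contains non-finite entries", arg), call. = FALSE)
  }
  x
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# deterministic substream seeds below 2^31, derived from a master seed and a tag
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483629 + 1)
}

# evaluate fn with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}
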