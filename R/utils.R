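# Internal helpers: seeded RNG scoping and image checks.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream-specific 31-bit seed from a base seed and a stream index.
mix_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stream) * 16807
  as.integer(s %% 2147483629) + 1L
}

is_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

assert_image <- function(x, what = "image") {
  if (!is_image(x)) stop(sprintf("`%s` must be an H x W x 3 numeric array", what), call. = FALSE)
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# (H, W) helpers --------------------------------------------------------

image_hw <- function(img) dim(img)[1:2]

check_size <- function(size, what = "size") {
  if (!is.numeric(size) || length(size) != 2L || any(size < 1)) {
    stop(sprintf("`%s` must be a length-2 (H, W) vector of positive sizes", what), call. = FALSE)
  }
  as.integer(size)
}
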