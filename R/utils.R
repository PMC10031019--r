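# Seed plumbing.  Every source of randomness in the package flows through
# explicit seeds: code that needs random numbers wraps itself in with_seed(),
# which saves and restores the caller's RNG state, and sub-seeds are derived
# deterministically with derive_seed() so one run seed fans out to phantom
# generation, splitting, weight init and batch shuffling without collisions.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sym <- function(...) stop(..., call. = FALSE)

assert_image01 <- function(image, what = "image") {
  if (!is.numeric(image)) stop_sym(what, " must be numeric")
  if (anyNA(image)) stop_sym(what, " contains NA values")
  rng <- range(image)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop_sym(what, " values must lie in [0, 1]")
  invisible(TRUE)
}

assert_binary_mask <- function(mask, what = "mask") {
  if (!all(mask %in% c(0, 1)))
    stop_sym(what, " must be binary (0/1); binarize first")
  invisible(TRUE)
}

# Coerce a matrix or [H,W] / [H,W,C] array to the internal [H,W,C,N] layout.
as_nhwc <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop_sym("expected a matrix or array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop_sym("expected 2-4 dimensions")
  x
}

# Drop trailing unit dims back to a matrix when the input was one image.
as_image_out <- function(x, like) {
  if (is.null(dim(like)) || length(dim(like)) == 2L) {
    y <- x[, , 1L, 1L]
    dim(y) <- dim(x)[1:2]
    y
  } else x
}
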