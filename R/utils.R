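# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Coerce x to an n x 2 numeric matrix of coordinates.
as_points_ <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 2L)
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 2L) stop("points must have two coordinate columns")
  x
}

stop_if_not_finite_ <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s must be finite", what), call. = FALSE)
  invisible(x)
}
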