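#' Well names for a rectangular plate, row-major
#'
#' 384-well plates are named A1..P24 row-major; 96-well (A1..H12) is supported
#' for small tests. Other formats must be a product of a row count in 1..26
#' and a column count.
#'
#' @param plate_format total number of wells (384 or 96, or any r x c with
#'   r <= 26 when given as `c(rows, cols)` via `dims`).
#' @param dims optional explicit `c(rows, cols)` overriding the lookup.
#' @return character vector of well names, length `plate_format`, row-major.
#' @export
well_names <- function(plate_format = 384, dims = NULL) {
  if (is.null(dims)) {
    dims <- switch(as.character(plate_format),
      "384" = c(16L, 24L),
      "96"  = c(8L, 12L),
      "24"  = c(4L, 6L),
      stop("unsupported plate_format ", plate_format,
           "; give dims = c(rows, cols)")
    )
  }
  stopifnot(dims[1] >= 1, dims[1] <= 26, dims[2] >= 1)
  as.vector(t(outer(LETTERS[seq_len(dims[1])], seq_len(dims[2]), paste0)))
}

# Named substreams off one top-level seed, so each pipeline stage has its own
# reproducible stream. Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * (31 ^ (seq_along(utf8ToInt(as.character(stream))) %% 7)))
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, stream))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# Multiplicative lognormal noise with unit mean and coefficient of variation cv.
lognorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
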