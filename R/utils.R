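#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed} and restores the
#' previous RNG state afterwards, so generators are deterministic without
#' leaking state into the caller's session.
#'
#' @param seed integer seed (mandatory; no hidden global randomness).
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("an explicit integer 'seed' is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# scalar validators used across the generators
check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

#' Single- or multi-channel raster image with physical pixel size
#'
#' The common currency of the imaging stages: a numeric matrix (one channel)
#' or rows x cols x 3 array (color), plus the pixel pitch in micrometers per
#' pixel.
#'
#' @param data numeric matrix or 3-channel array, values in [0, 1] for
#'   rendered images.
#' @param pixel_size physical pixel size, um/pixel (> 0).
#' @return object of class \code{raster_image}.
#' @export
raster_image <- function(data, pixel_size) {
  check_scalar(pixel_size, "pixel_size", lo = .Machine$double.eps)
  if (!(is.matrix(data) || (is.array(data) && length(dim(data)) == 3L)))
    stop("'data' must be a matrix or a 3-channel array", call. = FALSE)
  structure(list(data = data, pixel_size = pixel_size), class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$data)
  ch <- if (length(d) == 3L) d[3] else 1L
  cat(sprintf("<raster_image %d x %d px, %d channel(s), %.3g um/px>\n",
              d[1], d[2], ch, x$pixel_size))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$data)

# coerce a raster_image or plain matrix to a matrix (first channel)
as_channel <- function(image) {
  if (inherits(image, "raster_image")) image <- image$data
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (is.array(image) && length(dim(image)) == 3L) image <- image[, , 1]
  if (!is.matrix(image)) stop("expected a single-channel image", call. = FALSE)
  image
}
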