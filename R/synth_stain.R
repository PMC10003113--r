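# Synthetic immunostained section images: a 3-channel color image in which a
# known fraction of region-of-interest pixels carries the stain hue (violet-
# pink chromogen) and the remainder a pale tissue background. The stained set
# is the upper quantile of a smoothed random field, so it is spatially blobby
# (like real chromogen deposits) while the stained fraction is exact.

#' Generate a synthetic stained-section image with ground truth
#'
#' @param f target stained-pixel fraction of the ROI, in [0, 1].
#' @param seed mandatory integer seed.
#' @param dim image dimensions in pixels.
#' @param roi optional logical matrix marking the region of interest (the
#'   "dermis"); default is a central rectangle covering ~60\% of the image.
#' @param stain_hue center of the stain hue, in [0, 1) on the hue circle
#'   (default 0.87, violet-pink).
#' @param hue_width half-width of the rendered stain hue band.
#' @param pixel_size um per pixel.
#' @return list with \code{image} (\code{\link{raster_image}}, rows x cols x
#'   3 RGB in [0, 1]), \code{roi}, and \code{truth} (list: f, stain_hue,
#'   hue_width, n_stained).
#' @export
gen_stain_image <- function(f, seed, dim = c(160L, 160L), roi = NULL,
                            stain_hue = 0.87, hue_width = 0.03,
                            pixel_size = 1) {
  check_scalar(f, "f", 0, 1)
  if (is.null(roi)) {
    roi <- matrix(FALSE, dim[1], dim[2])
    r0 <- round(dim[1] * 0.2); r1 <- round(dim[1] * 0.8)
    c0 <- round(dim[2] * 0.2); c1 <- round(dim[2] * 0.8)
    roi[r0:r1, c0:c1] <- TRUE
  } else {
    roi <- as_channel(roi) > 0
    dim <- base::dim(roi)
  }
  n_roi <- sum(roi)
  if (n_roi == 0) stop("empty ROI", call. = FALSE)
  with_seed(seed, {
    field <- matrix(stats::rnorm(prod(dim)), dim[1], dim[2])
    field <- EBImage::imageData(EBImage::gblur(EBImage::Image(field),
                                               sigma = 3))
    n_stain <- floor(f * n_roi)
    stained <- matrix(FALSE, dim[1], dim[2])
    if (n_stain > 0) {
      v <- field[roi]
      cut <- sort(v, decreasing = TRUE)[n_stain]
      sel <- which(roi & field >= cut)
      # quantile ties could overshoot; trim deterministically
      sel <- sel[order(-field[sel])][seq_len(n_stain)]
      stained[sel] <- TRUE
    }
    n <- prod(dim)
    hue <- matrix(stats::runif(n, 0.06, 0.12), dim[1], dim[2])   # pale beige
    sat <- matrix(stats::runif(n, 0.02, 0.12), dim[1], dim[2])   # below band
    val <- matrix(stats::runif(n, 0.85, 0.98), dim[1], dim[2])
    ns <- sum(stained)
    hue[stained] <- stain_hue + stats::runif(ns, -hue_width, hue_width)
    sat[stained] <- stats::runif(ns, 0.45, 0.85)
    val[stained] <- stats::runif(ns, 0.55, 0.85)
    col <- grDevices::hsv(hue %% 1, sat, val)
    rgb <- grDevices::col2rgb(col) / 255
    img <- array(0, c(dim[1], dim[2], 3L))
    img[, , 1] <- matrix(rgb[1, ], dim[1], dim[2])
    img[, , 2] <- matrix(rgb[2, ], dim[1], dim[2])
    img[, , 3] <- matrix(rgb[3, ], dim[1], dim[2])
    list(image = raster_image(img, pixel_size), roi = roi,
         truth = list(f = f, stain_hue = stain_hue, hue_width = hue_width,
                      n_stained = ns))
  })
}
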