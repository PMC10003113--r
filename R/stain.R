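# Immunostain color-index quantification, following the GIMP/ImageJ recipe:
# select the stain-colored pixels, histogram hue into 255 color categories,
# sum the counts of the stain peak, and divide by the ROI surface area. The
# index of a treated section is then expressed as a percentage of the
# blue-light-stressed control.

#' Default stain color band (violet-pink chromogen)
#'
#' Contiguous hue interval (fractions of the hue circle) plus a minimum
#' saturation; echoed into outputs for provenance.
#' @return list with \code{hue_min}, \code{hue_max}, \code{min_sat}.
#' @export
stain_band <- function(hue_min = 0.78, hue_max = 0.96, min_sat = 0.15) {
  if (hue_min >= hue_max) stop("empty hue band", call. = FALSE)
  list(hue_min = hue_min, hue_max = hue_max, min_sat = min_sat)
}

# hue/saturation/value arrays from an RGB raster
image_hsv <- function(image) {
  x <- if (inherits(image, "raster_image")) image$data else image
  if (length(dim(x)) != 3L || dim(x)[3] < 3L)
    stop("a 3-channel image is required", call. = FALSE)
  hsv <- grDevices::rgb2hsv(r = as.vector(x[, , 1]), g = as.vector(x[, , 2]),
                            b = as.vector(x[, , 3]), maxColorValue = 1)
  list(h = matrix(hsv[1, ], dim(x)[1], dim(x)[2]),
       s = matrix(hsv[2, ], dim(x)[1], dim(x)[2]),
       v = matrix(hsv[3, ], dim(x)[1], dim(x)[2]))
}

#' Select stain-colored pixels
#'
#' @param image 3-channel \code{\link{raster_image}} or array.
#' @param band color band from \code{\link{stain_band}}.
#' @return logical matrix: pixels whose hue lies in the band at sufficient
#'   saturation.
#' @export
select_stain_pixels <- function(image, band = stain_band()) {
  if (band$hue_min >= band$hue_max) stop("empty hue band", call. = FALSE)
  hsv <- image_hsv(image)
  hsv$h >= band$hue_min & hsv$h <= band$hue_max & hsv$s >= band$min_sat
}

#' Hue histogram over a mask ("255 color categories")
#'
#' @param image 3-channel image.
#' @param mask logical matrix restricting the count (e.g. selected stain
#'   pixels within the ROI).
#' @param n_bins number of equal hue bins over the hue circle (default 255).
#' @return integer vector of per-bin counts; sums to the mask pixel count.
#' @export
color_histogram <- function(image, mask, n_bins = 255L) {
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  hsv <- image_hsv(image)
  m <- as_channel(mask) > 0
  h <- hsv$h[m]
  bin <- base::pmin(floor(h * n_bins) + 1L, n_bins)
  tabulate(bin, nbins = n_bins)
}

#' Hue bin index for a hue value
#' @param hue hue in [0, 1).
#' @param n_bins number of bins.
#' @return bin index in 1..n_bins.
#' @export
hue_bin <- function(hue, n_bins = 255L) {
  base::pmin(floor((hue %% 1) * n_bins) + 1L, n_bins)
}

#' Color index: stain peak sum count divided by ROI surface area
#'
#' @param counts histogram from \code{\link{color_histogram}}.
#' @param peak_bins indices of the bins forming the stain peak.
#' @param roi_area ROI surface area in pixels (> 0).
#' @return list: sum_count, roi_area, color_index in [0, 1].
#' @export
color_index <- function(counts, peak_bins, roi_area) {
  if (roi_area <= 0) stop("roi_area must be positive", call. = FALSE)
  if (any(peak_bins < 1 | peak_bins > length(counts)))
    stop("peak_bins outside histogram range", call. = FALSE)
  sum_count <- sum(counts[peak_bins])
  list(sum_count = sum_count, roi_area = roi_area,
       color_index = sum_count / roi_area)
}

#' Express a color index as a percentage of the stressed control
#'
#' @param index color index of the condition of interest.
#' @param control_index color index of the blue-light-stressed control (> 0).
#' @return percentage (100 = equal to control).
#' @export
normalize_to_control <- function(index, control_index) {
  if (control_index <= 0)
    stop("control index must be positive", call. = FALSE)
  100 * index / control_index
}

#' Full stain quantification for one section image
#'
#' Runs the selection, histogram, and index steps; the peak bins are the
#' bins covered by the configured hue band.
#'
#' @param image 3-channel image.
#' @param roi logical ROI matrix ("the dermis").
#' @param band color band from \code{\link{stain_band}}.
#' @param n_bins hue histogram resolution.
#' @return list with the \code{color_index} fields plus the echoed band.
#' @export
quantify_stain <- function(image, roi, band = stain_band(), n_bins = 255L) {
  roi <- as_channel(roi) > 0
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  sel <- select_stain_pixels(image, band) & roi
  counts <- color_histogram(image, sel, n_bins)
  peak <- hue_bin(band$hue_min, n_bins):hue_bin(band$hue_max, n_bins)
  res <- color_index(counts, peak, sum(roi))
  res$band <- band
  res
}
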