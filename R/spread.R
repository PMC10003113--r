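# Micropattern cell-spreading analysis: detect one cell per pattern site,
# measure its footprint area, and summarize mean area and the percentage of
# correctly spread cells (area strictly above the spread threshold).

#' Detect single cells on micropattern sites
#'
#' Thresholds the F-actin image, fills holes (the spreading area is the
#' footprint, not the stained skeleton), labels connected components, and
#' assigns each to the nearest pattern center. Sites holding zero or more
#' than one cell are excluded with the reason logged in the output.
#'
#' @param image \code{\link{raster_image}} or matrix (single channel).
#' @param layout list with \code{centers} (n x 2 matrix of pattern centers,
#'   um) and \code{pitch} (center spacing, um), as returned by
#'   \code{\link{gen_micropattern_image}}.
#' @param threshold intensity threshold (default 0.5 for rendered masks).
#' @return data.frame with one row per pattern: pattern id, status
#'   (\code{"ok"}, \code{"empty"}, \code{"multiple"}), cell pixel count,
#'   area um^2, centroid, spread flag unset (see
#'   \code{\link{spreading_metrics}}).
#' @export
detect_cells <- function(image, layout, threshold = 0.5) {
  if (is.null(layout) || is.null(layout$centers))
    stop("a pattern layout with centers is required", call. = FALSE)
  x <- as_channel(image)
  px <- if (inherits(image, "raster_image")) image$pixel_size else 1
  mask <- x > threshold
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  lab <- label_components(mask)
  n_comp <- max(lab)
  centers <- layout$centers
  n_pat <- nrow(centers)
  comp_pattern <- integer(n_comp)
  comp_size <- tabulate(lab[lab > 0], nbins = n_comp)
  comp_cx <- comp_cy <- numeric(n_comp)
  if (n_comp > 0) {
    idx <- which(lab > 0)
    rc <- arrayInd(idx, dim(lab))
    cx <- tapply((rc[, 2] - 0.5) * px, lab[idx], mean)
    cy <- tapply((rc[, 1] - 0.5) * px, lab[idx], mean)
    comp_cx[as.integer(names(cx))] <- cx
    comp_cy[as.integer(names(cy))] <- cy
    for (k in seq_len(n_comp)) {
      d <- sqrt((centers[, 1] - comp_cx[k])^2 + (centers[, 2] - comp_cy[k])^2)
      comp_pattern[k] <- which.min(d)
    }
  }
  out <- data.frame(pattern = seq_len(n_pat), status = "empty",
                    n_px = 0L, area_um2 = NA_real_,
                    cx = NA_real_, cy = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in seq_len(n_pat)) {
    comps <- which(comp_pattern == p & comp_size > 0)
    # ignore specks far below any plausible cell
    comps <- comps[comp_size[comps] * px^2 >= 50]
    if (length(comps) == 1L) {
      out$status[p] <- "ok"
      out$n_px[p] <- comp_size[comps]
      out$area_um2[p] <- comp_size[comps] * px^2
      out$cx[p] <- comp_cx[comps]
      out$cy[p] <- comp_cy[comps]
    } else if (length(comps) > 1L) {
      out$status[p] <- "multiple"
    }
  }
  out
}

#' Cell area from a binary mask
#'
#' Area = foreground pixel count x pixel_size^2.
#'
#' @param mask logical matrix (one cell).
#' @param pixel_size um per pixel.
#' @return area in um^2.
#' @export
cell_area <- function(mask, pixel_size) {
  check_scalar(pixel_size, "pixel_size", lo = .Machine$double.eps)
  m <- as_channel(mask) > 0
  if (!any(m)) stop("empty mask: no cell pixels", call. = FALSE)
  sum(m) * pixel_size^2
}

#' Spreading summary: mean area and percentage of correctly spread cells
#'
#' A cell counts as correctly spread when its area strictly exceeds the
#' threshold (1800 um^2 by default); a cell exactly at the threshold is not
#' counted.
#'
#' @param records data.frame from \code{\link{detect_cells}} (rows with
#'   status \code{"ok"} are used) or any data.frame with \code{area_um2}.
#' @param threshold spread threshold, um^2.
#' @return one-row data.frame: n_cells, mean_area_um2, pct_spread.
#' @export
spreading_metrics <- function(records, threshold = 1800) {
  if (!is.null(records$status)) records <- records[records$status == "ok", ]
  areas <- records$area_um2
  areas <- areas[!is.na(areas)]
  if (length(areas) == 0)
    stop("no measurable cells in the record list", call. = FALSE)
  data.frame(n_cells = length(areas),
             mean_area_um2 = mean(areas),
             pct_spread = 100 * mean(areas > threshold))
}
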