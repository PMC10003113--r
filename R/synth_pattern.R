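# Synthetic micropattern (F-actin) images: a grid of Y-micropattern sites
# whose adhesive envelope is an equilateral triangle; each occupied site
# carries one filled cell footprint of known area. Rendered pixel counts are
# corrected to the target area, so the truth area is conserved exactly (to
# one pixel) before noise.

#' Generate a synthetic micropattern field with ground truth
#'
#' Each pattern site holds, with the stated probabilities, nothing, one cell,
#' or two cells (a doublet, which the analysis must exclude). A single cell
#' is rendered as a filled equilateral-triangle footprint, eroded toward a
#' disk for small areas (poorly spread cells round up), with pixel count
#' matched to the true area.
#'
#' @param n_cells number of pattern sites.
#' @param seed mandatory integer seed.
#' @param mean_area,sd_area cell-area distribution, um^2 (truncated normal,
#'   areas >= 200). The default 2000 +/- 350 spans the spread threshold of
#'   1800 um^2, as in fibroblast micropattern experiments.
#' @param side triangle side length of the pattern envelope, um (default 90;
#'   an extra-large pattern whose full triangle area, side^2 sqrt(3)/4, is
#'   about 3500 um^2).
#' @param pixel_size um per pixel (default 1).
#' @param p_empty probability a site holds no cell.
#' @param p_doublet probability a site holds two cells.
#' @param noise Gaussian intensity noise sd (0 disables).
#' @return list with \code{image} (\code{\link{raster_image}}), \code{truth}
#'   (data.frame: pattern id, center x/y um, occupancy, true area um^2) and
#'   \code{layout} (pattern centers, side, pitch).
#' @export
gen_micropattern_image <- function(n_cells, seed, mean_area = 2000,
                                   sd_area = 350, side = 90, pixel_size = 1,
                                   p_empty = 0.05, p_doublet = 0.05,
                                   noise = 0.02) {
  check_scalar(side, "side", lo = .Machine$double.eps)
  check_scalar(pixel_size, "pixel_size", lo = .Machine$double.eps)
  check_scalar(n_cells, "n_cells", lo = 0)
  if (p_empty + p_doublet > 1)
    stop("p_empty + p_doublet must not exceed 1", call. = FALSE)
  pitch <- side * 1.3
  per_row <- max(1L, ceiling(sqrt(n_cells)))
  n_rows <- ceiling(n_cells / per_row)
  dim_px <- c(ceiling(n_rows * pitch / pixel_size) + 20L,
              ceiling(per_row * pitch / pixel_size) + 20L)
  empty_truth <- data.frame(pattern = integer(0), cx = numeric(0),
                            cy = numeric(0), occupancy = character(0),
                            area = numeric(0))
  with_seed(seed, {
    img <- matrix(0, dim_px[1], dim_px[2])
    truth <- empty_truth
    centers <- NULL
    for (i in seq_len(n_cells)) {
      r <- (i - 1L) %/% per_row
      c <- (i - 1L) %% per_row
      cx <- (c + 0.5) * pitch + 10 * pixel_size
      cy <- (r + 0.5) * pitch + 10 * pixel_size
      centers <- rbind(centers, c(cx, cy))
      occ <- sample(c("empty", "single", "doublet"), 1L,
                    prob = c(p_empty, 1 - p_empty - p_doublet, p_doublet))
      area <- NA_real_
      if (occ == "single") {
        area <- max(200, stats::rnorm(1, mean_area, sd_area))
        img <- draw_cell_footprint(img, cx, cy, area, side, pixel_size)
      } else if (occ == "doublet") {
        a2 <- base::pmax(200, stats::rnorm(2, mean_area / 2.5, sd_area / 2))
        off <- side * 0.28
        img <- draw_cell_footprint(img, cx - off, cy, a2[1], side * 0.42,
                                   pixel_size)
        img <- draw_cell_footprint(img, cx + off, cy, a2[2], side * 0.42,
                                   pixel_size)
        area <- sum(a2)
      }
      truth <- rbind(truth, data.frame(pattern = i, cx = cx, cy = cy,
                                       occupancy = occ, area = area,
                                       stringsAsFactors = FALSE))
    }
    if (noise > 0)
      img <- base::pmax(img + matrix(stats::rnorm(length(img), 0, noise),
                                     nrow(img)), 0)
    layout <- list(centers = centers, side = side, pitch = pitch)
    list(image = raster_image(img, pixel_size), truth = truth,
         layout = layout)
  })
}

# filled triangular footprint of exactly `area` um^2 (pixel count corrected
# by adding/removing boundary pixels deterministically)
draw_cell_footprint <- function(img, cx, cy, area, side, pixel_size) {
  target_px <- max(1L, round(area / pixel_size^2))
  # triangle with the same area as the target, capped at the pattern side
  tri_side <- min(sqrt(4 * area / sqrt(3)), side)
  # vertices of an equilateral triangle (flat bottom) centered at (cx, cy)
  h <- tri_side * sqrt(3) / 2
  vx <- c(cx - tri_side / 2, cx + tri_side / 2, cx)
  vy <- c(cy + h / 3, cy + h / 3, cy - 2 * h / 3)
  rr <- floor((cy - h) / pixel_size):ceiling((cy + h) / pixel_size)
  cc <- floor((cx - tri_side) / pixel_size):ceiling((cx + tri_side) / pixel_size)
  rr <- rr[rr >= 1 & rr <= nrow(img)]
  cc <- cc[cc >= 1 & cc <= ncol(img)]
  px <- expand.grid(r = rr, c = cc)
  x <- (px$c - 0.5) * pixel_size
  y <- (px$r - 0.5) * pixel_size
  inside <- point_in_triangle(x, y, vx, vy)
  sel <- px[inside, , drop = FALSE]
  if (nrow(sel) == 0) return(img)
  # correct the pixel count to the target area
  d2 <- ((sel$c - 0.5) * pixel_size - cx)^2 + ((sel$r - 0.5) * pixel_size - cy)^2
  ord <- order(d2)
  if (nrow(sel) > target_px) {
    sel <- sel[ord[seq_len(target_px)], , drop = FALSE]
  } else if (nrow(sel) < target_px) {
    # grow outward by rings around the triangle until the count matches
    need <- target_px - nrow(sel)
    ring <- px[!inside, , drop = FALSE]
    rd2 <- ((ring$c - 0.5) * pixel_size - cx)^2 +
      ((ring$r - 0.5) * pixel_size - cy)^2
    ring <- ring[order(rd2), , drop = FALSE]
    sel <- rbind(sel, ring[seq_len(min(need, nrow(ring))), , drop = FALSE])
  }
  img[cbind(sel$r, sel$c)] <- 1
  img
}

point_in_triangle <- function(x, y, vx, vy) {
  sign3 <- function(x1, y1, x2, y2) {
    (x - x2) * (y1 - y2) - (x1 - x2) * (y - y2)
  }
  d1 <- sign3(vx[1], vy[1], vx[2], vy[2])
  d2 <- sign3(vx[2], vy[2], vx[3], vy[3])
  d3 <- sign3(vx[3], vy[3], vx[1], vy[1])
  neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  !(neg & pos)
}
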