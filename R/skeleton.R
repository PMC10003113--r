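# Segmentation and thinning of filament images. Thresholding goes through
# EBImage's Otsu; thinning is a vectorized Zhang-Suen pass (no installed
# package provides binary skeletonization), which preserves 8-connectivity so
# the tree count of the mask carries over to the skeleton.

#' Segment mitochondrial filaments from a fluorescence image
#'
#' Gaussian-blurs the (normalized) channel and applies Otsu's threshold.
#'
#' @param image \code{\link{raster_image}} or numeric matrix, single channel.
#' @param method thresholding method; only \code{"otsu"} is implemented.
#' @param invert set \code{TRUE} for inverted-contrast input (dark filaments
#'   on bright background).
#' @param blur_sigma pre-threshold Gaussian blur sigma in pixels (0
#'   disables; the default 0.5 suppresses shot noise without widening
#'   filaments enough to merge neighbors).
#' @return logical matrix; \code{TRUE} = filament pixels.
#' @export
segment_mitochondria <- function(image, method = "otsu", invert = FALSE,
                                 blur_sigma = 0.5) {
  x <- as_channel(image)
  if (!all(is.finite(x))) stop("image contains non-finite intensities",
                               call. = FALSE)
  rng <- range(x)
  if (diff(rng) == 0) stop("no contrast: image is constant", call. = FALSE)
  x <- (x - rng[1]) / diff(rng)
  if (invert) x <- 1 - x
  if (blur_sigma > 0)
    x <- EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma = blur_sigma))
  method <- match.arg(method, "otsu")
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  x > th
}

# shift of a numeric matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# the 8 neighbors in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW);
# rows grow downward so "north" is row - 1
zs_neighbors <- function(m) {
  list(
    p2 = shift_mat(m, 1, 0),   # value of the pixel's north neighbor
    p3 = shift_mat(m, 1, -1),
    p4 = shift_mat(m, 0, -1),
    p5 = shift_mat(m, -1, -1),
    p6 = shift_mat(m, -1, 0),
    p7 = shift_mat(m, -1, 1),
    p8 = shift_mat(m, 0, 1),
    p9 = shift_mat(m, 1, 1)
  )
}

#' Skeletonize a binary mask (Guo-Hall thinning with tip re-extension)
#'
#' Two-subiteration Guo-Hall parallel thinning peels border pixels until a
#' one-pixel-wide, 8-connected medial representation remains; connected
#' component count is preserved, so each mask component maps to one skeleton
#' tree. Parallel thinning shortens line ends by about one pixel, so skeleton
#' tips are then re-extended along their local direction while still inside
#' the original mask, which restores the full medial axis of straight bars.
#'
#' @param mask logical or 0/1 matrix.
#' @param extend_tips re-extend skeleton endpoints into the mask
#'   (default TRUE).
#' @return logical matrix of skeleton pixels (empty mask gives empty skeleton).
#' @export
skeletonize <- function(mask, extend_tips = TRUE) {
  m <- (as_channel(mask) > 0) * 1
  if (!any(m == 1)) return(m > 0)
  orig <- m
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- zs_neighbors(m)
      p2 <- nb$p2; p3 <- nb$p3; p4 <- nb$p4; p5 <- nb$p5
      p6 <- nb$p6; p7 <- nb$p7; p8 <- nb$p8; p9 <- nb$p9
      cr <- (1 - p2) * base::pmax(p3, p4) + (1 - p4) * base::pmax(p5, p6) +
        (1 - p6) * base::pmax(p7, p8) + (1 - p8) * base::pmax(p9, p2)
      n1 <- base::pmax(p9, p2) + base::pmax(p3, p4) + base::pmax(p5, p6) + base::pmax(p7, p8)
      n2 <- base::pmax(p2, p3) + base::pmax(p4, p5) + base::pmax(p6, p7) + base::pmax(p8, p9)
      nn <- base::pmin(n1, n2)
      o <- if (sub == 1) base::pmax(p6, p7, 1 - p9) * p8
           else base::pmax(p2, p3, 1 - p5) * p4
      del <- m == 1 & cr == 1 & nn >= 2 & nn <= 3 & o == 0
      if (any(del)) {
        m[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (extend_tips) m <- extend_skeleton_tips(m, orig)
  m > 0
}

# grow each skeleton endpoint along its local direction while the candidate
# pixel lies in the original mask and touches no skeleton pixel other than
# the current tip (keeps the skeleton one pixel wide and cannot merge trees)
extend_skeleton_tips <- function(skel, mask, max_steps = 5L) {
  nr <- nrow(skel); nc <- ncol(skel)
  deg <- neighbor_counts(skel)
  tips <- which(skel == 1 & deg == 1)
  for (lin in tips) {
    p <- c((lin - 1L) %% nr + 1L, (lin - 1L) %/% nr + 1L)
    nbr <- NULL
    for (i in seq_len(nrow(NB_OFFSETS))) {
      q <- p + NB_OFFSETS[i, ]
      if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
          skel[q[1], q[2]] == 1) { nbr <- q; break }
    }
    if (is.null(nbr)) next
    d <- p - nbr
    cur <- p
    for (s in seq_len(max_steps)) {
      cand <- cur + d
      if (cand[1] < 1 || cand[1] > nr || cand[2] < 1 || cand[2] > nc) break
      if (mask[cand[1], cand[2]] != 1 || skel[cand[1], cand[2]] == 1) break
      # candidate may touch only the current tip
      touch <- 0L
      ok <- TRUE
      for (i in seq_len(nrow(NB_OFFSETS))) {
        q <- cand + NB_OFFSETS[i, ]
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
        if (skel[q[1], q[2]] == 1) {
          if (q[1] == cur[1] && q[2] == cur[2]) touch <- touch + 1L
          else { ok <- FALSE; break }
        }
      }
      if (!ok || touch != 1L) break
      skel[cand[1], cand[2]] <- 1
      cur <- cand
    }
  }
  skel
}

#' Label 8-connected components of a binary mask
#'
#' Iterative minimum-label propagation; used for tree counting, junction
#' clustering, and cell detection.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix; 0 = background, components labeled 1..k.
#' @export
label_components <- function(mask) {
  m <- as_channel(mask) > 0
  lab <- matrix(0, nrow(m), ncol(m))
  lab[m] <- seq_len(sum(m))
  lab[!m] <- Inf
  offs <- list(c(1, 0), c(1, -1), c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
               c(0, 1), c(1, 1))
  repeat {
    new <- lab
    for (o in offs) new <- base::pmin(new, shift_mat(lab, o[1], o[2], fill = Inf))
    new[!m] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!m] <- 0
  u <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(m), ncol(m))
  out[m] <- match(lab[m], u)
  out
}
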