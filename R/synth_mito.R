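# Synthetic single-cell mitochondrial filament networks with known ground
# truth. A cell is a disk in which `n_trees` spatially separated trees are
# grown as persistent random-walk polylines; a tree is a trunk plus short side
# branches, pre-split at attachment points so the truth branches coincide with
# the graph-theoretic branch definition (segments delimited by junctions or
# endpoints). Fragmentation moves the tree count at a fixed total length
# budget, mimicking the stress phenotype (many short trees instead of one
# connected network).

#' Generate a synthetic mitochondrial-network image with ground truth
#'
#' Renders one single-cell filament network. The controlling parameter is
#' \code{fragmentation}: at 0 the whole length budget goes into exactly one
#' tree; as it approaches 1 the budget is split across up to \code{max_trees}
#' trees, so mean tree count increases while total length stays fixed.
#'
#' @param fragmentation fraction in [0, 1]; expected tree count is
#'   \code{1 + fragmentation * (max_trees - 1)}.
#' @param seed mandatory integer seed.
#' @param total_length total filament length budget, um (default 450, the
#'   scale of an unstressed fibroblast network).
#' @param dim image dimensions in pixels (rows, cols).
#' @param pixel_size um per pixel (default 0.3, a 40x-objective scale).
#' @param max_trees maximum number of trees at fragmentation 1.
#' @param branch_rate expected short side branches per um of tree length.
#' @param cell_radius radius of the cell disk, um.
#' @param noise noise scale: 0 renders the clean blurred signal; 1 applies
#'   the full Poisson photon + Gaussian read-noise model; intermediate values
#'   scale the noise residual.
#' @param photons peak expected photon count of the filament signal.
#' @param read_sd Gaussian read-noise standard deviation, photons.
#' @return list with \code{image} (a \code{\link{raster_image}}) and
#'   \code{truth} (a \code{mito_truth} object).
#' @export
gen_mito_image <- function(fragmentation, seed, total_length = 450,
                           dim = c(320L, 320L), pixel_size = 0.3,
                           max_trees = 40L, branch_rate = 0.08,
                           cell_radius = NULL, noise = 1,
                           photons = 200, read_sd = 2) {
  check_scalar(fragmentation, "fragmentation", 0, 1)
  check_scalar(pixel_size, "pixel_size", lo = .Machine$double.eps)
  check_scalar(total_length, "total_length", lo = .Machine$double.eps)
  check_scalar(noise, "noise", lo = 0)
  if (length(dim) != 2L || any(dim < 32L))
    stop("image dimensions too small to contain any filament (need >= 32 px)",
         call. = FALSE)
  field_um <- min(dim) * pixel_size
  if (is.null(cell_radius)) cell_radius <- 0.42 * field_um
  if (cell_radius <= 2)
    stop("image dimensions too small to contain any filament", call. = FALSE)

  truth <- with_seed(seed, {
    n_trees <- 1L + stats::rbinom(1L, size = max_trees - 1L,
                                  prob = fragmentation)
    centre <- c(dim[2], dim[1]) * pixel_size / 2  # (x, y) um
    layout <- place_tree_sites(n_trees, centre, cell_radius)
    w <- layout$areas * stats::runif(n_trees, 0.7, 1.3)
    lens <- pmax(total_length * w / sum(w), 2)
    lens <- lens * total_length / sum(lens)
    occ <- new.env()
    occ$res <- 1.5
    occ$m <- matrix(0L, ceiling(dim[1] * pixel_size / occ$res) + 1L,
                    ceiling(dim[2] * pixel_size / occ$res) + 1L)
    trees <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      trees[[i]] <- grow_tree(i, layout$sites, lens[i], branch_rate, centre,
                              cell_radius, dim, pixel_size, occ = occ)
    }
    structure(list(trees = trees, fragmentation = fragmentation,
                   pixel_size = pixel_size, dim = as.integer(dim),
                   seed = seed, total_length = total_length,
                   cell_center = centre, cell_radius = cell_radius),
              class = "mito_truth")
  })

  img <- with_seed(seed + 1L, {
    render_filaments(unlist(truth$trees, recursive = FALSE), dim, pixel_size,
                     noise = noise, photons = photons, read_sd = read_sd)
  })
  list(image = raster_image(img, pixel_size), truth = truth)
}

#' @export
print.mito_truth <- function(x, ...) {
  cat(sprintf(
    "<mito_truth: %d tree(s), %d branch(es), total length %.1f um, fragmentation %.2f>\n",
    length(x$trees), sum(lengths(x$trees)), truth_total_length(x),
    x$fragmentation))
  invisible(x)
}

# polyline length in um
polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Total ground-truth filament length of a synthetic network
#' @param truth a \code{mito_truth} object.
#' @return length in um.
#' @export
truth_total_length <- function(truth) {
  sum(vapply(unlist(truth$trees, recursive = FALSE), polyline_length,
             numeric(1)))
}

#' Network metrics computed from ground truth
#'
#' Same fields as \code{\link{network_metrics}}, but computed from the
#' generating polylines rather than a detected skeleton; used for
#' generator-recovery checks.
#' @param truth a \code{mito_truth} object.
#' @return one-row data.frame of network metrics.
#' @export
truth_network_metrics <- function(truth) {
  tree_lengths <- vapply(truth$trees, function(tr)
    sum(vapply(tr, polyline_length, numeric(1))), numeric(1))
  branch_lengths <- vapply(unlist(truth$trees, recursive = FALSE),
                           polyline_length, numeric(1))
  metrics_from_lengths(tree_lengths, branch_lengths)
}

# farthest-point site sampling: one territory per tree inside the cell disk.
# Each tree is confined to the Voronoi cell of its site, so distinct trees
# never touch; the length budget is split in proportion to territory area.
place_tree_sites <- function(n, centre, cell_radius) {
  ncand <- 400L
  ang <- stats::runif(ncand, 0, 2 * pi)
  rad <- sqrt(stats::runif(ncand)) * cell_radius * 0.92
  cand <- cbind(centre[1] + rad * cos(ang), centre[2] + rad * sin(ang))
  sites <- matrix(centre, 1L, 2L)
  if (n > 1L) {
    dmin <- sqrt((cand[, 1] - centre[1])^2 + (cand[, 2] - centre[2])^2)
    for (i in 2:n) {
      k <- which.max(dmin)
      sites <- rbind(sites, cand[k, ])
      dmin <- pmin(dmin, sqrt((cand[, 1] - cand[k, 1])^2 +
                                (cand[, 2] - cand[k, 2])^2))
    }
  }
  # approximate Voronoi territory areas on a coarse grid
  gx <- seq(centre[1] - cell_radius, centre[1] + cell_radius, by = 2)
  gy <- seq(centre[2] - cell_radius, centre[2] + cell_radius, by = 2)
  gr <- expand.grid(x = gx, y = gy)
  gr <- gr[(gr$x - centre[1])^2 + (gr$y - centre[2])^2 <= cell_radius^2, ]
  d2 <- outer(gr$x, sites[, 1], "-")^2 + outer(gr$y, sites[, 2], "-")^2
  nearest <- max.col(-d2)
  areas <- tabulate(nearest, nbins = n)
  areas <- pmax(areas, 1)
  list(sites = sites, areas = areas / sum(areas))
}

# persistent random walk of total length `len` confined to one Voronoi
# territory (stay closer to the own site than to any other, with a margin,
# and inside the cell disk). A shared occupancy grid (~1.5 um cells) makes
# walks avoid already-drawn filament, so filaments rarely run parallel close
# enough to merge after rendering; on a blocked or out-of-territory step the
# heading is re-drawn from a fan of alternatives.
walk_polyline <- function(start, dir, len, sites, own, centre, cell_radius,
                          dim, pixel_size, occ = NULL, step = 2,
                          turn_sd = 0.15, sep = 1.5) {
  n_steps <- max(1L, round(len / step))
  pts <- matrix(0, n_steps + 1L, 2)
  pts[1, ] <- start
  margin <- 2 * pixel_size
  xmax <- dim[2] * pixel_size - margin
  ymax <- dim[1] * pixel_size - margin
  cell_of <- function(p) {
    if (is.null(occ)) return(c(1L, 1L))
    c(pmin(pmax(1L, 1L + (p[2] %/% occ$res)), nrow(occ$m)),
      pmin(pmax(1L, 1L + (p[1] %/% occ$res)), ncol(occ$m)))
  }
  inside <- function(p) {
    if (sqrt(sum((p - centre)^2)) > cell_radius) return(FALSE)
    if (nrow(sites) == 1L) return(TRUE)
    d <- sqrt((sites[, 1] - p[1])^2 + (sites[, 2] - p[2])^2)
    d[own] + sep <= min(d[-own])
  }
  free <- function(p, cur, prev) {
    # candidate and its 3x3 occupancy neighborhood must be clear, except the
    # cells the walk itself just came from
    if (is.null(occ)) return(TRUE)
    cc <- cell_of(p)
    for (di in -1:1) for (dj in -1:1) {
      ii <- cc[1] + di; jj <- cc[2] + dj
      if (ii < 1 || jj < 1 || ii > nrow(occ$m) || jj > ncol(occ$m)) next
      if (occ$m[ii, jj] == 1L && !(ii == cur[1] && jj == cur[2]) &&
          !(ii == prev[1] && jj == prev[2])) return(FALSE)
    }
    TRUE
  }
  prev_cell <- cell_of(pts[1, ])
  for (k in seq_len(n_steps)) {
    cur <- cell_of(pts[k, ])
    dir <- dir + stats::rnorm(1, 0, turn_sd)
    cand <- pts[k, ] + step * c(cos(dir), sin(dir))
    if (!inside(cand) || (k > 2L && !free(cand, cur, prev_cell))) {
      found <- FALSE
      for (ddir in c(-0.5, 0.5, -1, 1, -1.6, 1.6, -2.2, 2.2)) {
        d2 <- dir + ddir
        c2 <- pts[k, ] + step * c(cos(d2), sin(d2))
        if (inside(c2) && (k <= 2L || free(c2, cur, prev_cell))) {
          dir <- d2; cand <- c2; found <- TRUE; break
        }
      }
      if (!found && !inside(cand)) {
        dir <- atan2(sites[own, 2] - pts[k, 2],
                     sites[own, 1] - pts[k, 1]) + stats::rnorm(1, 0, 0.4)
        cand <- pts[k, ] + step * c(cos(dir), sin(dir))
      }
    }
    cand[1] <- min(max(cand[1], margin), xmax)
    cand[2] <- min(max(cand[2], margin), ymax)
    if (!is.null(occ)) occ$m[cur[1], cur[2]] <- 1L
    prev_cell <- cur
    pts[k + 1L, ] <- cand
  }
  if (!is.null(occ)) {
    cc <- cell_of(pts[n_steps + 1L, ])
    occ$m[cc[1], cc[2]] <- 1L
  }
  pts
}

# one tree, modeled as a branching reticulum: structural segments (20-45 um)
# are attached at random interior vertices of the existing structure, plus
# short side branches; every attachment splits the host polyline there, so
# the stored polylines are exactly the branches of the skeleton-graph
# definition (segments delimited by junctions or endpoints).
grow_tree <- function(site_idx, sites, len, branch_rate, centre, cell_radius,
                      dim, pixel_size, occ = NULL) {
  own <- sites[site_idx, ]
  wk <- function(start, dir, l) walk_polyline(start, dir, l, sites, site_idx,
                                              centre, cell_radius, dim,
                                              pixel_size, occ = occ)
  n_side <- stats::rpois(1L, branch_rate * len)
  side_lens <- if (n_side > 0) stats::runif(n_side, 4, 8) else numeric(0)
  if (sum(side_lens) > 0.4 * len)
    side_lens <- side_lens * 0.4 * len / sum(side_lens)
  arm_budget <- len - sum(side_lens)
  arm_lens <- c()
  while (arm_budget > 3) {
    l <- min(stats::runif(1, 20, 45), arm_budget)
    if (arm_budget - l < 3) l <- arm_budget
    arm_lens <- c(arm_lens, l)
    arm_budget <- arm_budget - l
  }
  if (length(arm_lens) == 0) arm_lens <- max(arm_budget, 2)

  branches <- list(wk(own, stats::runif(1, 0, 2 * pi), arm_lens[1]))
  attach_segment <- function(l, perp) {
    nv <- vapply(branches, nrow, integer(1))
    ok <- which(nv >= 4L)
    if (length(ok) == 0) return(invisible(NULL))
    b <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = nv[ok])
    host <- branches[[b]]
    j <- sample(2:(nrow(host) - 1L), 1L)
    tangent <- atan2(host[j, 2] - host[j - 1L, 2],
                     host[j, 1] - host[j - 1L, 1])
    off <- sample(c(-1, 1), 1L) *
      (if (perp) stats::runif(1, pi / 3, 2 * pi / 3)
       else stats::runif(1, pi / 4, 3 * pi / 4))
    arm <- wk(host[j, ], tangent + off, l)
    branches[[b]] <<- host[1:j, , drop = FALSE]
    branches[[length(branches) + 1L]] <<- host[j:nrow(host), , drop = FALSE]
    branches[[length(branches) + 1L]] <<- arm
    invisible(NULL)
  }
  for (l in arm_lens[-1]) attach_segment(l, perp = FALSE)
  for (l in side_lens) attach_segment(l, perp = TRUE)
  branches
}

# rasterize polylines one pixel wide, Gaussian-blur (sigma = 1 px),
# then apply the fluorescence noise model
render_filaments <- function(polylines, dim, pixel_size, noise = 1,
                             photons = 200, read_sd = 2, bg = 10) {
  stamp <- matrix(0, dim[1], dim[2])
  for (p in polylines) {
    if (nrow(p) < 2L) next
    seg <- diff(p)
    seg_len <- sqrt(rowSums(seg^2))
    for (s in seq_len(nrow(seg))) {
      n_pts <- max(2L, ceiling(seg_len[s] / (0.25 * pixel_size)))
      tt <- seq(0, 1, length.out = n_pts)
      xs <- p[s, 1] + tt * seg[s, 1]
      ys <- p[s, 2] + tt * seg[s, 2]
      cc <- pmin(pmax(round(xs / pixel_size + 0.5), 1L), dim[2])
      rr <- pmin(pmax(round(ys / pixel_size + 0.5), 1L), dim[1])
      stamp[cbind(rr, cc)] <- 1
    }
  }
  clean <- EBImage::imageData(EBImage::gblur(EBImage::Image(stamp), sigma = 1))
  clean <- clean / max(max(clean), 1e-12)
  lambda <- bg + photons * clean
  img <- lambda
  if (noise > 0) {
    n <- length(lambda)
    shot <- stats::rpois(n, lambda) - lambda
    read <- stats::rnorm(n, 0, read_sd)
    img <- lambda + noise * (shot + read)
  }
  img <- pmax(img, 0)
  img / ((bg + photons) * 1.2)
}
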