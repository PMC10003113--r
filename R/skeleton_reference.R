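# Exhaustive pixel-adjacency reference census of a skeleton.
#
# Independent validation route for the tracing-based decomposition in
# build_graph(): the skeleton is enumerated as an explicit igraph over all
# foreground pixels with 8-adjacency, and trees, nodes, and branches are
# derived purely by graph operations (components, induced subgraphs) rather
# than by path walking. Both routes must agree exactly on counts and lengths;
# tests and the acceptance suite assert this on a fixture set of small
# rasters.

#' Reference census of a skeleton by exhaustive pixel-graph enumeration
#'
#' @param skeleton logical matrix (one-pixel-wide skeleton).
#' @param pixel_size um per pixel.
#' @return list with counts (\code{n_endpoints}, \code{n_junctions},
#'   \code{n_isolated}, \code{n_trees}, \code{n_branches}),
#'   \code{total_length} (um), sorted \code{branch_lengths} and
#'   \code{tree_lengths}.
#' @export
skeleton_census <- function(skeleton, pixel_size = 1) {
  m <- (as_channel(skeleton) > 0)
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m)
  n_px <- length(idx)
  empty <- list(n_endpoints = 0L, n_junctions = 0L, n_isolated = 0L,
                n_trees = 0L, n_branches = 0L, total_length = 0,
                branch_lengths = numeric(0), tree_lengths = numeric(0))
  if (n_px == 0) return(empty)

  rc <- arrayInd(idx, c(nr, nc))
  pid <- match(seq_len(nr * nc), idx)  # linear index -> vertex id (or NA)

  # enumerate all unordered adjacent foreground pixel pairs with step weights
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    rr <- rc[, 1] + off[1]; cc <- rc[, 2] + off[2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    lin2 <- (cc[ok] - 1L) * nr + rr[ok]
    v2 <- pid[lin2]
    keep <- !is.na(v2)
    from <- c(from, which(ok)[keep])
    to <- c(to, v2[keep])
    w <- c(w, rep(if (all(off != 0)) sqrt(2) * pixel_size else pixel_size,
                  sum(keep)))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_px - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  deg <- igraph::degree(g)

  n_endpoints <- sum(deg == 1)
  n_isolated <- sum(deg == 0)
  jset <- which(deg >= 3)
  jcomp <- if (length(jset) > 0)
    igraph::components(igraph::induced_subgraph(g, jset)) else NULL
  n_junctions <- if (is.null(jcomp)) 0L else jcomp$no
  # node id per pixel: junction clusters, then endpoints/isolated singletons
  node_of <- rep(NA_integer_, n_px)
  if (!is.null(jcomp)) node_of[jset] <- jcomp$membership
  singles <- which(deg == 1 | deg == 0)
  node_of[singles] <- n_junctions + seq_along(singles)

  trees <- igraph::components(g)
  n_trees <- trees$no

  # centroid of each junction cluster; a branch end attached to a cluster is
  # extended from its attachment pixel to the centroid (same convention as
  # the tracing route, derived here purely from the pixel graph)
  jcentroid <- NULL
  if (n_junctions > 0) {
    jcentroid <- matrix(0, n_junctions, 2)
    for (k in seq_len(n_junctions)) {
      px <- jset[jcomp$membership == k]
      jcentroid[k, ] <- c(mean(rc[px, 1]), mean(rc[px, 2]))
    }
  }
  ext_of <- function(node_px) {
    # extension length for an attachment at node pixel `node_px` (0 unless
    # the pixel belongs to a junction cluster)
    if (deg[node_px] < 3) return(0)
    k <- jcomp$membership[match(node_px, jset)]
    sqrt(sum((rc[node_px, ] - jcentroid[k, ])^2)) * pixel_size
  }

  interior <- which(deg == 2)
  branch_lengths <- numeric(0)
  branch_tree <- integer(0)
  if (length(interior) > 0) {
    icomp <- igraph::components(igraph::induced_subgraph(g, interior))
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    # membership id of each edge endpoint if interior, else NA
    memb <- matrix(NA_integer_, nrow(ends), 2)
    for (k in 1:2) {
      mi <- match(ends[, k], interior)
      memb[, k] <- icomp$membership[mi]
    }
    touch <- !is.na(memb[, 1]) | !is.na(memb[, 2])
    comp_id <- ifelse(!is.na(memb[, 1]), memb[, 1], memb[, 2])
    # attachment edges: exactly one interior endpoint; the other end may add
    # a junction-centroid extension
    one_int <- xor(is.na(memb[, 1]), is.na(memb[, 2]))
    node_end <- ifelse(is.na(memb[, 1]), ends[, 1], ends[, 2])
    for (b in seq_len(icomp$no)) {
      sel <- touch & comp_id == b
      len <- sum(igraph::E(g)$weight[sel])
      att <- which(sel & one_int)
      for (e in att) len <- len + ext_of(node_end[e])
      branch_lengths <- c(branch_lengths, len)
      px <- interior[icomp$membership == b][1]
      branch_tree <- c(branch_tree, trees$membership[px])
    }
  }
  # direct node-to-node adjacencies (both ends node pixels, different nodes)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  a <- node_of[ends[, 1]]; b <- node_of[ends[, 2]]
  direct <- which(!is.na(a) & !is.na(b) & a != b)
  for (e in direct) {
    branch_lengths <- c(branch_lengths,
                        igraph::E(g)$weight[e] + ext_of(ends[e, 1]) +
                          ext_of(ends[e, 2]))
    branch_tree <- c(branch_tree, trees$membership[ends[e, 1]])
  }

  tree_lengths <- rep(0, n_trees)
  if (length(branch_lengths) > 0) {
    agg <- tapply(branch_lengths, branch_tree, sum)
    tree_lengths[as.integer(names(agg))] <- as.numeric(agg)
  }
  list(n_endpoints = as.integer(n_endpoints),
       n_junctions = as.integer(n_junctions),
       n_isolated = as.integer(n_isolated),
       n_trees = as.integer(n_trees),
       n_branches = length(branch_lengths),
       total_length = sum(branch_lengths),
       branch_lengths = sort(branch_lengths),
       tree_lengths = sort(tree_lengths))
}

#' Census of the tracing-based decomposition, for comparison
#'
#' Summarizes \code{\link{build_graph}} + \code{\link{decompose_trees}}
#' output in the same shape as \code{\link{skeleton_census}}.
#'
#' @param skeleton logical matrix.
#' @param pixel_size um per pixel.
#' @return same shape as \code{\link{skeleton_census}}.
#' @export
graph_census <- function(skeleton, pixel_size = 1) {
  g <- build_graph(skeleton, pixel_size)
  trees <- decompose_trees(g)
  br <- unlist(lapply(trees, `[[`, "branch_lengths"))
  if (is.null(br)) br <- numeric(0)
  list(n_endpoints = sum(g$nodes$kind == "endpoint"),
       n_junctions = sum(g$nodes$kind == "junction"),
       n_isolated = sum(g$nodes$kind == "isolated"),
       n_trees = length(trees),
       n_branches = length(g$edges),
       total_length = sum(vapply(trees, `[[`, numeric(1), "length_um")),
       branch_lengths = sort(br),
       tree_lengths = sort(vapply(trees, `[[`, numeric(1), "length_um")))
}
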