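# The three lateral-branch counting algorithms plus row-profile counts.
#
# LRB: with the primary path removed, a horizontal band of `band_px` rows
# slides down the image one row at a time; within each band the connected
# lateral segments are counted separately left and right of the primary
# path, and the per-side maxima over all bands are summed.
# NLR: branch nodes of the skeleton (crossing number >= 3, adjacent nodes
# merged) surviving spur removal.
# IRB: connected components of (skeleton - primary path).

#' Lateral root branch count (sliding-band method)
#'
#' @param graph Labelled `"skeleton_graph"`.
#' @param band_px Band height in px (default 5).
#' @return Integer count (0 when there are no laterals).
#' @export
count_lrb <- function(graph, band_px = 5) {
  stopifnot(inherits(graph, "skeleton_graph"))
  lats <- graph$laterals %||% list()
  if (!length(lats)) return(0L)
  best <- c(`-1` = 0L, `1` = 0L)
  for (side in c(-1, 1)) {
    vids <- unlist(lapply(lats[vapply(lats, `[[`, numeric(1), "side") == side],
                          `[[`, "vertices"))
    if (!length(vids)) next
    px <- graph$pixels[vids, , drop = FALSE]
    rmin <- min(px[, 1]); rmax <- max(px[, 1])
    # crop to the side's bounding box once; bands then label tiny strips
    cmin <- min(px[, 2]); cmax <- max(px[, 2])
    strip <- matrix(FALSE, rmax - rmin + 1, cmax - cmin + 1)
    strip[cbind(px[, 1] - rmin + 1, px[, 2] - cmin + 1)] <- TRUE
    m <- 0L
    for (r0 in rmin:max(rmin, rmax - band_px + 1)) {
      i0 <- r0 - rmin + 1
      band <- strip[i0:min(i0 + band_px - 1, nrow(strip)), , drop = FALSE]
      if (!any(band)) next
      m <- max(m, n_components8(band))
    }
    best[as.character(side)] <- m
  }
  as.integer(sum(best))
}

# 8-connected component count of a small logical strip.
n_components8 <- function(band) {
  pg <- skeleton_pixel_graph(band)
  if (nrow(pg$pix) == 0) return(0L)
  igraph::components(pg$graph)$no
}

# Merged branch-node clusters: connected components of the branch-node
# pixels (crossing number >= 3), so a thick junction counts once.
branch_node_clusters <- function(graph) {
  bn <- graph$branch_nodes
  if (!length(bn)) return(list())
  sub <- igraph::induced_subgraph(graph$graph, bn)
  comps <- igraph::components(sub)
  lapply(seq_len(comps$no), function(k) bn[comps$membership == k])
}

#' Count nodes of lateral roots
#'
#' Branch nodes of the (spur-pruned) skeleton: pixels with crossing
#' number >= 3, with adjacent branch-node pixels merged into one node.
#'
#' @param graph A `"skeleton_graph"`, normally after [prune_spurs()].
#' @return Integer node count.
#' @export
count_nlr <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  length(branch_node_clusters(graph))
}

#' Count independent lateral root branches
#'
#' Number of connected components of the skeleton with the primary path
#' removed.
#'
#' @param graph Labelled `"skeleton_graph"`.
#' @return Integer count.
#' @export
count_irb <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  length(graph$laterals %||% list())
}

#' Count lateral root tips
#'
#' Endpoints of lateral branches; the primary top and primary tip are
#' excluded. A forked lateral contributes one branch to IRB but two tips.
#'
#' @param graph Labelled `"skeleton_graph"`.
#' @return Integer count.
#' @export
count_tips <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  sum(vapply(graph$laterals %||% list(),
             function(L) length(L$tips), integer(1)))
}

#' Row-profile counts: MED, RMAX, MNR, BSH
#'
#' Builds the per-row profile of the skeleton over its occupied rows:
#' `run_count` is the number of maximal horizontal runs of skeleton pixels
#' in the row (a diagonal root counts once per row), `pixel_sum` the
#' skeleton pixels in the row. `MED`/`RMAX` are the median/maximum of
#' `run_count`, `MNR` the 84th percentile of `pixel_sum` (linear
#' interpolation), `BSH = RMAX/MED`.
#'
#' @param graph A `"skeleton_graph"`.
#' @return List with the four traits and the `profile` data frame
#'   (`row`, `run_count`, `pixel_sum`).
#' @export
row_profile_traits <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  px <- graph$pixels
  byrow <- split(px[, 2], px[, 1])
  prof <- data.frame(
    row = as.integer(names(byrow)),
    run_count = vapply(byrow, function(cc) {
      cc <- sort(cc)
      if (!length(cc)) 0L else sum(diff(cc) > 1) + 1L
    }, integer(1)),
    pixel_sum = vapply(byrow, length, integer(1))
  )
  med <- median(prof$run_count)
  rmax <- max(prof$run_count)
  list(
    MED = med,
    RMAX = rmax,
    MNR = as.numeric(quantile(prof$pixel_sum, 0.84, type = 7)),
    BSH = if (med > 0) rmax / med else NA_real_,
    profile = prof
  )
}
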