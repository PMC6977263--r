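# Skeleton topology: topology-preserving thinning to a 1-px skeleton,
# the pixel graph, automatic primary-root detection, spur pruning and
# lateral labelling. This is the substrate for every length/count/angle
# trait.

# Guo-Hall thinning, vectorised over shifted matrices. Produces cleanly
# 8-thin skeletons (no 2-px diagonal staircases, unlike Zhang-Suen).
# Input/output are logical H x W matrices; the border ring is background.
thin_gh <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(FALSE, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  idx <- 2:(H + 1); jdx <- 2:(W + 1)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- p[idx, jdx]
      P2 <- p[idx - 1, jdx];     P3 <- p[idx - 1, jdx + 1]
      P4 <- p[idx, jdx + 1];     P5 <- p[idx + 1, jdx + 1]
      P6 <- p[idx + 1, jdx];     P7 <- p[idx + 1, jdx - 1]
      P8 <- p[idx, jdx - 1];     P9 <- p[idx - 1, jdx - 1]
      C <- (!P2 & (P3 | P4)) + (!P4 & (P5 | P6)) +
        (!P6 & (P7 | P8)) + (!P8 & (P9 | P2))
      N1 <- (P9 | P2) + (P3 | P4) + (P5 | P6) + (P7 | P8)
      N2 <- (P2 | P3) + (P4 | P5) + (P6 | P7) + (P8 | P9)
      N <- pmin(N1, N2)
      m_cond <- if (step == 1) ((P6 | P7 | !P9) & P8) else ((P2 | P3 | !P5) & P4)
      cond <- P & C == 1 & N >= 2 & N <= 3 & !m_cond
      if (any(cond)) {
        changed <- TRUE
        P[cond] <- FALSE
        p[idx, jdx] <- P
      }
    }
    if (!changed) break
  }
  p[idx, jdx]
}

# Build the pixel graph of a skeleton matrix: vertices are skeleton pixels,
# edges connect 8-neighbours, weighted by Euclidean step length.
skeleton_pixel_graph <- function(skel) {
  pix <- which(skel, arr.ind = TRUE)
  colnames(pix) <- c("row", "col")
  n <- nrow(pix)
  H <- nrow(skel); W <- ncol(skel)
  idm <- matrix(0L, H, W)
  idm[pix] <- seq_len(n)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  for (o in offs) {
    r2 <- pix[, 1] + o[1]; c2 <- pix[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
    nb <- integer(n); nb[ok] <- idm[cbind(r2[ok], c2[ok])]
    hit <- which(nb > 0)
    from <- c(from, hit); to <- c(to, nb[hit])
    wt <- c(wt, rep(sqrt(sum(o^2)), length(hit)))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$weight <- wt
  }
  list(pix = pix, graph = g)
}

# Neighbour count B and Hilditch crossing number A for every pixel of a
# skeleton matrix. A is the number of 0->1 transitions around the
# 8-neighbourhood ring: endpoints have B == 1, true junctions A >= 3
# (plain neighbour counting misclassifies diagonal staircase pixels).
skeleton_ab <- function(skel) {
  H <- nrow(skel); W <- ncol(skel)
  p <- matrix(FALSE, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- skel
  i <- 2:(H + 1); j <- 2:(W + 1)
  P2 <- p[i - 1, j];     P3 <- p[i - 1, j + 1]
  P4 <- p[i, j + 1];     P5 <- p[i + 1, j + 1]
  P6 <- p[i + 1, j];     P7 <- p[i + 1, j - 1]
  P8 <- p[i, j - 1];     P9 <- p[i - 1, j - 1]
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
    (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
  list(B = B, A = A)
}

new_skeleton_graph <- function(pix, graph, dim, calibration, debris = 0L,
                               flag = character(0)) {
  skel <- matrix(FALSE, dim[1], dim[2])
  skel[pix] <- TRUE
  ab <- skeleton_ab(skel)
  B <- ab$B[pix]; A <- ab$A[pix]
  structure(list(
    pixels = pix, graph = graph, dim = dim,
    degree = if (igraph::vcount(graph)) igraph::degree(graph) else integer(0),
    nb_count = B, crossing_number = A,
    endpoints = which(B == 1),
    branch_nodes = which(A >= 3),
    primary_path = NULL, laterals = NULL,
    debris = debris, calibration = calibration, flag = flag
  ), class = "skeleton_graph")
}

#' Skeletonize a root mask
#'
#' Topology-preserving thinning (Zhang-Suen) to a 1-px-wide skeleton,
#' followed by construction of the pixel graph (8-connectivity edges
#' weighted by Euclidean step length). Only the largest connected skeleton
#' component is kept as the root system; smaller components are reported
#' as a debris count.
#'
#' @param mask A [root_mask()] or logical matrix with at least one
#'   foreground pixel.
#' @return An object of class `"skeleton_graph"` with fields `pixels`
#'   (n x 2 row/col matrix), `graph` (igraph), `endpoints`,
#'   `branch_nodes`, `debris`, and unlabelled `primary_path`/`laterals`.
# Fill enclosed background pockets of at most max_px pixels. Thin wedges
# trapped where a lateral stroke meets the taproot would otherwise survive
# thinning as spurious skeleton loops.
fill_small_holes <- function(m, max_px = 25) {
  lab <- EBImage::bwlabel((!m) * 1)
  if (max(lab) == 0) return(m)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0])
  fill <- setdiff(which(sizes <= max_px), border)
  if (length(fill)) m[matrix(lab %in% fill, nrow(m), ncol(m))] <- TRUE
  m
}

#' @export
skeletonize <- function(mask) {
  m <- mask_pixels(mask)
  if (!any(m)) stop("cannot skeletonize an empty mask")
  cal <- mask_cal(mask)
  skel <- thin_gh(fill_small_holes(m))
  pg <- skeleton_pixel_graph(skel)
  comps <- igraph::components(pg$graph)
  debris <- comps$no - 1L
  if (comps$no > 1) {
    keep <- which(comps$membership == which.max(comps$csize))
    sub <- igraph::induced_subgraph(pg$graph, keep)
    pix <- pg$pix[keep, , drop = FALSE]
  } else {
    sub <- pg$graph
    pix <- pg$pix
  }
  new_skeleton_graph(pix, sub, dim(m), cal, debris = debris)
}

# Order the start/target endpoints for primary-root routing.
pick_extreme_endpoints <- function(g) {
  cand <- if (length(g$endpoints) >= 2) g$endpoints else seq_len(nrow(g$pixels))
  rows <- g$pixels[cand, 1]; cols <- g$pixels[cand, 2]
  start <- cand[order(rows, cols)[1]]
  target <- cand[order(-rows, cols)[1]]
  c(start = start, target = target)
}

# Minimum-cost path where cost = Euclidean step length plus a per-turn
# penalty (turn_penalty px per radian of direction change), computed on
# the arc (directed-edge) graph.
turn_aware_path <- function(g, start, target, turn_penalty) {
  el <- igraph::as_edgelist(g$graph, names = FALSE)
  if (nrow(el) == 0) return(start)
  wts <- igraph::E(g$graph)$weight
  # arcs: both orientations of every edge
  tailv <- c(el[, 1], el[, 2])
  headv <- c(el[, 2], el[, 1])
  alen <- c(wts, wts)
  nA <- length(tailv)
  n <- nrow(g$pixels)
  dvec <- g$pixels[headv, , drop = FALSE] - g$pixels[tailv, , drop = FALSE]
  by_tail <- split(seq_len(nA), factor(tailv, levels = seq_len(n)))
  pf <- vector("list", nA); pt <- vector("list", nA)
  for (i in seq_len(nA)) {
    ss <- by_tail[[headv[i]]]
    ss <- ss[headv[ss] != tailv[i]]          # no immediate U-turn
    if (length(ss)) { pf[[i]] <- rep.int(i, length(ss)); pt[[i]] <- ss }
  }
  pair_from <- unlist(pf); pair_to <- unlist(pt)
  cosang <- numeric(length(pair_from))
  if (length(pair_from)) {
    v1 <- dvec[pair_from, , drop = FALSE]; v2 <- dvec[pair_to, , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    cosang <- pmin(pmax(cosang, -1), 1)
  }
  pair_cost <- alen[pair_to] + turn_penalty * acos(cosang)
  # super-source nA+1, super-sink nA+2 in the arc graph
  S <- nA + 1L; Tk <- nA + 2L
  src_arcs <- which(tailv == start)
  snk_arcs <- which(headv == target)
  if (!length(src_arcs) || !length(snk_arcs)) return(c(start, target))
  ag <- igraph::make_empty_graph(nA + 2L, directed = TRUE)
  edges <- rbind(cbind(pair_from, pair_to),
                 cbind(rep(S, length(src_arcs)), src_arcs),
                 cbind(snk_arcs, rep(Tk, length(snk_arcs))))
  ag <- igraph::add_edges(ag, t(edges))
  igraph::E(ag)$weight <- c(pair_cost, alen[src_arcs],
                            rep(0, length(snk_arcs)))
  sp <- suppressWarnings(
    igraph::shortest_paths(ag, from = S, to = Tk, mode = "out",
                           output = "vpath")$vpath[[1]])
  arcs <- as.integer(sp)
  arcs <- arcs[arcs <= nA]
  if (!length(arcs)) return(c(start, target))
  c(tailv[arcs[1]], headv[arcs])
}

#' Detect the primary root path
#'
#' The primary root is routed through the skeleton as the minimum-cost
#' path from the topmost endpoint (the seed attachment) to the deepest
#' endpoint (the taproot tip), where cost is the Euclidean step length
#' plus a turn-angle penalty that keeps the path from jumping onto steep
#' laterals. Ties break toward the smaller column index.
#'
#' @param g A `"skeleton_graph"` from [skeletonize()].
#' @param turn_penalty Penalty in px per radian of direction change;
#'   `0` reduces to the plain shortest path.
#' @return `g` with `$primary_path` set (ordered vertex indices, top to
#'   tip). A single-pixel skeleton yields a degenerate path with a
#'   `"degenerate_primary"` flag.
#' @export
detect_primary_root <- function(g, turn_penalty = 2) {
  stopifnot(inherits(g, "skeleton_graph"))
  n <- nrow(g$pixels)
  if (n == 1 || igraph::ecount(g$graph) == 0) {
    g$primary_path <- 1L
    g$flag <- union(g$flag, "degenerate_primary")
    return(g)
  }
  ends <- pick_extreme_endpoints(g)
  path <- if (turn_penalty > 0) {
    turn_aware_path(g, ends["start"], ends["target"], turn_penalty)
  } else {
    as.integer(suppressWarnings(
      igraph::shortest_paths(g$graph, ends["start"], ends["target"],
                             weights = igraph::E(g$graph)$weight,
                             output = "vpath")$vpath[[1]]))
  }
  if (length(path) < 2) {
    g$flag <- union(g$flag, "degenerate_primary")
    path <- unique(c(ends["start"], ends["target"]))
  }
  g$primary_path <- as.integer(path)
  g
}

# Chain-code length (px) of an ordered pixel path given as an n x 2 matrix.
chain_length_px <- function(coords, diagonal_correction = TRUE) {
  if (nrow(coords) < 2) return(0)
  d <- abs(diff(coords))
  if (any(d > 1)) stop("path pixels are not 8-adjacent")
  steps <- ifelse(rowSums(d) == 2,
                  if (diagonal_correction) sqrt(2) else 1, 1)
  sum(steps)
}

#' Length of an ordered skeleton path
#'
#' Chain-code length: 1 px per orthogonal step, sqrt(2) px per diagonal
#' step (the diagonal correction can be disabled), converted to cm.
#'
#' @param path n x 2 matrix of (row, col) pixel coordinates, ordered and
#'   8-connected.
#' @param cal A [calibration()] object.
#' @param diagonal_correction Count diagonal steps as sqrt(2) px (default).
#' @return Length in cm.
#' @export
path_length <- function(path, cal = calibration(), diagonal_correction = TRUE) {
  stopifnot(is.matrix(path), ncol(path) == 2)
  px_to_cm(chain_length_px(path, diagonal_correction), cal)
}

#' Prune spurious skeleton branches
#'
#' Thinning a wide region produces short spur branches that terminate in
#' an endpoint close to a branch node. Any terminal branch whose
#' chain-code length is below `radius_px` is deleted (iteratively, since a
#' deletion can expose a new spur). The primary path, when set, is never
#' deleted.
#'
#' @param g A `"skeleton_graph"`.
#' @param radius_px Spur length threshold in px (default 10).
#' @return A pruned `"skeleton_graph"`; the primary-path labelling is
#'   preserved.
#' @export
prune_spurs <- function(g, radius_px = 10) {
  stopifnot(inherits(g, "skeleton_graph"))
  cur <- g
  protect_key <- if (!is.null(g$primary_path))
    paste(g$pixels[g$primary_path, 1], g$pixels[g$primary_path, 2])
  else character(0)
  repeat {
    junctions <- cur$branch_nodes
    key <- paste(cur$pixels[, 1], cur$pixels[, 2])
    ends <- setdiff(cur$endpoints, which(key %in% protect_key))
    if (!length(junctions) || !length(ends)) break
    d <- igraph::distances(cur$graph, v = ends, to = junctions,
                           weights = igraph::E(cur$graph)$weight)
    drop_px <- NULL
    for (i in seq_along(ends)) {
      j <- which.min(d[i, ])
      if (!is.finite(d[i, j]) || d[i, j] >= radius_px) next
      sp <- as.integer(suppressWarnings(
        igraph::shortest_paths(cur$graph, ends[i], junctions[j],
                               weights = igraph::E(cur$graph)$weight,
                               output = "vpath")$vpath[[1]]))
      sp <- sp[-length(sp)]                     # keep the junction itself
      sp <- sp[!(key[sp] %in% protect_key)]
      if (length(sp)) drop_px <- rbind(drop_px, cur$pixels[sp, , drop = FALSE])
    }
    if (is.null(drop_px)) break
    skel <- matrix(FALSE, cur$dim[1], cur$dim[2])
    skel[cur$pixels] <- TRUE
    skel[drop_px] <- FALSE
    pg <- skeleton_pixel_graph(skel)
    cur <- new_skeleton_graph(pg$pix, pg$graph, g$dim, g$calibration,
                              debris = g$debris, flag = g$flag)
  }
  if (!is.null(g$primary_path)) {
    key <- paste(cur$pixels[, 1], cur$pixels[, 2])
    old <- g$pixels[g$primary_path, , drop = FALSE]
    pp <- match(paste(old[, 1], old[, 2]), key)
    cur$primary_path <- pp[!is.na(pp)]
  }
  cur
}

#' Label lateral branches left/right of the primary path
#'
#' Removes the primary-path pixels, takes the connected components of the
#' remaining skeleton, and attaches each component to the nearest
#' primary-path pixel. Each component is assigned a side (left/right of
#' the primary path) by the sign of its attachment column relative to the
#' primary path; an attachment exactly on the path column is decided by
#' its second pixel, with remaining ties going left.
#'
#' @param g A `"skeleton_graph"` with `$primary_path` set.
#' @return `g` with `$laterals`: one entry per lateral component, each a
#'   list with `vertices`, `attach` (component-side vertex),
#'   `attach_prim` (primary-path vertex), `side` (-1 left, +1 right),
#'   `tips`, `tip_paths`, `path` (attachment to farthest tip), and
#'   `length_px` (component skeleton length including the attachment
#'   step).
#' @export
label_laterals <- function(g) {
  stopifnot(inherits(g, "skeleton_graph"))
  if (is.null(g$primary_path)) stop("primary path not set; run detect_primary_root()")
  n <- nrow(g$pixels)
  prim <- g$primary_path
  rest <- setdiff(seq_len(n), prim)
  g$laterals <- list()
  if (!length(rest)) return(g)
  sub <- igraph::induced_subgraph(g$graph, rest)
  comps <- igraph::components(sub)
  prim_set <- logical(n); prim_set[prim] <- TRUE
  # order of primary vertices along the path, for column lookup
  adj <- igraph::adjacent_vertices(g$graph, rest)
  laterals <- list()
  for (k in seq_len(comps$no)) {
    vids <- rest[comps$membership == k]
    # attachment: component vertex adjacent to a primary vertex,
    # minimising the Euclidean step to it
    best <- NULL
    for (v in vids) {
      nb <- as.integer(adj[[match(v, rest)]])
      nb <- nb[prim_set[nb]]
      if (!length(nb)) next
      d <- sqrt(rowSums((g$pixels[nb, , drop = FALSE] -
                           matrix(g$pixels[v, ], length(nb), 2, byrow = TRUE))^2))
      j <- which.min(d)
      if (is.null(best) || d[j] < best$d)
        best <- list(v = v, p = nb[j], d = d[j])
    }
    if (is.null(best)) next  # not attached to the primary (nested); attach via another lateral later
    side <- sign(g$pixels[best$v, 2] - g$pixels[best$p, 2])
    csub <- igraph::induced_subgraph(g$graph, vids)
    attach_local <- match(best$v, vids)
    # tips: endpoints of the component (1 neighbour within the component)
    cskel <- matrix(FALSE, g$dim[1], g$dim[2])
    cskel[g$pixels[vids, , drop = FALSE]] <- TRUE
    cB <- skeleton_ab(cskel)$B
    tips_local <- which(cB[g$pixels[vids, , drop = FALSE]] == 1)
    tips_local <- setdiff(tips_local, attach_local)
    if (!length(tips_local)) tips_local <- attach_local
    tip_paths <- lapply(tips_local, function(tl) {
      vids[as.integer(suppressWarnings(
        igraph::shortest_paths(csub, attach_local, tl,
                               weights = igraph::E(csub)$weight,
                               output = "vpath")$vpath[[1]]))]
    })
    if (side == 0) {
      nxt <- if (length(tip_paths[[1]]) >= 2) tip_paths[[1]][2] else best$v
      side <- sign(g$pixels[nxt, 2] - g$pixels[best$p, 2])
      if (side == 0) side <- -1  # tie rule: left
    }
    plen <- vapply(tip_paths, function(pp)
      chain_length_px(g$pixels[pp, , drop = FALSE]), numeric(1))
    mst <- igraph::mst(csub, weights = igraph::E(csub)$weight)
    comp_len <- if (igraph::ecount(mst)) sum(igraph::E(mst)$weight) else 0
    laterals[[length(laterals) + 1]] <- list(
      vertices = vids,
      attach = best$v, attach_prim = best$p, side = side,
      tips = vids[tips_local], tip_paths = tip_paths,
      path = tip_paths[[which.max(plen)]],
      length_px = comp_len + best$d
    )
  }
  g$laterals <- laterals
  g
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d px, %d endpoints, %d branch nodes, debris %d\n",
              nrow(x$pixels), length(x$endpoints), length(x$branch_nodes),
              x$debris))
  if (!is.null(x$primary_path))
    cat(sprintf("  primary path: %d px\n", length(x$primary_path)))
  if (!is.null(x$laterals))
    cat(sprintf("  laterals: %d (%d left, %d right)\n", length(x$laterals),
                sum(vapply(x$laterals, `[[`, numeric(1), "side") < 0),
                sum(vapply(x$laterals, `[[`, numeric(1), "side") > 0)))
  invisible(x)
}

#' Plot a labelled skeleton as a debug overlay
#'
#' @param x A `"skeleton_graph"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.skeleton_graph <- function(x, ...) {
  graphics::plot(x$pixels[, 2], -x$pixels[, 1], pch = ".", col = "grey50",
                 xlab = "col", ylab = "-row", asp = 1, ...)
  if (!is.null(x$primary_path)) {
    pp <- x$pixels[x$primary_path, , drop = FALSE]
    graphics::points(pp[, 2], -pp[, 1], pch = ".", col = "red", cex = 2)
  }
  if (!is.null(x$laterals)) for (L in x$laterals) {
    lp <- x$pixels[L$vertices, , drop = FALSE]
    graphics::points(lp[, 2], -lp[, 1], pch = ".",
                     col = if (L$side < 0) "blue" else "darkgreen", cex = 2)
  }
  invisible(x)
}

# Edge table used by the length traits: primary chain edges plus, per
# lateral component, its spanning-tree edges and the attachment step.
# Columns: r1,c1,r2,c2,len,kind ("primary"/"lateral"), lateral id.
length_edge_table <- function(g, diagonal_correction = TRUE) {
  stopifnot(inherits(g, "skeleton_graph"))
  rows <- list()
  steplen <- function(a, b) {
    d <- abs(g$pixels[a, , drop = FALSE] - g$pixels[b, , drop = FALSE])
    ifelse(rowSums(d) == 2, if (diagonal_correction) sqrt(2) else 1,
           ifelse(rowSums(d) == 1, 1, sqrt(rowSums(d^2))))
  }
  if (!is.null(g$primary_path) && length(g$primary_path) >= 2) {
    a <- g$primary_path[-length(g$primary_path)]
    b <- g$primary_path[-1]
    rows[["primary"]] <- data.frame(
      r1 = g$pixels[a, 1], c1 = g$pixels[a, 2],
      r2 = g$pixels[b, 1], c2 = g$pixels[b, 2],
      len = steplen(a, b), kind = "primary", lateral = NA_integer_)
  }
  if (!is.null(g$laterals) && length(g$laterals)) {
    for (i in seq_along(g$laterals)) {
      L <- g$laterals[[i]]
      csub <- igraph::induced_subgraph(g$graph, L$vertices)
      mst <- igraph::mst(csub, weights = igraph::E(csub)$weight)
      el <- igraph::as_edgelist(mst, names = FALSE)
      a <- L$vertices[el[, 1]]; b <- L$vertices[el[, 2]]
      a <- c(a, L$attach_prim); b <- c(b, L$attach)
      rows[[paste0("lat", i)]] <- data.frame(
        r1 = g$pixels[a, 1], c1 = g$pixels[a, 2],
        r2 = g$pixels[b, 1], c2 = g$pixels[b, 2],
        len = steplen(a, b), kind = "lateral", lateral = i)
    }
  }
  if (!length(rows))
    return(data.frame(r1 = numeric(0), c1 = numeric(0), r2 = numeric(0),
                      c2 = numeric(0), len = numeric(0), kind = character(0),
                      lateral = integer(0)))
  do.call(rbind, rows)
}
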