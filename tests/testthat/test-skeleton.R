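# Skeletonization, primary-root detection, spur pruning, lateral labels.

test_that("a wide vertical bar thins to a single endpoint-to-endpoint path", {
  m <- matrix(FALSE, 220, 60); m[10:209, 28:32] <- TRUE
  g <- skeletonize(root_mask(m))
  expect_equal(length(g$endpoints), 2)
  expect_equal(length(g$branch_nodes), 0)
  expect_equal(g$debris, 0)
  # all pixels on one vertical line
  expect_equal(length(unique(g$pixels[, 2])), 1)
})

test_that("a plus sign has 4 endpoints and one merged branch node", {
  m <- matrix(FALSE, 101, 101)
  m[20:80, 49:51] <- TRUE; m[49:51, 20:80] <- TRUE
  g <- skeletonize(root_mask(m))
  expect_equal(length(g$endpoints), 4)
  expect_equal(count_nlr(g), 1)
})

test_that("skeletonizing a skeleton changes nothing", {
  sc <- fx_scene(31)
  g1 <- skeletonize(sc$truth$mask)
  skel <- matrix(FALSE, g1$dim[1], g1$dim[2]); skel[g1$pixels] <- TRUE
  g2 <- skeletonize(root_mask(skel))
  expect_equal(nrow(g2$pixels), nrow(g1$pixels))
  expect_equal(g2$pixels, g1$pixels)
})

test_that("empty masks are rejected", {
  expect_error(skeletonize(root_mask(matrix(FALSE, 5, 5))), "empty")
})

test_that("primary path spans a plain vertical path entirely", {
  m <- matrix(FALSE, 120, 30); m[10:110, 15] <- TRUE
  g <- detect_primary_root(skeletonize(root_mask(m)))
  expect_equal(length(g$primary_path), 101)
})

test_that("primary path follows the deeper arm of a Y", {
  m <- matrix(FALSE, 200, 120)
  m[10:100, 60] <- TRUE                                  # stem
  for (i in 0:79) m[100 + i, 60 + i %/% 2] <- TRUE        # deep right arm
  for (i in 0:39) m[100 + i, 60 - i] <- TRUE              # shallow left arm
  g <- detect_primary_root(skeletonize(root_mask(m)))
  tip <- g$pixels[g$primary_path[length(g$primary_path)], ]
  expect_equal(unname(tip[1]), 179)                       # deepest row
  expect_gt(tip[2], 60)                                   # via the right arm
})

test_that("a single-pixel skeleton yields a degenerate flagged path", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  g <- detect_primary_root(skeletonize(root_mask(m)))
  expect_equal(g$primary_path, 1L)
  expect_true("degenerate_primary" %in% g$flag)
})

test_that("recovered primary path stays within 2 px of the taproot polyline", {
  for (sd in c(31, 35)) {
    sc <- fx_scene(sd)
    g <- fx_skeleton(sd)
    pp <- g$pixels[g$primary_path, , drop = FALSE]
    tap <- sc$truth$taproot
    # directed Hausdorff: every primary pixel near the polyline. Pixels
    # inside a junction blob are excluded: there the thinned centreline of
    # the taproot/lateral union is displaced by construction and the
    # taproot centreline is unobservable.
    att <- do.call(rbind, lapply(sc$truth$laterals, function(p) p[1, , drop = FALSE]))
    near_junction <- vapply(seq_len(nrow(pp)), function(i)
      min(sqrt((att[, 1] - pp[i, 1])^2 + (att[, 2] - pp[i, 2])^2)) < 10, logical(1))
    d <- vapply(seq_len(nrow(pp)), function(i)
      min(sqrt((tap[, 1] - pp[i, 1])^2 + (tap[, 2] - pp[i, 2])^2)), numeric(1))
    expect_lt(max(d[!near_junction]), 2 + 1e-9)
    expect_lt(max(d), 4)
  }
})

test_that("chain-code path length follows the stated step weights", {
  cal <- calibration(100)
  vert <- cbind(1:301, rep(5, 301))
  expect_equal(path_length(vert, cal), 3)
  diag <- cbind(1:101, 1:101)
  expect_equal(path_length(diag, cal), sqrt(2), tolerance = 1e-12)
  expect_equal(path_length(diag, cal, diagonal_correction = FALSE), 1)
  # non-adjacent pixels are rejected
  expect_error(path_length(rbind(c(1, 1), c(3, 1)), cal), "adjacent")
})

test_that("short spurs are pruned, long laterals are kept", {
  m <- matrix(FALSE, 120, 60)
  m[10:110, 30] <- TRUE
  m[60, 31:33] <- TRUE                       # 3-px stub
  m[40, 31:55] <- TRUE                       # 25-px lateral
  g <- detect_primary_root(skeletonize(root_mask(m)))
  g <- prune_spurs(g, radius_px = 10)
  g <- label_laterals(g)
  expect_equal(length(g$laterals), 1)
  expect_gt(g$laterals[[1]]$length_px, 15)
})

test_that("laterals are labelled with the correct side and cover the skeleton", {
  g <- fx_skeleton(31)
  sc <- fx_scene(31)
  sides <- vapply(g$laterals, `[[`, numeric(1), "side")
  expect_equal(sum(sides < 0), sc$truth$n_left)
  expect_equal(sum(sides > 0), sc$truth$n_right)
  # primary + laterals cover all skeleton pixels
  covered <- sort(unique(c(g$primary_path,
                           unlist(lapply(g$laterals, `[[`, "vertices")))))
  expect_equal(covered, seq_len(nrow(g$pixels)))
  # every lateral's attachment touches the primary path (8-connectivity)
  for (L in g$laterals) {
    d <- abs(g$pixels[L$attach, , drop = FALSE] -
               g$pixels[L$attach_prim, , drop = FALSE])
    expect_true(all(d <= 1))
  }
})

test_that("rotating a mask by 90 degrees swaps depth and width coherently", {
  sc <- fx_scene(36)
  m <- sc$truth$mask$pixels
  mr <- t(m)[ncol(m):1, , drop = FALSE]
  fg <- which(m, arr.ind = TRUE); fgr <- which(mr, arr.ind = TRUE)
  expect_equal(diff(range(fgr[, 1])), diff(range(fg[, 2])))   # DEP' = WID
  expect_equal(diff(range(fgr[, 2])), diff(range(fg[, 1])))   # WID' = DEP
  # total skeleton length is rotation-invariant within 1%
  tot_len <- function(mm) {
    g <- skeletonize(root_mask(mm))
    mst <- igraph::mst(g$graph, weights = igraph::E(g$graph)$weight)
    sum(igraph::E(mst)$weight)
  }
  l1 <- tot_len(m); l2 <- tot_len(mr)
  expect_lt(abs(l2 - l1) / l1, 0.01)
})
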