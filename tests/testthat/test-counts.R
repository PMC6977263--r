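# Branch counting (LRB / NLR / IRB / tips) and row-profile traits.

test_that("a lateral-free skeleton counts zero everywhere", {
  m <- matrix(FALSE, 120, 30); m[10:110, 15] <- TRUE
  g <- label_laterals(detect_primary_root(skeletonize(root_mask(m))))
  expect_equal(count_lrb(g), 0L)
  expect_equal(count_irb(g), 0L)
  expect_equal(count_tips(g), 0L)
})

test_that("constructed overlapping laterals give the summed per-side maxima", {
  # 3 right and 2 left diagonal laterals, all crossing rows 135..215
  m <- matrix(FALSE, 300, 300)
  m[10:290, 150] <- TRUE
  add_lat <- function(m, d, side, len = 180) {
    for (u in 0:len) {
      r <- d + u; c <- 150 + side * u
      if (r <= 290 && c >= 2 && c <= 299) m[r, c] <- TRUE
    }
    m
  }
  for (d in c(50, 90, 130)) m <- add_lat(m, d, +1)
  for (d in c(70, 110)) m <- add_lat(m, d, -1)
  g <- label_laterals(prune_spurs(detect_primary_root(skeletonize(root_mask(m))), 10))
  expect_equal(count_lrb(g), 5L)
})

test_that("a Y junction is one node, even with a thinning stub", {
  m <- matrix(FALSE, 120, 80)
  m[10:110, 40] <- TRUE
  for (i in 0:39) m[60 + i, 40 + i] <- TRUE
  g <- prune_spurs(detect_primary_root(skeletonize(root_mask(m))), 10)
  expect_equal(count_nlr(g), 1L)
})

test_that("a forked lateral is one branch with two tips", {
  m <- matrix(FALSE, 200, 160)
  m[10:190, 40] <- TRUE
  m[60, 41:100] <- TRUE                       # lateral trunk
  for (i in 1:40) {
    m[60 - i, 100 + i] <- TRUE                # fork up
    m[60 + i, 100 + i] <- TRUE                # fork down
  }
  g <- label_laterals(prune_spurs(detect_primary_root(skeletonize(root_mask(m))), 10))
  expect_equal(count_irb(g), 1L)
  expect_equal(count_tips(g), 2L)
  # two disjoint laterals -> IRB 2
  m2 <- matrix(FALSE, 200, 120)
  m2[10:190, 60] <- TRUE
  m2[50, 61:100] <- TRUE
  m2[120, 20:59] <- TRUE
  g2 <- label_laterals(prune_spurs(detect_primary_root(skeletonize(root_mask(m2))), 10))
  expect_equal(count_irb(g2), 2L)
  expect_gte(count_tips(g2), count_irb(g2))   # tips >= independent branches
})

test_that("generator roots recover all four counts exactly", {
  for (sd in c(31, 35, 36, 37)) {
    sc <- fx_scene(sd)
    g <- fx_skeleton(sd)
    k <- sc$truth$n_lat
    expect_equal(count_lrb(g), k)
    expect_equal(count_nlr(g), k)
    expect_equal(count_irb(g), k)
    expect_equal(count_tips(g), k)
  }
})

test_that("row profiles match a brute-force row scan", {
  g <- fx_skeleton(31)
  rp <- row_profile_traits(g)
  skel <- matrix(FALSE, g$dim[1], g$dim[2]); skel[g$pixels] <- TRUE
  ora <- oracle_row_profile(skel)
  expect_equal(rp$profile$run_count, ora$run_count)
  expect_equal(rp$profile$pixel_sum, ora$pixel_sum)
  expect_equal(rp$MED, median(ora$run_count))
  expect_equal(rp$RMAX, max(ora$run_count))
  expect_equal(rp$MNR, unname(quantile(ora$pixel_sum, 0.84)))
  expect_gte(rp$BSH, 1)
})

test_that("row profile closed forms: single line and parallel pair", {
  m <- matrix(FALSE, 120, 30); m[10:110, 15] <- TRUE
  rp <- row_profile_traits(skeletonize(root_mask(m)))
  expect_equal(rp$MED, 1); expect_equal(rp$RMAX, 1)
  expect_equal(rp$BSH, 1); expect_equal(rp$MNR, 1)
  m[10:110, 25] <- TRUE                       # full-depth parallel lateral
  m[10, 15:25] <- TRUE                        # bridge keeps it connected
  rp2 <- row_profile_traits(skeletonize(root_mask(m)))
  expect_equal(rp2$MED, 2); expect_equal(rp2$RMAX, 2)
  expect_equal(rp2$BSH, 1)
})
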