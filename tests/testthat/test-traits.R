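# Geometric traits: lengths, areas, primary-root solids, centre measures.

bar_mask <- function(H = 320, W = 60, r0 = 11, r1 = 310, c0 = 28, c1 = 32) {
  m <- matrix(FALSE, H, W); m[r0:r1, c0:c1] <- TRUE
  root_mask(m)
}

labelled <- function(mask) {
  g <- skeletonize(mask)
  g <- detect_primary_root(g)
  g <- prune_spurs(g, 10)
  label_laterals(g)
}

test_that("a single vertical primary gives the closed-form length traits", {
  msk <- bar_mask()
  g <- labelled(msk)
  lt <- length_traits(g, msk, calibration())
  expect_equal(lt$PRL, lt$TRL)
  expect_equal(lt$LRL, 0)
  expect_equal(lt$DEP, 2.99)                      # (310 - 11)/100
  expect_equal(lt$WID, 0.04)
  expect_equal(lt$WDR, 4 / 299)
  expect_equal(lt$LED, 0.5, tolerance = 0.02)     # (1/3)/(2/3) for a uniform bar
  expect_true(is.na(lt$MSL))
  # TRL is close to the bar height (thinning erodes the two end caps)
  expect_equal(lt$TRL, 2.99, tolerance = 0.02)
})

test_that("a primary with one horizontal lateral decomposes additively", {
  m <- matrix(FALSE, 340, 140)
  m[11:310, 20] <- TRUE                    # 300-px primary
  m[60, 21:120] <- TRUE                    # 100-px horizontal lateral at depth 50
  msk <- root_mask(m)
  g <- labelled(msk)
  lt <- length_traits(g, msk, calibration())
  expect_equal(lt$TRL, 4.00, tolerance = 0.01)
  expect_equal(lt$LRL, 1.00, tolerance = 0.015)   # one pixel-step semantics
  expect_equal(lt$MSL, 1.00, tolerance = 0.015)
  # the upper third (rows < 11 + 100) holds 100 px of primary + the lateral
  expect_equal(lt$TRLUpper, 2.00, tolerance = 0.02)
  expect_equal(lt$TRLUpper + lt$TRLLower, lt$TRL, tolerance = 1e-9)
  expect_equal(length_traits(g, msk, calibration(), lrb = 1)$LSLP,
               1 / lt$PRL)
})

test_that("upper + lower skeleton lengths always reconstruct the total", {
  for (sd in c(31, 35, 36)) {
    sc <- fx_scene(sd)
    g <- fx_skeleton(sd)
    lt <- length_traits(g, sc$truth$mask, calibration())
    expect_equal(lt$TRLUpper + lt$TRLLower, lt$TRL, tolerance = 1e-9)
    expect_equal(lt$TRL, lt$PRL + lt$LRL, tolerance = 1e-9)
  }
})

test_that("area traits on a filled square match direct enumeration", {
  m <- matrix(FALSE, 140, 140); m[21:120, 21:120] <- TRUE
  msk <- root_mask(m)
  g <- skeletonize(msk)
  at <- area_traits(msk, g, calibration())
  expect_equal(at$TRArea, 1)                               # 10000 px^2
  expect_equal(at$CVA, 0.9801)                             # 99 x 99 centre hull
  expect_equal(at$SOL, 1)                                  # clipped ratio
  expect_equal(at$PER, oracle_perimeter(m) / 100)
  expect_equal(oracle_perimeter(m), 396)
})

test_that("area oracles hold on random small masks", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(runif(48 * 48) > 0.6, 48, 48)
    m[1, ] <- FALSE; m[, 1] <- FALSE                       # keep a border
    if (!any(m)) next
    expect_equal(rootarch:::perimeter_px(m), oracle_perimeter(m))
    hull <- rootarch:::hull_of_mask(m)
    if (!is.null(hull)) {
      pts <- which(m, arr.ind = TRUE)[, c(2, 1)]
      ora <- oracle_hull_vertices(pts)
      expect_equal(rootarch:::poly_area(hull),
                   rootarch:::poly_area(ora[grDevices::chull(ora), , drop = FALSE]))
    }
  }
})

test_that("degenerate masks yield missing hull traits", {
  m <- matrix(FALSE, 20, 20); m[5, 5:7] <- TRUE            # collinear
  at <- area_traits(root_mask(m), skeletonize(root_mask(m)), calibration())
  expect_true(is.na(at$CVA))
  expect_true(is.na(at$SOL))
})

test_that("rhizosphere band contains the root body for thin strokes", {
  sc <- fx_scene(31)
  g <- fx_skeleton(31)
  at <- area_traits(sc$truth$mask, g, calibration())
  expect_gte(at$RHZO, at$TRArea)
  expect_gt(at$SOL, 0); expect_lte(at$SOL, 1)
})

test_that("a straight cylinder gives the closed-form diameter and volume", {
  msk <- bar_mask(340, 60, 11, 310, 26, 35)                # width 10, length 300
  g <- detect_primary_root(skeletonize(msk))
  st <- primary_solid_traits(msk, g, calibration())
  expect_equal(st$DIA, 0.10, tolerance = 0.01)
  expect_equal(st$VOL, pi * 0.05^2 * 3.00, tolerance = 0.10)
  expect_equal(st$PRA, 2 * pi * 0.05 * 3.00, tolerance = 0.10)
  # the same cylinder rotated 45 degrees: exact perpendicular band of
  # half-width 5 around the diagonal centreline
  H <- 340
  g45 <- expand.grid(r = 1:H, c = 1:H)
  u <- ((g45$r - 20) + (g45$c - 20)) / 2               # position along the line
  perp <- abs((g45$r - 20) - (g45$c - 20)) / sqrt(2)
  m <- matrix(perp <= 5 & u >= 0 & u <= 300 / sqrt(2), H, H)
  g2 <- detect_primary_root(skeletonize(root_mask(m)))
  st2 <- primary_solid_traits(root_mask(m), g2, calibration())
  expect_equal(st2$VOL, pi * 0.05^2 * 3.00, tolerance = 0.12)
})

test_that("too-short primary paths return missing solid traits", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  g <- detect_primary_root(skeletonize(root_mask(m)))
  st <- primary_solid_traits(root_mask(m), g, calibration())
  expect_true(is.na(st$DIA) && is.na(st$VOL) && is.na(st$PRA))
})

test_that("centre measures of a uniform bar match the uniform-density values", {
  ct <- center_traits(bar_mask())
  expect_equal(ct$COM, 0.5, tolerance = 0.005)
  expect_equal(ct$COP, 0.5, tolerance = 0.005)
  expect_equal(ct$CMT, 1 / 6, tolerance = 0.01)
  expect_equal(ct$CMM, 1 / 2, tolerance = 0.01)
  expect_equal(ct$CMB, 5 / 6, tolerance = 0.01)
})

test_that("bottom-heavy mass pulls the centre of mass to 1", {
  m <- matrix(FALSE, 100, 30)
  m[10, 15] <- TRUE; m[99, 5:25] <- TRUE
  ct <- center_traits(root_mask(m))
  expect_gt(ct$COM, 0.95)
  # dense upper mass puts COM above COP (brute-force pixel sums agree)
  m2 <- matrix(FALSE, 100, 60)
  m2[10:90, 30] <- TRUE
  m2[12:30, 10:50] <- TRUE
  ct2 <- center_traits(root_mask(m2))
  fg <- which(m2, arr.ind = TRUE)
  com_bf <- (mean(fg[, 1]) - min(fg[, 1])) / diff(range(fg[, 1]))
  expect_equal(ct2$COM, com_bf)
  expect_lt(ct2$COM, ct2$COP)
})

test_that("traits are invariant under horizontal mirroring", {
  sc <- fx_scene(31)
  m <- sc$truth$mask$pixels
  mm <- m[, ncol(m):1, drop = FALSE]
  g1 <- labelled(root_mask(m)); g2 <- labelled(root_mask(mm))
  lt1 <- length_traits(g1, root_mask(m), calibration())
  lt2 <- length_traits(g2, root_mask(mm), calibration())
  expect_equal(lt2$TRL, lt1$TRL, tolerance = 0.01)
  expect_equal(lt2$DEP, lt1$DEP)
  expect_equal(lt2$WID, lt1$WID)
  at1 <- area_traits(root_mask(m), g1, calibration())
  at2 <- area_traits(root_mask(mm), g2, calibration())
  expect_equal(at2$TRArea, at1$TRArea)
  expect_equal(at2$PER, at1$PER)
  expect_equal(at2$CVA, at1$CVA, tolerance = 1e-9)
  expect_equal(count_lrb(g2), count_lrb(g1))
})
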