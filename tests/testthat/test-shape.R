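# Shape profiles: mean-boundary radial profile, hull contour, Fourier
# expansion/reconstruction.

disc_mask <- function(H, W, ctr, r, ry = r) {
  g <- expand.grid(r = 1:H, c = 1:W)
  m <- matrix((g$r - ctr[1])^2 / ry^2 + (g$c - ctr[2])^2 / r^2 <= 1, H, W)
  root_mask(m)
}

test_that("a filled circle has a constant radial profile", {
  msk <- disc_mask(120, 120, c(60, 60), 50)
  rp <- mean_boundary_profile(msk)
  expect_true(all(abs(rp$profile - 50) <= 1.5))
})

test_that("a 2:1 ellipse has a 2:1 profile ratio", {
  msk <- disc_mask(140, 140, c(70, 70), 30, 60)
  rp <- mean_boundary_profile(msk)
  expect_equal(max(rp$profile) / min(rp$profile), 2, tolerance = 0.05)
})

test_that("hull contours match the O(n^3) oracle on random points", {
  set.seed(11)
  m <- matrix(FALSE, 64, 64)
  pts <- cbind(sample(5:60, 50, TRUE), sample(5:60, 50, TRUE))
  m[pts] <- TRUE
  hc <- hull_contour(root_mask(m))
  ora <- oracle_hull_vertices(which(m, arr.ind = TRUE)[, c(2, 1)])
  # same vertex sets
  expect_setequal(paste(hc[, 1], hc[, 2]), paste(ora[, 1], ora[, 2]))
  # starts at the lowest row, ties to the lowest column
  expect_equal(unname(hc[1, 2]), min(hc[, 2]))
  # square + interior point: interior point absent
  m2 <- matrix(FALSE, 20, 20)
  m2[cbind(c(3, 3, 15, 15, 9), c(3, 15, 3, 15, 9))] <- TRUE
  h2 <- hull_contour(root_mask(m2))
  expect_equal(nrow(h2), 4)
  expect_false(any(h2[, 1] == 9 & h2[, 2] == 9))
  # collinear mask is an error
  m3 <- matrix(FALSE, 10, 10); m3[4, 2:8] <- TRUE
  expect_error(hull_contour(root_mask(m3)), "degenerate")
})

test_that("hull area equals the convex-area trait exactly (shared routine)", {
  sc <- fx_scene(31)
  g <- fx_skeleton(31)
  hc <- hull_contour(sc$truth$mask)
  at <- area_traits(sc$truth$mask, g, calibration())
  expect_equal(rootarch:::poly_area(hc) / 100^2, at$CVA, tolerance = 1e-12)
})

test_that("radial Fourier expansion matches direct DFT sums", {
  msk <- disc_mask(120, 120, c(60, 60), 50)
  rp <- mean_boundary_profile(msk, samples = 180)
  sp <- fourier_expand(rp, N = 10)
  # constant profile: all harmonics near zero
  expect_true(all(abs(sp$coefficients$a) < 0.5))
  expect_true(all(abs(sp$coefficients$b) < 0.5))
  # direct-sum oracle on an arbitrary profile
  p <- 40 + 5 * cos(2 * pi * (0:179) * 3 / 180) + 2 * sin(2 * pi * (0:179) * 7 / 180)
  rp2 <- structure(list(profile = p, centroid = c(0, 0), samples = 180),
                   class = "radial_profile")
  sp2 <- fourier_expand(rp2, N = 10)
  expect_equal(sp2$coefficients$a[3], 5, tolerance = 1e-9)
  expect_equal(sp2$coefficients$b[7], 2, tolerance = 1e-9)
  expect_equal(sp2$offset, 40, tolerance = 1e-9)
  # Parseval: profile energy = coefficient energy for band-limited input
  lhs <- mean(p^2)
  rhs <- sp2$offset^2 + sum(sp2$coefficients$a^2 + sp2$coefficients$b^2) / 2
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # aliasing guard
  expect_error(fourier_expand(rp2, N = 100), "aliasing")
})

test_that("elliptical descriptors match the quadrature oracle to 1e-6", {
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  r <- 40 + 8 * cos(2 * th) + 3 * sin(3 * th)
  poly <- cbind(100 + r * cos(th), 100 + r * sin(th))
  imp <- fourier_expand(poly, N = 5)$coefficients
  ora <- oracle_efd(poly, 5)
  expect_equal(as.matrix(imp[, c("a", "b", "c", "d")]),
               as.matrix(ora[, c("a", "b", "c", "d")]), tolerance = 1e-6)
})

test_that("a circle contour reduces to a circular first harmonic", {
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  poly <- cbind(50 + 30 * cos(th), 50 + 30 * sin(th))
  sp <- fourier_expand(poly, N = 5, normalize = TRUE)
  co <- sp$coefficients
  M1 <- matrix(as.numeric(co[1, c("a", "b", "c", "d")]), 2, 2, byrow = TRUE)
  sv <- svd(M1)$d
  expect_equal(sv[1], 1, tolerance = 1e-6)          # normalised semi-major
  expect_equal(sv[2], 1, tolerance = 1e-3)          # circular: axes equal
  expect_true(all(abs(as.matrix(co[2:5, c("a", "b", "c", "d")])) < 1e-3))
  # reconstruction of the circle from one harmonic is a circle
  rec <- fourier_reconstruct(sp, N_use = 1, samples = 100)
  rad <- sqrt((rec[, 1] - mean(rec[, 1]))^2 + (rec[, 2] - mean(rec[, 2]))^2)
  expect_lt(diff(range(rad)) / mean(rad), 0.01)
})

test_that("mirrored masks give mirror-transformed elliptical descriptors", {
  sc <- fx_scene(31)
  m <- sc$truth$mask$pixels
  hc <- hull_contour(root_mask(m))
  hm <- hull_contour(root_mask(m[, ncol(m):1, drop = FALSE]))
  s1 <- fourier_expand(hc, N = 4)
  s2 <- fourier_expand(hm, N = 4)
  # mirroring x flips the sign pattern of the x-coefficients; harmonic
  # amplitudes per harmonic are preserved
  amp <- function(s) sqrt(s$coefficients$a^2 + s$coefficients$b^2 +
                            s$coefficients$c^2 + s$coefficients$d^2)
  expect_equal(amp(s2), amp(s1), tolerance = 1e-6)
})

test_that("reconstruction error is non-increasing in harmonic count", {
  sc <- fx_scene(35)
  rp <- mean_boundary_profile(sc$truth$mask, samples = 240)
  sp <- fourier_expand(rp, N = 100)
  errs <- vapply(c(2, 5, 10, 20, 100), function(nu) {
    rec <- fourier_reconstruct(sp, N_use = nu, samples = 240)
    sqrt(mean((rec$radius - rp$profile)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_error(fourier_reconstruct(sp, N_use = 200), "harmonic")
  # a band-limited profile is recovered exactly once N covers its band
  p <- 40 + 5 * cos(2 * pi * (0:179) * 3 / 180)
  rpb <- structure(list(profile = p, centroid = c(0, 0), samples = 180),
                   class = "radial_profile")
  rec <- fourier_reconstruct(fourier_expand(rpb, N = 5), N_use = 5,
                             samples = 180)
  expect_equal(rec$radius, p, tolerance = 1e-9)
})
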