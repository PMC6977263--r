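# Quantitative genetics: IQR filter, random-effects model, heritability,
# Tukey HSD, CV_G, correlations.

sim_panel <- function(n_g, reps, s2g, s2e, seed, mu = 10) {
  set.seed(seed)
  g <- rnorm(n_g, 0, sqrt(s2g))
  data.frame(
    genotype = rep(sprintf("G%03d", seq_len(n_g)), each = reps),
    value = mu + rep(g, each = reps) + rnorm(n_g * reps, 0, sqrt(s2e)))
}

test_that("the IQR filter removes exactly the fence violations", {
  obs <- data.frame(genotype = "A", trait = "TRL", value = c(1, 2, 3, 100))
  out <- iqr_filter(obs)
  expect_equal(out$removed$value, 100)
  q <- quantile(c(1, 2, 3, 100), c(0.25, 0.75))
  expect_true(all(out$kept$value >= q[1] - 1.5 * diff(q) &
                    out$kept$value <= q[2] + 1.5 * diff(q)))
  # all-equal group: nothing removed
  same <- data.frame(genotype = "A", trait = "TRL", value = rep(5, 6))
  expect_equal(nrow(iqr_filter(same)$removed), 0)
  # small groups pass through with a flag
  small <- data.frame(genotype = "B", trait = "TRL", value = c(1, 2, 1000))
  res <- iqr_filter(small)
  expect_equal(nrow(res$kept), 3)
  expect_length(res$flagged_groups, 1)
})

test_that("REML matches the balanced ANOVA method-of-moments estimates", {
  obs <- sim_panel(8, 6, s2g = 4, s2e = 1, seed = 11)
  mdl <- fit_random_model(obs)
  fitA <- aov(value ~ genotype, data = obs)
  ms <- summary(fitA)[[1]]$`Mean Sq`
  s2e_anova <- ms[2]
  s2g_anova <- max(0, (ms[1] - ms[2]) / 6)
  expect_equal(mdl$sigma2_e, s2e_anova, tolerance = 1e-5)
  expect_equal(mdl$sigma2_g, s2g_anova, tolerance = 1e-5)
  expect_equal(mdl$grand_mean, mean(obs$value), tolerance = 1e-6)
})

test_that("genetic variance is recovered from a replicated simulation", {
  obs <- sim_panel(100, 14, s2g = 4, s2e = 1, seed = 5)
  mdl <- fit_random_model(obs)
  expect_gt(mdl$sigma2_g, 3.2)
  expect_lt(mdl$sigma2_g, 4.8)
})

test_that("a null genetic signal shrinks BLUPs toward the grand mean", {
  obs <- sim_panel(30, 6, s2g = 0, s2e = 1, seed = 2)
  mdl <- fit_random_model(obs)
  expect_lt(mdl$sigma2_g, 0.1)
  expect_true(all(abs(coef(mdl)) < 0.5))
  # shrinkage: |BLUP| <= |raw deviation| in balanced designs
  raw <- tapply(obs$value, obs$genotype, mean) - mean(obs$value)
  expect_true(all(abs(coef(mdl)) <= abs(raw[names(coef(mdl))]) + 1e-9))
})

test_that("a block effect is separated when blocks are present", {
  set.seed(9)
  obs <- sim_panel(20, 8, s2g = 2, s2e = 1, seed = 9)
  obs$block <- rep(rep(1:2, each = 4), 20)
  obs$value <- obs$value + c(-1.5, 1.5)[obs$block]
  mdl <- fit_random_model(obs)
  expect_gt(mdl$sigma2_b, 0.5)
  # single genotype is rejected
  expect_error(fit_random_model(data.frame(genotype = "A", value = rnorm(5))),
               "genotypes")
})

test_that("entry-mean heritability follows its closed form", {
  vc <- list(sigma2_g = 1, sigma2_e = 14)
  expect_equal(heritability(vc, 14), 0.5)
  expect_equal(heritability(list(sigma2_g = 0, sigma2_e = 3), 14), 0)
  expect_true(is.na(heritability(list(sigma2_g = 0, sigma2_e = 0), 14)))
  # monotone non-decreasing in the replicate count
  h <- vapply(1:14, function(n) heritability(vc, n), numeric(1))
  expect_true(all(diff(h) >= 0))
})

test_that("Tukey HSD equals the hand computation and separates clear means", {
  set.seed(4)
  obs <- data.frame(
    genotype = rep(c("A", "B", "C"), each = 14),
    value = c(rnorm(14, 10), rnorm(14, 10.2), rnorm(14, 30)))
  res <- tukey_hsd(obs)
  fit <- aov(value ~ genotype, data = obs)
  mse <- deviance(fit) / df.residual(fit)
  expect_equal(res$hsd, qtukey(0.95, 3, 39) * sqrt(mse / 14), tolerance = 1e-10)
  lets <- setNames(res$groups$letters, res$groups$genotype)
  expect_equal(lets[["A"]], lets[["B"]])
  expect_false(lets[["C"]] == lets[["A"]])
  # equal means share one letter
  set.seed(8)
  eq <- data.frame(genotype = rep(c("A", "B", "C"), each = 14),
                   value = rnorm(42, 10, 1))
  expect_equal(length(unique(tukey_hsd(eq)$groups$letters)), 1)
  expect_error(tukey_hsd(data.frame(genotype = "A", value = rnorm(5))),
               "2 genotypes")
})

test_that("HSD letter groupings agree with multcomp on a 4-group case", {
  skip_if_not_installed("multcomp")
  set.seed(12)
  obs <- data.frame(
    genotype = factor(rep(c("A", "B", "C", "D"), each = 14)),
    value = c(rnorm(14, 0), rnorm(14, 0.4), rnorm(14, 3), rnorm(14, 6)))
  res <- tukey_hsd(obs)
  fit <- aov(value ~ genotype, data = obs)
  cld <- multcomp::cld(multcomp::glht(fit, multcomp::mcp(genotype = "Tukey")))
  ref <- cld$mcletters$Letters
  mine <- setNames(res$groups$letters, res$groups$genotype)
  # identical partition structure: same genotypes share letters
  same_group <- function(lets) outer(lets, lets,
                                     Vectorize(function(x, y)
                                       any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]])))
  expect_equal(unname(same_group(mine[names(ref)])), unname(same_group(ref)))
})

test_that("the genetic coefficient of variation follows Eq-form", {
  expect_equal(cv_g(list(sigma2_g = 4), 10), 0.2)
  expect_equal(cv_g(list(sigma2_g = 0), 10), 0)
  expect_true(is.na(cv_g(list(sigma2_g = 1), 0)))
  # recovery from simulation: sqrt(1)/5 = 0.2
  obs <- sim_panel(80, 10, s2g = 1, s2e = 0.5, seed = 14, mu = 5)
  mdl <- fit_random_model(obs)
  expect_lt(abs(cv_g(mdl, mdl$grand_mean) - 0.2), 0.04)
})

test_that("trait correlations behave on duplicates, negations and samples", {
  set.seed(9)
  x <- rnorm(115)
  m <- cbind(t1 = x, t2 = x, t3 = -x)
  cc <- trait_correlations(m)
  expect_equal(cc["t1", "t2"], 1)
  expect_equal(cc["t1", "t3"], -1)
  # population correlation 0.86 recovered inside its Fisher-z interval
  z <- atanh(0.86); n <- 115
  y <- 0.86 * x + sqrt(1 - 0.86^2) * rnorm(n)
  r <- trait_correlations(cbind(a = x, b = y))["a", "b"]
  expect_gt(r, tanh(z - 2.58 / sqrt(n - 3)))
  expect_lt(r, tanh(z + 2.58 / sqrt(n - 3)))
  # constant columns give NA
  cc2 <- suppressWarnings(trait_correlations(cbind(a = x, k = rep(1, n))))
  expect_true(is.na(cc2["a", "k"]))
})
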