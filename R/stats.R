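# Quantitative-genetics post-processing of extracted trait tables:
# IQR outlier filtering, the two-way random-effects model
# y_ik = mu + g_i + b_k + e_ik (all factors random, REML) with genotype
# BLUPs, entry-mean broad-sense heritability H2 = s2g / (s2g + s2e/n),
# Tukey HSD groupings HSD = q * sqrt(MSE/n*), the genetic coefficient of
# variation CV_G = sqrt(V_G)/mean, and Pearson trait correlations.

#' IQR outlier filter
#'
#' Within each (genotype, trait, day) group, observations outside the
#' Tukey fences `[Q1 - k*IQR, Q3 + k*IQR]` are removed. Groups smaller
#' than `min_group` pass through unfiltered and are flagged.
#'
#' @param obs Data frame with columns `genotype`, `value` and optionally
#'   `trait`, `day`.
#' @param k Fence multiplier (default 1.5).
#' @param min_group Minimum group size for filtering (default 4).
#' @return List with `kept`, `removed` (data frames) and
#'   `flagged_groups` (character vector of unfiltered small groups).
#' @export
iqr_filter <- function(obs, k = 1.5, min_group = 4) {
  stopifnot(is.data.frame(obs), all(c("genotype", "value") %in% names(obs)))
  key_cols <- intersect(c("genotype", "trait", "day"), names(obs))
  key <- interaction(obs[key_cols], drop = TRUE)
  keep <- rep(TRUE, nrow(obs))
  flagged <- character(0)
  for (g in levels(key)) {
    i <- which(key == g)
    v <- obs$value[i]
    if (length(i) < min_group) {
      flagged <- c(flagged, g)
      next
    }
    q <- quantile(v, c(0.25, 0.75), na.rm = TRUE, type = 7)
    iqr <- q[2] - q[1]
    out <- v < q[1] - k * iqr | v > q[2] + k * iqr
    keep[i[out & !is.na(out)]] <- FALSE
  }
  list(kept = obs[keep, , drop = FALSE],
       removed = obs[!keep, , drop = FALSE],
       flagged_groups = flagged)
}

#' Fit the two-way random-effects model
#'
#' REML fit (via lme4) of `value ~ (1|genotype) + (1|block)` — the model
#' in which the response of genotype i in block k is the grand mean plus
#' a random genetic effect, a random block effect and residual error.
#' With a single block the block term is dropped and its variance fixed
#' at zero (flagged).
#'
#' @param obs Data frame with columns `genotype`, `value` and optionally
#'   `block`.
#' @return Object of class `"rsa_model"`: variance components
#'   (`sigma2_g`, `sigma2_b`, `sigma2_e`), `grand_mean`, per-genotype
#'   `blups`, the `fit`, and `flag`. Negative variance estimates are
#'   truncated at 0 by the REML fit itself.
#' @export
fit_random_model <- function(obs) {
  stopifnot(is.data.frame(obs), all(c("genotype", "value") %in% names(obs)))
  obs <- obs[is.finite(obs$value), , drop = FALSE]
  if (length(unique(obs$genotype)) < 2)
    stop("need at least 2 genotypes to separate genetic variance")
  nblock <- if ("block" %in% names(obs)) length(unique(obs$block)) else 1
  flag <- if (nblock > 1) character(0) else "single_block"
  fit <- tryCatch({
    if (nblock > 1) {
      lme4::lmer(value ~ 1 + (1 | genotype) + (1 | block), data = obs,
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    } else {
      lme4::lmer(value ~ 1 + (1 | genotype), data = obs, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    }
  }, error = function(e) stop("random-effects fit failed: ",
                              conditionMessage(e), call. = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2 <- setNames(vc$vcov, vc$grp)
  re <- lme4::ranef(fit)$genotype
  blups <- setNames(re[, 1], rownames(re))
  structure(list(
    sigma2_g = unname(s2["genotype"]),
    sigma2_b = if (nblock > 1) unname(s2["block"]) else 0,
    sigma2_e = unname(s2["Residual"]),
    grand_mean = unname(lme4::fixef(fit)[1]),
    blups = blups, fit = fit, flag = flag,
    n_genotypes = length(blups), n_obs = nrow(obs)
  ), class = "rsa_model")
}

#' @export
print.rsa_model <- function(x, ...) {
  cat(sprintf("Random-effects RSA model: %d genotypes, %d observations\n",
              x$n_genotypes, x$n_obs))
  cat(sprintf("  sigma2_g = %.4g, sigma2_b = %.4g, sigma2_e = %.4g, mean = %.4g\n",
              x$sigma2_g, x$sigma2_b, x$sigma2_e, x$grand_mean))
  invisible(x)
}

#' @export
coef.rsa_model <- function(object, ...) object$blups

#' @export
summary.rsa_model <- function(object, ...) {
  list(variance_components = c(sigma2_g = object$sigma2_g,
                               sigma2_b = object$sigma2_b,
                               sigma2_e = object$sigma2_e),
       grand_mean = object$grand_mean,
       blups = object$blups,
       flag = object$flag)
}

#' Entry-mean broad-sense heritability
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_e / n)` with `n` the number of
#' replications per genotype.
#'
#' @param vc An `"rsa_model"` or a list with `sigma2_g` and `sigma2_e`.
#' @param n Replicate count (>= 1).
#' @return H2 in `[0, 1]`; `NA` when both variance components are zero.
#' @export
heritability <- function(vc, n) {
  stopifnot(n >= 1)
  s2g <- vc$sigma2_g; s2e <- vc$sigma2_e
  if ((s2g + s2e) == 0) return(NA_real_)
  s2g / (s2g + s2e / n)
}

#' Genetic coefficient of variation
#'
#' `CV_G = sqrt(V_G) / mean`.
#'
#' @param vc An `"rsa_model"` or a list with `sigma2_g`.
#' @param trait_mean Trait mean; must be nonzero.
#' @return CV_G, or `NA` for a zero mean.
#' @export
cv_g <- function(vc, trait_mean) {
  if (!is.finite(trait_mean) || trait_mean == 0) return(NA_real_)
  sqrt(vc$sigma2_g) / trait_mean
}

# Compact letter display. Means sorted descending form an interval graph
# under "differ by less than HSD": maximal cliques are the maximal
# contiguous ranges [i, end_i]; each gets one letter.
letter_display <- function(means, hsd) {
  ord <- order(-means)
  k <- length(means)
  ms <- means[ord]
  # every mean groups at least with itself (degenerate HSD = 0 included)
  ends <- vapply(seq_len(k), function(i)
    max(c(i, which(ms[i] - ms < hsd))), integer(1))
  lets <- rep("", k)
  ci <- 0L; last_end <- 0L
  for (i in seq_len(k)) {
    if (ends[i] > last_end) {
      ci <- ci + 1L
      for (j in i:ends[i])
        lets[ord[j]] <- paste0(lets[ord[j]], letters[ci])
      last_end <- ends[i]
    }
  }
  lets
}

#' Tukey HSD groupings
#'
#' One-way fixed-genotype ANOVA provides the mean squared error; the
#' honest significant difference is `q * sqrt(MSE / n*)` with `q` the
#' studentized-range quantile at level `alpha` for the number of groups
#' and residual degrees of freedom, and `n*` the (harmonic mean)
#' replicate count. Genotypes whose means differ by less than the HSD
#' share a letter.
#'
#' @param obs Data frame with columns `genotype` and `value` for one
#'   trait/day.
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `groups` (data frame: genotype, mean, n, letters),
#'   `hsd`, `q`, `mse`, `df_resid`, `alpha`.
#' @export
tukey_hsd <- function(obs, alpha = 0.05) {
  stopifnot(is.data.frame(obs), all(c("genotype", "value") %in% names(obs)))
  obs <- obs[is.finite(obs$value), , drop = FALSE]
  obs$genotype <- factor(obs$genotype)
  kg <- nlevels(obs$genotype)
  if (kg < 2) stop("Tukey HSD needs at least 2 genotypes")
  fit <- aov(value ~ genotype, data = obs)
  mse <- deviance(fit) / df.residual(fit)
  ns <- tapply(obs$value, obs$genotype, length)
  nstar <- length(ns) / sum(1 / ns)            # harmonic mean replicate count
  q <- qtukey(1 - alpha, kg, df.residual(fit))
  hsd <- q * sqrt(mse / nstar)
  means <- tapply(obs$value, obs$genotype, mean)
  lets <- letter_display(as.numeric(means), hsd)
  list(groups = data.frame(genotype = names(means),
                           mean = as.numeric(means),
                           n = as.integer(ns),
                           letters = lets,
                           stringsAsFactors = FALSE),
       hsd = hsd, q = q, mse = mse, df_resid = df.residual(fit),
       alpha = alpha)
}

#' Pearson correlations between trait BLUP profiles
#'
#' @param blups Numeric matrix or data frame, genotypes in rows, traits
#'   in columns (>= 3 rows, >= 2 columns).
#' @return Pairwise-complete Pearson correlation matrix; pairs involving
#'   a constant column are `NA`.
#' @export
trait_correlations <- function(blups) {
  blups <- as.matrix(blups)
  stopifnot(nrow(blups) >= 3, ncol(blups) >= 2)
  suppressWarnings(cor(blups, use = "pairwise.complete.obs",
                       method = "pearson"))
}
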