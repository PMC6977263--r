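# Convolutional auto-encoder segmentation, implemented as a small
# self-contained conv-net engine (im2col convolutions, 2x2 max pooling,
# nearest-neighbour upsampling, Adam) so the learned segmenter runs on a
# plain CPU with no external deep-learning runtime.
#
# Architecture (encoder): three 3x3 convolution layers with 32 feature
# maps each and ReLU activations, with 2x2 pooling after the first and
# second; the decoder mirrors the encoder with nearest-neighbour
# upsampling; a final 1-map convolution with a sigmoid yields per-pixel
# foreground probabilities. Loss: binary cross-entropy plus Jaccard loss.
# Optimiser: Adam at learning rate 0.001.

#' CAE architecture specification
#'
#' @param feature_maps Feature maps per convolution layer (default 32).
#' @param kernel Convolution kernel side (default 3).
#' @param patch_px Training patch side; inputs larger than this are
#'   cropped around a balanced random centre. Must be divisible by 4
#'   (two 2x2 poolings).
#' @return Object of class `"cae_spec"`.
#' @export
cae_spec <- function(feature_maps = 32, kernel = 3, patch_px = 32) {
  stopifnot(feature_maps >= 1, kernel == 3, patch_px %% 4 == 0)
  structure(list(feature_maps = as.integer(feature_maps),
                 kernel = as.integer(kernel),
                 patch_px = as.integer(patch_px)),
            class = "cae_spec")
}

#' CAE training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Training epochs per fold.
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed controlling initialisation, fold assignment
#'   and patch sampling.
#' @return Object of class `"cae_config"`.
#' @export
cae_config <- function(learning_rate = 0.001, epochs = 20, folds = 5,
                       seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, folds >= 2)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "cae_config")
}

# ---- tensor ops ------------------------------------------------------------
# Feature maps are flat (H*W) x C matrices in column-major pixel order,
# with the spatial size carried alongside. Convolutions, pooling and
# upsampling are precomputed row-gather operations (cached per spatial
# size), so every layer reduces to indexing plus one matrix multiply.

cae_idx_cache <- new.env(parent = emptyenv())

# Gather indices for the nine 3x3 neighbourhood offsets ("same" padding:
# out-of-bounds neighbours point at a trailing zero row), plus the 2x2
# quadrant indices used by pooling/upsampling.
spatial_idx <- function(H, W) {
  key <- paste0(H, "x", W)
  hit <- cae_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  HW <- H * W
  zero_row <- HW + 1L
  gr <- rep(seq_len(H), times = W)
  gc <- rep(seq_len(W), each = H)
  nb <- vector("list", 9)
  k <- 0
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1
    r2 <- gr + dr; c2 <- gc + dc
    ok <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
    v <- rep(zero_row, HW)
    v[ok] <- r2[ok] + (c2[ok] - 1L) * H
    nb[[k]] <- v
  }
  quad <- NULL
  if (H %% 2 == 0 && W %% 2 == 0) {
    i <- rep(seq_len(H / 2), times = W / 2)
    j <- rep(seq_len(W / 2), each = H / 2)
    quad <- list(`11` = (2 * i - 1) + (2 * j - 2) * H,
                 `21` = (2 * i)     + (2 * j - 2) * H,
                 `12` = (2 * i - 1) + (2 * j - 1) * H,
                 `22` = (2 * i)     + (2 * j - 1) * H)
  }
  out <- list(nb = nb, quad = quad, H = H, W = W)
  cae_idx_cache[[key]] <- out
  out
}

im2col_m <- function(x, si) {
  C <- ncol(x)
  x_ext <- rbind(x, 0)
  cols <- matrix(0, nrow(x), 9 * C)
  for (k in 1:9)
    cols[, ((k - 1) * C + 1):(k * C)] <- x_ext[si$nb[[k]], , drop = FALSE]
  cols
}

conv_fwd <- function(x, Wm, b, si) {
  cols <- im2col_m(x, si)
  y <- cols %*% Wm
  y <- sweep(y, 2, b, `+`)
  list(y = y, cols = cols)
}

conv_bwd <- function(dy, cache_cols, Wm, C_in, si) {
  dW <- crossprod(cache_cols, dy)
  db <- colSums(dy)
  dcols <- dy %*% t(Wm)
  dcols_ext <- rbind(dcols, 0)
  dx <- matrix(0, nrow(dy), C_in)
  for (k in 1:9) {
    # scatter at offset k == gather at the mirrored offset 10 - k
    blk <- dcols_ext[si$nb[[10 - k]], ((k - 1) * C_in + 1):(k * C_in), drop = FALSE]
    dx <- dx + blk
  }
  list(dW = dW, db = db, dx = dx)
}

pool_fwd <- function(x, si) {
  q <- si$quad
  parts <- list(x[q$`11`, , drop = FALSE], x[q$`21`, , drop = FALSE],
                x[q$`12`, , drop = FALSE], x[q$`22`, , drop = FALSE])
  y <- pmax(parts[[1]], parts[[2]], parts[[3]], parts[[4]])
  list(y = y, parts = parts)
}

pool_bwd <- function(dy, cache, si) {
  q <- cache_quad <- si$quad
  y <- pmax(cache$parts[[1]], cache$parts[[2]], cache$parts[[3]], cache$parts[[4]])
  dx <- matrix(0, si$H * si$W, ncol(dy))
  taken <- matrix(FALSE, nrow(dy), ncol(dy))
  ord <- c("11", "21", "12", "22")
  for (k in 1:4) {
    hit <- (cache$parts[[k]] == y) & !taken    # route grad to first max
    taken <- taken | hit
    dx[q[[ord[k]]], ] <- dy * hit
  }
  dx
}

# Nearest-neighbour 2x upsampling: each source cell fills its 2x2 block.
upsample_fwd <- function(x, si_big) {
  q <- si_big$quad
  y <- matrix(0, si_big$H * si_big$W, ncol(x))
  y[q$`11`, ] <- x; y[q$`21`, ] <- x; y[q$`12`, ] <- x; y[q$`22`, ] <- x
  y
}

upsample_bwd <- function(dy, si_big) {
  q <- si_big$quad
  dy[q$`11`, , drop = FALSE] + dy[q$`21`, , drop = FALSE] +
    dy[q$`12`, , drop = FALSE] + dy[q$`22`, , drop = FALSE]
}

cae_init_weights <- function(spec, seed) {
  set.seed(seed)
  Fm <- spec$feature_maps
  sizes <- list(c(9 * 3, Fm), c(9 * Fm, Fm), c(9 * Fm, Fm),
                c(9 * Fm, Fm), c(9 * Fm, Fm), c(9 * Fm, 1))
  lapply(sizes, function(s) {
    list(W = matrix(rnorm(prod(s), 0, sqrt(2 / s[1])), s[1], s[2]),
         b = rep(0, s[2]))
  })
}

# Forward pass through the full auto-encoder; x is (H*W) x 3 with the
# spatial size in `si1`. Returns per-pixel sigmoid probabilities and the
# caches needed for backprop.
cae_forward <- function(x, wts, si1) {
  si2 <- spatial_idx(si1$H / 2, si1$W / 2)
  si3 <- spatial_idx(si1$H / 4, si1$W / 4)
  c1 <- conv_fwd(x, wts[[1]]$W, wts[[1]]$b, si1); a1 <- pmax(c1$y, 0)
  p1 <- pool_fwd(a1, si1)
  c2 <- conv_fwd(p1$y, wts[[2]]$W, wts[[2]]$b, si2); a2 <- pmax(c2$y, 0)
  p2 <- pool_fwd(a2, si2)
  c3 <- conv_fwd(p2$y, wts[[3]]$W, wts[[3]]$b, si3); a3 <- pmax(c3$y, 0)
  u1 <- upsample_fwd(a3, si2)
  c4 <- conv_fwd(u1, wts[[4]]$W, wts[[4]]$b, si2); a4 <- pmax(c4$y, 0)
  u2 <- upsample_fwd(a4, si1)
  c5 <- conv_fwd(u2, wts[[5]]$W, wts[[5]]$b, si1); a5 <- pmax(c5$y, 0)
  c6 <- conv_fwd(a5, wts[[6]]$W, wts[[6]]$b, si1)
  prob <- 1 / (1 + exp(-c6$y))
  list(prob = prob,
       cache = list(si1 = si1, si2 = si2, si3 = si3,
                    c1 = c1, p1 = p1, c2 = c2, p2 = p2, c3 = c3,
                    c4 = c4, c5 = c5, c6 = c6))
}

# Gradient of (BCE + Jaccard) wrt the sigmoid logits, then backprop.
cae_backward <- function(fw, truth, wts) {
  p <- fw$prob
  t <- matrix(truth * 1, nrow(p), 1)
  n <- length(p)
  Si <- sum(p * t); Su <- sum(p + t - p * t)
  # d/dp of mean BCE and of (1 - Si/Su)
  dL_dp <- ((p - t) / pmax(p * (1 - p), 1e-7)) / n -
    (t * Su - (1 - t) * Si) / max(Su^2, 1e-7)
  dz <- dL_dp * p * (1 - p)                    # through the sigmoid
  ch <- fw$cache
  Fm <- ncol(ch$c1$y)
  grads <- vector("list", 6)
  b6 <- conv_bwd(dz, ch$c6$cols, wts[[6]]$W, Fm, ch$si1)
  grads[[6]] <- b6[c("dW", "db")]
  d5 <- b6$dx * (ch$c5$y > 0)
  b5 <- conv_bwd(d5, ch$c5$cols, wts[[5]]$W, Fm, ch$si1)
  grads[[5]] <- b5[c("dW", "db")]
  d4 <- upsample_bwd(b5$dx, ch$si1) * (ch$c4$y > 0)
  b4 <- conv_bwd(d4, ch$c4$cols, wts[[4]]$W, Fm, ch$si2)
  grads[[4]] <- b4[c("dW", "db")]
  d3 <- upsample_bwd(b4$dx, ch$si2) * (ch$c3$y > 0)
  b3 <- conv_bwd(d3, ch$c3$cols, wts[[3]]$W, Fm, ch$si3)
  grads[[3]] <- b3[c("dW", "db")]
  d2 <- pool_bwd(b3$dx, ch$p2, ch$si2) * (ch$c2$y > 0)
  b2 <- conv_bwd(d2, ch$c2$cols, wts[[2]]$W, Fm, ch$si2)
  grads[[2]] <- b2[c("dW", "db")]
  d1 <- pool_bwd(b2$dx, ch$p1, ch$si1) * (ch$c1$y > 0)
  b1 <- conv_bwd(d1, ch$c1$cols, wts[[1]]$W, 3L, ch$si1)
  grads[[1]] <- b1[c("dW", "db")]
  grads
}

cae_loss <- function(prob, truth) {
  truth <- matrix(truth * 1, nrow(prob), ncol(prob))
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  bce <- -mean(truth * log(p) + (1 - truth) * log(1 - p))
  bce + jaccard_loss(prob, truth)
}

#' Soft Jaccard loss
#'
#' `1 - sum(p * t) / sum(p + t - p * t)`, in `[0, 1]`; 0 exactly when the
#' probabilities equal the binary truth.
#'
#' @param prob Numeric array/matrix of probabilities in `[0, 1]`.
#' @param truth Binary array/matrix of the same shape.
#' @return The Jaccard loss.
#' @export
jaccard_loss <- function(prob, truth) {
  truth <- truth * 1
  if (!identical(dim(prob) %||% length(prob), dim(truth) %||% length(truth)))
    stop("probability raster and truth mask have different shapes")
  Su <- sum(prob + truth - prob * truth)
  if (Su == 0) return(0)                      # both empty: perfect
  1 - sum(prob * truth) / Su
}

adam_step <- function(wts, grads, state, lr, t_step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(wts)) {
    for (nm in c("W", "b")) {
      g <- if (nm == "W") grads[[l]]$dW else grads[[l]]$db
      state$m[[l]][[nm]] <- beta1 * state$m[[l]][[nm]] + (1 - beta1) * g
      state$v[[l]][[nm]] <- beta2 * state$v[[l]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[nm]] / (1 - beta1^t_step)
      vhat <- state$v[[l]][[nm]] / (1 - beta2^t_step)
      wts[[l]][[nm]] <- wts[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(wts = wts, state = state)
}

adam_init <- function(wts) {
  zero <- lapply(wts, function(w) list(W = w$W * 0, b = w$b * 0))
  list(m = zero, v = zero)
}

# Extract a training patch (x: H x W x 3 in [0,1], t: H x W binary) from
# an image/mask pair, cropping around a random foreground pixel when the
# raster exceeds the patch size.
cae_patch <- function(img, msk, patch_px) {
  px <- if (inherits(img, "root_image")) img$pixels else img
  mt <- mask_pixels(msk) * 1
  H <- dim(px)[1]; W <- dim(px)[2]
  if (H < patch_px || W < patch_px)
    stop("image smaller than the CAE patch size")
  if (H > patch_px || W > patch_px) {
    fg <- which(mt > 0, arr.ind = TRUE)
    ctr <- if (nrow(fg)) fg[sample.int(nrow(fg), 1), ] else c(H / 2, W / 2)
    r0 <- min(max(1, round(ctr[1]) - patch_px %/% 2), H - patch_px + 1)
    c0 <- min(max(1, round(ctr[2]) - patch_px %/% 2), W - patch_px + 1)
    px <- px[r0:(r0 + patch_px - 1), c0:(c0 + patch_px - 1), , drop = FALSE]
    mt <- mt[r0:(r0 + patch_px - 1), c0:(c0 + patch_px - 1)]
  }
  list(x = matrix(px, patch_px * patch_px, 3), t = as.vector(mt))
}

train_cae_single <- function(patches, spec, cfg, seed, track_loss = FALSE) {
  wts <- cae_init_weights(spec, seed)
  state <- adam_init(wts)
  si1 <- spatial_idx(spec$patch_px, spec$patch_px)
  t_step <- 0
  epoch_loss <- numeric(0)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(patches))
    tot <- 0
    for (i in ord) {
      fw <- cae_forward(patches[[i]]$x, wts, si1)
      if (!all(is.finite(fw$prob)))
        stop("non-finite CAE activations at epoch ", ep)
      loss <- cae_loss(fw$prob, patches[[i]]$t)
      if (!is.finite(loss)) stop("non-finite CAE loss at epoch ", ep)
      tot <- tot + loss
      grads <- cae_backward(fw, patches[[i]]$t, wts)
      t_step <- t_step + 1
      up <- adam_step(wts, grads, state, cfg$learning_rate, t_step)
      wts <- up$wts; state <- up$state
    }
    if (track_loss) epoch_loss <- c(epoch_loss, tot / length(patches))
  }
  list(weights = wts, epoch_loss = epoch_loss)
}

#' Train the convolutional auto-encoder segmenter
#'
#' K-fold cross-validated training on (image, mask) pairs: for each fold
#' the network is trained on the remaining pairs and evaluated on the
#' held-out ones (pixelwise F1 and IoU, reported both pooled over pixels
#' and averaged over images); a final model is then trained on all pairs.
#' Fully deterministic for a fixed seed.
#'
#' @param pairs List of `list(image =, mask =)` pairs ([root_image()] /
#'   [root_mask()] or raw arrays), at least `2 * folds` of them.
#' @param spec A [cae_spec()].
#' @param cfg A [cae_config()].
#' @return Object of class `"cae_model"`: final `weights`, `spec`, `cfg`,
#'   `cv` (per-fold and mean F1/IoU), `epoch_loss` of the final run.
#' @export
train_cae <- function(pairs, spec = cae_spec(), cfg = cae_config()) {
  stopifnot(inherits(spec, "cae_spec"), inherits(cfg, "cae_config"))
  n <- length(pairs)
  if (n < 2 * cfg$folds)
    stop("need at least ", 2 * cfg$folds, " pairs for ", cfg$folds,
         "-fold cross-validation")
  set.seed(cfg$seed)
  patches <- lapply(pairs, function(p) cae_patch(p$image, p$mask, spec$patch_px))
  fold_of <- sample(rep(seq_len(cfg$folds), length.out = n))
  fold_stats <- NULL
  for (f in seq_len(cfg$folds)) {
    tr <- patches[fold_of != f]
    te <- patches[fold_of == f]
    set.seed(cfg$seed * 1000L + f)
    run <- train_cae_single(tr, spec, cfg, seed = cfg$seed * 1000L + f)
    tp <- fp <- fn <- 0
    per_img <- NULL
    for (p in te) {
      pr <- cae_forward(p$x, run$weights,
                        spatial_idx(spec$patch_px, spec$patch_px))$prob >= 0.5
      t <- p$t > 0.5
      tp_i <- sum(pr & t); fp_i <- sum(pr & !t); fn_i <- sum(!pr & t)
      tp <- tp + tp_i; fp <- fp + fp_i; fn <- fn + fn_i
      per_img <- rbind(per_img, c(
        F1 = if (2 * tp_i + fp_i + fn_i > 0) 2 * tp_i / (2 * tp_i + fp_i + fn_i) else 1,
        IoU = if (tp_i + fp_i + fn_i > 0) tp_i / (tp_i + fp_i + fn_i) else 1))
    }
    fold_stats <- rbind(fold_stats, data.frame(
      fold = f,
      F1_pooled = 2 * tp / (2 * tp + fp + fn),
      IoU_pooled = tp / (tp + fp + fn),
      F1_mean = mean(per_img[, "F1"]),
      IoU_mean = mean(per_img[, "IoU"])))
  }
  set.seed(cfg$seed)
  final <- train_cae_single(patches, spec, cfg, seed = cfg$seed,
                            track_loss = TRUE)
  structure(list(
    weights = final$weights, spec = spec, cfg = cfg,
    cv = list(folds = fold_stats,
              F1 = mean(fold_stats$F1_pooled),
              IoU = mean(fold_stats$IoU_pooled),
              F1_mean_image = mean(fold_stats$F1_mean),
              IoU_mean_image = mean(fold_stats$IoU_mean)),
    epoch_loss = final$epoch_loss
  ), class = "cae_model")
}

#' @export
print.cae_model <- function(x, ...) {
  cat(sprintf("CAE segmenter: %d feature maps, patch %d px, %d-fold CV F1 %.4f / IoU %.4f\n",
              x$spec$feature_maps, x$spec$patch_px, x$cfg$folds,
              x$cv$F1, x$cv$IoU))
  invisible(x)
}

#' Segment an image with a trained CAE
#'
#' Runs the forward pass (the raster is zero-padded to a multiple of 4 if
#' needed) and thresholds the probability map; the same connected
#' component cleanup as the classical segmenters is applied.
#'
#' @param model A trained `"cae_model"`.
#' @param image A [root_image()].
#' @param threshold Probability threshold (default 0.5).
#' @param min_object_px Minimum connected-component size kept.
#' @return A [root_mask()]; empty masks carry a `"no_root"` flag.
#' @export
segment_cae <- function(model, image, threshold = 0.5, min_object_px = 100) {
  stopifnot(inherits(model, "cae_model"), inherits(image, "root_image"))
  px <- image$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  H4 <- ceiling(H / 4) * 4; W4 <- ceiling(W / 4) * 4
  if (H4 != H || W4 != W) {
    pad <- array(0, c(H4, W4, 3))
    pad[1:H, 1:W, ] <- px
    px <- pad
  }
  xm <- matrix(px, H4 * W4, 3)
  prob <- matrix(cae_forward(xm, model$weights, spatial_idx(H4, W4))$prob,
                 H4, W4)[1:H, 1:W]
  m <- prob >= threshold
  m <- clean_mask(m, min_object_px)
  root_mask(m, image$calibration,
            flag = if (!any(m)) "no_root" else character(0))
}
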