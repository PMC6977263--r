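# Small internal helpers shared across modules.

# Shoelace area of a closed polygon given as a 2-column matrix (x, y).
# Vertices need not repeat the first point at the end.
poly_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b
  A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# Integrate f over [a, b] with composite Gauss-Legendre quadrature.
gl_integrate <- function(f, a, b, nodes = 16, pieces = 8) {
  gl <- gauss_legendre(nodes)
  edges <- seq(a, b, length.out = pieces + 1)
  total <- 0
  for (k in seq_len(pieces)) {
    lo <- edges[k]; hi <- edges[k + 1]
    x <- (hi - lo) / 2 * gl$x + (hi + lo) / 2
    total <- total + (hi - lo) / 2 * sum(gl$w * f(x))
  }
  total
}

# Deterministic polynomial string hash (8 hex digits), used only to
# fingerprint pipeline configurations for batch resumability. The modulus
# keeps every intermediate below 2^31 so arithmetic stays exact.
str_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 67108859
  sprintf("%08x", h)
}

# Pixel-overlap metrics between two logical masks of equal shape.
mask_iou <- function(pred, truth) {
  pred <- mask_pixels(pred); truth <- mask_pixels(truth)
  stopifnot(identical(dim(pred), dim(truth)))
  inter <- sum(pred & truth)
  union <- sum(pred | truth)
  if (union == 0) return(1)
  inter / union
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
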