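# Internal helpers shared across modules. Error classes used throughout:
#   rp_invalid_argument, rp_registration_failure, rp_seed_error,
#   rp_tracking_error.

stop_invalid <- function(msg) {
  abort(msg, class = "rp_invalid_argument")
}

check_number <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop_invalid(sprintf("`%s` must be positive (got %g)", name, x))
  }
  if (integer && x != round(x)) {
    stop_invalid(sprintf("`%s` must be a whole number (got %g)", name, x))
  }
  invisible(x)
}

check_matrix_image <- function(img, name = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop_invalid(sprintf("`%s` must be a numeric matrix (single-channel image)",
                         name))
  }
  invisible(img)
}

# Extract the green channel from an H x W x 3 array; pass matrices through.
as_green_channel <- function(img) {
  if (is.matrix(img)) return(img)
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] >= 2L) {
    return(img[, , 2L])
  }
  stop_invalid("frames must be numeric matrices or H x W x 3 RGB arrays")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Replicate-pad a matrix by `r` pixels on every side.
pad_replicate <- function(img, r) {
  h <- nrow(img)
  w <- ncol(img)
  img[c(rep(1L, r), seq_len(h), rep(h, r)),
      c(rep(1L, r), seq_len(w), rep(w, r)),
      drop = FALSE]
}

# Bilinear sampling at 0-based, pixel-centered coordinates (x along columns,
# y along rows). Points outside the image return `fill`.
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  inside <- x >= 0 & x <= (w - 1) & y >= 0 & y <= (h - 1)
  x0 <- pmin(pmax(floor(x), 0), w - 2)
  y0 <- pmin(pmax(floor(y), 0), h - 2)
  fx <- x - x0
  fy <- y - y0
  i00 <- y0 + 1 + x0 * h
  v <- (1 - fx) * (1 - fy) * img[i00] +
    fx * (1 - fy) * img[i00 + h] +
    (1 - fx) * fy * img[i00 + 1] +
    fx * fy * img[i00 + h + 1]
  v[!inside] <- fill
  v
}

# Sampled Gaussian and derivative-of-Gaussian kernels. Discrete responses
# are renormalized so that order 0 sums to 1, order 1 reproduces unit slope
# on a ramp, and order 2 reproduces the second derivative of x^2/2 exactly.
gaussian_kernel_1d <- function(sigma, order = 0, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0) return(g)
  if (order == 1) {
    g1 <- -x / sigma^2 * g
    g1 <- g1 - mean(g1)
    return(g1 / sum(-x * g1))
  }
  if (order == 2) {
    g2 <- (x^2 - sigma^2) / sigma^4 * g
    g2 <- g2 - mean(g2)
    return(g2 / sum(x^2 / 2 * g2))
  }
  stop_invalid("kernel `order` must be 0, 1 or 2")
}

# Separable convolution with replicate boundary; kx runs along columns (x),
# ky along rows (y).
conv_sep <- function(img, kx, ky) {
  EBImage::filter2(img, outer(ky, kx), boundary = "replicate")
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-stage seed fan-out from a single global seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}
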