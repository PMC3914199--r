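# Brute-force Tomasi-Manduchi bilateral filter: the double-loop oracle.
bilateral_oracle <- function(img, sigma_s, sigma_r, radius) {
  h <- nrow(img)
  w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      norm <- 0
      for (di in -radius:radius) {
        for (dj in -radius:radius) {
          ii <- min(max(i + di, 1), h) # replicate boundary
          jj <- min(max(j + dj, 1), w)
          ws <- exp(-(di^2 + dj^2) / (2 * sigma_s^2))
          if (ws < 1e-8) next
          wr <- exp(-(img[ii, jj] - img[i, j])^2 / (2 * sigma_r^2))
          acc <- acc + ws * wr * img[ii, jj]
          norm <- norm + ws * wr
        }
      }
      out[i, j] <- acc / norm
    }
  }
  out
}

test_that("bilateral filter leaves constant images unchanged", {
  img <- matrix(0.4, 20, 25)
  expect_equal(bilateral_filter(img), img)
})

test_that("bilateral filter matches the double-loop oracle on random images", {
  set.seed(314)
  for (rep in 1:4) {
    img <- matrix(runif(16 * 16), 16, 16)
    got <- bilateral_filter(img, sigma_spatial_px = 2, sigma_range = 0.15,
                            radius = 4)
    want <- bilateral_oracle(img, 2, 0.15, 4)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("bilateral filter preserves edges better than a plain Gaussian", {
  img <- cbind(matrix(0.2, 40, 20), matrix(0.8, 40, 20))
  img <- img + matrix(rnorm(40 * 40, 0, 0.01), 40, 40)
  bf <- bilateral_filter(img, sigma_spatial_px = 3, sigma_range = 0.1)
  g0 <- retinapulse:::gaussian_kernel_1d(3, 0)
  gf <- retinapulse:::conv_sep(img, g0, g0)
  # 10-90% transition width of the row-averaged edge profile
  trans_width <- function(m) {
    prof <- colMeans(m)
    lo <- min(prof) + 0.1 * diff(range(prof))
    hi <- min(prof) + 0.9 * diff(range(prof))
    xs <- seq_along(prof)
    f <- approxfun(xs, prof)
    g <- Vectorize(function(v) {
      uniroot(function(x) f(x) - v, c(10, 31))$root
    })
    diff(g(c(lo, hi)))
  }
  expect_lt(trans_width(bf), trans_width(gf))
  # output range stays within the input range
  expect_gte(min(bf), min(img))
  expect_lte(max(bf), max(img))
})

test_that("bilateral filter rejects non-positive sigmas", {
  img <- matrix(0.5, 8, 8)
  expect_error(bilateral_filter(img, sigma_spatial_px = 0),
               class = "rp_invalid_argument")
  expect_error(bilateral_filter(img, sigma_range = -1),
               class = "rp_invalid_argument")
})

test_that("Hessian of f(x,y) = x^2 gives Ixx = 2, Ixy = Iyy = 0", {
  n <- 48
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  hf <- hessian_field(X^2, sigma_px = 2)
  inner <- 17:32
  expect_lt(max(abs(hf$ixx[inner, inner] - 2)), 1e-3)
  expect_lt(max(abs(hf$ixy[inner, inner])), 1e-3)
  expect_lt(max(abs(hf$iyy[inner, inner])), 1e-3)
  expect_lt(max(abs(hf$lambda_large[inner, inner] - 2)), 1e-3)
  expect_lt(max(abs(hf$lambda_small[inner, inner])), 1e-3)
})

test_that("Hessian eigenvalues are equal at the center of a symmetric blob", {
  n <- 41
  c0 <- (n - 1) / 2
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  Y <- matrix(0:(n - 1), n, n)
  img <- exp(-((X - c0)^2 + (Y - c0)^2) / (2 * 5^2))
  hf <- hessian_field(img, sigma_px = 2)
  k <- c0 + 1
  expect_lt(abs(hf$lambda_large[k, k] - hf$lambda_small[k, k]), 1e-6)
})

test_that("on a dark vertical bar the large-eigenvalue eigenvector is horizontal", {
  n <- 60
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  img <- 0.8 - 0.4 * (abs(X - 30) <= 5)
  hf <- hessian_field(img, sigma_px = 2)
  rows <- 20:40
  ang_large <- atan2(hf$v_large_y[rows, 31], hf$v_large_x[rows, 31])
  ang_large <- abs(((ang_large * 180 / pi) + 90) %% 180 - 90) # fold to [0,90]
  expect_true(all(ang_large < 2))
  # small-eigenvalue eigenvector is vertical (along the bar)
  expect_true(all(abs(hf$v_small_x[rows, 31]) < 0.05))
  # per-pixel orthonormality
  dot <- hf$v_small_x * hf$v_large_x + hf$v_small_y * hf$v_large_y
  expect_lt(max(abs(dot)), 1e-9)
  expect_lt(max(abs(hf$v_small_x^2 + hf$v_small_y^2 - 1)), 1e-9)
  expect_error(hessian_field(img, sigma_px = 0),
               class = "rp_invalid_argument")
})

# build a hessian_field carrying prescribed unit eigenvectors
fake_field <- function(vsx, vsy, vlx, vly) {
  m <- function(v) matrix(v, 1, 1)
  structure(list(ixx = m(0), ixy = m(0), iyy = m(0),
                 lambda_small = m(0), lambda_large = m(1),
                 v_small_x = m(vsx), v_small_y = m(vsy),
                 v_large_x = m(vlx), v_large_y = m(vly), sigma_px = 2),
            class = "hessian_field")
}

test_that("eigenvector-sum orientation follows the sign canonicalization", {
  f1 <- fake_field(1, 0, 0, 1)
  expect_equal(as.numeric(orientation_map(f1, "eigvec_sum")), pi / 4)
  # (0,1) and (-1,0) canonicalize to (0,1) and (1,0)
  f2 <- fake_field(0, 1, -1, 0)
  expect_equal(as.numeric(orientation_map(f2, "eigvec_sum")), pi / 4)
})

test_that("eigenvector-sum orientation is equivariant under pair rotation", {
  # an orthonormal pair is invariant under quarter turns, and the sign
  # canonicalization folds the sum accordingly: rotating the pair by phi
  # rotates the summed orientation by phi modulo pi/2
  for (phi in seq(0.1, 3, by = 0.35)) {
    f0 <- fake_field(1, 0, 0, 1)
    fr <- fake_field(cos(phi), sin(phi),
                     -sin(phi), cos(phi))
    a0 <- as.numeric(orientation_map(f0, "eigvec_sum"))
    ar <- as.numeric(orientation_map(fr, "eigvec_sum"))
    d <- abs((ar - a0 - phi) %% (pi / 2))
    expect_lt(min(d, pi / 2 - d), 1e-9)
  }
})

test_that("orientation maps live in [0, pi) for both formulations", {
  set.seed(8)
  img <- matrix(runif(40 * 40), 40, 40)
  hf <- hessian_field(img, 2)
  for (m in c("principal", "eigvec_sum")) {
    om <- orientation_map(hf, m)
    expect_true(all(om >= 0 & om < pi))
  }
})

test_that("vesselness is zero for constant orientation and ridges at orientation steps", {
  om_const <- structure(matrix(0.7, 20, 20),
                        class = c("orientation_map", "matrix"))
  expect_true(all(vesselness_map(om_const) == 0))

  # two half-planes at 0 and pi/2: single response ridge at the boundary
  om <- structure(cbind(matrix(0, 20, 10), matrix(pi / 2, 20, 10)),
                  class = c("orientation_map", "matrix"))
  vm <- vesselness_map(om)
  expect_true(all(vm[, c(1:8, 13:20)] == 0))
  expect_true(all(vm[, 10:11] > 0))
  expect_true(all(vm >= 0))

  # wrap-around: 0.05 vs pi - 0.05 differ by 0.10 circularly, not pi - 0.10
  om2 <- structure(cbind(matrix(0.05, 20, 10), matrix(pi - 0.05, 20, 10)),
                   class = c("orientation_map", "matrix"))
  vm2 <- vesselness_map(om2)
  expect_lt(max(vm2), 0.10) # central difference halves the 0.10 step
  expect_equal(max(vm2), 0.05)
})

test_that("vesselness map rotates with the image", {
  ph <- line_phantom(noise = 0, seed = 3, shape = c(160, 160),
                     angle_slope = 0.3)
  img <- ph$sequence$frames[[1]]
  vm <- vesselness_map(orientation_map(hessian_field(img, 2)))
  # rotate image 90 deg counterclockwise in matrix terms
  img_r <- t(img)[ncol(img):1, ]
  vm_r <- vesselness_map(orientation_map(hessian_field(img_r, 2)))
  vm_expect <- t(unclass(vm))[ncol(vm):1, ]
  inner <- 20:140
  expect_lt(max(abs(vm_r[inner, inner] - vm_expect[inner, inner])), 1e-6)
})

test_that("response ridges localize the true vessel edges within 1 px", {
  # noise-free oblique vessel, width 12
  ph <- line_phantom(width = 12, noise = 0, seed = 1, shape = c(140, 220))
  img <- bilateral_filter(ph$sequence$frames[[1]])
  vm <- unclass(vesselness_map(orientation_map(hessian_field(img, 2))))
  cl <- ph$truth$centerlines[[1]]
  slope <- (cl[2, 2] - cl[1, 2]) / (cl[2, 1] - cl[1, 1])
  half_col <- 6 * sqrt(1 + slope^2) # vertical offset of edges at a column
  for (x in c(70, 110, 150)) {
    yc <- cl[1, 2] + slope * (x - cl[1, 1])
    col <- vm[, x + 1]
    top <- which.max(col[round(yc - half_col) + 1 + (-3:3)]) - 4 +
      round(yc - half_col)
    bot <- which.max(col[round(yc + half_col) + 1 + (-3:3)]) - 4 +
      round(yc + half_col)
    expect_lt(abs(top - (yc - half_col)), 1)
    expect_lt(abs(bot - (yc + half_col)), 1)
  }
})

test_that("vesselness maps round-trip through scaled 32-bit TIFF", {
  set.seed(4)
  m <- structure(matrix(runif(100) * 2, 10, 10),
                 class = c("vesselness_map", "matrix"))
  f <- withr::local_tempfile(fileext = ".tif")
  write_map(m, path_tiff = f)
  back <- read_map(f)
  expect_lt(max(abs(back - m)), 1e-6)
})
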