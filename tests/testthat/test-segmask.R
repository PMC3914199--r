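test_that("the orientation grid spans 0 to 170 degrees in 10-degree steps", {
  ang <- gabor_orientations(10)
  expect_length(ang, 18)
  expect_equal(ang, seq(0, 170, by = 10))
  expect_error(gabor_orientations(0), class = "rp_invalid_argument")
})

test_that("zero-mean Gabor kernels give no response on constant images", {
  img <- matrix(0.6, 40, 40)
  resp <- retinapulse:::gabor_max_response(img, scale = 2)
  expect_lt(max(abs(resp)), 1e-6)
})

test_that("max-modulus response is invariant across grid-aligned bar angles", {
  bar_image <- function(theta_deg, n = 81) {
    c0 <- (n - 1) / 2
    X <- matrix(0:(n - 1), n, n, byrow = TRUE) - c0
    Y <- matrix(0:(n - 1), n, n) - c0
    th <- theta_deg * pi / 180
    d <- abs(-sin(th) * X + cos(th) * Y)
    0.8 - 0.4 * pmax(pmin(3.5 - d, 1), 0) # soft-edged bar along theta
  }
  k <- 41 # center pixel
  r30 <- retinapulse:::gabor_max_response(bar_image(30), scale = 3)[k, k]
  r70 <- retinapulse:::gabor_max_response(bar_image(70), scale = 3)[k, k]
  expect_lt(abs(r30 - r70) / r30, 0.02)
})

test_that("feature stacks have one max-modulus channel per scale", {
  set.seed(1)
  img <- matrix(runif(30 * 30), 30, 30)
  fs <- gabor_feature_stack(img, scales = c(2, 3))
  expect_named(fs$features, c("intensity", "gabor_s2", "gabor_s3"))
  expect_length(fs$angles_deg, 18)
  expect_error(gabor_feature_stack(img, scales = numeric(0)),
               class = "rp_invalid_argument")
})

test_that("the Bayes classifier separates separable classes perfectly", {
  lab <- matrix(rep(c(0L, 1L), each = 50), 10, 10)
  feat <- list(f = matrix(as.numeric(lab) + rnorm(100, 0, 0.01), 10, 10))
  model <- train_pixel_classifier(feat, lab)
  pred <- matrix(classify_pixels(model, feat), 10, 10)
  expect_equal(pred, lab)
  expect_equal(unname(model$priors), c(0.5, 0.5))
})

test_that("identical feature distributions yield the prior (majority) class", {
  set.seed(5)
  feat <- list(f = matrix(rnorm(400), 20, 20))
  lab <- matrix(0L, 20, 20)
  lab[1:6, ] <- 1L # vessel prior 0.3 < background prior 0.7
  model <- train_pixel_classifier(feat, lab)
  model$vessel <- model$background # force identical class likelihoods
  pred <- classify_pixels(model, feat)
  expect_true(all(pred == 0L)) # priors favor background everywhere
})

test_that("Gaussian class parameters are recovered from labeled samples", {
  set.seed(11)
  n <- 10000
  x_v <- cbind(rnorm(n, 2, 1), rnorm(n, -1, 0.5))
  x_b <- cbind(rnorm(n, 0, 1), rnorm(n, 1, 0.5))
  X <- rbind(x_v, x_b)
  lab <- c(rep(1L, n), rep(0L, n))
  feat <- list(f1 = matrix(X[, 1], ncol = 1), f2 = matrix(X[, 2], ncol = 1))
  model <- train_pixel_classifier(feat, matrix(lab, ncol = 1),
                                  max_per_class = Inf)
  se1 <- 1 / sqrt(n)
  se2 <- 0.5 / sqrt(n)
  expect_lt(abs(model$vessel$means[1, 1] - 2), 3 * se1)
  expect_lt(abs(model$vessel$means[1, 2] - (-1)), 3 * se2)
  expect_lt(abs(model$background$means[1, 1] - 0), 3 * se1)
  expect_lt(abs(model$background$means[1, 2] - 1), 3 * se2)
})

test_that("single-class labels are rejected", {
  feat <- list(f = matrix(runif(64), 8, 8))
  expect_error(train_pixel_classifier(feat, matrix(1L, 8, 8)),
               class = "rp_invalid_argument")
})

test_that("classification equals the brute-force posterior rule, ties to background", {
  # symmetric 1-D model: vessel ~ N(2,1), background ~ N(0,1), priors equal
  model <- structure(
    list(priors = c(vessel = 0.5, background = 0.5),
         vessel = list(weights = 1, means = matrix(2, 1),
                       covs = list(matrix(1, 1))),
         background = list(weights = 1, means = matrix(0, 1),
                           covs = list(matrix(1, 1))),
         n_features = 1L, k = 1L),
    class = "pixel_classifier"
  )
  expect_equal(classify_pixels(model, matrix(0, 1)), 0L)   # background side
  expect_equal(classify_pixels(model, matrix(1, 1)), 0L)   # exact tie
  expect_equal(classify_pixels(model, matrix(1.01, 1)), 1L)

  # random features: label = argmax of prior-weighted likelihood, per pixel
  set.seed(7)
  x <- matrix(rnorm(500, 1, 2), ncol = 1)
  got <- classify_pixels(model, x)
  post_v <- 0.5 * stats::dnorm(x, 2, 1)
  post_b <- 0.5 * stats::dnorm(x, 0, 1)
  expect_equal(got, as.integer(post_v > post_b))

  expect_error(classify_pixels(model, matrix(rnorm(10), ncol = 2)),
               class = "rp_invalid_argument")
})

test_that("mask cleanup removes isolated pixels and dilates as specified", {
  m <- matrix(0L, 15, 15)
  m[8, 8] <- 1L # isolated speckle
  expect_true(all(clean_mask(m, n_dilations = 0) == 0))

  # 1-px vertical line widens to 1 + 2*5 = 11 px after 5 dilations
  ln <- matrix(0L, 25, 25)
  ln[, 13] <- 1L
  out <- clean_mask(ln, n_dilations = 5)
  expect_equal(sum(out[13, ]), 11)
  expect_equal(range(which(out[13, ] == 1)), c(8, 18))

  empty <- matrix(0L, 10, 10)
  expect_true(all(clean_mask(empty) == 0))
})

test_that("dilation stage is extensive and increasing", {
  set.seed(3)
  a <- matrix(as.integer(matrix(runif(400), 20, 20) < 0.3), 20, 20)
  a <- clean_mask(a, n_dilations = 0) # strip singletons first
  b <- a
  b[5:10, 5:10] <- 1L
  b <- clean_mask(b, n_dilations = 0)
  ca <- clean_mask(a, n_dilations = 2)
  cb <- clean_mask(b, n_dilations = 2)
  expect_true(all(ca >= a))        # extensive: input subset of output
  expect_true(all(cb >= ca))       # increasing: A subset B -> C(A) subset C(B)
})

test_that("masking zeroes the map outside the mask and keeps it inside", {
  set.seed(9)
  vmap <- structure(matrix(runif(100), 10, 10),
                    class = c("vesselness_map", "matrix"))
  ones <- matrix(1L, 10, 10)
  zeros <- matrix(0L, 10, 10)
  expect_equal(unclass(mask_vesselness(vmap, ones)), unclass(vmap))
  expect_true(all(mask_vesselness(vmap, zeros) == 0))
  mask <- matrix(rbinom(100, 1, 0.4), 10, 10)
  out <- mask_vesselness(vmap, mask)
  expect_true(all(out[mask == 0] == 0))
  expect_equal(out[mask == 1], unclass(vmap)[mask == 1])
  expect_error(mask_vesselness(vmap, matrix(1, 5, 5)),
               class = "rp_invalid_argument")
})

test_that("a classifier trained on one phantom segments another", {
  ph_a <- line_phantom(noise = 0.01, seed = 31, shape = c(120, 180))
  ph_b <- line_phantom(noise = 0.01, seed = 77, shape = c(120, 180))
  f_a <- gabor_feature_stack(bilateral_filter(ph_a$sequence$frames[[1]]))
  f_b <- gabor_feature_stack(bilateral_filter(ph_b$sequence$frames[[1]]))
  model <- train_pixel_classifier(f_a, ph_a$truth$vessel_mask)
  pred <- classify_pixels(model, f_b)
  truth <- ph_b$truth$vessel_mask
  sens <- sum(pred == 1 & truth == 1) / sum(truth == 1)
  spec <- sum(pred == 0 & truth == 0) / sum(truth == 0)
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})

test_that("classifier models survive a JSON round-trip", {
  set.seed(21)
  feat <- list(a = matrix(rnorm(400), 20, 20),
               b = matrix(rnorm(400, 1), 20, 20))
  lab <- matrix(as.integer(feat$a + feat$b > 1), 20, 20)
  model <- train_pixel_classifier(feat, lab)
  f <- withr::local_tempfile(fileext = ".json")
  write_classifier_json(model, f)
  back <- read_classifier_json(f)
  expect_identical(classify_pixels(back, feat), classify_pixels(model, feat))
})
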