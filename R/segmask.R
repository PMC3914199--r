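#' Orientation grid for Gabor filtering
#'
#' @param step_deg angular step in degrees (default 10, giving the 18
#'   orientations 0, 10, ..., 170).
#' @return Numeric vector of orientations in degrees, `[0, 180)`.
#' @export
gabor_orientations <- function(step_deg = 10) {
  check_number(step_deg, "step_deg", positive = TRUE)
  seq(0, 180 - step_deg, by = step_deg)
}

# Complex 2-D Gabor (Morlet) wavelet kernel at scale `scale` (px) and
# orientation `theta_deg`: an elongated Gaussian envelope (elongation
# `epsilon` across vs along) modulated by a complex exponential with
# frequency vector `k0` (in envelope units). DC-corrected so the response
# to a constant image is zero.
gabor_kernel <- function(scale, theta_deg, epsilon = 4, k0 = c(0, 3)) {
  sig_long <- scale * sqrt(epsilon)
  r <- ceiling(3.5 * sig_long)
  xs <- seq(-r, r)
  X <- matrix(xs, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  Y <- matrix(xs, 2 * r + 1, 2 * r + 1)
  th <- theta_deg * pi / 180
  # rotate into the wavelet frame
  u <- (cos(th) * X + sin(th) * Y) / scale
  v <- (-sin(th) * X + cos(th) * Y) / scale
  env <- exp(-(u^2 / epsilon + v^2) / 2)
  ker <- env * exp(1i * (k0[1] * u + k0[2] * v))
  ker <- ker / sum(Mod(ker))
  ker - mean(ker) # zero-mean (DC correction)
}

#' Gabor wavelet feature stack for pixel classification
#'
#' For each scale, the response is the maximum over all grid orientations of
#' the modulus of the complex Gabor transform; the stack is completed by the
#' normalized inverted intensity (vessels are dark, so inversion makes them
#' the high-valued class). Every channel is standardized to zero mean and
#' unit variance within the image, as is usual for per-image supervised
#' vessel segmentation.
#'
#' @param img single-channel matrix in `[0, 1]`.
#' @param scales Gabor scales in px (default `c(2, 3, 4)`).
#' @param step_deg orientation step in degrees (default 10).
#' @param epsilon filter elongation (default 4).
#' @param k0 frequency vector of the complex exponential (default `c(0, 3)`).
#' @return A `gabor_feature_stack`: list with `features` (list of matrices:
#'   `intensity` then one `gabor_s<scale>` per scale), `scales`, `angles_deg`.
#' @export
gabor_feature_stack <- function(img, scales = c(2, 3, 4), step_deg = 10,
                                epsilon = 4, k0 = c(0, 3)) {
  check_matrix_image(img)
  if (length(scales) < 1L) stop_invalid("`scales` must be non-empty")
  angles <- gabor_orientations(step_deg)
  standardize <- function(m) {
    s <- sd(m)
    if (s < 1e-12) matrix(0, nrow(m), ncol(m)) else (m - mean(m)) / s
  }
  feats <- list(intensity = standardize(1 - img))
  for (a in scales) {
    resp <- NULL
    for (th in angles) {
      ker <- gabor_kernel(a, th, epsilon = epsilon, k0 = k0)
      re <- safe_filter2(img, Re(ker))
      im <- safe_filter2(img, Im(ker))
      m <- sqrt(re^2 + im^2)
      resp <- if (is.null(resp)) m else pmax(resp, m)
    }
    feats[[sprintf("gabor_s%g", a)]] <- standardize(resp)
  }
  structure(list(features = feats, scales = scales, angles_deg = angles),
            class = "gabor_feature_stack")
}

# Raw (unstandardized) max-modulus Gabor response at one scale; used by
# tests probing orientation invariance.
gabor_max_response <- function(img, scale, step_deg = 10, epsilon = 4,
                               k0 = c(0, 3)) {
  resp <- NULL
  for (th in gabor_orientations(step_deg)) {
    ker <- gabor_kernel(scale, th, epsilon = epsilon, k0 = k0)
    re <- safe_filter2(img, Re(ker))
    im <- safe_filter2(img, Im(ker))
    m <- sqrt(re^2 + im^2)
    resp <- if (is.null(resp)) m else pmax(resp, m)
  }
  resp
}

# filter2 requires the kernel to fit inside the image; replicate-pad small
# images before filtering and crop back.
safe_filter2 <- function(img, ker) {
  kr <- (dim(ker) - 1L) %/% 2L
  need <- pmax(dim(ker) - dim(img), 0L)
  if (all(need == 0L)) {
    return(EBImage::filter2(img, ker, boundary = "replicate"))
  }
  r <- max(ceiling(need / 2)) + 1L
  padded <- pad_replicate(img, r)
  out <- EBImage::filter2(padded, ker, boundary = "replicate")
  out[(r + 1):(r + nrow(img)), (r + 1):(r + ncol(img))]
}

stack_to_matrix <- function(features) {
  if (inherits(features, "gabor_feature_stack")) {
    do.call(cbind, lapply(features$features, as.vector))
  } else if (is.list(features)) {
    do.call(cbind, lapply(features, as.vector))
  } else if (is.matrix(features)) {
    features
  } else {
    stop_invalid("`features` must be a gabor_feature_stack, list or matrix")
  }
}

log_mvn_density <- function(x, mean, cov) {
  d <- length(mean)
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) {
    cov <- cov + diag(1e-6, d)
    ch <- chol(cov)
  }
  logdet <- 2 * sum(log(diag(ch)))
  centered <- sweep(x, 2, mean)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + logdet + colSums(z^2))
}

# log density of a Gaussian mixture (weights w, list of means/covs)
log_gmm_density <- function(x, comp) {
  k <- length(comp$weights)
  ll <- matrix(NA_real_, nrow(x), k)
  for (j in seq_len(k)) {
    ll[, j] <- log(comp$weights[j]) +
      log_mvn_density(x, comp$means[j, ], comp$covs[[j]])
  }
  m <- apply(ll, 1, max)
  m + log(rowSums(exp(ll - m)))
}

fit_gaussian <- function(x) {
  mu <- colMeans(x)
  cv <- stats::cov(x)
  if (length(mu) == 1L) cv <- matrix(cv, 1, 1)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    warn("near-singular covariance; adding 1e-6 ridge")
    cv <- cv + diag(1e-6, length(mu))
  }
  list(mean = mu, cov = cv)
}

fit_gmm <- function(x, k, max_iter = 50, tol = 1e-8) {
  if (k == 1L) {
    g <- fit_gaussian(x)
    return(list(weights = 1, means = matrix(g$mean, 1), covs = list(g$cov)))
  }
  km <- kmeans(x, centers = k, nstart = 3, iter.max = 50)
  weights <- as.numeric(table(factor(km$cluster, levels = seq_len(k))))
  weights <- weights / sum(weights)
  means <- km$centers
  covs <- lapply(seq_len(k), function(j) {
    xi <- x[km$cluster == j, , drop = FALSE]
    if (nrow(xi) < 2L) diag(1e-3, ncol(x)) else fit_gaussian(xi)$cov
  })
  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    lw <- matrix(NA_real_, nrow(x), k)
    for (j in seq_len(k)) {
      lw[, j] <- log(weights[j]) + log_mvn_density(x, means[j, ], covs[[j]])
    }
    m <- apply(lw, 1, max)
    ll <- sum(m + log(rowSums(exp(lw - m))))
    resp <- exp(lw - m - log(rowSums(exp(lw - m))))
    nk <- colSums(resp)
    weights <- nk / nrow(x)
    for (j in seq_len(k)) {
      means[j, ] <- colSums(resp[, j] * x) / nk[j]
      centered <- sweep(x, 2, means[j, ])
      cv <- crossprod(centered * sqrt(resp[, j])) / nk[j]
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-8) cv <- cv + diag(1e-6, ncol(x))
      covs[[j]] <- cv
    }
    if (abs(ll - prev_ll) < tol * (1 + abs(ll))) break
    prev_ll <- ll
  }
  list(weights = weights, means = means, covs = covs)
}

#' Train the Bayes pixel classifier on labeled features
#'
#' Fits a Gaussian (mixture) to the feature vectors of each class; class
#' priors are the labeled pixel fractions. With `k = 1` (default) the fit is
#' closed form and fully deterministic; for `k > 1` the mixture is fitted by
#' EM from a seeded k-means initialization. Near-singular covariances get a
#' `1e-6` identity ridge (with a warning).
#'
#' @param features a [gabor_feature_stack()] (or list of feature matrices).
#' @param labels binary matrix, 1 = vessel, 0 = background, same shape as
#'   the feature images.
#' @param k Gaussian components per class (default 1).
#' @param max_per_class optional cap on training pixels per class
#'   (subsampled deterministically under `seed`); `Inf` uses all.
#' @param seed RNG seed for subsampling / k-means.
#' @return A `pixel_classifier` with `priors` and per-class mixtures.
#' @export
train_pixel_classifier <- function(features, labels, k = 1,
                                   max_per_class = 50000L, seed = 1L) {
  X <- stack_to_matrix(features)
  lab <- as.integer(as.vector(labels))
  if (length(lab) != nrow(X)) {
    stop_invalid("`labels` must match the feature image shape")
  }
  if (!all(lab %in% c(0L, 1L))) stop_invalid("`labels` must be binary 0/1")
  if (length(unique(lab)) < 2L) {
    stop_invalid("both classes must be present in `labels`")
  }
  check_number(k, "k", positive = TRUE, integer = TRUE)
  priors <- c(vessel = mean(lab == 1L), background = mean(lab == 0L))
  set.seed(seed)
  take <- function(idx) {
    if (length(idx) > max_per_class) sort(sample(idx, max_per_class)) else idx
  }
  iv <- take(which(lab == 1L))
  ib <- take(which(lab == 0L))
  structure(
    list(priors = priors,
         vessel = fit_gmm(X[iv, , drop = FALSE], k),
         background = fit_gmm(X[ib, , drop = FALSE], k),
         n_features = ncol(X), k = as.integer(k)),
    class = "pixel_classifier"
  )
}

#' Classify pixels with the Bayes decision rule
#'
#' A pixel is labeled vessel iff its prior-weighted class likelihood for
#' vessel strictly exceeds that for background; exact ties go to background
#' (a conservative mask avoids spurious vesselness responses).
#'
#' @param model a [train_pixel_classifier()] fit.
#' @param features a [gabor_feature_stack()] (or feature matrix).
#' @return A binary `vessel_mask` matrix (1 = vessel) with the shape of the
#'   feature images (or a vector for matrix input).
#' @export
classify_pixels <- function(model, features) {
  if (!inherits(model, "pixel_classifier")) {
    stop_invalid("`model` must be a pixel_classifier")
  }
  X <- stack_to_matrix(features)
  if (ncol(X) != model$n_features) {
    stop_invalid(sprintf("feature dimensionality %d does not match model (%d)",
                         ncol(X), model$n_features))
  }
  lv <- log(model$priors[["vessel"]]) + log_gmm_density(X, model$vessel)
  lb <- log(model$priors[["background"]]) + log_gmm_density(X, model$background)
  out <- as.integer(lv > lb)
  if (inherits(features, "gabor_feature_stack")) {
    ref <- features$features[[1]]
    out <- matrix(out, nrow(ref), ncol(ref))
  }
  out
}

#' Morphological cleanup of the vessel mask
#'
#' First, every foreground pixel whose 8-neighborhood is entirely background
#' is removed (an edge always has adjoining transition points, so isolated
#' 1's are speckle). Then the mask is dilated `n_dilations` times with the
#' 3x3 square structuring element to widen the vessel cover. Optionally a
#' full 3x3 binary opening replaces the isolated-pixel removal.
#'
#' @param mask binary matrix.
#' @param n_dilations number of consecutive 3x3 dilations (default 5).
#' @param opening if `TRUE`, apply a general 3x3 opening instead of
#'   isolated-pixel removal.
#' @return Cleaned binary matrix.
#' @export
clean_mask <- function(mask, n_dilations = 5, opening = FALSE) {
  if (!all(mask %in% c(0, 1))) stop_invalid("`mask` must be binary 0/1")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  se <- matrix(1, 3, 3)
  if (opening) {
    m <- EBImage::opening(m, se)
  } else {
    p <- pad_replicate(m, 1)
    h <- nrow(m)
    w <- ncol(m)
    neighbors <- p[1:h, 1:w] + p[1:h, 2:(w + 1)] + p[1:h, 3:(w + 2)] +
      p[2:(h + 1), 1:w] + p[2:(h + 1), 3:(w + 2)] +
      p[3:(h + 2), 1:w] + p[3:(h + 2), 2:(w + 1)] + p[3:(h + 2), 3:(w + 2)]
    m[m == 1 & neighbors == 0] <- 0
  }
  for (i in seq_len(n_dilations)) m <- EBImage::dilate(m, se)
  matrix(as.integer(m > 0), nrow(mask), ncol(mask))
}

#' Apply the binary mask to a vesselness map
#'
#' Elementwise product: responses are kept inside the mask and zeroed
#' outside, removing the background noise that the orientation gradient
#' introduces.
#'
#' @param vmap a [vesselness_map()] (or numeric matrix).
#' @param mask binary matrix of the same shape.
#' @return Masked `vesselness_map`.
#' @export
mask_vesselness <- function(vmap, mask) {
  if (!all(dim(vmap) == dim(mask))) {
    stop_invalid("`vmap` and `mask` must have the same shape")
  }
  structure(unclass(vmap) * as.numeric(mask),
            dim = dim(vmap), class = c("vesselness_map", "matrix"))
}

#' Build a vessel mask for a frame
#'
#' Convenience chain: Gabor feature stack, Bayes classification with a
#' trained model, morphological cleanup.
#'
#' @param img single-channel frame.
#' @param model a [train_pixel_classifier()] fit.
#' @param scales,step_deg Gabor parameters (must match training).
#' @param n_dilations see [clean_mask()].
#' @return Binary mask matrix.
#' @export
build_vessel_mask <- function(img, model, scales = c(2, 3, 4), step_deg = 10,
                              n_dilations = 5) {
  feats <- gabor_feature_stack(img, scales = scales, step_deg = step_deg)
  clean_mask(classify_pixels(model, feats), n_dilations = n_dilations)
}

#' Serialize / restore a pixel classifier as JSON
#' @param model a `pixel_classifier`.
#' @param path JSON path.
#' @return `write_classifier_json` returns `path` invisibly;
#'   `read_classifier_json` returns the `pixel_classifier`.
#' @export
write_classifier_json <- function(model, path) {
  x <- list(priors = as.list(model$priors),
            n_features = model$n_features, k = model$k)
  for (cls in c("vessel", "background")) {
    comp <- model[[cls]]
    x[[cls]] <- list(weights = comp$weights, means = comp$means,
                     covs = comp$covs)
  }
  jsonlite::write_json(x, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  restore <- function(comp) {
    list(weights = as.numeric(comp$weights),
         means = matrix(as.numeric(comp$means), nrow = length(comp$weights)),
         covs = if (is.list(comp$covs)) {
           lapply(comp$covs, function(cv) {
             matrix(as.numeric(unlist(cv)), nrow = sqrt(length(unlist(cv))))
           })
         } else {
           list(matrix(as.numeric(comp$covs), nrow = sqrt(length(unlist(comp$covs)))))
         })
  }
  structure(
    list(priors = unlist(x$priors), vessel = restore(x$vessel),
         background = restore(x$background),
         n_features = x$n_features, k = x$k),
    class = "pixel_classifier"
  )
}
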