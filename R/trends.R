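#' Dynamic time warping of one diameter trend onto a reference
#'
#' Classic DTW with squared-difference local cost, boundary conditions
#' `(1,1) -> (n,n)` and step set `{(1,0), (0,1), (1,1)}`. Used to remove the
#' location-dependent phase lag between measuring sites before trends are
#' averaged. Aligned values map `trend` onto the reference indices, taking
#' the mean over many-to-one matches.
#'
#' @param trend,reference numeric vectors of equal length (one diameter per
#'   cardiac point).
#' @return List with `path` (m x 2 matrix of (trend index, reference
#'   index)), `cost` (total cumulative cost), `aligned` (trend values on
#'   reference indices).
#' @export
dtw_align <- function(trend, reference) {
  if (length(trend) != length(reference)) {
    stop_invalid("`trend` and `reference` must have the same length")
  }
  n <- length(trend)
  m <- length(reference)
  local <- outer(trend, reference, function(a, b) (a - b)^2)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- local[i, j] +
        min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  # backtrack, preferring the diagonal on ties
  i <- n
  j <- m
  path <- list(c(i, j))
  while (i > 1 || j > 1) {
    choices <- c(diag = D[i, j], up = D[i, j + 1], left = D[i + 1, j])
    if (i == 1) choices[c("diag", "up")] <- Inf
    if (j == 1) choices[c("diag", "left")] <- Inf
    pick <- names(choices)[which.min(choices)]
    if (pick == "diag") {
      i <- i - 1
      j <- j - 1
    } else if (pick == "up") {
      i <- i - 1
    } else {
      j <- j - 1
    }
    path[[length(path) + 1]] <- c(i, j)
  }
  path <- do.call(rbind, rev(path))
  colnames(path) <- c("trend", "reference")
  aligned <- vapply(seq_len(m), function(jj) {
    mean(trend[path[path[, 2] == jj, 1]])
  }, numeric(1))
  list(path = path, cost = D[n + 1, m + 1], aligned = aligned)
}

dtw_cost <- function(a, b) dtw_align(a, b)$cost

# Medoid trend of a class: smallest mean DTW cost to all others.
dtw_medoid <- function(mat) {
  n <- nrow(mat)
  if (n == 1L) return(1L)
  costs <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      costs[i, j] <- costs[j, i] <- dtw_cost(mat[i, ], mat[j, ])
    }
  }
  which.min(rowMeans(costs))
}

#' Average per-vessel diameter trends at each cardiac point
#'
#' Trends of one vessel class are DTW-aligned to a reference trend (the
#' class medoid: the trend with the smallest mean DTW cost to all others),
#' then averaged elementwise; the SD at each cardiac point is computed over
#' the aligned trends.
#'
#' @param trends tibble with columns `subject`, `vessel_id`, `vessel_class`,
#'   `phase`, `diameter_um` (one row per vessel per cardiac point); a single
#'   vessel class per call.
#' @param use_dtw disable to average raw (unaligned) trends.
#' @return List with `summary` (tibble `phase`, `mean_um`, `sd_um`),
#'   `aligned` (vessel x phase matrix), `reference_id` (medoid row).
#' @export
average_trends <- function(trends, use_dtw = TRUE) {
  need <- c("vessel_id", "vessel_class", "phase", "diameter_um")
  if (!all(need %in% names(trends))) {
    stop_invalid(sprintf("`trends` must have columns %s",
                         paste(need, collapse = ", ")))
  }
  if (nrow(trends) == 0L) stop_invalid("`trends` is empty")
  if (length(unique(trends$vessel_class)) != 1L) {
    stop_invalid("`trends` must contain a single vessel class; split first")
  }
  wide <- tidyr::pivot_wider(
    dplyr::arrange(trends, .data$vessel_id, .data$phase),
    id_cols = "vessel_id", names_from = "phase", values_from = "diameter_um"
  )
  mat <- as.matrix(wide[, -1])
  if (anyNA(mat)) stop_invalid("every vessel needs a diameter at every phase")
  if (use_dtw && nrow(mat) > 1L) {
    ref_row <- dtw_medoid(mat)
    aligned <- t(apply(mat, 1, function(v) {
      dtw_align(v, mat[ref_row, ])$aligned
    }))
  } else {
    ref_row <- 1L
    aligned <- mat
  }
  list(
    summary = tibble::tibble(
      phase = seq_len(ncol(mat)),
      mean_um = unname(colMeans(aligned)),
      sd_um = if (nrow(aligned) == 1L) rep(0, ncol(mat))
              else unname(apply(aligned, 2, sd))
    ),
    aligned = aligned,
    reference_id = wide$vessel_id[ref_row]
  )
}

#' One-way repeated-measures ANOVA across cardiac points
#'
#' Within-subject partition of the sums of squares: total variation splits
#' into between-subject, between-condition (cardiac point), and residual
#' components; `F = MS_condition / MS_error` with `(k - 1, (k - 1)(n - 1))`
#' degrees of freedom. Optional Greenhouse-Geisser sphericity correction
#' scales both df by the epsilon estimated from the condition covariance.
#'
#' @param mat n_subjects x k_conditions numeric matrix, no missing cells.
#' @param gg_correction apply Greenhouse-Geisser correction (default off).
#' @return An `rm_anova` object: `F`, `df_condition`, `df_error`, `p_value`,
#'   the sums of squares, and `epsilon` when corrected.
#' @export
rm_anova <- function(mat, gg_correction = FALSE) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop_invalid("`mat` must have no missing cells")
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2L || k < 2L) {
    stop_invalid("need at least 2 subjects and 2 conditions")
  }
  grand <- mean(mat)
  ss_total <- sum((mat - grand)^2)
  ss_subject <- k * sum((rowMeans(mat) - grand)^2)
  ss_condition <- n * sum((colMeans(mat) - grand)^2)
  ss_error <- ss_total - ss_subject - ss_condition
  df_c <- k - 1
  df_e <- (k - 1) * (n - 1)
  ms_c <- ss_condition / df_c
  ms_e <- ss_error / df_e
  eps <- NA_real_
  if (ms_e <= 0) {
    # degenerate: no residual variation; all-constant rows give F = 0
    Fstat <- if (ss_condition <= 1e-12) 0 else Inf
    p <- if (ss_condition <= 1e-12) 1 else 0
  } else {
    Fstat <- ms_c / ms_e
    if (gg_correction) {
      S <- stats::cov(mat)
      dbar <- mean(diag(S))
      sbar <- mean(S)
      rowm <- rowMeans(S)
      eps <- (k^2 * (dbar - sbar)^2) /
        ((k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * sbar^2))
      eps <- min(max(eps, 1 / (k - 1)), 1)
      p <- pf(Fstat, df_c * eps, df_e * eps, lower.tail = FALSE)
    } else {
      p <- pf(Fstat, df_c, df_e, lower.tail = FALSE)
    }
  }
  structure(
    list(F = Fstat, df_condition = df_c, df_error = df_e, p_value = p,
         ss_condition = ss_condition, ss_subject = ss_subject,
         ss_error = ss_error, n_subjects = n, n_conditions = k,
         gg_correction = gg_correction, epsilon = eps),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%g, %g) = %.4g, p = %.4g\n",
              x$df_condition, x$df_error, x$F, x$p_value))
  invisible(x)
}

#' @rdname rm_anova
#' @param x an `rm_anova` object.
#' @param ... unused.
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(
    term = c("condition", "subject", "error"),
    df = c(x$df_condition, x$n_subjects - 1, x$df_error),
    sumsq = c(x$ss_condition, x$ss_subject, x$ss_error),
    meansq = c(x$ss_condition / x$df_condition,
               x$ss_subject / (x$n_subjects - 1),
               x$ss_error / x$df_error),
    statistic = c(x$F, NA, NA),
    p.value = c(x$p_value, NA, NA)
  )
}

#' @rdname rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$F, p.value = x$p_value,
                 df = x$df_condition, df.residual = x$df_error,
                 n_subjects = x$n_subjects, n_conditions = x$n_conditions)
}

#' Post hoc paired comparisons against cardiac point 1
#'
#' Paired t-tests of every cardiac point against point 1, with Bonferroni
#' correction over the `k - 1` comparisons.
#'
#' @param mat n_subjects x k_conditions matrix.
#' @return Tibble: `phase`, `mean_diff_um`, `statistic`, `p.value`,
#'   `p.adjusted`.
#' @export
posthoc_vs_first <- function(mat) {
  mat <- as.matrix(mat)
  k <- ncol(mat)
  if (k < 2L) stop_invalid("need at least 2 conditions")
  rows <- lapply(2:k, function(j) {
    d <- mat[, j] - mat[, 1]
    tt <- stats::t.test(d)
    tibble::tibble(phase = j, mean_diff_um = mean(d),
                   statistic = unname(tt$statistic), p.value = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p.adjusted <- p.adjust(out$p.value, method = "bonferroni")
  out
}

#' Cardiac-cycle trend summary
#'
#' From the 8 per-point mean diameters: the variation of each point from
#' point 1 (`|mean_i - mean_1|`, reported for points 2..k), the maximum
#' minus minimum over the cycle, and the 1-based peak point (first index on
#' ties). When a per-subject matrix is supplied, the overall p-value for
#' the variations comes from [rm_anova()].
#'
#' @param means per-point mean diameters (um), length = number of cardiac
#'   points.
#' @param sds optional per-point SDs (um).
#' @param subject_matrix optional n_subjects x k matrix for the
#'   repeated-measures test.
#' @param n_phases expected number of cardiac points (default 8).
#' @return A `trend_summary`: list with `means`, `sds`, `variations`
#'   (named, points 2..k), `max_min`, `peak_point`, `p_value`.
#' @export
trend_summary <- function(means, sds = NULL, subject_matrix = NULL,
                          n_phases = 8) {
  if (length(means) != n_phases) {
    stop_invalid(sprintf("`means` must have %d entries (one per cardiac point)",
                         n_phases))
  }
  variations <- abs(means[-1] - means[1])
  names(variations) <- paste0("point_", 2:n_phases)
  p <- NA_real_
  if (!is.null(subject_matrix)) p <- rm_anova(subject_matrix)$p_value
  structure(
    list(means = means, sds = sds, variations = variations,
         max_min = max(means) - min(means),
         peak_point = which.max(means)[1],
         p_value = p),
    class = "trend_summary"
  )
}

#' @export
print.trend_summary <- function(x, ...) {
  cat(sprintf("Trend over %d cardiac points: max-min %.1f um, peak at point %d",
              length(x$means), round_half_up(x$max_min, 1), x$peak_point))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.3g", x$p_value))
  cat("\n")
  invisible(x)
}

#' @rdname trend_summary
#' @param x a `trend_summary`.
#' @param ... unused.
#' @export
tidy.trend_summary <- function(x, ...) {
  k <- length(x$means)
  tibble::tibble(
    phase = seq_len(k),
    mean_um = x$means,
    sd_um = if (is.null(x$sds)) NA_real_ else x$sds,
    variation_um = c(NA, unname(x$variations))
  )
}

#' @rdname trend_summary
#' @export
glance.trend_summary <- function(x, ...) {
  tibble::tibble(max_min_um = x$max_min, peak_point = x$peak_point,
                 p.value = x$p_value)
}

#' Summarize a grader count table
#'
#' Averages the per-subject, per-grader pulsatile-feature counts (and the
#' ten-point quality score) over subjects and graders, for each feature and
#' visualization method. Values are reported to 1 decimal place
#' (round-half-up); the quality score additionally to the nearest integer
#' for headline comparisons.
#'
#' @param table long tibble with columns `subject`, `feature`, `method`,
#'   `grader`, `value` -- complete (no missing cells).
#' @return Tibble: `feature`, `method`, `mean` (1 dp), `mean_int` (nearest
#'   integer, populated for the quality feature).
#' @export
grader_table_summary <- function(table) {
  need <- c("subject", "feature", "method", "grader", "value")
  if (!all(need %in% names(table))) {
    stop_invalid(sprintf("`table` must have columns %s",
                         paste(need, collapse = ", ")))
  }
  if (anyNA(table$value)) stop_invalid("`table` has missing cells")
  counts <- dplyr::count(table, .data$feature, .data$method)
  if (length(unique(counts$n)) != 1L) {
    stop_invalid("`table` is incomplete: unequal cell counts per feature/method")
  }
  out <- dplyr::summarise(
    dplyr::group_by(table, .data$feature, .data$method),
    mean_raw = mean(.data$value), .groups = "drop"
  )
  out$mean <- round_half_up(out$mean_raw, 1)
  out$mean_int <- round_half_up(out$mean_raw, 0)
  dplyr::select(out, "feature", "method", "mean", "mean_int")
}

#' Bundled summary tables from a twelve-subject gated fundus study
#'
#' Worked-example inputs distributed with the package: per-cardiac-point
#' mean (SD) calibers of individual arterioles and venules averaged over 12
#' subjects, measured either from single frames (`"unaided"`) or after
#' viewing the pulsation playback (`"visualized"`); and the per-subject
#' grader counts of pulsatile features (plus ten-point quality scores) under
#' the proposed vesselness playback versus a principal-component baseline.
#'
#' @param which `"unaided"`, `"visualized"`, or `"grader_counts"`.
#' @return A tibble.
#' @export
example_table <- function(which = c("unaided", "visualized",
                                    "grader_counts")) {
  which <- match.arg(which)
  f <- switch(which,
              unaided = "caliber_means_unaided.csv",
              visualized = "caliber_means_visualized.csv",
              grader_counts = "grader_counts.csv")
  path <- system.file("extdata", f, package = "retinapulse")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Read / write diameter trend tables as CSV
#' @param trends tibble (`subject`, `vessel_id`, `vessel_class`, `phase`,
#'   `diameter_um`).
#' @param path CSV path.
#' @return `write_trends_csv` returns `path` invisibly; `read_trends_csv`
#'   the tibble.
#' @export
write_trends_csv <- function(trends, path) {
  write.csv(trends, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trends_csv
#' @export
read_trends_csv <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
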