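#' @title Supporting statistics
#' @description
#' Pairwise Mann--Whitney U matrices for comparing replicate sampling points
#' and roughness traces, Pearson correlation between substrate-scale and
#' projection-scale coverage, five-number summaries backing box-whisker
#' displays, and ISO 4287-style roughness parameters of stylus profiles.
#' @name arch-stats
NULL

#' Pairwise Mann--Whitney U test matrix
#'
#' Two-sided Mann--Whitney (Wilcoxon rank-sum) tests for every pair of
#' groups, testing equality of medians. The exact null distribution is used
#' when both samples have at most 8 observations and no ties are present;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param groups named list of numeric samples (>= 2 groups, each non-empty).
#' @param alpha significance level for the decision matrix; default 0.05.
#' @return A list of class `"pairwise_test_matrix"` with the symmetric
#'   `p_value` matrix (diagonal `NA`), the logical `reject` matrix
#'   (`p < alpha`), `alpha` and the group names.
#' @export
mann_whitney_matrix <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 1L))
    stop("every group needs at least one observation")
  k <- length(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- groups[[i]]; y <- groups[[j]]
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- length(x) <= 8L && length(y) <= 8L && !ties
    pv <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value)
    p[i, j] <- p[j, i] <- pv
  }
  structure(list(p_value = p, reject = p < alpha, alpha = alpha,
                 groups = names(groups)),
            class = "pairwise_test_matrix")
}

#' @export
print.pairwise_test_matrix <- function(x, ...) {
  cat(sprintf("Pairwise Mann-Whitney U tests (alpha = %.3f)\n", x$alpha))
  print(round(x$p_value, 4))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with explicit validation of the contract the
#' pipeline relies on (equal lengths of at least 3, nonzero variance in both
#' series).
#'
#' @param x,y numeric series of equal length >= 3.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("series contain missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y, method = "pearson")
}

#' Five-number summary for box-whisker display
#'
#' Minimum, lower quartile, median, upper quartile and maximum; quartiles by
#' linear interpolation of the empirical CDF (the inclusive method,
#' `quantile` type 7), whiskers spanning the full min--max range.
#'
#' @param data numeric sample (n >= 1).
#' @return Named numeric vector `(min, q1, median, q3, max)`.
#' @export
five_number_summary <- function(data) {
  if (!length(data)) stop("empty sample")
  if (anyNA(data)) stop("sample contains missing values")
  q <- stats::quantile(data, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Roughness parameters of a height profile
#'
#' Computes, after subtracting the profile mean: the average roughness
#' `Ra = mean(|z|)`, root-mean-square roughness `Rq = sqrt(mean(z^2))`,
#' total roughness `Rt = max(z) - min(z)`, and mean roughness depth `Rz`,
#' the mean over `n_segments` equal contiguous segments of the segment
#' peak-to-valley height. Parameters are computed on the raw mean-centered
#' profile with no filtering; always `Ra <= Rq <= Rt` and `Rz <= Rt`.
#'
#' @param profile numeric height series (n >= 2), e.g. from
#'   [generate_roughness_profile()].
#' @param n_segments number of sampling lengths for Rz; default 5. When the
#'   profile is shorter than `n_segments`, Rz falls back to fewer segments
#'   with a warning.
#' @return A list of class `"roughness_summary"` with `Ra`, `Rq`, `Rz`,
#'   `Rt` and `n_points`.
#' @export
roughness_parameters <- function(profile, n_segments = 5L) {
  n <- length(profile)
  if (n < 2L) stop("a profile needs at least 2 points")
  if (anyNA(profile)) stop("profile contains missing values")
  z <- profile - mean(profile)
  n_seg <- as.integer(n_segments)
  if (n < n_seg) {
    warning("profile shorter than n_segments; Rz computed on ", n, " segment(s)")
    n_seg <- n
  }
  seg <- cut(seq_len(n), breaks = n_seg, labels = FALSE)
  rz <- mean(tapply(z, seg, function(s) max(s) - min(s)))
  structure(list(Ra = mean(abs(z)), Rq = sqrt(mean(z^2)),
                 Rz = rz, Rt = max(z) - min(z), n_points = n),
            class = "roughness_summary")
}

#' @export
print.roughness_summary <- function(x, ...) {
  cat(sprintf("Roughness (n = %d): Ra = %.4f, Rq = %.4f, Rz = %.4f, Rt = %.4f\n",
              x$n_points, x$Ra, x$Rq, x$Rz, x$Rt))
  invisible(x)
}
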