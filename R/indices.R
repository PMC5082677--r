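#' @title Dimensionless architecture quantities and the colonization index
#' @description
#' The quantitative core of the pipeline. Each slice of a strain's Z-stack is
#' summarized by three dimensionless quantities in \[0, 1\]: the substratum
#' coverage (microbial area over slice area), the linear-measure ratio (the
#' pattern's area/perimeter over the characteristic linear measure of the
#' slice, sqrt(a)/4), and the normalized box-counting fractal dimension
#' (D_B / 2). Per-slice series are collapsed with three aggregation operators
#' (maximum, arithmetic mean, Gaussian-weighted mean), rescaled across strains
#' to \[0, 1\], and averaged into a colonization index I_C per operator that
#' classifies a strain as a porous (< 0.5), intermediate (0.5--0.7) or compact
#' (>= 0.7) colonizer.
#' @name indices
NULL

#' Substratum coverage fraction
#'
#' The fraction of available area covered by microbial biomass: `A / a`,
#' where `A` is the microbial area and `a` the slice (or whole-substrate)
#' area, in the same units.
#'
#' @param A microbial area, `0 <= A <= a`.
#' @param a slice or substrate area, positive.
#' @return Coverage fraction in \[0, 1\].
#' @export
coverage_fraction <- function(A, a) {
  if (any(!is.finite(A)) || any(!is.finite(a)) || any(a <= 0))
    stop("slice area must be positive and finite")
  if (any(A < 0)) stop("area must be non-negative")
  if (any(A > a))
    stop("microbial area exceeds slice area; check that both use the same units")
  A / a
}

#' Linear-measure ratio of a microbial pattern
#'
#' Ratio between the characteristic linear measure of the pattern, `A / P`,
#' and that of the slice, `sqrt(a) / 4` (the area-to-perimeter ratio of a
#' square of area `a`), i.e. `4 A / (P sqrt(a))`. A fully covering compact
#' mat gives values near 1, a reticulate filament network values near 0.
#' By convention the ratio is 0 for an empty pattern, and the result is
#' clamped to \[0, 1\] with the raw value kept in attribute `"raw"` (under
#' the pixel-center contour convention, blocky near-full patterns can
#' slightly exceed 1).
#'
#' @param A pattern area.
#' @param P pattern perimeter (total contour length).
#' @param a slice area, positive.
#' @param strict when TRUE (default), a positive area with zero perimeter is
#'   rejected as geometrically impossible for a resolvable pattern; when
#'   FALSE (the batch-pipeline setting) it is clamped to 1 with a warning,
#'   so an isolated single pixel in a tail slice does not abort a run.
#' @return The ratio, clamped to \[0, 1\], with attribute `"raw"`.
#' @export
linear_ratio <- function(A, P, a, strict = TRUE) {
  stopifnot(length(A) == 1, length(P) == 1, length(a) == 1)
  if (!is.finite(a) || a <= 0) stop("slice area must be positive")
  if (A < 0 || P < 0) stop("area and perimeter must be non-negative")
  if (A == 0) return(structure(0, raw = 0))
  if (P == 0) {
    if (strict)
      stop("positive area with zero perimeter: pattern below the contour ",
           "resolution (isolated pixels); linear ratio undefined")
    warning("positive area with zero perimeter; linear ratio clamped to 1")
    return(structure(1, raw = Inf))
  }
  raw <- 4 * A / (P * sqrt(a))
  structure(min(raw, 1), raw = raw)
}

#' Normalized fractal dimension
#'
#' The box-counting dimension of a planar pattern lies in \[0, 2\]; dividing
#' by 2 maps it to \[0, 1\] on the common scale of the other architecture
#' quantities. Input outside \[0, 2\] (a raw regression slope) is clamped
#' first.
#'
#' @param D_B box-counting fractal dimension (or raw slope).
#' @return `D_B / 2` in \[0, 1\]; `NA` input propagates.
#' @export
normalized_fractal <- function(D_B) {
  pmin(pmax(D_B, 0), 2) / 2
}

#' Gaussian ordinal weights for depth-weighted aggregation
#'
#' Weights over slice ordinals `j = 1..N` generated from the Gaussian density
#' centered at `mu_N = lambda (1 + N)` with standard deviation
#' `sigma_N = sqrt(mean((j - mu_N)^2))` (the population sd of the ordinals
#' when `lambda = 0.5`), normalized to sum 1. `lambda` sets the ordinal
#' position receiving the maximum weight; at the default 0.5 the weights are
#' symmetric about the median ordinal, emphasizing the middle layers of the
#' biofilm where coverage peaks.
#'
#' @param N number of slices (>= 1).
#' @param lambda ordinal-position parameter, typically in (0, 1); default 0.5.
#' @param literal_sigma reproduce the printed-form exponent denominator
#'   `2 sigma` instead of the standard Gaussian `2 sigma^2`; provided for
#'   sensitivity checks only.
#' @return A list of class `"weight_scheme"` with `N`, `lambda`, `mu_N`,
#'   `sigma_N` and the normalized weights `w`.
#' @examples
#' round(gaussian_weights(3)$w, 4)  # 0.2429 0.5142 0.2429
#' @export
gaussian_weights <- function(N, lambda = 0.5, literal_sigma = FALSE) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be a positive integer")
  j <- seq_len(N)
  mu <- lambda * (1 + N)
  sigma <- sqrt(mean((j - mu)^2))
  if (sigma == 0) {
    w <- rep(1, N)  # only possible at N = 1 with lambda = 0.5
  } else {
    denom <- if (literal_sigma) 2 * sigma else 2 * sigma^2
    w <- exp(-(j - mu)^2 / denom)
  }
  w <- w / sum(w)
  structure(list(N = N, lambda = lambda, mu_N = mu, sigma_N = sigma, w = w),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat(sprintf("Gaussian ordinal weights: N = %d, lambda = %.3f, mu = %.3f, sigma = %.4f\n",
              x$N, x$lambda, x$mu_N, x$sigma_N))
  cat("  w:", paste(sprintf("%.4f", x$w), collapse = " "), "\n")
  invisible(x)
}

#' Aggregate a per-slice series to a scalar
#'
#' The three aggregation operators: `"max"` keeps only the fullest slice,
#' `"mean"` the arithmetic mean over slices, and `"weighted"` the
#' Gaussian-weighted mean emphasizing the ordinal position chosen by the
#' weight scheme. For any nonnegative series the mean and weighted values
#' never exceed the maximum.
#'
#' @param series numeric per-slice values (non-empty).
#' @param operator `"max"`, `"mean"` or `"weighted"`.
#' @param weights a [gaussian_weights()] scheme, required for `"weighted"`
#'   and matching the series length.
#' @return A scalar.
#' @export
aggregate_series <- function(series, operator = c("max", "mean", "weighted"),
                             weights = NULL) {
  operator <- match.arg(operator)
  if (!length(series)) stop("empty series")
  if (anyNA(series)) stop("series contains missing values")
  switch(operator,
         max = max(series),
         mean = mean(series),
         weighted = {
           if (is.null(weights)) stop("operator 'weighted' requires weights")
           if (inherits(weights, "weight_scheme")) weights <- weights$w
           if (length(weights) != length(series))
             stop("weights length (", length(weights),
                  ") does not match series length (", length(series), ")")
           sum(weights * series)
         })
}

#' Build the strain x quantity x operator aggregation table
#'
#' Applies all three aggregation operators to each strain's per-slice series
#' of the three dimensionless quantities.
#'
#' @param profiles named list (one element per strain) of data frames with
#'   columns `A_cov`, `L_ratio`, `D_norm` (one row per slice, bottom to top).
#' @param lambda ordinal-position parameter of the Gaussian weights.
#' @param literal_sigma passed to [gaussian_weights()].
#' @return A long data frame of class `"aggregation_table"` with columns
#'   `strain`, `quantity` (`A`, `L`, `D`), `operator` (`max`, `mean`,
#'   `weighted`), `value`, `n_slices`.
#' @export
aggregation_table <- function(profiles, lambda = 0.5, literal_sigma = FALSE) {
  if (!length(profiles)) stop("no strains")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be a named list (one element per strain)")
  qcols <- c(A = "A_cov", L = "L_ratio", D = "D_norm")
  rows <- list()
  for (s in names(profiles)) {
    pr <- profiles[[s]]
    if (!all(qcols %in% names(pr)))
      stop("profile for strain ", s, " lacks columns ",
           paste(setdiff(qcols, names(pr)), collapse = ", "))
    ws <- gaussian_weights(nrow(pr), lambda, literal_sigma)
    for (q in names(qcols)) for (op in c("max", "mean", "weighted")) {
      rows[[length(rows) + 1L]] <- data.frame(
        strain = s, quantity = q, operator = op,
        value = aggregate_series(pr[[qcols[q]]], op, ws),
        n_slices = nrow(pr))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("aggregation_table", "data.frame")
  attr(out, "lambda") <- lambda
  out
}

#' Rescale aggregated quantities across strains
#'
#' Divides every value by the maximum over strains of the same quantity and
#' operator, so that for each quantity x operator column the maximal strain
#' maps to exactly 1 and all values lie in \[0, 1\]. Rescaling an already
#' rescaled table is the identity.
#'
#' @param table an [aggregation_table()] (long data frame with `strain`,
#'   `quantity`, `operator`, `value`).
#' @return The table with `value` replaced by the rescaled value.
#' @export
rescale_across_strains <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("strain", "quantity", "operator", "value") %in% names(table)))
  key <- interaction(table$quantity, table$operator, drop = TRUE)
  colmax <- tapply(table$value, key, max)
  if (any(colmax <= 0))
    stop("a quantity/operator column has maximum <= 0 over all strains ",
         "(no biomass anywhere); rescaling undefined")
  out <- table
  out$value <- table$value / as.numeric(colmax[as.character(key)])
  out
}

#' Colonization index of one strain under one operator
#'
#' The mean of the three cross-strain-rescaled architecture quantities
#' (coverage, linear ratio, normalized fractal dimension) for a fixed
#' aggregation operator.
#'
#' @param A_resc,L_resc,D_resc rescaled quantities in \[0, 1\].
#' @return I_C in \[0, 1\].
#' @export
colonization_index <- function(A_resc, L_resc, D_resc) {
  v <- c(A_resc, L_resc, D_resc)
  if (any(!is.finite(v)) || any(v < 0 | v > 1))
    stop("rescaled quantities must lie in [0, 1]")
  (A_resc + L_resc + D_resc) / 3
}

#' Classify a strain from its colonization indices
#'
#' Per-operator rule: I_C < 0.5 is a porous colonizer, 0.5 <= I_C < 0.7
#' intermediate, and I_C >= 0.7 compact (boundaries assigned upward). The
#' strain-level label is the majority over the operators, since the index is
#' defined for any fixed aggregation operator; disagreement between operators
#' is reported.
#'
#' @param ic numeric vector of I_C values (one per operator), each in
#'   \[0, 1\]; names are kept in the per-operator labels.
#' @return A list with `per_operator` (character vector of labels), `label`
#'   (majority label) and `unanimous` (logical).
#' @export
classify_strain <- function(ic) {
  if (!length(ic)) stop("no colonization indices given")
  if (any(!is.finite(ic)) || any(ic < 0 | ic > 1))
    stop("colonization indices must lie in [0, 1]")
  lab <- ifelse(ic < 0.5, "porous", ifelse(ic < 0.7, "intermediate", "compact"))
  names(lab) <- names(ic)
  counts <- table(factor(lab, levels = c("porous", "intermediate", "compact")))
  majority <- names(counts)[which.max(counts)]
  list(per_operator = lab, label = majority,
       unanimous = length(unique(lab)) == 1L)
}

# Per-slice dimensionless triples from a slice morphometry table.
architecture_profile <- function(morph, strict = FALSE) {
  A_cov <- coverage_fraction(morph$area_px, morph$a_px)
  L_ratio <- vapply(seq_len(nrow(morph)), function(j)
    as.numeric(linear_ratio(morph$area_px[j], morph$perimeter_px[j],
                            morph$a_px[j], strict = strict)), numeric(1))
  D_norm <- ifelse(morph$area_px == 0, 0, normalized_fractal(morph$D_B))
  data.frame(slice = morph$slice, A_cov = A_cov, L_ratio = L_ratio,
             D_norm = D_norm)
}
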