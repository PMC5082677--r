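#' @title Per-slice morphometrics
#' @description
#' Particle analysis (8-connected components, total area, contour perimeter)
#' and box-counting fractal dimension with log--log regression, applied to the
#' binary mask of each optical section. The perimeter is the total length of
#' the closed polygons through the centers of boundary pixels, including the
#' contours of holes; under this convention a solid w x h block has perimeter
#' 2(w - 1) + 2(h - 1) and an isolated pixel has perimeter 0.
#' @name morphometrics
NULL

shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  r_out <- max(1L, 1L + dr):min(h, h + dr)
  c_out <- max(1L, 1L + dc):min(w, w + dc)
  if (length(r_out) && length(c_out))
    out[r_out, c_out] <- m[r_out - dr, c_out - dc]
  out
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 8)
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
}

#' Label connected particles in a binary mask
#'
#' Connected-component labeling by iterated minimum-label propagation.
#' Particles use 8-connectivity (diagonally touching pixels belong to the
#' same particle), the convention used throughout the morphometrics.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix; background 0, particles labeled 1..k in raster
#'   order of their first pixel.
#' @export
label_particles <- function(mask, connectivity = 8) {
  m <- as_mask_matrix(mask)
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0, h, w)
  lab[m] <- which(m)
  off <- neighbor_offsets(connectivity)
  repeat {
    prev <- lab
    for (k in seq_len(nrow(off))) {
      sh <- shift_mat(lab, off[k, 1], off[k, 2])
      upd <- sh > 0 & lab > 0 & sh < lab
      lab[upd] <- sh[upd]
    }
    if (identical(lab, prev)) break
  }
  u <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], u)
  storage.mode(lab) <- "integer"
  lab
}

# Clockwise Moore neighborhood, starting north.
.moore_dirs <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                      ncol = 2, byrow = TRUE)

# Length of one closed boundary polygon traced with the Moore-neighbor
# algorithm from a start pixel with a known background backtrack pixel.
# `m` must be padded so no foreground pixel touches the matrix border.
trace_contour_length <- function(m, sr, sc, br, bc) {
  dirs <- .moore_dirs
  find_next <- function(pr, pc, tr, tc) {
    d0 <- which(dirs[, 1] == tr - pr & dirs[, 2] == tc - pc)
    for (k in 1:8) {
      d <- ((d0 - 1L + k) %% 8L) + 1L
      nr <- pr + dirs[d, 1]; nc <- pc + dirs[d, 2]
      if (m[nr, nc]) {
        dp <- ((d0 - 1L + k - 1L) %% 8L) + 1L
        return(c(nr, nc, pr + dirs[dp, 1], pc + dirs[dp, 2]))
      }
    }
    NULL
  }
  total <- 0
  pr <- sr; pc <- sc; tr <- br; tc <- bc
  first_move <- NULL
  steps <- 0L
  max_steps <- 8L * length(m)
  repeat {
    nx <- find_next(pr, pc, tr, tc)
    if (is.null(nx)) return(0)  # isolated pixel: degenerate contour
    if (is.null(first_move)) first_move <- nx[1:2]
    else if (pr == sr && pc == sc &&
             nx[1] == first_move[1] && nx[2] == first_move[2]) break
    total <- total + sqrt((pr - nx[1])^2 + (pc - nx[2])^2)
    pr <- nx[1]; pc <- nx[2]; tr <- nx[3]; tc <- nx[4]
    steps <- steps + 1L
    if (steps > max_steps) stop("contour tracing failed to terminate")
  }
  total
}

#' Total contour perimeter of a binary mask
#'
#' Sum of the lengths of all boundary contours (outer boundaries of particles
#' and inner boundaries around holes), each a closed polygon through the
#' centers of boundary pixels with steps of length 1 or sqrt(2).
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @return Total perimeter in pixel units.
#' @export
mask_perimeter <- function(mask) {
  m <- as_mask_matrix(mask)
  h <- nrow(m); w <- ncol(m)
  mp <- matrix(FALSE, h + 2L, w + 2L)
  mp[2:(h + 1L), 2:(w + 1L)] <- m
  total <- 0
  # outer contours: one per particle, from its topmost-leftmost pixel
  lab <- label_particles(mp, connectivity = 8)
  k <- max(lab)
  if (k == 0L) return(0)
  for (i in seq_len(k)) {
    px <- which(lab == i, arr.ind = TRUE)
    top <- px[px[, 1] == min(px[, 1]), , drop = FALSE]
    sr <- unname(top[1, 1]); sc <- unname(min(top[, 2]))
    total <- total + trace_contour_length(mp, sr, sc, sr, sc - 1L)
  }
  # inner contours: background components (4-connectivity) not touching the
  # padded border are holes; trace the foreground boundary around each
  bg <- label_particles(!mp, connectivity = 4)
  border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  holes <- setdiff(unique(bg[bg > 0]), border_labs)
  for (hlab in holes) {
    px <- which(bg == hlab, arr.ind = TRUE)
    top <- px[px[, 1] == min(px[, 1]), , drop = FALSE]
    hr <- unname(top[1, 1]); hc <- unname(min(top[, 2]))
    total <- total + trace_contour_length(mp, hr - 1L, hc, hr, hc)
  }
  total
}

#' Particle analysis of one slice mask
#'
#' Connected components under 8-connectivity; particles smaller than
#' `min_particle_px` are discarded. Reports the total retained foreground
#' area, the total contour perimeter of the retained pattern (see
#' [mask_perimeter()]) and the particle count.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param min_particle_px smallest particle size (in pixels) retained;
#'   default 1, i.e. no size filter.
#' @return A list of class `"slice_morphometry"` with `area_px`,
#'   `perimeter_px`, `particle_count` and `slice_area_px`.
#' @examples
#' sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
#' particle_analysis(sq)$perimeter_px  # 36
#' @export
particle_analysis <- function(mask, min_particle_px = 1) {
  m <- as_mask_matrix(mask)
  lab <- label_particles(m)
  if (max(lab) > 0L && min_particle_px > 1) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes >= min_particle_px)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
    lab <- label_particles(m)
  }
  n_particles <- max(lab)
  structure(
    list(area_px = sum(m),
         perimeter_px = if (n_particles > 0L) mask_perimeter(m) else 0,
         particle_count = as.integer(n_particles),
         slice_area_px = length(m)),
    class = "slice_morphometry")
}

#' @export
print.slice_morphometry <- function(x, ...) {
  cat(sprintf("Slice morphometry: area %d px, perimeter %.2f px, %d particle(s) in %d px\n",
              x$area_px, x$perimeter_px, x$particle_count, x$slice_area_px))
  invisible(x)
}

#' Box counts of a binary mask
#'
#' For each box side `delta`, partitions the image into a fixed grid of
#' `delta x delta` boxes anchored at the origin (no offset averaging) and
#' counts the boxes containing at least one foreground pixel.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param sizes positive integer box sides, each at most `min(dim(mask))`.
#' @return A data frame with columns `delta` and `n_boxes`. An empty mask
#'   gives all-zero counts with attribute `"empty" = TRUE` (the fractal
#'   estimate is then undefined).
#' @export
box_counts <- function(mask, sizes) {
  m <- as_mask_matrix(mask)
  sizes <- as.integer(sizes)
  if (!length(sizes) || any(sizes < 1L))
    stop("box sizes must be positive integers")
  if (any(sizes > min(dim(m))))
    stop("box sizes must not exceed the smallest image dimension")
  idx <- which(m, arr.ind = TRUE)
  counts <- vapply(sizes, function(s) {
    if (nrow(idx) == 0L) return(0L)
    bi <- (idx[, 1] - 1L) %/% s
    bj <- (idx[, 2] - 1L) %/% s
    length(unique(bi * ((ncol(m) - 1L) %/% s + 1L) + bj))
  }, integer(1))
  out <- data.frame(delta = sizes, n_boxes = counts)
  if (nrow(idx) == 0L) attr(out, "empty") <- TRUE
  out
}

#' Box-counting fractal dimension by log--log regression
#'
#' Ordinary least-squares fit of `log(n_boxes)` against `-log(delta)`: the
#' slope estimates the box-counting dimension D_B, and the coefficient of
#' determination of the fit is reported as the quality measure. For
#' downstream normalization D_B is clamped to \[0, 2\] (the range of a planar
#' pattern); the raw slope is retained for diagnostics.
#'
#' @param pairs a data frame from [box_counts()], or a numeric vector of box
#'   sides when `n_boxes` is given separately.
#' @param n_boxes counts matching `pairs` when the latter is a vector.
#' @return A list of class `"fractal_estimate"` with `D_B` (clamped),
#'   `raw_slope`, `r_squared`, `delta`, `n_boxes` and `valid`. Fewer than two
#'   usable (positive-count, distinct-size) pairs give `valid = FALSE` and an
#'   `NA` estimate.
#' @export
fractal_dimension <- function(pairs, n_boxes = NULL) {
  if (is.data.frame(pairs)) {
    delta <- pairs$delta
    n_boxes <- pairs$n_boxes
  } else delta <- pairs
  stopifnot(length(delta) == length(n_boxes))
  keep <- is.finite(n_boxes) & n_boxes > 0
  est <- list(D_B = NA_real_, raw_slope = NA_real_, r_squared = NA_real_,
              delta = delta, n_boxes = n_boxes, valid = FALSE)
  class(est) <- "fractal_estimate"
  if (sum(keep) < 2L || length(unique(delta[keep])) < 2L) return(est)
  x <- -log(delta[keep])
  y <- log(n_boxes[keep])
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  fitted <- my + slope * (x - mx)
  sst <- sum((y - my)^2)
  ssr <- sum((y - fitted)^2)
  est$raw_slope <- slope
  est$D_B <- min(max(slope, 0), 2)
  est$r_squared <- if (sst == 0) 1 else 1 - ssr / sst
  est$valid <- TRUE
  est
}

#' @export
print.fractal_estimate <- function(x, ...) {
  if (!x$valid) cat("Fractal estimate: undefined (fewer than 2 usable box sizes)\n")
  else cat(sprintf("Fractal estimate: D_B = %.4f (raw slope %.4f), R2 = %.4f over %d box sizes\n",
                   x$D_B, x$raw_slope, x$r_squared, sum(x$n_boxes > 0)))
  invisible(x)
}

default_box_sizes <- function(h, w) {
  top <- min(h, w) / 4
  if (top < 2) return(c(1L, 2L))
  as.integer(2^seq(1L, floor(log2(top))))
}

#' Morphometrics of every slice of a binary stack
#'
#' Batch driver: runs [particle_analysis()] and the box-counting fractal
#' estimate on each slice mask of a (harmonized) stack, bottom to top. Box
#' sides default to powers of 2 from 2 up to a quarter of the smallest slice
#' dimension.
#'
#' @param binary_stack list of [binary_mask()] objects (or logical matrices),
#'   ordered bottom to top.
#' @param pixel_size lateral pixel size in micrometres per pixel (reported in
#'   the output, measurements stay in pixel units).
#' @param box_sizes optional integer vector of box sides.
#' @param min_particle_px passed to [particle_analysis()].
#' @return A data frame with one row per slice: `slice`, `area_px`,
#'   `perimeter_px`, `particles`, `a_px`, `D_B`, `R2`, `raw_slope`.
#' @export
slice_morphometrics <- function(binary_stack, pixel_size = 1,
                                box_sizes = NULL, min_particle_px = 1) {
  if (!length(binary_stack)) stop("empty stack")
  masks <- lapply(binary_stack, as_mask_matrix)
  d <- dim(masks[[1]])
  if (is.null(box_sizes)) box_sizes <- default_box_sizes(d[1], d[2])
  rows <- lapply(seq_along(masks), function(j) {
    pa <- particle_analysis(masks[[j]], min_particle_px)
    fr <- fractal_dimension(box_counts(masks[[j]], box_sizes))
    data.frame(slice = j, area_px = pa$area_px,
               perimeter_px = pa$perimeter_px,
               particles = pa$particle_count, a_px = pa$slice_area_px,
               D_B = fr$D_B, R2 = fr$r_squared, raw_slope = fr$raw_slope)
  })
  out <- do.call(rbind, rows)
  attr(out, "pixel_size") <- pixel_size
  attr(out, "box_sizes") <- box_sizes
  out
}
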