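# Independent oracles used to validate the implementation paths.

# Brute-force box count: loop over every box of the origin-anchored grid.
brute_force_box_count <- function(mask, delta) {
  m <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  h <- nrow(m); w <- ncol(m)
  n <- 0L
  for (r0 in seq(1L, h, by = delta)) for (c0 in seq(1L, w, by = delta)) {
    rows <- r0:min(r0 + delta - 1L, h)
    cols <- c0:min(c0 + delta - 1L, w)
    if (any(m[rows, cols])) n <- n + 1L
  }
  n
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n1 + n2, n1) assignments of the pooled ranks to group 1.
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Perimeter of a hole-free 4-connected particle via EBImage's oriented
# contour: closed polygon through the traced boundary pixel centers.
ocontour_perimeter <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  lab <- EBImage::bwlabel(m * 1)
  total <- 0
  for (oc in EBImage::ocontour(lab)) {
    if (nrow(oc) < 2) next
    closed <- rbind(oc, oc[1, ])
    total <- total + sum(sqrt(rowSums(diff(closed)^2)))
  }
  total
}

# A random hole-free, 4-connected blob: largest 4-connected component of a
# thresholded smooth field, with interior background components filled.
random_blob <- function(n = 24, seed = 1) {
  set.seed(seed)
  g <- function(k, s) { d <- abs(outer(1:k, 1:k, "-")); k2 <- exp(-d^2 / (2 * s^2)); k2 / rowSums(k2) }
  z <- g(n, 3) %*% matrix(rnorm(n * n), n, n) %*% t(g(n, 3))
  m <- z >= quantile(z, 0.7)
  lab <- biofilmarch::label_particles(m, connectivity = 4)
  if (max(lab) == 0) return(matrix(FALSE, n, n))
  sizes <- tabulate(lab[lab > 0])
  m <- lab == which.max(sizes)
  # fill holes: background components not touching the border become foreground
  bg <- biofilmarch::label_particles(!m, connectivity = 4)
  edge <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  m[bg > 0 & !(bg %in% edge)] <- TRUE
  m
}

# Per-slice dimensionless triples computed from ground-truth masks (skipping
# intensity synthesis and thresholding), for generator-property tests.
triples_from_masks <- function(masks) {
  morph <- biofilmarch::slice_morphometrics(masks)
  data.frame(
    A_cov = biofilmarch::coverage_fraction(morph$area_px, morph$a_px),
    L_ratio = vapply(seq_len(nrow(morph)), function(j)
      as.numeric(suppressWarnings(biofilmarch::linear_ratio(
        morph$area_px[j], morph$perimeter_px[j], morph$a_px[j],
        strict = FALSE))), numeric(1)),
    D_norm = ifelse(morph$area_px == 0, 0,
                    biofilmarch::normalized_fractal(morph$D_B)))
}
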