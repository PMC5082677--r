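#' @title Synthetic biofilm imagery with known ground truth
#' @description
#' Generators for seeded synthetic inputs emulating the statistical structure
#' the architecture analysis assumes: near-binary autofluorescence Z-stacks
#' whose per-slice substratum coverage follows a Gaussian profile along depth,
#' pale-gray tessera photographs with blue-green colonized patches, and
#' correlated surface roughness profiles. Every generator is deterministic for
#' a fixed seed, and returns the ground truth (per-slice coverage targets,
#' architecture label, colonized-pixel mask) alongside the imagery so that
#' every downstream stage can be validated without real micrographs.
#' @name synthetic
NULL

# Run code under a locally seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fixed arithmetic for deriving reproducible sub-seeds from a master seed.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2000000000
  for (k in ks) s <- (s * 7919 + as.double(k) * 101 + 13) %% 2000000000
  as.integer(s)
}

#' Specification of a synthetic confocal stack
#'
#' Collects and validates the parameters of one synthetic Z-stack: the
#' architecture regime, stack geometry, and the Gaussian depth profile of the
#' per-slice substratum coverage
#' \eqn{c_j = \mathrm{peak} \cdot \exp(-(j - \mathrm{center})^2 / (2\,\mathrm{width}^2))}.
#'
#' @param architecture `"compact"` (few large smooth-boundary blobs, emulating
#'   dense mats with few empty spaces) or `"porous"` (a reticulate network of
#'   1--3 pixel wide filaments with many voids).
#' @param n_slices number of optical sections (>= 3); slice 1 is the bottom of
#'   the biofilm.
#' @param width,height slice dimensions in pixels.
#' @param peak_coverage target coverage fraction of the fullest slice, in (0, 1].
#' @param profile_center slice index (may be fractional) at which coverage
#'   peaks; defaults to the middle of the stack, `(n_slices + 1) / 2`.
#' @param profile_width standard deviation of the Gaussian depth profile, in
#'   slices; defaults to `n_slices / 4`.
#' @param seed integer seed; identical spec + seed give a bit-identical stack.
#' @return An object of class `"stack_spec"`.
#' @seealso [generate_stack()]
#' @export
synthetic_stack_spec <- function(architecture = c("compact", "porous"),
                                 n_slices = 9L, width = 64L, height = 64L,
                                 peak_coverage = 0.5,
                                 profile_center = (n_slices + 1) / 2,
                                 profile_width = n_slices / 4,
                                 seed = 1L) {
  architecture <- match.arg(architecture)
  n_slices <- as.integer(n_slices)
  width <- as.integer(width)
  height <- as.integer(height)
  if (n_slices < 3L)
    stop("a synthetic stack needs at least 3 slices, got ", n_slices)
  if (width < 8L || height < 8L)
    stop("slice dimensions must be at least 8x8 pixels, got ",
         width, "x", height)
  if (!is.finite(peak_coverage) || peak_coverage <= 0 || peak_coverage > 1)
    stop("peak_coverage must lie in (0, 1], got ", peak_coverage)
  if (!is.finite(profile_width) || profile_width <= 0)
    stop("profile_width must be positive, got ", profile_width)
  structure(
    list(architecture = architecture, n_slices = n_slices,
         width = width, height = height, peak_coverage = peak_coverage,
         profile_center = profile_center, profile_width = profile_width,
         seed = as.integer(seed)),
    class = "stack_spec")
}

#' @export
print.stack_spec <- function(x, ...) {
  cat(sprintf("Synthetic stack spec: %s, %d slices of %dx%d px\n",
              x$architecture, x$n_slices, x$width, x$height))
  cat(sprintf("  coverage profile: peak %.3f at slice %.2f, width %.2f; seed %d\n",
              x$peak_coverage, x$profile_center, x$profile_width, x$seed))
  invisible(x)
}

# Gaussian depth profile of per-slice coverage targets.
coverage_profile <- function(spec) {
  j <- seq_len(spec$n_slices)
  spec$peak_coverage *
    exp(-(j - spec$profile_center)^2 / (2 * spec$profile_width^2))
}

# Banded row-normalized Gaussian smoothing operator; blur = K %*% X %*% t(K').
gaussian_smoother <- function(n, sigma) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- exp(-d^2 / (2 * sigma^2))
  k / rowSums(k)
}

# Ordered foreground pixel indices for a compact pattern: a smooth random
# field; taking the top-k field values for growing k yields nested level sets.
compact_pixel_order <- function(height, width, sigma = 3) {
  z <- gaussian_smoother(height, sigma) %*%
    matrix(stats::rnorm(height * width), height, width) %*%
    t(gaussian_smoother(width, sigma))
  order(z, decreasing = TRUE)
}

# Ordered foreground pixel indices for a porous pattern: 8-neighbour random
# walks stamped with a 1-3 px square footprint, appended until the budget is
# met; a prefix of the order realizes any smaller coverage, so slices nest.
porous_pixel_order <- function(height, width, budget_px,
                               walk_steps = 60L, stamp_sizes = 1:3) {
  visited <- matrix(FALSE, height, width)
  ord <- integer(0)
  steps8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                  dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  while (length(ord) < budget_px) {
    r <- sample.int(height, 1L)
    c <- sample.int(width, 1L)
    s <- sample(stamp_sizes, 1L)
    for (step in seq_len(walk_steps)) {
      rr <- pmin(pmax(r + seq_len(s) - 1L - (s %/% 2L), 1L), height)
      cc <- pmin(pmax(c + seq_len(s) - 1L - (s %/% 2L), 1L), width)
      px <- unique(as.vector(outer(rr, (cc - 1L) * height, "+")))
      new <- px[!visited[px]]
      visited[new] <- TRUE
      ord <- c(ord, new)
      if (length(ord) >= budget_px) break
      mv <- steps8[sample.int(8L, 1L), ]
      r <- min(max(r + mv[["dr"]], 1L), height)
      c <- min(max(c + mv[["dc"]], 1L), width)
    }
  }
  ord
}

#' Generate a synthetic confocal Z-stack
#'
#' Builds a near-binary 8-bit grayscale stack whose per-slice coverage follows
#' the Gaussian depth profile of the spec. The slice masks are nested level
#' sets of one per-stack structure (a thresholded smooth random field for the
#' compact regime, an ordered filament network for the porous regime), so the
#' maximum intensity projection of the stack covers essentially the same area
#' as the fullest slice, mirroring the concordance between substrate-scale and
#' projection-scale coverage that the analysis measures. Foreground intensities
#' are high (around 220) and background near zero, with slight per-slice noise.
#'
#' @param spec a [synthetic_stack_spec()].
#' @param strain_id,sampling_point labels carried into the [image_stack()].
#' @return A list with components `stack` (an [image_stack()]) and
#'   `ground_truth` (per-slice coverage targets and realized coverages, the
#'   architecture label, and the per-slice boolean masks).
#' @examples
#' st <- generate_stack(synthetic_stack_spec("compact", seed = 7))
#' round(st$ground_truth$realized_coverage, 2)
#' @export
generate_stack <- function(spec, strain_id = "synthetic",
                           sampling_point = 1L) {
  stopifnot(inherits(spec, "stack_spec"))
  targets <- coverage_profile(spec)
  npx <- spec$height * spec$width
  counts <- pmin(round(targets * npx), npx)

  masks <- vector("list", spec$n_slices)
  vox <- array(0L, dim = c(spec$height, spec$width, spec$n_slices))
  ord <- with_seed(derive_seed(spec$seed, 1L), {
    if (spec$architecture == "compact")
      compact_pixel_order(spec$height, spec$width)
    else
      porous_pixel_order(spec$height, spec$width, budget_px = max(counts))
  })
  for (j in seq_len(spec$n_slices)) {
    m <- matrix(FALSE, spec$height, spec$width)
    if (counts[j] > 0) m[ord[seq_len(counts[j])]] <- TRUE
    masks[[j]] <- m
    vox[, , j] <- with_seed(derive_seed(spec$seed, 2L, j), {
      fg <- round(pmin(pmax(stats::rnorm(npx, 220, 12), 160), 255))
      bg <- round(pmin(pmax(abs(stats::rnorm(npx, 0, 6)), 0), 40))
      matrix(as.integer(ifelse(m, fg, bg)), spec$height, spec$width)
    })
  }

  stack <- image_stack(vox, pixel_size = 1, slice_thickness = 5.5,
                       strain_id = strain_id, sampling_point = sampling_point)
  gt <- list(architecture = spec$architecture,
             target_coverage = targets,
             realized_coverage = counts / npx,
             masks = masks)
  list(stack = stack, ground_truth = gt)
}

#' Generate a synthetic tessera photograph
#'
#' Produces an RGB image of a pale-gray textured stone surface with blue-green
#' colonized patches occupying a target area fraction. The colonized mask is a
#' level set of a smooth random field, giving a few coherent patches rather
#' than salt-and-pepper pixels, and is returned as ground truth.
#'
#' @param coverage target colonized area fraction in \[0, 1\].
#' @param width,height image dimensions in pixels.
#' @param seed integer seed.
#' @param background_gray background RGB in \[0, 1\] (pale gray by default,
#'   about 200/255 per channel).
#' @return A list with `photo` (height x width x 3 array in \[0, 1\]) and
#'   `ground_truth` (colonized mask and its realized fraction).
#' @export
generate_tessera_photo <- function(coverage, width = 128L, height = 128L,
                                   seed = 1L,
                                   background_gray = c(200, 200, 200) / 255) {
  if (!is.finite(coverage) || coverage < 0 || coverage > 1)
    stop("coverage must lie in [0, 1], got ", coverage)
  width <- as.integer(width); height <- as.integer(height)
  npx <- width * height
  n_col <- round(coverage * npx)
  with_seed(derive_seed(seed, 17L), {
    mask <- matrix(FALSE, height, width)
    if (n_col > 0)
      mask[compact_pixel_order(height, width, sigma = 4)[seq_len(n_col)]] <- TRUE
    photo <- array(0, dim = c(height, width, 3))
    # pale-gray textured background
    tex <- matrix(stats::rnorm(npx, 0, 5) / 255, height, width)
    for (ch in 1:3) photo[, , ch] <- background_gray[ch] + tex
    # blue-green biomass: green dominates red
    col_rgb <- c(60, 125, 95) / 255
    for (ch in 1:3) {
      plane <- photo[, , ch]
      plane[mask] <- col_rgb[ch] + stats::rnorm(sum(mask), 0, 10) / 255
      photo[, , ch] <- plane
    }
    photo <- pmin(pmax(photo, 0), 1)
    list(photo = photo,
         ground_truth = list(mask = mask, coverage = sum(mask) / npx))
  })
}

#' Generate a synthetic surface roughness profile
#'
#' Zero-mean correlated random heights emulating a stylus-rugosimeter trace.
#' The default length of 1600 points matches the per-tessera sampling count of
#' the study design the package targets.
#'
#' @param n number of sampling points (>= 2); default 1600.
#' @param amplitude standard deviation of the heights, in micrometres;
#'   `amplitude = 0` yields a constant (all-zero) profile.
#' @param correlation_length smoothing scale in samples.
#' @param seed integer seed.
#' @return Numeric vector of length `n` with zero mean.
#' @export
generate_roughness_profile <- function(n = 1600L, amplitude = 2.5,
                                       correlation_length = 8, seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop("a roughness profile needs at least 2 points, got ", n)
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (amplitude == 0) return(numeric(n))
  with_seed(derive_seed(seed, 23L), {
    z <- as.vector(gaussian_smoother(n, correlation_length) %*% stats::rnorm(n))
    z <- z - mean(z)
    z * amplitude / stats::sd(z)
  })
}

#' Generate a full synthetic strain suite
#'
#' Emulates the study layout: each strain contributes three replicate Z-stacks
#' (three sampling points on the same tessera, sharing the architecture and
#' coverage profile but differing by sub-seed) plus one tessera photograph
#' whose coverage tracks the stack's projected coverage up to small noise.
#' Compact strains default to a much higher peak coverage (0.70) than porous
#' ones (0.12): dense mats blanket far more of the substrate than sparse
#' reticulate networks, the regime the per-slice coverage profiles and
#' aggregated magnitudes of the targeted study design exhibit. A small
#' deterministic per-strain jitter keeps strains from being clones.
#'
#' @param n_strains number of strains (>= 1).
#' @param labels character vector of length `n_strains` with entries
#'   `"compact"` or `"porous"`.
#' @param seed master integer seed; all sub-seeds derive from it by fixed
#'   arithmetic.
#' @param n_slices,width,height stack geometry shared by the suite.
#' @param peak_coverage optional numeric vector of per-strain peak coverages
#'   overriding the architecture-based defaults.
#' @return A list of class `"strain_suite"`; one element per strain with
#'   components `strain_id`, `architecture`, `stacks` (list of 3 generated
#'   stacks with ground truth), `photo` (tessera photograph with ground
#'   truth), and `photo_coverage`.
#' @examples
#' suite <- generate_strain_suite(2, c("compact", "porous"), seed = 11,
#'                                width = 32, height = 32, n_slices = 5)
#' sapply(suite, function(s) s$architecture)
#' @export
generate_strain_suite <- function(n_strains, labels, seed = 1L,
                                  n_slices = 9L, width = 64L, height = 64L,
                                  peak_coverage = NULL) {
  n_strains <- as.integer(n_strains)
  if (n_strains < 1L) stop("a suite needs at least one strain")
  if (length(labels) != n_strains)
    stop("labels must have length n_strains (", n_strains, "), got ",
         length(labels))
  if (!all(labels %in% c("compact", "porous")))
    stop("labels must be 'compact' or 'porous'")
  if (!is.null(peak_coverage) && length(peak_coverage) != n_strains)
    stop("peak_coverage must have one value per strain")

  suite <- vector("list", n_strains)
  for (i in seq_len(n_strains)) {
    base <- if (labels[i] == "compact") 0.70 else 0.12
    jitter <- with_seed(derive_seed(seed, 31L, i), stats::runif(1, -0.04, 0.04))
    peak <- if (is.null(peak_coverage)) base + jitter else peak_coverage[i]
    peak <- min(max(peak, 0.05), 1)
    sid <- sprintf("strain_%02d", i)
    stacks <- lapply(1:3, function(k) {
      sp <- synthetic_stack_spec(labels[i], n_slices = n_slices,
                                 width = width, height = height,
                                 peak_coverage = peak,
                                 seed = derive_seed(seed, i, k))
      generate_stack(sp, strain_id = sid, sampling_point = k)
    })
    # tessera coverage tracks the projected (union = peak-slice) coverage
    mip_cov <- max(stacks[[1]]$ground_truth$realized_coverage)
    photo_cov <- with_seed(derive_seed(seed, 47L, i),
                           min(max(mip_cov + stats::rnorm(1, 0, 0.02), 0), 1))
    photo <- generate_tessera_photo(photo_cov, width = width, height = height,
                                    seed = derive_seed(seed, 53L, i))
    suite[[i]] <- list(strain_id = sid, architecture = labels[i],
                       peak_coverage = peak, stacks = stacks,
                       photo = photo, photo_coverage = photo_cov)
  }
  names(suite) <- vapply(suite, `[[`, "", "strain_id")
  structure(suite, class = "strain_suite", seed = as.integer(seed))
}

#' @export
print.strain_suite <- function(x, ...) {
  cat(sprintf("Synthetic strain suite: %d strains (seed %d)\n",
              length(x), attr(x, "seed")))
  for (s in x)
    cat(sprintf("  %s  %-8s peak coverage %.2f, photo coverage %.2f\n",
                s$strain_id, s$architecture, s$peak_coverage,
                s$photo_coverage))
  invisible(x)
}
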