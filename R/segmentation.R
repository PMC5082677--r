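#' Confocal image stack container
#'
#' A light container for a 3-D grayscale intensity grid with its acquisition
#' metadata. Slices are indexed 1..N from the bottom to the top of the
#' biofilm; all slices share the same width and height.
#'
#' @param voxels 3-D numeric/integer array, `dim = c(height, width, n_slices)`.
#'   A matrix is promoted to a single-slice stack.
#' @param pixel_size lateral pixel size in micrometres per pixel.
#' @param slice_thickness optical section thickness in micrometres (the study
#'   design this package targets used 5--6 um sections).
#' @param strain_id label of the strain imaged.
#' @param sampling_point replicate sampling-point index (1..3 in the study
#'   layout).
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(voxels, pixel_size = 1, slice_thickness = NA_real_,
                        strain_id = NA_character_, sampling_point = NA_integer_) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array (height x width x slices)")
  if (any(dim(voxels) < 1L)) stop("empty image stack")
  if (!all(is.finite(voxels))) stop("voxels must be finite")
  structure(list(voxels = voxels, pixel_size = pixel_size,
                 slice_thickness = slice_thickness, strain_id = strain_id,
                 sampling_point = sampling_point),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Image stack: %d slice(s) of %dx%d px (strain %s, point %s)\n",
              d[3], d[1], d[2], x$strain_id, x$sampling_point))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[3]

get_slice <- function(stack, j) stack$voxels[, , j, drop = TRUE]

#' Binary mask container
#'
#' @param pixels logical matrix.
#' @param pixel_size lateral pixel size in micrometres per pixel.
#' @return An object of class `"binary_mask"`.
#' @export
binary_mask <- function(pixels, pixel_size = 1) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "logical"
  if (anyNA(pixels)) stop("mask contains missing values")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("Binary mask %dx%d px, coverage %.3f\n",
              nrow(x$pixels), ncol(x$pixels), mean(x$pixels)))
  invisible(x)
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$pixels
  else if (is.matrix(mask)) {
    m <- mask != 0
    storage.mode(m) <- "logical"
    m
  } else stop("expected a binary_mask or a matrix")
}

#' Convert an intensity image to 8-bit
#'
#' Linear min--max rescaling to the 0--255 range with round-half-up, the
#' conversion applied to raw intensity grids before thresholding. A constant
#' image carries no contrast and maps to all zeros with a warning.
#'
#' @param image numeric matrix or array of finite intensities.
#' @return Integer array of the same shape with values in 0..255.
#' @examples
#' to_8bit(matrix(c(0, 0.5, 1), 1))
#' @export
to_8bit <- function(image) {
  if (length(image) == 0) stop("empty image")
  if (!all(is.finite(image))) stop("image intensities must be finite")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image: no contrast, converted to all zeros")
    out <- image
    out[] <- 0L
    storage.mode(out) <- "integer"
    return(out)
  }
  scaled <- (image - rng[1]) / (rng[2] - rng[1]) * 255
  out <- image
  out[] <- as.integer(floor(scaled + 0.5))  # round half up
  storage.mode(out) <- "integer"
  out
}

# Otsu threshold over the 256-bin histogram of an 8-bit image: the integer
# t in 1..255 maximizing the between-class variance of {<t} vs {>=t}.
otsu_threshold <- function(values) {
  counts <- tabulate(values + 1L, nbins = 256L)
  p <- counts / sum(counts)
  v <- 0:255
  w0 <- cumsum(p)[1:255]          # weight of class {< t} for t = 1..255
  m0 <- cumsum(p * v)[1:255]      # unnormalized class-0 mean
  mt <- sum(p * v)
  w1 <- 1 - w0
  between <- (mt * w0 - m0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  which.max(between)              # t = index since t runs 1..255
}

#' Threshold an 8-bit image to a binary mask
#'
#' Foreground is every pixel with intensity greater than or equal to the
#' threshold. The Otsu threshold maximizes the between-class variance over the
#' 256-bin histogram; a fixed threshold reproduces a manual setting.
#'
#' @param image integer matrix with values in 0..255 (see [to_8bit()]).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold intensity, required when `method = "fixed"`.
#' @param pixel_size carried into the returned mask.
#' @return A [binary_mask()]. The threshold used is stored in attribute
#'   `"threshold"`.
#' @examples
#' threshold_mask(matrix(c(50L, 100L, 150L), 1), "fixed", fixed_value = 100)
#' @export
threshold_mask <- function(image, method = c("otsu", "fixed"),
                           fixed_value = NULL, pixel_size = 1) {
  method <- match.arg(method)
  if (!is.matrix(image)) stop("expected a 2-D image matrix")
  v <- as.vector(image)
  if (anyNA(v) || any(v < 0 | v > 255) || any(v != floor(v)))
    stop("threshold_mask expects an 8-bit image (integers in 0..255)")
  if (method == "fixed") {
    if (is.null(fixed_value)) stop("method 'fixed' requires fixed_value")
    th <- fixed_value
  } else {
    if (length(unique(v)) < 2L) {
      warning("single-valued histogram: Otsu threshold undefined, ",
              "returning an all-background mask")
      m <- binary_mask(matrix(FALSE, nrow(image), ncol(image)), pixel_size)
      attr(m, "threshold") <- NA_real_
      return(m)
    }
    th <- otsu_threshold(as.integer(v))
  }
  m <- binary_mask(image >= th, pixel_size)
  attr(m, "threshold") <- th
  m
}

#' Maximum intensity projection of a stack
#'
#' Each output pixel is the maximum over all slices at that position. The MIP
#' of a stack of binary masks is their pixelwise logical union.
#'
#' @param stack an [image_stack()] or a 3-D array.
#' @return A matrix of the same width and height as the slices.
#' @export
max_intensity_projection <- function(stack) {
  vox <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (!is.array(vox) || length(dim(vox)) != 3L || dim(vox)[3] < 1L)
    stop("expected a non-empty stack")
  out <- vox[, , 1, drop = TRUE]
  if (!is.matrix(out)) out <- matrix(out, dim(vox)[1], dim(vox)[2])
  for (j in seq_len(dim(vox)[3])[-1])
    out <- pmax(out, vox[, , j, drop = TRUE])
  out
}

#' Harmonize slice counts across stacks
#'
#' Stacks acquired with different numbers of optical sections are reduced to a
#' common depth before slice-wise comparison: the target N is the minimum
#' slice count among the inputs, and each stack keeps the slices at indices
#' `round(seq(1, N_orig, length.out = N))`, preserving order and never
#' duplicating a slice.
#'
#' @param stacks list of [image_stack()] objects.
#' @return List of stacks, all with the same number of slices. The selected
#'   indices are stored per stack in attribute `"kept_slices"`.
#' @export
harmonize_slice_count <- function(stacks) {
  if (!length(stacks)) stop("need at least one stack")
  ns <- vapply(stacks, n_slices, integer(1))
  if (any(ns < 1L)) stop("stacks must have at least one slice")
  target <- min(ns)
  lapply(stacks, function(s) {
    n0 <- n_slices(s)
    idx <- unique(as.integer(round(seq(1, n0, length.out = target))))
    out <- s
    out$voxels <- s$voxels[, , idx, drop = FALSE]
    attr(out, "kept_slices") <- idx
    out
  })
}

#' Segment a tessera photograph into colonized and bare areas
#'
#' Classifies a pixel as colonized when its chromatic (Euclidean RGB) distance
#' from the pale-gray background reference exceeds a tolerance and its green
#' channel dominates red, the signature of blue-green phototrophic biomass.
#'
#' @param photo height x width x 3 array with values in \[0, 1\].
#' @param background_gray reference background RGB in \[0, 1\].
#' @param chroma_tol chromatic distance above which a pixel is a candidate
#'   colonized pixel.
#' @param green_over_red require G > R for colonized pixels (default TRUE).
#' @param pixel_size carried into the returned mask.
#' @return A [binary_mask()] of colonized pixels; the colonized area fraction
#'   is stored in attribute `"coverage"`.
#' @export
segment_tessera_photo <- function(photo,
                                  background_gray = c(200, 200, 200) / 255,
                                  chroma_tol = 0.2, green_over_red = TRUE,
                                  pixel_size = 1) {
  if (!is.array(photo) || length(dim(photo)) != 3L || dim(photo)[3] != 3L)
    stop("expected an RGB array (height x width x 3)")
  d2 <- (photo[, , 1] - background_gray[1])^2 +
    (photo[, , 2] - background_gray[2])^2 +
    (photo[, , 3] - background_gray[3])^2
  mask <- sqrt(d2) > chroma_tol
  if (green_over_red) mask <- mask & (photo[, , 2] > photo[, , 1])
  cov <- mean(mask)
  if (cov == 0 || cov == 1)
    warning("degenerate segmentation: image classed entirely as ",
            if (cov == 0) "background" else "colonized")
  m <- binary_mask(mask, pixel_size)
  attr(m, "coverage") <- cov
  m
}
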