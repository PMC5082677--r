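#' @title Reading and writing imagery and reports
#' @description
#' Multi-page 8-bit grayscale TIFF for stacks, 8-bit RGB PNG for tessera
#' photographs and masks, single-column CSV for roughness profiles, and JSON
#' sidecars for ground truth.
#' @name io
NULL

#' Write an image stack as multi-page 8-bit TIFF
#'
#' @param stack an [image_stack()] with intensities in 0..255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(n_slices(stack)),
                  function(j) get_slice(stack, j) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param pixel_size,slice_thickness,strain_id,sampling_point metadata for
#'   the returned [image_stack()] (TIFF carries none).
#' @return An [image_stack()] with 8-bit integer intensities.
#' @export
read_stack <- function(path, pixel_size = 1, slice_thickness = NA_real_,
                       strain_id = NA_character_, sampling_point = NA_integer_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # grayscale stored with channels
    matrix(as.integer(round(p * 255)), nrow(p), ncol(p))
  })
  vox <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (j in seq_along(pages)) vox[, , j] <- pages[[j]]
  image_stack(vox, pixel_size, slice_thickness, strain_id, sampling_point)
}

#' Write an RGB photograph as 8-bit PNG
#'
#' @param photo height x width x 3 array in \[0, 1\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_photo <- function(photo, path) {
  png::writePNG(photo, path)
  invisible(path)
}

#' Read an RGB photograph
#'
#' @param path PNG file path.
#' @return height x width x 3 array in \[0, 1\].
#' @export
read_photo <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a binary mask as 8-bit PNG (0/255)
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask_matrix(mask)
  png::writePNG(m * 1, path)
  invisible(path)
}

#' Write a synthetic strain suite to disk
#'
#' One directory per strain holding the three sampling-point stacks as
#' multi-page TIFF, the tessera photograph as PNG, and a JSON ground-truth
#' sidecar (architecture label, per-slice coverage targets, photo coverage).
#'
#' @param suite a [generate_strain_suite()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_suite <- function(suite, dir) {
  stopifnot(inherits(suite, "strain_suite"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in suite) {
    sd <- file.path(dir, s$strain_id)
    dir.create(sd, showWarnings = FALSE)
    for (k in seq_along(s$stacks))
      write_stack(s$stacks[[k]]$stack, file.path(sd, sprintf("stack_%d.tif", k)))
    write_photo(s$photo$photo, file.path(sd, "tessera.png"))
    gt <- list(strain_id = s$strain_id, architecture = s$architecture,
               peak_coverage = s$peak_coverage,
               target_coverage = s$stacks[[1]]$ground_truth$target_coverage,
               photo_coverage = s$photo_coverage)
    jsonlite::write_json(gt, file.path(sd, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Write a roughness profile as single-column CSV
#'
#' @param profile numeric height series.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(data.frame(height = profile), path, row.names = FALSE)
  invisible(path)
}

#' Read a roughness profile from single-column CSV
#'
#' @param path CSV file path (column `height`, or first column).
#' @return Numeric vector.
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path)
  as.numeric(if ("height" %in% names(df)) df$height else df[[1]])
}
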