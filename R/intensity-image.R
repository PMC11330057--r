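#' Create an intensity image
#'
#' The common carrier for all 2-D grayscale frames in the package: SWIR
#' reflectance/transillumination frames, radiographs, and (via [bscan()]) OCT
#' b-scans. Pixels are stored as a numeric matrix in arbitrary units; most
#' workflows keep them in `[0, 1]`.
#'
#' @param pixels Numeric matrix of intensities; all values must be finite and
#'   non-negative.
#' @param modality One of `"reflectance"`, `"occlusal_trans"`,
#'   `"proximal_trans"`, `"radiograph"`, `"oct_bscan"`.
#' @param mm_per_pixel Physical scale in mm per pixel, or `NA` if the image has
#'   not been calibrated yet (see [calibrate_px_to_mm()]).
#'
#' @return An object of class `intensity_image`: a list with elements
#'   `pixels`, `modality`, `mm_per_pixel`.
#' @export
#' @examples
#' img <- intensity_image(matrix(0.5, 8, 8), "reflectance", mm_per_pixel = 0.05)
#' img
intensity_image <- function(pixels, modality, mm_per_pixel = NA_real_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels))) stop("intensities must all be finite")
  if (any(pixels < 0)) stop("intensities must be >= 0")
  modality <- match.arg(modality, all_modalities)
  if (!is.na(mm_per_pixel) && mm_per_pixel <= 0) {
    stop("mm_per_pixel must be positive")
  }
  structure(
    list(pixels = pixels, modality = modality,
         mm_per_pixel = as.numeric(mm_per_pixel)),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf(
    "<intensity_image> %d x %d px, modality %s, scale %s\n",
    nrow(x$pixels), ncol(x$pixels), x$modality,
    if (is.na(x$mm_per_pixel)) "uncalibrated"
    else sprintf("%.4g mm/px", x$mm_per_pixel)
  ))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

is_transillumination <- function(modality) {
  modality %in% c("occlusal_trans", "proximal_trans")
}

#' Attach a physical scale from a reference target
#'
#' Cross-calibrates pixels to millimetres using a reference target of known
#' length imaged alongside the tooth.
#'
#' @param img An [intensity_image()].
#' @param reference_length_mm Known physical length of the target, mm.
#' @param reference_length_px Measured length of the target in the image,
#'   pixels.
#'
#' @return The image with `mm_per_pixel` set to
#'   `reference_length_mm / reference_length_px`.
#' @export
#' @examples
#' img <- intensity_image(matrix(0.5, 8, 8), "reflectance")
#' calibrate_px_to_mm(img, 10, 200)$mm_per_pixel # 0.05
calibrate_px_to_mm <- function(img, reference_length_mm, reference_length_px) {
  stopifnot(inherits(img, "intensity_image"))
  if (!is.numeric(reference_length_mm) || !is.numeric(reference_length_px) ||
      length(reference_length_mm) != 1L || length(reference_length_px) != 1L ||
      !is.finite(reference_length_mm) || !is.finite(reference_length_px) ||
      reference_length_mm <= 0 || reference_length_px <= 0) {
    stop("reference lengths must be positive finite scalars")
  }
  img$mm_per_pixel <- reference_length_mm / reference_length_px
  img
}

#' Read a grayscale image from TIFF, PNG, or CSV
#'
#' TIFF and PNG are read with the tiff and png packages (values scaled to
#' `[0, 1]`); a CSV is read as a plain numeric matrix. Multi-channel images are
#' averaged to one channel.
#'
#' @param path File path; format inferred from the extension.
#' @param modality Modality tag to attach (see [intensity_image()]).
#' @param mm_per_pixel Optional physical scale, mm per pixel.
#' @return An [intensity_image()].
#' @export
read_intensity_image <- function(path, modality, mm_per_pixel = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    csv = as.matrix(read.csv(path, header = FALSE)),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  dimnames(px) <- NULL
  storage.mode(px) <- "double"
  intensity_image(px, modality, mm_per_pixel)
}

#' Write a grayscale image to 16-bit TIFF, PNG, or CSV
#'
#' TIFF output is 16-bit grayscale to preserve contrast resolution near the
#' detection threshold; pixel values are clipped to `[0, 1]` for TIFF/PNG.
#'
#' @param img An [intensity_image()] (or bare numeric matrix).
#' @param path Output path; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_intensity_image <- function(img, path) {
  px <- if (inherits(img, "intensity_image")) img$pixels else img
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(pmin(pmax(px, 0), 1), path, bits.per.sample = 16L),
    png = png::writePNG(pmin(pmax(px, 0), 1), path),
    csv = write.table(px, path, sep = ",", row.names = FALSE,
                      col.names = FALSE),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}
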