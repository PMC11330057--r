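#' Radiographic lesion contrast
#'
#' Computes `(i_s - i_l) / i_s` from an examiner-drawn lesion ROI and a sound
#' reference region chosen directly above or below the lesion (same column
#' band, so enamel thickness is comparable). Lesions are radiolucent on
#' digital radiographs, so true lesions give positive contrast; a negative
#' value is flagged as non-lesion-like. For inverted-polarity images set
#' `polarity = "inverted"`, which computes the contrast on the inverted
#' intensity convention `(i_l - i_s) / i_l`.
#'
#' @param img An [intensity_image()] (`modality = "radiograph"`).
#' @param roi An [roi_set()] with `lesion` and `sound` regions.
#' @param polarity `"radiolucent"` (lesions darker, default) or
#'   `"inverted"`.
#' @param overlap_tol Minimum fraction of lesion columns that the sound
#'   region must share for the similar-enamel-thickness rule; a smaller
#'   overlap triggers a warning.
#' @param depth_segment Optional 2 x 2 matrix of two `(row, col)` points
#'   (enamel surface to lesion front) defining the manually drawn lesion
#'   depth.
#' @return A one-row tibble of class `radiograph_measurement`: `i_l`, `i_s`,
#'   `contrast`, `lesion_like`, `lesion_depth_mm` (`NA` without a depth
#'   segment or scale).
#' @export
#' @examples
#' px <- matrix(200, 20, 20); px[10:14, 8:12] <- 174
#' img <- intensity_image(px, "radiograph")
#' roi <- roi_set(sound = roi_rect(c(20, 20), 3:7, 8:12),
#'                contact = roi_rect(c(20, 20), 1:20, 15),
#'                lesion = roi_rect(c(20, 20), 10:14, 8:12))
#' radiograph_contrast(img, roi)$contrast # 0.13
radiograph_contrast <- function(img, roi, polarity = c("radiolucent",
                                                       "inverted"),
                                overlap_tol = 0.8, depth_segment = NULL) {
  stopifnot(inherits(img, "intensity_image"), inherits(roi, "roi_set"))
  polarity <- match.arg(polarity)
  if (is.null(roi$lesion) || !any(roi$lesion)) {
    stop("radiograph_contrast requires a lesion ROI")
  }
  if (!any(roi$sound)) stop("sound region is empty")
  lesion_cols <- unique(which(roi$lesion, arr.ind = TRUE)[, 2])
  sound_cols <- unique(which(roi$sound, arr.ind = TRUE)[, 2])
  overlap <- mean(lesion_cols %in% sound_cols)
  if (overlap < overlap_tol) {
    warning(sprintf(
      "sound region shares only %.0f%% of the lesion columns; it should sit directly above or below the lesion (similar enamel thickness)",
      100 * overlap
    ))
  }
  i_l <- mean(img$pixels[roi$lesion])
  i_s <- mean(img$pixels[roi$sound])
  if (i_s <= 0) stop("mean sound intensity must be positive")
  contrast <- if (polarity == "radiolucent") {
    (i_s - i_l) / i_s
  } else {
    if (i_l <= 0) stop("mean lesion intensity must be positive for inverted polarity")
    (i_l - i_s) / i_l
  }
  depth_mm <- NA_real_
  if (!is.null(depth_segment)) {
    stopifnot(is.matrix(depth_segment), all(dim(depth_segment) == c(2, 2)))
    if (is.na(img$mm_per_pixel)) {
      warning("mm_per_pixel unset: lesion depth not converted to mm")
    } else {
      depth_mm <- sqrt(sum((depth_segment[2, ] - depth_segment[1, ])^2)) *
        img$mm_per_pixel
    }
  }
  out <- tibble::tibble(
    i_l = i_l, i_s = i_s, contrast = contrast,
    lesion_like = contrast > 0, lesion_depth_mm = depth_mm
  )
  class(out) <- c("radiograph_measurement", class(out))
  out
}

#' Transfer the physical scale from a SWIR image to a radiograph
#'
#' The mesial-to-distal span of the tooth, measured in both images, converts
#' the calibrated SWIR scale to the radiograph:
#' `mm_per_pixel_rad = mm_per_pixel_swir * span_swir_px / span_rad_px`.
#'
#' @param radiograph,swir [intensity_image()]s; the SWIR image must be
#'   calibrated.
#' @param span_rad_px,span_swir_px The matched mesial-distal spans, pixels.
#' @return The radiograph with `mm_per_pixel` set.
#' @export
#' @examples
#' swir <- intensity_image(matrix(0.5, 4, 4), "reflectance", 0.05)
#' rad <- intensity_image(matrix(0.5, 4, 4), "radiograph")
#' transfer_scale(rad, swir, span_rad_px = 100, span_swir_px = 160)$mm_per_pixel
transfer_scale <- function(radiograph, swir, span_rad_px, span_swir_px) {
  stopifnot(inherits(radiograph, "intensity_image"),
            inherits(swir, "intensity_image"))
  if (is.na(swir$mm_per_pixel)) stop("the SWIR image has no mm_per_pixel set")
  if (!is.finite(span_rad_px) || !is.finite(span_swir_px) ||
      span_rad_px <= 0 || span_swir_px <= 0) {
    stop("spans must be positive")
  }
  radiograph$mm_per_pixel <- swir$mm_per_pixel * span_swir_px / span_rad_px
  radiograph
}
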