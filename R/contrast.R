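#' Convert a SWIR frame to a contrast map
#'
#' Applies the per-pixel contrast transform against the mean sound-enamel
#' intensity `i_s` taken from the sound ROI: `(I_t - i_s) / I_t` for
#' reflectance (lesions scatter more and appear bright) and
#' `(i_s - I_t) / i_s` for transillumination and radiographs (lesions
#' attenuate and appear dark). `I_t` is the target pixel. Reflectance pixels
#' with `I_t = 0` have no finite contrast; they are flagged and excluded from
#' downstream masks.
#'
#' @param img An [intensity_image()].
#' @param roi An [roi_set()] providing the sound-reference region.
#' @param stat Statistic for `i_s` over the sound ROI: arithmetic mean
#'   (default) or median.
#' @return An object of class `contrast_map`: `values` (numeric matrix,
#'   dimensionless, may be negative), `i_s`, `modality`, and `excluded`
#'   (logical matrix of undefined pixels).
#' @export
#' @examples
#' img <- intensity_image(matrix(c(125, 100), 1, 2), "reflectance")
#' roi <- roi_set(sound = matrix(c(FALSE, TRUE), 1, 2),
#'                contact = matrix(c(TRUE, FALSE), 1, 2))
#' contrast_map(img, roi)$values[1, 1] # 0.2
contrast_map <- function(img, roi, stat = c("mean", "median")) {
  stopifnot(inherits(img, "intensity_image"), inherits(roi, "roi_set"))
  stat <- match.arg(stat)
  if (!identical(dim(roi$sound), dim(img$pixels))) {
    stop("ROI masks must match the image dimensions")
  }
  sound_px <- img$pixels[roi$sound]
  if (length(sound_px) == 0) stop("sound region is empty")
  i_s <- if (stat == "mean") mean(sound_px) else stats::median(sound_px)
  if (i_s <= 0) stop("mean sound intensity must be positive")
  px <- img$pixels
  excluded <- matrix(FALSE, nrow(px), ncol(px))
  if (img$modality == "reflectance") {
    excluded <- px == 0
    values <- (px - i_s) / px
    values[excluded] <- -Inf
  } else {
    values <- (i_s - px) / i_s
  }
  structure(list(values = values, i_s = i_s, modality = img$modality,
                 excluded = excluded),
            class = "contrast_map")
}

#' @export
print.contrast_map <- function(x, ...) {
  finite <- x$values[!x$excluded]
  cat(sprintf(
    "<contrast_map> %d x %d px (%s), i_s = %.4g, contrast range [%.3g, %.3g]\n",
    nrow(x$values), ncol(x$values), x$modality, x$i_s,
    min(finite), max(finite)
  ))
  invisible(x)
}

#' Threshold a contrast map into a binary detection mask
#'
#' A contrast of 0.1 is the reference threshold for positive lesion
#' detection: pixels with contrast *lower than* the threshold are removed, so
#' a pixel exactly at the threshold is kept. Flagged (undefined) pixels are
#' always removed.
#'
#' @param cm A [contrast_map()].
#' @param threshold Detection threshold (default 0.1).
#' @return Logical matrix.
#' @export
threshold_mask <- function(cm, threshold = 0.1) {
  stopifnot(inherits(cm, "contrast_map"), is.finite(threshold))
  cm$values >= threshold & !cm$excluded
}

#' Label connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default; diagonal neighbours connect) or 4.
#' @return Integer matrix of component labels (`0` = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  .label_components_cpp(mask, as.integer(connectivity))
}

dilate_mask <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  shift <- function(m, dr, dc) {
    res <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    res[rs, cs] <- m[rs - dr, cs - dc]
    res
  }
  steps <- if (connectivity == 8L) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  for (s in steps) out <- out | shift(mask, s[1], s[2])
  out
}

#' Select the contact-adjoining lesion component
#'
#' Labels the connected components of a thresholded contrast mask and keeps
#' those that adjoin (share a pixel with, or are 8-adjacent to) the proximal
#' contact ROI: these are designated the proximal lesion. All other
#' components — specular highlights in reflectance, direct-light bleed and
#' dark background in transillumination — are discarded. Multiple adjoining
#' components are merged into one lesion. An empty result is a negative
#' detection.
#'
#' @param mask Logical matrix (from [threshold_mask()]).
#' @param roi An [roi_set()] with a non-empty contact ROI.
#' @param connectivity Component and adjacency connectivity (8 or 4).
#' @return An object of class `lesion_segment` with `mask`, `detected`, and
#'   `area_px`; metric fields are filled by [lesion_metrics()].
#' @export
select_lesion <- function(mask, roi, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask), inherits(roi, "roi_set"))
  if (!any(roi$contact)) stop("contact ROI must be non-empty")
  labels <- label_components(mask, connectivity)
  touch_zone <- roi$contact | dilate_mask(roi$contact, connectivity)
  keep <- setdiff(unique(labels[touch_zone]), 0L)
  lesion <- matrix(FALSE, nrow(mask), ncol(mask))
  if (length(keep)) lesion <- matrix(labels %in% keep, nrow(mask))
  structure(list(
    mask = lesion,
    detected = any(lesion),
    area_px = sum(lesion),
    area_mm2 = NA_real_,
    mean_contrast = NA_real_,
    depth_mm = NA_real_,
    depth_px = NA_real_
  ), class = "lesion_segment")
}

#' @export
print.lesion_segment <- function(x, ...) {
  if (!x$detected) {
    cat("<lesion_segment> negative detection (empty lesion)\n")
  } else {
    cat(sprintf(
      "<lesion_segment> %d px%s, mean contrast %s, depth %s\n",
      x$area_px,
      if (is.na(x$area_mm2)) "" else sprintf(" (%.3g mm^2)", x$area_mm2),
      if (is.na(x$mean_contrast)) "?" else sprintf("%.3f", x$mean_contrast),
      if (is.na(x$depth_mm)) {
        if (is.na(x$depth_px)) "?" else sprintf("%g px", x$depth_px)
      } else sprintf("%.3f mm", x$depth_mm)
    ))
  }
  invisible(x)
}

# Unit normal to the contact line (fitted through the contact ROI pixels by
# principal axis); falls back to a horizontal normal for a 1-px contact.
contact_normal <- function(contact) {
  pts <- which(contact, arr.ind = TRUE)
  if (nrow(pts) < 2) return(c(0, 1))
  ctr <- scale(pts, scale = FALSE)
  v <- svd(ctr, nu = 0, nv = 2)$v[, 1]
  c(-v[2], v[1])
}

#' Compute lesion area, mean contrast, and depth
#'
#' Fills the metric fields of a detected [select_lesion()] segment: pixel and
#' physical area, mean contrast over the lesion mask, and lesion depth as the
#' maximal extent of the mask measured perpendicular to the contact line
#' (penetration away from the proximal surface), in pixels and — when the
#' image is calibrated — millimetres.
#'
#' @param seg A `lesion_segment` with `detected = TRUE`.
#' @param cm The [contrast_map()] the mask came from.
#' @param roi The [roi_set()] providing the contact line.
#' @param mm_per_pixel Physical scale; `NA` reports pixel units only, with a
#'   warning.
#' @return The segment with `area_mm2`, `mean_contrast`, `depth_px`,
#'   `depth_mm` filled.
#' @export
lesion_metrics <- function(seg, cm, roi, mm_per_pixel = NA_real_) {
  stopifnot(inherits(seg, "lesion_segment"), inherits(cm, "contrast_map"),
            inherits(roi, "roi_set"))
  if (!seg$detected) stop("lesion_metrics requires a positive detection")
  seg$area_px <- sum(seg$mask)
  seg$mean_contrast <- mean(cm$values[seg$mask])
  u <- contact_normal(roi$contact)
  pts <- which(seg$mask, arr.ind = TRUE)
  d <- pts[, 1] * u[1] + pts[, 2] * u[2]
  seg$depth_px <- max(d) - min(d) + 1
  if (is.na(mm_per_pixel)) {
    warning("mm_per_pixel unset: depth and area reported in pixels only")
    seg$depth_mm <- NA_real_
    seg$area_mm2 <- NA_real_
  } else {
    seg$depth_mm <- seg$depth_px * mm_per_pixel
    seg$area_mm2 <- seg$area_px * mm_per_pixel^2
  }
  seg
}

#' One-call semi-automatic lesion segmentation
#'
#' The full SWIR chain: contrast map, threshold, contact-adjoining component
#' selection, and (for positive detections) lesion metrics.
#'
#' @inheritParams contrast_map
#' @inheritParams threshold_mask
#' @inheritParams select_lesion
#' @return A `lesion_segment`.
#' @export
#' @examples
#' ph <- make_swir_phantom(phantom_config(noise_sigma = 0))
#' seg <- segment_lesion(ph$image, ph$roi)
#' seg$mean_contrast # recovers the phantom's true contrast
segment_lesion <- function(img, roi, threshold = 0.1, connectivity = 8L,
                           stat = c("mean", "median")) {
  cm <- contrast_map(img, roi, stat = stat)
  mask <- threshold_mask(cm, threshold)
  seg <- select_lesion(mask, roi, connectivity)
  if (seg$detected) {
    seg <- lesion_metrics(seg, cm, roi, mm_per_pixel = img$mm_per_pixel)
  }
  seg
}

#' @export
tidy.lesion_segment <- function(x, ...) {
  tibble::tibble(
    detected = x$detected, area_px = x$area_px, area_mm2 = x$area_mm2,
    mean_contrast = x$mean_contrast, depth_px = x$depth_px,
    depth_mm = x$depth_mm
  )
}

#' Write / read a lesion segment (JSON metrics + PNG mask)
#'
#' @param seg A `lesion_segment`.
#' @param stem Output path stem; writes `<stem>.json` and `<stem>_mask.png`.
#' @return The JSON path, invisibly.
#' @export
write_lesion_segment <- function(seg, stem) {
  stopifnot(inherits(seg, "lesion_segment"))
  png::writePNG(seg$mask * 1, paste0(stem, "_mask.png"))
  jsonlite::write_json(
    list(detected = seg$detected, area_px = seg$area_px,
         area_mm2 = seg$area_mm2, mean_contrast = seg$mean_contrast,
         depth_px = seg$depth_px, depth_mm = seg$depth_mm),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(paste0(stem, ".json"))
}

#' @rdname write_lesion_segment
#' @param stem_or_json Path stem or JSON path written by
#'   [write_lesion_segment()].
#' @export
read_lesion_segment <- function(stem_or_json) {
  stem <- sub("\\.json$", "", stem_or_json)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  mask <- png::readPNG(paste0(stem, "_mask.png")) > 0.5
  null_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  structure(list(
    mask = mask, detected = isTRUE(meta$detected),
    area_px = as.integer(meta$area_px), area_mm2 = null_na(meta$area_mm2),
    mean_contrast = null_na(meta$mean_contrast),
    depth_mm = null_na(meta$depth_mm), depth_px = null_na(meta$depth_px)
  ), class = "lesion_segment")
}
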