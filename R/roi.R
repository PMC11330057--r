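#' Region-of-interest set for the semi-automatic segmentation
#'
#' Holds the manual inputs of the segmentation procedure: the sound-enamel
#' reference region (used to estimate the reference intensity `i_s`), the
#' proximal contact ROI (a thin band at the contact that lesion components
#' must adjoin), and — for radiographs — an examiner-drawn lesion ROI.
#'
#' All regions are logical masks with the dimensions of the image they
#' annotate.
#'
#' @param sound Logical matrix; sound-enamel reference region. Must be
#'   non-empty and disjoint from `contact`.
#' @param contact Logical matrix; contact ROI (rasterized polyline or thin
#'   band).
#' @param lesion Optional logical matrix; lesion ROI (radiographs only).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(sound, contact, lesion = NULL) {
  stopifnot(is.matrix(sound), is.logical(sound),
            is.matrix(contact), is.logical(contact))
  if (!identical(dim(sound), dim(contact))) {
    stop("sound and contact masks must share dimensions")
  }
  if (!any(sound)) stop("sound region must be non-empty")
  if (any(sound & contact)) {
    stop("sound region must be disjoint from the contact ROI")
  }
  if (!is.null(lesion)) {
    stopifnot(is.matrix(lesion), is.logical(lesion))
    if (!identical(dim(lesion), dim(sound))) {
      stop("lesion mask must share dimensions with the other ROIs")
    }
  }
  structure(list(sound = sound, contact = contact, lesion = lesion),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d x %d px: sound %d px, contact %d px%s\n",
              nrow(x$sound), ncol(x$sound), sum(x$sound), sum(x$contact),
              if (is.null(x$lesion)) ""
              else sprintf(", lesion %d px", sum(x$lesion))))
  invisible(x)
}

#' Build a rectangular logical mask
#'
#' @param dim Image dimensions `c(rows, cols)`.
#' @param rows,cols Integer ranges of rows/columns to set.
#' @return A logical matrix.
#' @export
roi_rect <- function(dim, rows, cols) {
  m <- matrix(FALSE, dim[1], dim[2])
  rows <- rows[rows >= 1 & rows <= dim[1]]
  cols <- cols[cols >= 1 & cols <= dim[2]]
  m[rows, cols] <- TRUE
  m
}

mask_to_coords <- function(m) {
  w <- which(m, arr.ind = TRUE)
  list(row = as.integer(w[, 1]), col = as.integer(w[, 2]))
}

coords_to_mask <- function(coords, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  if (length(coords$row)) m[cbind(coords$row, coords$col)] <- TRUE
  m
}

#' Write / read ROI sets as JSON
#'
#' ROIs are serialized as named pixel-coordinate lists (1-based row/col) plus
#' the image dimensions, a plain-text format that round-trips exactly.
#'
#' @param roi An [roi_set()].
#' @param path JSON file path.
#' @return `write_roi_json()` returns `path` invisibly; `read_roi_json()`
#'   returns an [roi_set()].
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "roi_set"))
  obj <- list(
    dim = dim(roi$sound),
    sound = mask_to_coords(roi$sound),
    contact = mask_to_coords(roi$contact)
  )
  if (!is.null(roi$lesion)) obj$lesion <- mask_to_coords(roi$lesion)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.integer(obj$dim)
  roi_set(
    sound = coords_to_mask(obj$sound, d),
    contact = coords_to_mask(obj$contact, d),
    lesion = if (!is.null(obj$lesion)) coords_to_mask(obj$lesion, d)
  )
}
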