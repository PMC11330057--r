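#' Create a CP-OCT b-scan
#'
#' A 2-D cross-sectional OCT frame: rows are axial (optical) depth, columns
#' lateral position. The axial scale is stored as *optical* distance; dividing
#' by the enamel refractive index converts to physical depth.
#'
#' @param pixels Numeric matrix of intensities (finite, `>= 0`).
#' @param mm_axial_optical Axial scale, mm of optical path per pixel row.
#' @param mm_lateral Lateral scale, mm per pixel column.
#' @param refractive_index Refractive index used for optical-to-physical
#'   conversion (enamel is about 1.6).
#' @return An object of class `bscan`.
#' @export
bscan <- function(pixels, mm_axial_optical, mm_lateral,
                  refractive_index = 1.6) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("intensities must be finite and >= 0")
  }
  if (mm_axial_optical <= 0 || mm_lateral <= 0) {
    stop("pixel scales must be positive")
  }
  if (refractive_index < 1) stop("refractive_index must be >= 1")
  structure(list(pixels = pixels, mm_axial_optical = mm_axial_optical,
                 mm_lateral = mm_lateral,
                 refractive_index = refractive_index),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf(
    "<bscan> %d axial x %d lateral px, %.4g mm/px optical axial, n = %.2f\n",
    nrow(x$pixels), ncol(x$pixels), x$mm_axial_optical, x$refractive_index
  ))
  invisible(x)
}

#' Median-filter speckle reduction
#'
#' Applies a kernel x kernel median filter; border pixels use the median of
#' the in-image (clipped) part of the window. Kernel 1 is the identity. The
#' default kernel of 3 is the standard pre-processing step before depth
#' measurement.
#'
#' @param b A [bscan()], [intensity_image()], or numeric matrix.
#' @param kernel Odd window size, `>= 1`.
#' @return The same type as `b`, filtered.
#' @export
despeckle <- function(b, kernel = 3L) {
  if (length(kernel) != 1L || kernel < 1 || kernel %% 2 == 0) {
    stop("kernel must be an odd integer >= 1")
  }
  kernel <- as.integer(kernel)
  px <- if (inherits(b, "bscan") || inherits(b, "intensity_image")) b$pixels
        else b
  out <- if (kernel == 1L) px else .median_filter_cpp(px, kernel)
  if (inherits(b, "bscan") || inherits(b, "intensity_image")) {
    b$pixels <- out
    b
  } else {
    out
  }
}

# First axial index in each column whose intensity reaches frac * column max.
surface_rows <- function(px, cols, frac) {
  vapply(cols, function(j) {
    col <- px[, j]
    s <- which(col >= frac * max(col))[1]
    if (is.na(s)) NA_integer_ else as.integer(s)
  }, integer(1))
}

#' Fit the enamel surface and return its inward normal
#'
#' Detects the surface in each column of a lateral window (first axial
#' intensity rise above a fraction of the column maximum), fits a straight
#' line to the surface points by least squares in physical (mm) coordinates,
#' and returns the unit normal perpendicular to the fit, pointing into the
#' tissue. This is where the cylindrical depth ruler starts.
#'
#' @param b A [bscan()].
#' @param lateral_pos Lateral pixel column at which the ruler starts.
#' @param window Half-width of the lateral fitting window, pixels.
#' @param frac Fraction of the column maximum that defines the surface rise.
#' @return A list: `origin` (fractional `(row, col)` of the surface at
#'   `lateral_pos`), `direction` (unit vector `(axial, lateral)` in mm space),
#'   and `angle_deg` (angle of the normal from the axial axis).
#' @export
surface_normal <- function(b, lateral_pos, window = 10L, frac = 0.5) {
  stopifnot(inherits(b, "bscan"))
  px <- b$pixels
  cols <- max(1, lateral_pos - window):min(ncol(px), lateral_pos + window)
  srows <- surface_rows(px, cols, frac)
  ok <- !is.na(srows)
  if (sum(ok) < 2) stop("no detectable surface in the lateral window")
  # physical-plane coordinates: axial uses the optical scale
  y <- (cols[ok] - 1) * b$mm_lateral
  x <- (srows[ok] - 1) * b$mm_axial_optical
  fit <- stats::lm.fit(cbind(1, y), x)
  slope <- fit$coefficients[2] # d axial_mm / d lateral_mm
  normal <- c(1, -slope)
  normal <- normal / sqrt(sum(normal^2))
  if (normal[1] < 0) normal <- -normal
  origin_row <- unname(1 + (fit$coefficients[1] +
                              slope * (lateral_pos - 1) * b$mm_lateral) /
                         b$mm_axial_optical)
  list(origin = c(origin_row, lateral_pos),
       direction = unname(normal),
       angle_deg = unname(atan2(abs(normal[2]), normal[1]) * 180 / pi))
}

bilinear_sample <- function(px, r, c) {
  nr <- nrow(px); nc <- ncol(px)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  px[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    px[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    px[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    px[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Sample a cylindrical-ruler intensity profile
#'
#' Walks from `origin` along `direction` in fixed steps and records, at each
#' step, the mean of bilinearly interpolated intensities over a disk of the
#' stated diameter centred on the ruler axis. In the 2-D b-scan plane the disk
#' reduces to a transverse segment of that width, sampled uniformly and
#' symmetrically about the axis. The profile is truncated where the axis
#' leaves the image.
#'
#' @param b A [bscan()].
#' @param origin `(row, col)` start point (fractional pixels allowed),
#'   typically the detected surface from [surface_normal()].
#' @param direction Unit vector `(axial, lateral)` in mm space.
#' @param disk_diameter_um Averaging disk diameter, micrometres.
#' @param step_um Step along the axis, micrometres (optical distance).
#' @return A `ruler_profile`: a tibble with `distance_mm` (optical distance
#'   along the axis) and `intensity`, carrying the b-scan geometry as
#'   attributes.
#' @export
ruler_profile <- function(b, origin, direction, disk_diameter_um = 100,
                          step_um = 10) {
  stopifnot(inherits(b, "bscan"), length(origin) == 2, length(direction) == 2)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) direction <- direction / nrm
  px <- b$pixels
  step_mm <- step_um / 1000
  radius_mm <- disk_diameter_um / 2000
  # transverse unit vector and symmetric sample offsets across the disk
  trans <- c(-direction[2], direction[1])
  n_off <- max(1L, ceiling(radius_mm / min(b$mm_axial_optical, b$mm_lateral)))
  offsets <- seq(-radius_mm, radius_mm, length.out = 2L * n_off + 1L)

  origin_mm <- c((origin[1] - 1) * b$mm_axial_optical,
                 (origin[2] - 1) * b$mm_lateral)
  max_mm <- c((nrow(px) - 1) * b$mm_axial_optical,
              (ncol(px) - 1) * b$mm_lateral)
  dist <- numeric(0)
  val <- numeric(0)
  d <- 0
  repeat {
    p <- origin_mm + d * direction
    if (p[1] < 0 || p[1] > max_mm[1] || p[2] < 0 || p[2] > max_mm[2]) break
    pts_ax <- p[1] + offsets * trans[1]
    pts_lat <- p[2] + offsets * trans[2]
    keep <- pts_ax >= 0 & pts_ax <= max_mm[1] &
      pts_lat >= 0 & pts_lat <= max_mm[2]
    if (!any(keep)) break
    v <- bilinear_sample(px, pts_ax[keep] / b$mm_axial_optical + 1,
                         pts_lat[keep] / b$mm_lateral + 1)
    dist <- c(dist, d)
    val <- c(val, mean(v))
    d <- d + step_mm
  }
  if (length(dist) == 0L) stop("ruler axis immediately exits the image")
  out <- tibble::tibble(distance_mm = dist, intensity = val)
  attr(out, "origin") <- origin
  attr(out, "direction") <- direction
  attr(out, "refractive_index") <- b$refractive_index
  attr(out, "step_mm") <- step_mm
  attr(out, "disk_diameter_um") <- disk_diameter_um
  class(out) <- c("ruler_profile", class(out))
  out
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  h <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# Local minima of a numeric vector; plateaus contribute their midpoint.
# Endpoints are never minima.
local_minima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  if (k < 3) return(integer(0))
  idx <- integer(0)
  for (i in 2:(k - 1)) {
    if (r$values[i] < r$values[i - 1] && r$values[i] < r$values[i + 1]) {
      idx <- c(idx, as.integer(round((starts[i] + ends[i]) / 2)))
    }
  }
  idx
}

#' Measure lesion depth from a ruler profile
#'
#' Identifies the two lowest local intensity minima along the (lightly
#' smoothed) ruler profile — these bracket the elevated-reflectivity lesion
#' band — and reports the axial distance between them, divided by the
#' refractive index to convert optical to physical depth. A prominence guard
#' requires the profile to rise by at least `prominence` above both minima in
#' between; this rejects the shallow modulation of enamel birefringence
#' banding so a band maximum is not mistaken for a lesion.
#'
#' @param profile A [ruler_profile()].
#' @param refractive_index Override for the profile's refractive index.
#' @param smooth_window Moving-average window (samples) applied before minima
#'   detection.
#' @param prominence Minimum rise between the two minima, as a fraction of
#'   the profile's intensity range (which makes the guard, and hence the
#'   depth, invariant to global intensity scaling).
#' @param correct_index If `FALSE`, report optical rather than physical depth.
#' @return A list of class `depth_measurement`: `detected`, `depth_mm`
#'   (physical, `NA` when no lesion is found), and `minima` (tibble of the two
#'   chosen minima with optical distances and intensities).
#' @export
measure_depth <- function(profile, refractive_index = NULL,
                          smooth_window = 3L, prominence = 0.1,
                          correct_index = TRUE) {
  stopifnot(inherits(profile, "ruler_profile"))
  n_idx <- refractive_index %||% attr(profile, "refractive_index") %||% 1.6
  x <- moving_average(profile$intensity, smooth_window)
  rng <- max(x) - min(x)
  if (rng < .Machine$double.eps^0.5 * max(abs(x), 1)) {
    stop("degenerate (constant) ruler profile")
  }
  x <- (x - min(x)) / rng
  no_lesion <- structure(
    list(detected = FALSE, depth_mm = NA_real_, minima = NULL),
    class = "depth_measurement"
  )
  mins <- local_minima(x)
  if (length(mins) < 2) return(no_lesion)
  two <- mins[order(x[mins])][1:2]
  two <- sort(two)
  between <- x[two[1]:two[2]]
  if (max(between) < max(x[two]) + prominence) return(no_lesion)
  # refine each minimum on the unsmoothed profile: smoothing biases the
  # location of a sharp dip by up to half the window
  raw <- profile$intensity
  h <- max(1L, smooth_window %/% 2L)
  two <- vapply(two, function(i) {
    w <- max(1L, i - h):min(length(raw), i + h)
    w[which.min(raw[w])]
  }, integer(1))
  two <- sort(two)
  d_opt <- abs(profile$distance_mm[two[2]] - profile$distance_mm[two[1]])
  structure(list(
    detected = TRUE,
    depth_mm = if (correct_index) d_opt / n_idx else d_opt,
    minima = tibble::tibble(distance_mm = profile$distance_mm[two],
                            intensity = profile$intensity[two]),
    refractive_index = n_idx
  ), class = "depth_measurement")
}

#' @export
print.depth_measurement <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("<depth_measurement> lesion depth %.3f mm (physical)\n",
                x$depth_mm))
  } else {
    cat("<depth_measurement> no lesion\n")
  }
  invisible(x)
}

#' End-to-end lesion depth on a b-scan
#'
#' Convenience chain: median-filter despeckle, surface detection and normal
#' fit at a lateral position, cylindrical-ruler profile along the normal, and
#' minima-pair depth measurement.
#'
#' @param b A [bscan()].
#' @param lateral_pos Lateral column of the ruler (defaults to mid-scan).
#' @param kernel Median-filter kernel (see [despeckle()]).
#' @param disk_diameter_um,step_um Ruler sampling (see [ruler_profile()]).
#' @param smooth_window,prominence Depth-measurement settings (see
#'   [measure_depth()]).
#' @param window,frac Surface-fit settings (see [surface_normal()]).
#' @return A `depth_measurement` (see [measure_depth()]).
#' @export
oct_lesion_depth <- function(b, lateral_pos = NULL, kernel = 3L,
                             disk_diameter_um = 100, step_um = 10,
                             smooth_window = 3L, prominence = 0.1,
                             window = 10L, frac = 0.5) {
  stopifnot(inherits(b, "bscan"))
  if (is.null(lateral_pos)) lateral_pos <- round(ncol(b$pixels) / 2)
  bf <- despeckle(b, kernel)
  sn <- surface_normal(bf, lateral_pos, window = window, frac = frac)
  prof <- ruler_profile(bf, sn$origin, sn$direction,
                        disk_diameter_um = disk_diameter_um,
                        step_um = step_um)
  measure_depth(prof, smooth_window = smooth_window, prominence = prominence)
}

#' Maximum physical imaging depth of a b-scan
#'
#' The axial scan range is an optical distance in air; inside enamel it is
#' compressed by the refractive index. A 7 mm air range at n = 1.6 reaches
#' 4.4 mm of enamel.
#'
#' @param b A [bscan()], or a numeric axial extent in mm (optical) combined
#'   with `refractive_index`.
#' @param refractive_index Used when `b` is a bare numeric extent.
#' @return Physical range in mm, reported to one decimal (half-up).
#' @export
#' @examples
#' max_physical_range(7, refractive_index = 1.6) # 4.4
max_physical_range <- function(b, refractive_index = 1.6) {
  if (inherits(b, "bscan")) {
    extent <- nrow(b$pixels) * b$mm_axial_optical
    n_idx <- b$refractive_index
  } else {
    extent <- b
    n_idx <- refractive_index
  }
  round_half_up(extent / n_idx, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
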