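#' Phantom configuration
#'
#' Describes a synthetic tooth-contact phantom with known ground truth. The
#' defaults define the package's reference study conditions: a 160 x 220 px
#' SWIR frame at 0.05 mm/px (a roughly 8 x 11 mm field of view), sound enamel
#' at 0.6 on a `[0, 1]` intensity scale, a half-elliptical lesion adjoining
#' the proximal contact, 0.5% additive sensor noise for SWIR frames and 15%
#' multiplicative speckle for OCT b-scans, enamel refractive index 1.6, and a
#' 7 mm (optical, in air) axial scan range over 512 axial pixels.
#'
#' @param image_height,image_width Frame size, pixels. OCT b-scans use
#'   `image_height` as the axial (depth) dimension.
#' @param mm_per_pixel Lateral physical scale, mm per pixel.
#' @param modality One of `"reflectance"`, `"occlusal_trans"`,
#'   `"proximal_trans"`, `"radiograph"`, `"oct_bscan"`.
#' @param sound_intensity Sound-enamel intensity in `(0, 1]`.
#' @param lesion_contrast_true Target lesion contrast `c_true` (dimensionless,
#'   `>= 0`). The generator places lesion pixels so that the matching contrast
#'   transform recovers exactly this value.
#' @param lesion_center `(row, col)` of the lesion ellipse centre, pixels.
#'   Defaults to the contact line at mid-height.
#' @param lesion_axes `(a, b)` semi-axes of the lesion ellipse in rows and
#'   columns, pixels. The lesion is clipped to the far side of the contact
#'   line (a half-ellipse), so `b` sets the penetration depth in pixels.
#' @param contact_line Column index of the proximal contact.
#' @param noise_sigma Noise level: additive Gaussian sd for SWIR/radiograph
#'   frames, multiplicative speckle sd for OCT. `NULL` picks the modality
#'   default (0.005 additive, 0.15 speckle).
#' @param specular_spots For reflectance: list of
#'   `list(center = c(row, col), radius, intensity)` specular highlights. Must
#'   sit at least 10 px from the contact ROI.
#' @param bleed_margin Border width, pixels, of the outside-tooth zone that
#'   carries direct-light bleed (transillumination) or dark background.
#' @param oct_attenuation Sound-enamel signal decay, 1/mm of physical depth.
#' @param oct_band_period Birefringence banding period, mm of physical depth.
#' @param oct_band_amp Relative amplitude of the banding modulation.
#' @param oct_lesion_depth_true Physical lesion depth, mm, between the two
#'   intensity minima flanking the lesion band. `NA` generates a lesion-free
#'   b-scan.
#' @param oct_lesion_top_mm Physical depth of the lesion top below the enamel
#'   surface, mm.
#' @param oct_axial_extent_mm Axial scan range, mm of optical path in air.
#' @param oct_surface_row Axial pixel row of the enamel surface.
#' @param oct_surface_slope Surface tilt, axial px per lateral px (for testing
#'   the surface-normal fit).
#' @param refractive_index Enamel refractive index (`>= 1`), used to convert
#'   optical to physical depth.
#' @param seed Integer seed; identical configurations generate bit-identical
#'   phantoms.
#'
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_height = 160L, image_width = 220L,
                           mm_per_pixel = 0.05,
                           modality = "reflectance",
                           sound_intensity = 0.6,
                           lesion_contrast_true = 0.2,
                           lesion_center = NULL,
                           lesion_axes = c(20L, 17L),
                           contact_line = NULL,
                           noise_sigma = NULL,
                           specular_spots = NULL,
                           bleed_margin = 12L,
                           oct_attenuation = 1.5,
                           oct_band_period = 0.5,
                           oct_band_amp = 0.1,
                           oct_lesion_depth_true = 1.069,
                           oct_lesion_top_mm = 0.3,
                           oct_axial_extent_mm = 7,
                           oct_surface_row = 40L,
                           oct_surface_slope = 0,
                           refractive_index = 1.6,
                           seed = 20240817L) {
  modality <- match.arg(modality, all_modalities)
  if (is.null(contact_line)) contact_line <- round(0.55 * image_width)
  if (is.null(lesion_center)) {
    lesion_center <- c(round(image_height / 2), contact_line)
  }
  if (is.null(noise_sigma)) {
    noise_sigma <- if (modality == "oct_bscan") 0.15 else 0.005
  }
  if (is.null(specular_spots) && modality == "reflectance") {
    specular_spots <- list(list(
      center = c(round(image_height / 4), round(image_width / 4)),
      radius = 7, intensity = 0.95
    ))
  }
  cfg <- structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    mm_per_pixel = mm_per_pixel, modality = modality,
    sound_intensity = sound_intensity,
    lesion_contrast_true = lesion_contrast_true,
    lesion_center = lesion_center, lesion_axes = lesion_axes,
    contact_line = as.integer(contact_line), noise_sigma = noise_sigma,
    specular_spots = specular_spots, bleed_margin = as.integer(bleed_margin),
    oct_attenuation = oct_attenuation, oct_band_period = oct_band_period,
    oct_band_amp = oct_band_amp,
    oct_lesion_depth_true = oct_lesion_depth_true,
    oct_lesion_top_mm = oct_lesion_top_mm,
    oct_axial_extent_mm = oct_axial_extent_mm,
    oct_surface_row = as.integer(oct_surface_row),
    oct_surface_slope = oct_surface_slope,
    refractive_index = refractive_index,
    seed = as.integer(seed)
  ), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (sound_intensity <= 0 || sound_intensity > 1) {
      stop("sound_intensity must lie in (0, 1]")
    }
    if (!is.na(lesion_contrast_true) && lesion_contrast_true < 0) {
      stop("lesion_contrast_true must be >= 0")
    }
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
    if (mm_per_pixel <= 0) stop("mm_per_pixel must be positive")
    if (refractive_index < 1) stop("refractive_index must be >= 1")
    if (modality != "oct_bscan" &&
        abs(lesion_center[2] - contact_line) > lesion_axes[2]) {
      stop("lesion ellipse must intersect the contact line")
    }
  })
  invisible(cfg)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

ellipse_mask <- function(h, w, center, axes) {
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2 <= 1
}

disk_mask <- function(h, w, center, radius) {
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# Chebyshev distance between two pixel sets (logical masks).
mask_distance <- function(a, b) {
  pa <- which(a, arr.ind = TRUE)
  pb <- which(b, arr.ind = TRUE)
  if (!nrow(pa) || !nrow(pb)) return(Inf)
  min(vapply(seq_len(nrow(pa)), function(i) {
    min(pmax(abs(pb[, 1] - pa[i, 1]), abs(pb[, 2] - pa[i, 2])))
  }, numeric(1)))
}

swir_phantom_geometry <- function(cfg) {
  h <- cfg$image_height; w <- cfg$image_width
  m <- cfg$bleed_margin
  tooth <- roi_rect(c(h, w), (m + 1):(h - m), (m + 1):(w - m))
  lesion_full <- ellipse_mask(h, w, cfg$lesion_center, cfg$lesion_axes)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  lesion <- lesion_full & cols >= cfg$contact_line & tooth
  a <- cfg$lesion_axes[1]
  contact_rows <- max(m + 11, cfg$lesion_center[1] - a - 15):
    min(h - m - 10, cfg$lesion_center[1] + a + 15)
  contact <- roi_rect(c(h, w), contact_rows, cfg$contact_line)
  sound_rows <- (cfg$lesion_center[1] - a - 25):(cfg$lesion_center[1] - a - 8)
  sound <- roi_rect(c(h, w), sound_rows,
                    (cfg$contact_line - 6):(cfg$contact_line + 6)) & tooth
  sound <- sound & !lesion & !contact
  list(tooth = tooth, lesion = lesion, contact = contact, sound = sound)
}

#' Generate a SWIR phantom with known ground truth
#'
#' Builds a synthetic tooth frame for reflectance or transillumination
#' imaging. Lesion pixels are placed so that the matching contrast transform
#' recovers `lesion_contrast_true` exactly: `I_s / (1 - c)` for reflectance
#' (lesions scatter more and appear bright) and `I_s * (1 - c)` for
#' transillumination (lesions attenuate and appear dark). Reflectance frames
#' carry bright specular-highlight artifacts and transillumination frames a
#' saturated direct-light bleed border, both away from the contact, so the
#' contact-adjacency selection rule is exercised. Gaussian noise is added and
#' the frame clipped to `[0, 1]`.
#'
#' @param config A [phantom_config()] with a SWIR modality.
#' @return A list of class `swir_phantom`: `image` (an [intensity_image()]),
#'   `truth` (lesion mask, `true_area_px`, `true_mean_contrast`,
#'   `true_depth_mm`, `contact_line`), and `roi` (an [roi_set()] with the
#'   sound-reference and contact regions the segmentation needs).
#' @export
#' @examples
#' ph <- make_swir_phantom(phantom_config(modality = "reflectance",
#'                                        lesion_contrast_true = 0.2,
#'                                        noise_sigma = 0))
#' ph$truth$true_mean_contrast
make_swir_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (!config$modality %in% swir_modalities) {
    stop("make_swir_phantom requires a SWIR modality (reflectance, ",
         "occlusal_trans, proximal_trans)")
  }
  cfg <- config
  cs <- cfg$lesion_contrast_true
  if (cfg$modality == "reflectance" && cs >= 1) {
    stop("reflectance phantoms require lesion_contrast_true < 1 ",
         "(lesion intensity I_s/(1 - c) is unbounded otherwise)")
  }
  h <- cfg$image_height; w <- cfg$image_width
  if (cfg$lesion_center[1] + cfg$lesion_axes[1] < 1 ||
      cfg$lesion_center[1] - cfg$lesion_axes[1] > h ||
      cfg$lesion_center[2] + cfg$lesion_axes[2] < 1 ||
      cfg$lesion_center[2] - cfg$lesion_axes[2] > w) {
    stop("lesion ellipse lies fully outside the image")
  }
  geo <- swir_phantom_geometry(cfg)

  px <- matrix(0.03, h, w)
  px[geo$tooth] <- cfg$sound_intensity
  lesion_value <- if (cfg$modality == "reflectance") {
    cfg$sound_intensity / (1 - cs)
  } else {
    cfg$sound_intensity * (1 - cs)
  }
  px[geo$lesion] <- lesion_value

  if (cfg$modality == "reflectance" && length(cfg$specular_spots)) {
    for (sp in cfg$specular_spots) {
      spot <- disk_mask(h, w, sp$center, sp$radius)
      if (mask_distance(spot, geo$contact) < 10) {
        stop("specular spots must sit at least 10 px from the contact ROI")
      }
      px[spot] <- sp$intensity
    }
  }
  if (is_transillumination(cfg$modality) && cfg$bleed_margin > 0) {
    bleed <- roi_rect(c(h, w), 1:h, 1:cfg$bleed_margin) |
      roi_rect(c(h, w), 1:h, (w - cfg$bleed_margin + 1):w)
    px[bleed] <- 1
  }

  if (cfg$noise_sigma > 0) {
    px <- with_seed(cfg$seed,
                    px + matrix(rnorm(h * w, 0, cfg$noise_sigma), h, w))
  }
  px <- pmin(pmax(px, 0), 1)

  truth <- list(
    lesion_mask = geo$lesion,
    true_area_px = sum(geo$lesion),
    true_mean_contrast = cs,
    true_depth_mm = length(unique(which(geo$lesion, arr.ind = TRUE)[, 2])) *
      cfg$mm_per_pixel,
    contact_line = cfg$contact_line
  )
  structure(list(
    image = intensity_image(px, cfg$modality, cfg$mm_per_pixel),
    truth = truth,
    roi = roi_set(geo$sound, geo$contact),
    config = cfg
  ), class = "swir_phantom")
}

#' Generate a radiograph phantom
#'
#' Radiographic lesions are radiolucent: lesion pixels are placed at
#' `I_s * (1 - c)` so that the radiographic contrast `(I_s - I_L) / I_s`
#' recovers `lesion_contrast_true`. The returned ROI set carries the
#' examiner-style lesion ROI plus a sound region directly above the lesion in
#' the same column band (the similar-enamel-thickness convention).
#'
#' @param config A [phantom_config()] with `modality = "radiograph"`.
#' @return A list of class `swir_phantom` (same layout as
#'   [make_swir_phantom()]), with `roi$lesion` set.
#' @export
make_radiograph_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"),
            config$modality == "radiograph")
  cfg <- config
  h <- cfg$image_height; w <- cfg$image_width
  geo <- swir_phantom_geometry(cfg)
  px <- matrix(0.1, h, w)
  px[geo$tooth] <- cfg$sound_intensity
  px[geo$lesion] <- cfg$sound_intensity * (1 - cfg$lesion_contrast_true)
  if (cfg$noise_sigma > 0) {
    px <- with_seed(cfg$seed,
                    px + matrix(rnorm(h * w, 0, cfg$noise_sigma), h, w))
  }
  px <- pmin(pmax(px, 0), 1)

  # sound reference directly above the lesion, same columns
  lcols <- sort(unique(which(geo$lesion, arr.ind = TRUE)[, 2]))
  top <- min(which(geo$lesion, arr.ind = TRUE)[, 1])
  sound <- roi_rect(c(h, w), (top - 20):(top - 6), lcols) & geo$tooth &
    !geo$contact & !geo$lesion
  truth <- list(
    lesion_mask = geo$lesion, true_area_px = sum(geo$lesion),
    true_mean_contrast = cfg$lesion_contrast_true,
    true_depth_mm = length(lcols) * cfg$mm_per_pixel,
    contact_line = cfg$contact_line
  )
  structure(list(
    image = intensity_image(px, "radiograph", cfg$mm_per_pixel),
    truth = truth,
    roi = roi_set(sound, geo$contact, lesion = geo$lesion),
    config = cfg
  ), class = "swir_phantom")
}

#' Generate a CP-OCT b-scan phantom
#'
#' Builds a synthetic b-scan (rows = axial optical depth, columns = lateral
#' position) with a bright enamel surface line, exponentially attenuating
#' sound-enamel signal, multiplicative sinusoidal birefringence banding, and
#' optionally an elevated-reflectivity subsurface lesion band whose two
#' flanking intensity minima are separated by `oct_lesion_depth_true` mm of
#' physical distance (the generator converts physical depth to optical pixels
#' with the refractive index). Speckle is multiplicative Gaussian noise.
#'
#' @param config A [phantom_config()] with `modality = "oct_bscan"`. Set
#'   `oct_lesion_depth_true = NA` for a lesion-free scan.
#' @return A list of class `oct_phantom`: `bscan` (a [bscan()]) and `truth`
#'   with `lesion_present`, `true_depth_mm`, the lesion lateral band, and the
#'   axial pixel rows of the two flanking minima.
#' @export
make_oct_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"),
            config$modality == "oct_bscan")
  cfg <- config
  h <- cfg$image_height; w <- cfg$image_width
  n_idx <- cfg$refractive_index
  mm_ax <- cfg$oct_axial_extent_mm / h # optical mm per axial pixel
  lesion_present <- !is.na(cfg$oct_lesion_depth_true)
  if (lesion_present &&
      cfg$oct_lesion_depth_true > cfg$oct_axial_extent_mm / n_idx) {
    stop(sprintf(
      "true lesion depth %.3f mm exceeds the physical scan range %.3f mm",
      cfg$oct_lesion_depth_true, cfg$oct_axial_extent_mm / n_idx
    ))
  }

  floor_i <- 0.08
  px <- matrix(0.06, h, w)
  surf_rows <- pmin(pmax(round(
    cfg$oct_surface_row + cfg$oct_surface_slope * (seq_len(w) - 1)
  ), 1L), h - 2L)

  lesion_cols <- if (lesion_present) {
    c0 <- round(w / 2)
    hw <- max(4L, round(w / 10))
    (c0 - hw):(c0 + hw)
  } else {
    integer(0)
  }
  # lesion band in axial pixels below the surface (physical -> optical)
  r_off1 <- round(cfg$oct_lesion_top_mm * n_idx / mm_ax)
  r_off2 <- r_off1 +
    round((if (lesion_present) cfg$oct_lesion_depth_true else 0) *
            n_idx / mm_ax)

  for (j in seq_len(w)) {
    s <- surf_rows[j]
    z_phys <- ((s:h) - s) * mm_ax / n_idx # physical depth below surface, mm
    prof <- floor_i + cfg$sound_intensity * exp(-cfg$oct_attenuation * z_phys) *
      (1 + cfg$oct_band_amp * sin(2 * pi * z_phys / cfg$oct_band_period))
    prof[1:min(3, length(prof))] <- 0.95 # surface echo
    if (j %in% lesion_cols) {
      r1 <- r_off1 + 1L
      r2 <- min(r_off2 + 1L, length(prof))
      if (r2 > r1 + 1L) {
        # elevated-reflectivity bump between the flanking minima
        t <- (seq(r1, r2) - r1) / (r2 - r1)
        prof[r1:r2] <- pmax(prof[r1:r2],
                            0.02 + (0.75 - 0.02) * sin(pi * t))
        # demineralization front and lesion floor: V-shaped dark notches a
        # few pixels wide, so the dips survive the kernel-3 median filter
        for (r0 in c(r1, r2)) {
          o <- max(1, r0 - 2):min(length(prof), r0 + 2)
          prof[o] <- pmin(prof[o], 0.02 + 0.012 * abs(o - r0))
        }
      }
    }
    px[s:h, j] <- prof
  }

  if (cfg$noise_sigma > 0) {
    px <- with_seed(cfg$seed,
                    px * (1 + matrix(rnorm(h * w, 0, cfg$noise_sigma), h, w)))
  }
  px <- pmin(pmax(px, 0), 1)

  lesion_mask <- matrix(FALSE, h, w)
  if (lesion_present) {
    for (j in lesion_cols) {
      lesion_mask[(surf_rows[j] + r_off1):(surf_rows[j] + r_off2), j] <- TRUE
    }
  }
  truth <- list(
    lesion_present = lesion_present,
    lesion_mask = lesion_mask,
    true_depth_mm = if (lesion_present) cfg$oct_lesion_depth_true else NA_real_,
    lesion_cols = lesion_cols,
    minima_rows_offset = c(r_off1, r_off2),
    surface_rows = surf_rows
  )
  structure(list(
    bscan = bscan(px, mm_axial_optical = mm_ax, mm_lateral = cfg$mm_per_pixel,
                  refractive_index = n_idx),
    truth = truth,
    config = cfg
  ), class = "oct_phantom")
}

#' Write a phantom to disk (16-bit TIFF + JSON sidecar)
#'
#' The image goes to `<stem>.tif` and the configuration plus ground truth to
#' `<stem>.json` (masks serialized as pixel coordinate lists).
#'
#' @param phantom A `swir_phantom` or `oct_phantom`.
#' @param dir Output directory (created if needed).
#' @param stem File stem.
#' @return The TIFF path, invisibly.
#' @export
write_phantom <- function(phantom, dir, stem = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".tif"))
  px <- if (inherits(phantom, "oct_phantom")) phantom$bscan$pixels
        else phantom$image$pixels
  write_intensity_image(px, img_path)
  truth <- phantom$truth
  truth$lesion_mask <- mask_to_coords(truth$lesion_mask)
  cfg <- unclass(phantom$config)
  jsonlite::write_json(
    list(config = cfg, truth = truth, dim = dim(px)),
    file.path(dir, paste0(stem, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(img_path)
}
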