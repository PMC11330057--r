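#' Study configuration for the synthetic end-to-end pipeline
#'
#' Collects every tunable of the synthetic study in one place. The defaults
#' are the package's reference conditions: 29 contacts (58 lesion surfaces),
#' the 0.1 contrast detection threshold, median-filter kernel 3, a 100 µm
#' ruler disk, enamel refractive index 1.6, and alpha 0.05. Per-method lesion
#' contrast and depth distributions, and per-surface-group detection
#' probabilities, parameterise how severe and how conspicuous the simulated
#' lesions are for each imaging method.
#'
#' @param n_contacts Number of proximal contacts (each contributes a restored
#'   and an opposing surface).
#' @param seed Integer master seed; everything downstream derives from it.
#' @param contrast_threshold SWIR detection threshold on the contrast map.
#' @param median_kernel Median-filter kernel for OCT despeckling.
#' @param disk_um Ruler averaging-disk diameter, micrometres.
#' @param refractive_index Enamel refractive index.
#' @param alpha Significance level.
#' @param swir_size,oct_size Phantom frame sizes `c(rows, cols)`.
#' @param mm_per_pixel Lateral scale of the SWIR phantoms, mm/px.
#' @param method_contrast Named list of `c(mean, sd)` lesion contrast per
#'   method.
#' @param method_depth_um Named list of `c(mean, sd)` lesion depth per
#'   method, micrometres.
#' @param detect_prob Named list of `c(restored, opposing)` probabilities
#'   that a lesion presents detectably to each method.
#' @param out_dir Optional output directory for the report bundle.
#' @param overrides Named list applied over the defaults (each override is
#'   reported via `message()` as an audit trail).
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_contacts = 29L, seed = 20240817L,
                         contrast_threshold = 0.1, median_kernel = 3L,
                         disk_um = 100, refractive_index = 1.6, alpha = 0.05,
                         swir_size = c(160L, 220L), oct_size = c(512L, 120L),
                         mm_per_pixel = 0.05,
                         method_contrast = list(
                           radiograph = c(0.13, 0.064),
                           swir_r = c(0.22, 0.063),
                           swir_ot = c(0.20, 0.010),
                           swir_pt = c(0.27, 0.013)
                         ),
                         method_depth_um = list(
                           radiograph = c(851, 422), oct = c(1069, 363),
                           swir_r = c(830, 379), swir_ot = c(1049, 514),
                           swir_pt = c(289, 189)
                         ),
                         detect_prob = list(
                           radiograph = c(restored = 0.93, opposing = 0.38),
                           oct = c(restored = 0.83, opposing = 0.76),
                           visual_before = c(restored = 0.10, opposing = 0),
                           visual_after = c(restored = NA, opposing = 0.86),
                           swir_r = c(restored = 0.90, opposing = 0.93),
                           swir_ot = c(restored = 0.76, opposing = 0.72),
                           swir_pt = c(restored = 0.93, opposing = 0.86)
                         ),
                         out_dir = NULL, overrides = NULL) {
  cfg <- list(
    n_contacts = as.integer(n_contacts), seed = as.integer(seed),
    contrast_threshold = contrast_threshold,
    median_kernel = as.integer(median_kernel), disk_um = disk_um,
    refractive_index = refractive_index, alpha = alpha,
    swir_size = as.integer(swir_size), oct_size = as.integer(oct_size),
    mm_per_pixel = mm_per_pixel,
    method_contrast = method_contrast, method_depth_um = method_depth_um,
    detect_prob = detect_prob, out_dir = out_dir
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      message(sprintf("study_config override: %s", nm))
    }
    cfg <- modifyList(cfg, overrides)
  }
  structure(cfg, class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Entries in the file override the [study_config()] defaults; every
#' override is logged.
#'
#' @param path YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_study_config requires the yaml package")
  }
  study_config(overrides = yaml::read_yaml(path))
}

# Truncated normal draw by inverse-CDF sampling (no rejection loop).
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) return(rep(pmin(pmax(mean, lo), hi), n))
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

simulate_swir_surface <- function(cfg, method, surface, phantom_seed) {
  modality <- switch(method, swir_r = "reflectance",
                     swir_ot = "occlusal_trans", swir_pt = "proximal_trans")
  p_det <- cfg$detect_prob[[method]][[surface]]
  mc <- cfg$method_contrast[[method]]
  md <- cfg$method_depth_um[[method]]
  # lesion severity: detectable lesions sit above the reference 0.1
  # contrast, undetectable ones below it (the mixture sets the method's
  # expected detection rate); the segmentation threshold itself is applied
  # downstream, never here
  presents <- runif(1) < p_det
  c_true <- if (presents) {
    rnorm_trunc(1, mc[1], mc[2], lo = 0.12, hi = 0.6)
  } else {
    runif(1, 0.02, 0.08)
  }
  depth_um <- rnorm_trunc(1, md[1], md[2], lo = 150, hi = 2500)
  b_px <- max(3L, min(round(depth_um / 1000 / cfg$mm_per_pixel),
                      cfg$swir_size[2] %/% 4))
  ph <- make_swir_phantom(phantom_config(
    image_height = cfg$swir_size[1], image_width = cfg$swir_size[2],
    mm_per_pixel = cfg$mm_per_pixel, modality = modality,
    lesion_contrast_true = c_true, lesion_axes = c(20L, b_px),
    seed = phantom_seed
  ))
  seg <- segment_lesion(ph$image, ph$roi, threshold = cfg$contrast_threshold)
  tibble::tibble(
    method = method, detected = seg$detected,
    contrast = if (seg$detected) seg$mean_contrast else NA_real_,
    depth_um = if (seg$detected) seg$depth_mm * 1000 else NA_real_
  )
}

simulate_oct_surface <- function(cfg, surface, phantom_seed) {
  p_det <- cfg$detect_prob$oct[[surface]]
  presents <- runif(1) < p_det
  depth_mm <- if (presents) {
    rnorm_trunc(1, cfg$method_depth_um$oct[1] / 1000,
                cfg$method_depth_um$oct[2] / 1000, lo = 0.3, hi = 2.4)
  } else {
    NA_real_
  }
  ph <- make_oct_phantom(phantom_config(
    image_height = cfg$oct_size[1], image_width = cfg$oct_size[2],
    mm_per_pixel = cfg$mm_per_pixel, modality = "oct_bscan",
    oct_lesion_depth_true = depth_mm,
    refractive_index = cfg$refractive_index, seed = phantom_seed
  ))
  dm <- oct_lesion_depth(ph$bscan, kernel = cfg$median_kernel,
                         disk_diameter_um = cfg$disk_um)
  tibble::tibble(
    method = "oct", detected = dm$detected,
    contrast = NA_real_,
    depth_um = if (dm$detected) dm$depth_mm * 1000 else NA_real_
  )
}

simulate_radiograph_surface <- function(cfg, surface, phantom_seed) {
  p_det <- cfg$detect_prob$radiograph[[surface]]
  mc <- cfg$method_contrast$radiograph
  md <- cfg$method_depth_um$radiograph
  examiner_call <- runif(1) < p_det
  c_true <- rnorm_trunc(1, mc[1], mc[2], lo = 0.02, hi = 0.6)
  depth_um <- rnorm_trunc(1, md[1], md[2], lo = 150, hi = 2500)
  b_px <- max(3L, min(round(depth_um / 1000 / cfg$mm_per_pixel),
                      cfg$swir_size[2] %/% 4))
  ph <- make_radiograph_phantom(phantom_config(
    image_height = cfg$swir_size[1], image_width = cfg$swir_size[2],
    mm_per_pixel = cfg$mm_per_pixel, modality = "radiograph",
    lesion_contrast_true = c_true, lesion_axes = c(20L, b_px),
    seed = phantom_seed
  ))
  meas <- radiograph_contrast(ph$image, ph$roi)
  tibble::tibble(
    method = "radiograph", detected = examiner_call,
    contrast = if (examiner_call) meas$contrast else NA_real_,
    depth_um = if (examiner_call) ph$truth$true_depth_mm * 1000 else NA_real_
  )
}

simulate_visual_surface <- function(method, cfg, surface) {
  p_det <- cfg$detect_prob[[method]][[surface]]
  tibble::tibble(
    method = method,
    detected = if (is.na(p_det)) NA else runif(1) < p_det,
    contrast = NA_real_, depth_um = NA_real_
  )
}

#' Simulate the full synthetic study
#'
#' Generates `n_contacts` proximal contacts, each with a restored and an
#' opposing lesion surface, images every surface with every modality via the
#' phantom generators, runs the package's own detection pipelines (contrast
#' segmentation for the SWIR methods, the cylindrical-ruler depth measurement
#' for CP-OCT), simulates the examiner calls for radiography and visual
#' inspection, and assembles everything into a [detection_table()].
#'
#' @param config A [study_config()].
#' @return A `detection_table` tibble.
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_phantoms <- cfg$n_contacts * 2L * 5L
    seeds <- sample.int(.Machine$integer.max - 1L, n_phantoms)
    idx <- 0L
    rows <- list()
    for (contact in seq_len(cfg$n_contacts)) {
      for (surface in c("restored", "opposing")) {
        res <- list()
        for (method in c("swir_r", "swir_ot", "swir_pt")) {
          idx <- idx + 1L
          res[[method]] <- simulate_swir_surface(cfg, method, surface,
                                                 seeds[idx])
        }
        idx <- idx + 1L
        res$oct <- simulate_oct_surface(cfg, surface, seeds[idx])
        idx <- idx + 1L
        res$radiograph <- simulate_radiograph_surface(cfg, surface,
                                                      seeds[idx])
        res$visual_before <- simulate_visual_surface("visual_before", cfg,
                                                     surface)
        res$visual_after <- simulate_visual_surface("visual_after", cfg,
                                                    surface)
        rows[[length(rows) + 1L]] <- dplyr::bind_rows(res) |>
          dplyr::mutate(contact_id = contact, surface = surface,
                        .before = 1)
      }
    }
    detection_table(dplyr::bind_rows(rows))
  })
}

fit_stat <- function(fit, methods, what) {
  blank <- if (what == "letters") NA_character_ else NA_real_
  vapply(methods, function(m) {
    if (!is.null(fit) && m %in% fit$methods) fit[[what]][[m]] else blank
  }, blank)
}

#' Run the full pipeline and assemble a summary report
#'
#' Executes the synthetic study end to end: phantom generation, segmentation
#' and OCT depth measurement, detection-rate computation, Fisher comparisons
#' against radiography, and repeated-measures ANOVA on lesion contrast and
#' depth with compact letter displays. When `config$out_dir` is set, the
#' detection table, rate summary, and report are written as CSV/JSON. The
#' result is fully reproducible from the configuration (including its seed).
#'
#' @param config A [study_config()].
#' @return A list of class `study_report`: `table` (the detection table),
#'   `rates`, `fisher` (comparisons vs radiography), `anova_contrast`,
#'   `anova_depth`, `report` (a Table-1-style summary tibble), and
#'   `n_surfaces`.
#' @export
run_all <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  tbl <- simulate_study(config)
  rates <- detection_rates(tbl)
  fisher <- compare_detection(tbl, reference = "radiograph",
                              alpha = config$alpha)
  contrast_methods <- c("radiograph", "swir_r", "swir_ot", "swir_pt")
  depth_methods <- c("radiograph", "oct", "swir_r", "swir_ot", "swir_pt")
  # small studies may not retain enough complete cases for the
  # repeated-measures comparison; the report then omits it
  try_anova <- function(measure, methods) {
    tryCatch(
      rm_anova(tbl, measure, methods = methods, alpha = config$alpha),
      error = function(e) {
        message(sprintf("repeated-measures comparison of %s skipped: %s",
                        measure, conditionMessage(e)))
        NULL
      }
    )
  }
  anova_contrast <- try_anova("contrast", contrast_methods)
  anova_depth <- try_anova("depth_um", depth_methods)
  methods <- unique(tbl$method)
  report <- tibble::tibble(method = methods) |>
    dplyr::left_join(
      tidyr::pivot_wider(rates, names_from = "group",
                         values_from = c("n", "k_detected", "rate")),
      by = "method"
    ) |>
    dplyr::mutate(
      contrast_mean = fit_stat(anova_contrast, methods, "means"),
      contrast_sd = fit_stat(anova_contrast, methods, "sds"),
      contrast_letter = fit_stat(anova_contrast, methods, "letters"),
      depth_mean_um = fit_stat(anova_depth, methods, "means"),
      depth_sd_um = fit_stat(anova_depth, methods, "sds"),
      depth_letter = fit_stat(anova_depth, methods, "letters")
    )
  out <- structure(list(
    table = tbl, rates = rates, fisher = fisher,
    anova_contrast = anova_contrast, anova_depth = anova_depth,
    report = report,
    n_surfaces = nrow(dplyr::distinct(tbl, .data$contact_id, .data$surface)),
    config = config
  ), class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(out, config$out_dir)
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d contacts, %d lesion surfaces\n",
              x$config$n_contacts, x$n_surfaces))
  print(x$report)
  invisible(x)
}

#' Write a study report bundle to disk
#'
#' Writes `detection_table.csv`, `rates.csv`, `report.csv`, and a
#' `summary.json` with the statistical results.
#'
#' @param report A `study_report` from [run_all()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$table, file.path(dir, "detection_table.csv"),
            row.names = FALSE)
  write.csv(report$rates, file.path(dir, "rates.csv"), row.names = FALSE)
  write.csv(report$report, file.path(dir, "report.csv"), row.names = FALSE)
  fit_json <- function(fit) {
    if (is.null(fit)) return(NULL)
    c(glance(fit), list(letters = as.list(fit$letters)))
  }
  jsonlite::write_json(list(
    n_surfaces = report$n_surfaces,
    fisher = report$fisher,
    anova_contrast = fit_json(report$anova_contrast),
    anova_depth = fit_json(report$anova_depth)
  ), file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
  invisible(dir)
}

#' Simulate within-subject contrast values at fixed method means
#'
#' Draws a complete-case repeated-measures data set: each subject (a
#' contact-surface) gets one contrast value per method, equal to the method
#' mean plus a shared subject effect plus within-subject noise. Used to study
#' which significance letter patterns the repeated-measures comparison
#' recovers under the reference conditions.
#'
#' @param n_subjects Number of complete cases.
#' @param means Named method means.
#' @param sigma Within-subject (residual) noise sd.
#' @param subject_sd Between-subject (lesion severity) sd.
#' @return A [detection_table()] with one contrast value per subject and
#'   method.
#' @export
simulate_contrast_values <- function(n_subjects = 26L,
                                     means = c(radiograph = 0.13,
                                               swir_r = 0.22,
                                               swir_ot = 0.20,
                                               swir_pt = 0.27),
                                     sigma = 0.03, subject_sd = 0.05) {
  k <- length(means)
  subj <- rnorm(n_subjects, 0, subject_sd)
  grid <- tidyr::expand_grid(subject = seq_len(n_subjects),
                             method = names(means))
  grid$contrast <- means[grid$method] + subj[grid$subject] +
    rnorm(nrow(grid), 0, sigma)
  # subjects here are individual contact-surfaces (a complete-case set may
  # hold an odd number of surfaces), so the both-surfaces design check is
  # waived
  detection_table(tibble::tibble(
    contact_id = (grid$subject + 1L) %/% 2L,
    surface = ifelse(grid$subject %% 2L == 1L, "restored", "opposing"),
    method = grid$method, detected = TRUE, contrast = grid$contrast,
    depth_um = NA_real_
  ), complete_contacts = FALSE)
}

#' Letter-pattern recovery rate over replicate simulated studies
#'
#' Repeats [simulate_contrast_values()] plus [rm_anova()] and reports the
#' fraction of replicates whose compact letter display matches a target
#' pattern (by default: radiography alone in the lowest group, SWIR-R and
#' SWIR-OT sharing a middle letter, SWIR-PT alone on top).
#'
#' @param n_rep Number of replicate studies.
#' @param n_subjects,means,sigma,subject_sd Passed to
#'   [simulate_contrast_values()].
#' @param target Named character vector of expected letters.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return A list: `recovery` (fraction of replicates matching) and
#'   `n_rep`.
#' @export
contrast_letter_recovery <- function(n_rep = 500L, n_subjects = 26L,
                                     means = c(radiograph = 0.13,
                                               swir_r = 0.22,
                                               swir_ot = 0.20,
                                               swir_pt = 0.27),
                                     sigma = 0.03, subject_sd = 0.05,
                                     target = c(radiograph = "a",
                                                swir_r = "b",
                                                swir_ot = "b",
                                                swir_pt = "c"),
                                     alpha = 0.05, seed = 20240817L) {
  with_seed(seed, {
    hits <- vapply(seq_len(n_rep), function(i) {
      tbl <- simulate_contrast_values(n_subjects, means, sigma, subject_sd)
      fit <- rm_anova(tbl, "contrast", methods = names(means), alpha = alpha)
      identical(unname(fit$letters[names(target)]), unname(target))
    }, logical(1))
    list(recovery = mean(hits), n_rep = n_rep)
  })
}
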