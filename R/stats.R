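#' Assemble a detection table
#'
#' The tidy carrier for per-surface results: one row per contact, surface,
#' and imaging method, with the method's call (`detected`), lesion contrast,
#' and lesion depth in micrometres (either may be missing, e.g. when a method
#' did not detect the lesion). Every contact contributes a restored and an
#' opposing surface.
#'
#' @param x A data frame with columns `contact_id`, `surface`
#'   (`"restored"`/`"opposing"`), `method`, `detected` (logical, may be `NA`),
#'   and optionally `contrast` and `depth_um`.
#' @param complete_contacts Require every contact to contribute both surfaces
#'   (the study design invariant). Disable for tables that hold a filtered
#'   subset of surfaces, e.g. complete cases only.
#' @return A tibble of class `detection_table`.
#' @export
detection_table <- function(x, complete_contacts = TRUE) {
  x <- tibble::as_tibble(x)
  need <- c("contact_id", "surface", "method", "detected")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(x$surface %in% c("restored", "opposing"))) {
    stop("surface must be 'restored' or 'opposing'")
  }
  if (!"contrast" %in% names(x)) x$contrast <- NA_real_
  if (!"depth_um" %in% names(x)) x$depth_um <- NA_real_
  if (complete_contacts) {
    bad <- x |>
      dplyr::distinct(.data$contact_id, .data$surface) |>
      dplyr::count(.data$contact_id) |>
      dplyr::filter(.data$n != 2L)
    if (nrow(bad)) {
      stop("every contact must contribute exactly two surfaces; offending: ",
           paste(bad$contact_id, collapse = ", "))
    }
  }
  class(x) <- c("detection_table", class(x))
  x
}

#' Detection rates per method and surface group
#'
#' The detection rate is the fraction of lesion-positive surfaces on which a
#' method registers a lesion (every surface in the study design is a true
#' positive). Missing calls are excluded from both numerator and
#' denominator. Rates are rounded half-up to two decimals for reporting.
#'
#' @param tbl A [detection_table()].
#' @return A tibble with `method`, `group` (`all`, `restored`, `opposing`),
#'   `n`, `k_detected`, `rate`.
#' @export
detection_rates <- function(tbl) {
  stopifnot(inherits(tbl, "detection_table"))
  if (!nrow(tbl)) stop("detection table is empty")
  one <- function(d, label) {
    d |>
      dplyr::filter(!is.na(.data$detected)) |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(n = dplyr::n(), k_detected = sum(.data$detected),
                       .groups = "drop") |>
      dplyr::mutate(group = label,
                    rate = round_half_up(.data$k_detected / .data$n, 2))
  }
  dplyr::bind_rows(
    one(tbl, "all"),
    one(dplyr::filter(tbl, .data$surface == "restored"), "restored"),
    one(dplyr::filter(tbl, .data$surface == "opposing"), "opposing")
  ) |>
    dplyr::select("method", "group", "n", "k_detected", "rate")
}

#' Two-sided Fisher's exact test on two detection counts
#'
#' Compares `k1/n1` detected against `k2/n2` with the two-sided Fisher exact
#' test (the two-sided p-value is the sum of the probabilities of all tables,
#' under fixed margins, no more probable than the observed one).
#'
#' @param k1,n1 Detections and surfaces for the first method.
#' @param k2,n2 Detections and surfaces for the second method.
#' @return The p-value.
#' @export
#' @examples
#' fisher_exact(11, 29, 27, 29) < 0.05
fisher_exact <- function(k1, n1, k2, n2) {
  v <- c(k1, n1, k2, n2)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers")
  }
  if (k1 > n1 || k2 > n2) stop("k must not exceed n")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Compare each method's detection rate against a reference method
#'
#' Runs [fisher_exact()] per method and surface group against the reference
#' (radiography by default).
#'
#' @param tbl A [detection_table()].
#' @param reference Reference method name.
#' @param alpha Significance level.
#' @return A tibble with counts, p-values, and `significant`.
#' @export
compare_detection <- function(tbl, reference = "radiograph", alpha = 0.05) {
  rates <- detection_rates(tbl)
  ref <- dplyr::filter(rates, .data$method == reference)
  if (!nrow(ref)) stop("reference method not present: ", reference)
  rates |>
    dplyr::filter(.data$method != reference) |>
    dplyr::inner_join(ref, by = "group", suffix = c("", "_ref")) |>
    dplyr::mutate(
      p_value = purrr::pmap_dbl(
        list(.data$k_detected, .data$n, .data$k_detected_ref, .data$n_ref),
        fisher_exact
      ),
      significant = .data$p_value < alpha
    ) |>
    dplyr::select("method", "group", "n", "k_detected", "rate",
                  "k_detected_ref", "n_ref", "rate_ref", "p_value",
                  "significant")
}

complete_case_wide <- function(tbl, measure, methods = NULL) {
  col <- match.arg(measure, c("contrast", "depth_um"))
  d <- tbl |>
    dplyr::mutate(subject = paste(.data$contact_id, .data$surface,
                                  sep = ":")) |>
    dplyr::select("subject", "method", dplyr::all_of(col))
  if (!is.null(methods)) d <- dplyr::filter(d, .data$method %in% methods)
  wide <- tidyr::pivot_wider(d, names_from = "method",
                             values_from = dplyr::all_of(col))
  wide[complete.cases(wide), ]
}

#' One-way repeated-measures ANOVA across imaging methods
#'
#' Compares lesion contrast (or depth) across methods with each
#' contact-surface as its own subject. Subjects with a missing value in any
#' compared method are removed first (complete-case analysis), then the
#' classical one-way repeated-measures decomposition is computed: total sum
#' of squares split into subject, method, and residual components, with
#' `F = MS_method / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom. Pairwise post-hoc comparisons use the Tukey studentized range on
#' the repeated-measures error term by default (Bonferroni-adjusted paired
#' contrasts are available), and a compact letter display summarises the
#' significance pattern, letters assigned in ascending order of method means.
#'
#' @param tbl A [detection_table()].
#' @param measure `"contrast"` or `"depth_um"`.
#' @param methods Optional subset of methods to compare (default: all methods
#'   with any non-missing value of the measure).
#' @param alpha Significance level for the letter display.
#' @param adjust `"tukey"` (default) or `"bonferroni"`.
#' @return An object of class `rm_anova`; see [tidy.rm_anova()] and
#'   [glance.rm_anova()].
#' @export
rm_anova <- function(tbl, measure = c("contrast", "depth_um"),
                     methods = NULL, alpha = 0.05,
                     adjust = c("tukey", "bonferroni")) {
  stopifnot(inherits(tbl, "detection_table"))
  measure <- match.arg(measure)
  adjust <- match.arg(adjust)
  if (is.null(methods)) {
    methods <- tbl |>
      dplyr::filter(!is.na(.data[[measure]])) |>
      dplyr::pull(.data$method) |>
      unique()
  }
  if (length(methods) < 2) stop("need at least 2 methods to compare")
  wide <- complete_case_wide(tbl, measure, methods)
  n <- nrow(wide)
  if (n < 3) stop("fewer than 3 complete cases after missing-value removal")
  y <- as.matrix(wide[, methods, drop = FALSE])
  k <- length(methods)
  grand <- mean(y)
  m_means <- colMeans(y)
  s_means <- rowMeans(y)
  ss_total <- sum((y - grand)^2)
  ss_method <- n * sum((m_means - grand)^2)
  ss_subject <- k * sum((s_means - grand)^2)
  ss_error <- max(0, ss_total - ss_method - ss_subject)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_method <- ss_method / df1
  ms_error <- ss_error / df2
  eps <- .Machine$double.eps * max(1, ss_total)
  if (ss_method <= eps) {
    f_stat <- 0
    p <- 1
  } else if (ms_error <= eps) {
    f_stat <- Inf
    p <- 0
  } else {
    f_stat <- ms_method / ms_error
    p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  }

  pairs <- utils::combn(methods, 2)
  pair_p <- vapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    diff <- abs(m_means[a] - m_means[b])
    if (diff <= eps) return(1)
    if (ms_error <= eps) return(0)
    if (adjust == "tukey") {
      q <- diff / sqrt(ms_error / n)
      ptukey(q, k, df2, lower.tail = FALSE)
    } else {
      t_stat <- diff / sqrt(2 * ms_error / n)
      min(1, 2 * stats::pt(t_stat, df2, lower.tail = FALSE) * ncol(pairs))
    }
  }, numeric(1))
  pairwise <- tibble::tibble(
    method1 = pairs[1, ], method2 = pairs[2, ],
    diff = m_means[pairs[1, ]] - m_means[pairs[2, ]],
    p_value = pair_p, significant = pair_p < alpha
  )
  pmat <- matrix(1, k, k, dimnames = list(methods, methods))
  for (i in seq_len(nrow(pairwise))) {
    pmat[pairwise$method1[i], pairwise$method2[i]] <- pairwise$p_value[i]
    pmat[pairwise$method2[i], pairwise$method1[i]] <- pairwise$p_value[i]
  }
  letters <- letter_groups(pmat, alpha = alpha, means = m_means)

  structure(list(
    measure = measure, methods = methods, n_complete = n,
    means = m_means, sds = apply(y, 2, sd),
    ss = c(method = ss_method, subject = ss_subject, error = ss_error,
           total = ss_total),
    df = c(method = df1, error = df2),
    f_statistic = f_stat, p_value = p,
    pairwise = pairwise, letters = letters,
    alpha = alpha, adjust = adjust
  ), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "<rm_anova> %s across %d methods, n = %d complete cases\n",
    x$measure, length(x$methods), x$n_complete
  ))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df["method"], x$df["error"], x$f_statistic, x$p_value))
  cat("  ", paste(sprintf("%s %.3g (%s)", x$methods, x$means[x$methods],
                          x$letters[x$methods]), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy pairwise comparisons of an rm_anova fit
#'
#' @param x An [rm_anova()] object.
#' @param ... Unused.
#' @return A tibble of pairwise contrasts with adjusted p-values.
#' @export
tidy.rm_anova <- function(x, ...) x$pairwise

#' One-row summary of an rm_anova fit
#'
#' @param x An [rm_anova()] object.
#' @param ... Unused.
#' @return A one-row tibble with the F statistic, degrees of freedom,
#'   p-value, and complete-case count.
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    measure = x$measure, statistic = x$f_statistic,
    df = x$df[["method"]], df_error = x$df[["error"]],
    p_value = x$p_value, n_complete = x$n_complete,
    n_methods = length(x$methods)
  )
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Methods share a letter exactly when every pairwise comparison within the
#' lettered set is non-significant (`p > alpha`). Letter groups are the
#' maximal cliques of the non-significance graph, ordered by the method means
#' so that `"a"` marks the lowest group.
#'
#' @param pairwise_p Symmetric matrix of pairwise p-values with method names
#'   as dimnames.
#' @param alpha Significance level.
#' @param means Optional named method means used to order the letters.
#' @return Named character vector of letter codes.
#' @export
#' @examples
#' p <- matrix(c(1, .5, .01, .5, 1, .5, .01, .5, 1), 3,
#'             dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
#' letter_groups(p) # x "a", y "ab", z "b"
letter_groups <- function(pairwise_p, alpha = 0.05, means = NULL) {
  stopifnot(is.matrix(pairwise_p), nrow(pairwise_p) == ncol(pairwise_p))
  if (max(abs(pairwise_p - t(pairwise_p))) > 1e-12) {
    stop("pairwise_p must be symmetric")
  }
  k <- nrow(pairwise_p)
  if (k > 16) stop("letter display supports at most 16 methods")
  nms <- rownames(pairwise_p) %||% as.character(seq_len(k))
  adj <- pairwise_p > alpha
  diag(adj) <- TRUE
  subsets <- lapply(seq_len(2^k - 1), function(b) which(bitwAnd(b, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) all(adj[s, s]), logical(1))
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(o) {
      length(o) > length(cliques[[i]]) && all(cliques[[i]] %in% o)
    }, logical(1)))
  }, logical(1))]
  ord <- if (!is.null(means)) {
    order(vapply(maximal, function(s) mean(means[nms[s]]), numeric(1)))
  } else {
    order(vapply(maximal, min, numeric(1)))
  }
  maximal <- maximal[ord]
  out <- stats::setNames(rep("", k), nms)
  for (i in seq_along(maximal)) {
    out[maximal[[i]]] <- paste0(out[maximal[[i]]], letters[i])
  }
  out
}

#' Mixed-effects cross-check of the repeated-measures comparison
#'
#' Fits `measure ~ method + (1 | subject)` with lme4 and extracts
#' Tukey-adjusted pairwise comparisons with emmeans. Unlike [rm_anova()] this
#' model tolerates missing values; it is a verification path for the primary
#' repeated-measures analysis, not a replacement.
#'
#' @inheritParams rm_anova
#' @return A tibble of pairwise contrasts with adjusted p-values.
#' @export
mixed_effects_check <- function(tbl, measure = c("contrast", "depth_um"),
                                methods = NULL) {
  if (!requireNamespace("lme4", quietly = TRUE) ||
      !requireNamespace("emmeans", quietly = TRUE)) {
    stop("mixed_effects_check requires the lme4 and emmeans packages")
  }
  measure <- match.arg(measure)
  d <- tbl |>
    dplyr::mutate(subject = paste(.data$contact_id, .data$surface,
                                  sep = ":")) |>
    dplyr::filter(!is.na(.data[[measure]]))
  if (!is.null(methods)) d <- dplyr::filter(d, .data$method %in% methods)
  d$value <- d[[measure]]
  fit <- lme4::lmer(value ~ method + (1 | subject), data = d)
  cmp <- summary(emmeans::contrast(emmeans::emmeans(fit, "method"),
                                   method = "pairwise", adjust = "tukey"))
  tibble::tibble(contrast = cmp$contrast, estimate = cmp$estimate,
                 p_value = cmp$p.value)
}
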