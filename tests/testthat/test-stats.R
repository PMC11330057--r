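toy_table <- function(det) {
  # det: named list method -> logical/NA vector over contact-surfaces
  n <- length(det[[1]])
  stopifnot(n %% 2 == 0)
  rows <- lapply(names(det), function(m) {
    tibble::tibble(
      contact_id = rep(seq_len(n / 2), each = 2),
      surface = rep(c("restored", "opposing"), n / 2),
      method = m, detected = det[[m]]
    )
  })
  detection_table(dplyr::bind_rows(rows))
}

test_that("detection rates count non-missing calls and round half-up", {
  tbl <- toy_table(list(
    radiograph = rep(c(TRUE, FALSE), c(11, 18)) |> rep(2) |> head(58),
    oct = c(rep(TRUE, 54), NA, NA, FALSE, FALSE)
  ))
  r <- detection_rates(tbl)
  rad_all <- r[r$method == "radiograph" & r$group == "all", ]
  expect_identical(rad_all$n, 58L)
  oct_all <- r[r$method == "oct" & r$group == "all", ]
  expect_identical(oct_all$n, 56L) # two missing calls drop out of n
  expect_identical(oct_all$k_detected, 54L)
  expect_equal(oct_all$rate, 0.96)
  # 11/29 and 27/29 print as the reference rates 0.38 and 0.93
  expect_equal(swircaries:::round_half_up(11 / 29, 2), 0.38)
  expect_equal(swircaries:::round_half_up(27 / 29, 2), 0.93)
  expect_equal(swircaries:::round_half_up(0 / 29, 2), 0)
})

test_that("rates are invariant to duplicating every row", {
  tbl <- toy_table(list(swir_r = c(TRUE, TRUE, FALSE, TRUE, NA, TRUE)))
  doubled <- tbl |>
    dplyr::mutate(contact_id = contact_id + 100L) |>
    dplyr::bind_rows(tbl) |>
    detection_table()
  r1 <- detection_rates(tbl)
  r2 <- detection_rates(doubled)
  expect_equal(r1$rate, r2$rate)
})

test_that("fisher_exact matches exhaustive enumeration on small tables", {
  for (n1 in 1:12) for (n2 in 1:12) {
    for (k1 in c(0, 1, n1 %/% 2, n1)) for (k2 in c(0, n2 %/% 2, n2)) {
      expect_equal(fisher_exact(k1, n1, k2, n2),
                   oracle_fisher(k1, n1, k2, n2), tolerance = 1e-9)
    }
  }
})

test_that("fisher_exact is symmetric and unity on identical tables", {
  expect_equal(fisher_exact(5, 10, 5, 10), 1)
  expect_equal(fisher_exact(11, 29, 11, 29), 1)
  set.seed(3)
  for (i in 1:25) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(fisher_exact(k1, n1, k2, n2), fisher_exact(k2, n2, k1, n1))
  }
  expect_error(fisher_exact(-1, 10, 2, 10), "non-negative")
  expect_error(fisher_exact(11, 10, 2, 10), "exceed")
  expect_error(fisher_exact(1.5, 10, 2, 10), "integers")
})

test_that("the headline rate comparison is significant", {
  expect_lt(fisher_exact(11, 29, 21, 29), 0.05)
  expect_lt(fisher_exact(11, 29, 27, 29), 0.05)
})

contrast_tbl <- function(n_subjects, means, sigma = 0.03, subject_sd = 0.05,
                         seed = 1) {
  set.seed(seed)
  simulate_contrast_values(n_subjects, means, sigma, subject_sd)
}

test_that("rm_anova reduces to the paired t-test for two methods", {
  for (seed in 1:5) {
    tbl <- contrast_tbl(12, c(m1 = 0.15, m2 = 0.18), seed = seed)
    fit <- rm_anova(tbl, "contrast", methods = c("m1", "m2"))
    wide <- tidyr::pivot_wider(
      dplyr::mutate(tbl, s = paste(contact_id, surface)),
      id_cols = "s", names_from = "method", values_from = "contrast"
    )
    tt <- t.test(wide$m1, wide$m2, paired = TRUE)
    expect_lt(abs(fit$f_statistic - tt$statistic^2), 1e-9)
    expect_lt(abs(fit$p_value - tt$p.value), 1e-9)
  }
})

test_that("rm_anova agrees with aov's repeated-measures decomposition", {
  tbl <- contrast_tbl(10, c(a = 0.1, b = 0.14, c = 0.2), seed = 2)
  fit <- rm_anova(tbl, "contrast", methods = c("a", "b", "c"))
  long <- dplyr::mutate(tbl, s = factor(paste(contact_id, surface)),
                        method = factor(method))
  ref <- summary(aov(contrast ~ method + Error(s), data = long))
  ref_tab <- ref[["Error: Within"]][[1]]
  expect_equal(fit$f_statistic, ref_tab["method", "F value"],
               tolerance = 1e-9)
  expect_equal(fit$p_value, ref_tab["method", "Pr(>F)"], tolerance = 1e-9)
})

test_that("identical values per subject give F = 0 and p = 1", {
  vals <- tibble::tibble(
    contact_id = rep(1:3, each = 2),
    surface = rep(c("restored", "opposing"), 3)
  )
  tbl <- detection_table(dplyr::bind_rows(
    dplyr::mutate(vals, method = "m1", detected = TRUE,
                  contrast = c(1, 2, 3, 4, 5, 6) / 10),
    dplyr::mutate(vals, method = "m2", detected = TRUE,
                  contrast = c(1, 2, 3, 4, 5, 6) / 10)
  ))
  fit <- rm_anova(tbl, "contrast")
  expect_equal(fit$f_statistic, 0)
  expect_equal(fit$p_value, 1)
})

test_that("complete-case filtering reproduces the reported n", {
  # 29 subjects, 3 with a missing contrast in one method -> n = 26
  tbl <- contrast_tbl(29, c(radiograph = 0.13, swir_r = 0.22), seed = 4)
  tbl$contrast[tbl$method == "radiograph"][c(2, 9, 17)] <- NA
  fit <- rm_anova(tbl, "contrast", methods = c("radiograph", "swir_r"))
  expect_identical(fit$n_complete, 26L)
  expect_error(
    rm_anova(dplyr::mutate(tbl, contrast = NA_real_), "contrast",
             methods = c("radiograph", "swir_r")),
    "complete cases"
  )
})

test_that("rm_anova pairwise p-values track the mixed-effects cross-check", {
  skip_if_not_installed("lme4")
  skip_if_not_installed("emmeans")
  tbl <- contrast_tbl(20, c(a = 0.13, b = 0.20, c = 0.22), seed = 11)
  fit <- rm_anova(tbl, "contrast", methods = c("a", "b", "c"))
  mm <- mixed_effects_check(tbl, "contrast", methods = c("a", "b", "c"))
  # same data, same balanced design: significance calls agree
  expect_identical(fit$pairwise$p_value < 0.05, mm$p_value < 0.05)
})

test_that("letter display matches exhaustive assignment for 3 methods", {
  mk <- function(p12, p23, p13) {
    m <- matrix(c(1, p12, p13, p12, 1, p23, p13, p23, 1), 3,
                dimnames = list(c("m1", "m2", "m3"), c("m1", "m2", "m3")))
    m
  }
  cases <- expand.grid(p12 = c(0.01, 0.5), p23 = c(0.01, 0.5),
                       p13 = c(0.01, 0.5))
  for (i in seq_len(nrow(cases))) {
    p <- cases[i, ]
    got <- letter_groups(mk(p$p12, p$p23, p$p13), alpha = 0.05)
    want <- oracle_letters3(p$p12 > 0.05, p$p23 > 0.05, p$p13 > 0.05)
    expect_identical(unname(got), want)
  }
  # chain pattern: a, ab, b
  expect_identical(unname(letter_groups(mk(0.5, 0.5, 0.01))),
                   c("a", "ab", "b"))
  allsame <- letter_groups(mk(1, 1, 1))
  expect_identical(unname(allsame), c("a", "a", "a"))
  alldiff <- letter_groups(mk(0, 0, 0) + diag(3))
  expect_identical(unname(alldiff), c("a", "b", "c"))
})

test_that("tidy and glance summarise rm_anova fits", {
  tbl <- contrast_tbl(10, c(a = 0.1, b = 0.2), seed = 3)
  fit <- rm_anova(tbl, "contrast")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  gl <- glance(fit)
  expect_identical(gl$n_complete, 10L)
  expect_identical(gl$n_methods, 2L)
})
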