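accepted_cluster <- function(report, mk) {
  sort(report$clusters$cytokine[report$clusters$marker == mk])
}

test_that("filtering is inclusive at both cut-offs and monotone in them", {
  fits <- fit_all_pairs(example_panel())
  at_bound <- tibble::tibble(
    cytokine = "c", marker = "m", slope = 1, intercept = 0,
    adj_rsq = 0.82, p_value = 0.05, n_points = 6L, degenerate = FALSE
  )
  expect_equal(nrow(filter_fits(at_bound, alpha = 0.05, rsq_min = 0.82)), 1)

  # unattainable threshold
  expect_equal(nrow(filter_fits(fits, rsq_min = 1.01)), 0)
  expect_error(filter_fits(fits, alpha = 0), "probability")

  # raising rsq_min or lowering alpha never adds an accepted fit
  keys <- function(f) paste(f$cytokine, f$marker)
  for (alpha in c(0.2, 0.05, 0.01)) {
    prev <- NULL
    for (rsq in c(0.5, 0.7, 0.796, 0.82, 0.9)) {
      acc <- keys(filter_fits(fits, alpha = alpha, rsq_min = rsq))
      if (!is.null(prev)) expect_true(all(acc %in% prev))
      prev <- acc
    }
  }
  for (rsq in c(0.5, 0.796, 0.9)) {
    prev <- NULL
    for (alpha in c(0.2, 0.05, 0.01)) {
      acc <- keys(filter_fits(fits, alpha = alpha, rsq_min = rsq))
      if (!is.null(prev)) expect_true(all(acc %in% prev))
      prev <- acc
    }
  }
})

test_that("the bundled panel reproduces the published cluster memberships", {
  panel <- example_panel()
  il1b <- canonical_profile_names("IL1b")
  for (thr in c(0.796, 0.82)) {
    report <- link_profiles(panel, alpha = 0.05, rsq_threshold = thr)
    expect_equal(accepted_cluster(report, "CD11b"),
                 sort(c(il1b, "IL6", "IL8")))
    expect_equal(accepted_cluster(report, "CD63"), character(0))
    expect_true("IL8" %in% accepted_cluster(report, "CD66b"))
    expect_true("IL8" %in% accepted_cluster(report, "CD45"))
    # the gelatinase/specific/secretory-vesicle clusters involve 3 cytokines
    linked <- report$clusters$cytokine[report$clusters$marker %in%
                                         c("CD66b", "CD11b", "CD45")]
    expect_equal(sort(unique(linked)), sort(c(il1b, "IL6", "IL8")))
  }
})

test_that("clusters order cytokines by descending fit quality", {
  acc <- tibble::tibble(
    cytokine = c("B", "A", "C"), marker = "M",
    slope = 1, intercept = 0,
    adj_rsq = c(0.9, 0.95, 0.9), p_value = 0.01,
    n_points = 6L, degenerate = FALSE
  )
  cl <- build_clusters(acc)
  expect_equal(cl$cytokine, c("A", "B", "C")) # tie B/C broken alphabetically
  expect_equal(cl$rank, 1:3)
  expect_equal(nrow(build_clusters(acc[0, ])), 0)
})

test_that("slope normalization rescales the log series by the fitted slope", {
  prof <- norm_profile(c(0, 1, 2), "c")
  fit1 <- tibble::tibble(slope = 1)
  expect_equal(slope_normalize(prof, fit1)$overlay, c(0, 1, 2))
  fit2 <- tibble::tibble(slope = 2)
  expect_equal(slope_normalize(prof, fit2)$overlay, c(0, 0.5, 1))
  expect_error(slope_normalize(prof, tibble::tibble(slope = 0)), "zero")

  # noiseless construction: the rescaled cytokine reproduces the marker
  pair <- simulate_linked_pair(slope = 3, intercept = 0, noise_e = 0)
  fit <- fit_all_pairs(pair)
  overlay <- slope_normalize(dplyr::filter(pair, kind == "cytokine"), fit)
  marker <- dplyr::filter(pair, kind == "granule_marker")
  expect_equal(overlay$overlay, marker$log_value, tolerance = 1e-10)
})

test_that("the report object is coherent and its accessors work", {
  report <- link_profiles(example_panel(), rsq_threshold = "strict")
  expect_s3_class(report, "linkage_report")
  expect_equal(report$rsq_min, 0.82)
  expect_equal(report$threshold_source, "strict")

  td <- tidy(report)
  expect_equal(nrow(td), 80)
  acc <- td[td$accepted, ]
  expect_true(all(acc$p_value <= report$alpha))
  expect_true(all(acc$adj_rsq >= report$rsq_min))
  # clusters contain exactly the accepted cytokines per marker
  expect_equal(
    sort(paste(report$clusters$marker, report$clusters$cytokine)),
    sort(paste(acc$marker, acc$cytokine))
  )
  # overlays exist for every accepted pair on the shared grid
  expect_equal(nrow(report$overlays), nrow(acc) * 6)

  gl <- glance(report)
  expect_equal(gl$n_accepted, nrow(acc))
  expect_s3_class(autoplot(report), "ggplot")

  expect_error(link_profiles(example_panel(), rsq_threshold = "bogus"),
               "preset")
})

test_that("calibrated linkage is reproducible under a fixed seed", {
  panel <- example_panel()
  r1 <- link_profiles(panel, rsq_threshold = "calibrate", n_reps = 60,
                      seed = 7)
  r2 <- link_profiles(panel, rsq_threshold = "calibrate", n_reps = 60,
                      seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$threshold_source, "calibrated")
  expect_equal(r1$rsq_min, r1$calibration$threshold)
})
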