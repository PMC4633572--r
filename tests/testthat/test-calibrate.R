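test_that("perturbation draws stay inside [value - e, value + e] with the right mean", {
  prof <- ratio_profile(c(2, 2, 2), time = c(0, 2, 4))
  # e = 0: zero-width interval, output identical to input
  set.seed(1)
  expect_identical(perturb_profile(prof, 0)$value, prof$value)
  expect_error(perturb_profile(prof, -0.1), "nonnegative")

  set.seed(11)
  draws <- replicate(4000, perturb_profile(prof, 0.5)$value[1])
  expect_true(all(draws >= 1.5) && all(draws <= 2.5))
  se <- 0.5 / sqrt(3) / sqrt(length(draws)) # sd of U(-e, e) is e/sqrt(3)
  expect_lt(abs(mean(draws) - 2), 3 * se)
})

test_that("vectorized average-RSQ computation matches per-replicate lm fits", {
  # IL1-beta's baseline ratio (0.69) is below the larger amplitude, so the
  # e = 0.8 case exercises the nonpositive-draw omission path
  prof <- dplyr::filter(example_panel(), name == canonical_profile_names("IL1b"))
  n_reps <- 40
  for (e in c(0.2, 0.8)) { # 0.8 > min ratio - guard: exercises point omission
    set.seed(99)
    got <- average_rsq_curve(prof, e_grid = c(0, e), n_reps = n_reps)
    # replay the identical uniform draws, then fit each replicate with lm()
    # (the e = 0 block consumes no draws: runif() with min == max returns
    # the boundary without touching the stream)
    set.seed(99)
    centers <- rep(prof$value, each = n_reps)
    perturbed <- matrix(runif(n_reps * nrow(prof), centers - e, centers + e),
                        nrow = n_reps)
    adj <- apply(perturbed, 1, function(p) {
      keep <- p > 0
      m <- stats::lm(log10(p[keep]) ~ log10(prof$value[keep]))
      summary(m)$adj.r.squared
    })
    expect_equal(got$avg_rsq[2], mean(adj), tolerance = 1e-10)
  }
})

test_that("average RSQ is exactly 1 at e = 0 for every bundled profile", {
  panel <- example_panel()
  for (s in split(panel, panel$name)) {
    curve <- average_rsq_curve(s, e_grid = c(0, 0.1), n_reps = 25, seed = 3)
    expect_identical(curve$avg_rsq[1], 1)
  }
})

test_that("average RSQ decays with the perturbation amplitude", {
  panel <- example_panel()
  set.seed(5)
  for (s in split(panel, panel$name)) {
    curve <- average_rsq_curve(s, n_reps = 1000)
    # nonincreasing up to Monte-Carlo noise
    expect_true(all(diff(curve$avg_rsq) <= 0.05))
  }
})

test_that("exact 1-D k-means is globally optimal and deterministic", {
  km <- kmeans_1d(c(0, 0, 1, 1), k = 2)
  expect_equal(km$cluster, c(1, 1, 2, 2))
  expect_equal(km$centers, c(0, 1))

  set.seed(8)
  for (i in 1:10) {
    x <- runif(sample(6:10, 1))
    for (k in 2:3) {
      km <- kmeans_1d(x, k)
      expect_equal(km$tot_withinss, kmeans_brute(x, k), tolerance = 1e-12)
      # labels are contiguous in sorted order
      expect_true(all(diff(km$cluster[order(x)]) >= 0))
    }
  }
  expect_error(kmeans_1d(c(1, 1, 2), k = 3), "distinct")
  x <- runif(9)
  expect_identical(kmeans_1d(x, 3), kmeans_1d(x, 3))
})

test_that("mean silhouette matches the defining formula", {
  tight <- c(0.01, 0.02, 0.03, 0.99, 1.00, 1.01)
  lab <- rep(1:2, each = 3)
  expect_gt(silhouette_mean(tight, lab), 0.9)

  # one tight group split arbitrarily in half scores near zero or below
  one_group <- c(0.50, 0.51, 0.52, 0.53, 0.54, 0.55)
  expect_lt(silhouette_mean(one_group, c(1, 2, 1, 2, 1, 2)), 0.1)

  set.seed(21)
  for (i in 1:8) {
    x <- runif(9)
    lab <- sample(1:3, 9, replace = TRUE)
    if (length(unique(lab)) < 2 || all(table(lab) == 1)) next
    expect_equal(silhouette_mean(x, lab), silhouette_oracle(x, lab),
                 tolerance = 1e-10)
  }
  expect_error(silhouette_mean(c(1, 2), c(1, 2)), "singleton")
  expect_error(silhouette_mean(c(1, 2, 3), c(1, 1, 1)), "2 clusters")
})

test_that("threshold extraction takes the boundary element of the high cluster", {
  got <- granulink:::threshold_from_values(c(0.2, 0.25, 0.9, 0.95), k = 2)
  expect_equal(got$threshold, 0.9)
})

test_that("calibration is reproducible and structurally coherent", {
  panel <- example_panel()
  cal1 <- calibrate_rsq_threshold(panel, n_reps = 60, seed = 123)
  cal2 <- calibrate_rsq_threshold(panel, n_reps = 60, seed = 123)
  expect_identical(cal1, cal2)

  # the threshold separates the two cluster centers
  expect_gt(cal1$threshold, min(cal1$centers))
  expect_lte(cal1$threshold, max(cal1$centers))
  # pooled curve: one mean per amplitude, exactly 1 at e = 0
  expect_equal(nrow(cal1$pooled), 11)
  expect_identical(cal1$pooled$avg_rsq[cal1$pooled$e == 0], 1)
  expect_error(calibrate_rsq_threshold(dplyr::filter(panel, name == "IL8")),
               "at least 2")
})

test_that("silhouette model selection favours two clusters on a bimodal RSQ set", {
  # strongly bimodal synthetic averaged-RSQ distribution
  set.seed(17)
  vals <- c(runif(20, 0.05, 0.15), runif(20, 0.85, 0.95))
  scores <- vapply(2:10, function(k) {
    silhouette_mean(vals, kmeans_1d(vals, k)$cluster)
  }, numeric(1))
  expect_equal((2:10)[which.max(scores)], 2)
})
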