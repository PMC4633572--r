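#' Published adjusted R-squared cut-offs
#'
#' Two conventional cut-offs for the bundled LPS-stimulation panel:
#' `"simulation"` (0.796), the value the perturbation calibration of
#' [calibrate_rsq_threshold()] reproduces on this panel, and `"strict"`
#' (0.82), the slightly more conservative rounded cut-off used for the
#' cluster figures. On the bundled data both produce the same accepted
#' clusters for CD63, CD66b, CD11b and CD45.
#'
#' @return a named numeric vector.
#' @export
#' @examples
#' rsq_threshold_presets()
rsq_threshold_presets <- function() {
  c(simulation = 0.796, strict = 0.82)
}

#' Perturb a ratio profile with uniform noise
#'
#' Draws each perturbed ratio independently and uniformly from
#' `[value - e, value + e]`, the noise model used by the threshold
#' calibration. The perturbation acts on the raw ratio scale; with large `e`
#' a draw may be nonpositive, which downstream fitting handles by omitting
#' that point (its log10 is undefined).
#'
#' @param profile a single-series profile table with a `value` column.
#' @param e nonnegative noise half-width; `e = 0` returns the input values
#'   exactly.
#' @return the profile with perturbed `value`s; the input is not modified.
#' @export
#' @examples
#' set.seed(1)
#' cd11b <- dplyr::filter(example_profiles(), name == "CD11b")
#' perturb_profile(cd11b, e = 0.3)
perturb_profile <- function(profile, e) {
  if (!is.numeric(e) || length(e) != 1 || is.na(e) || e < 0) {
    abort("`e` must be a single nonnegative number.")
  }
  validate_profiles(profile)
  mutate(profile, value = runif(dplyr::n(), .data$value - e, .data$value + e))
}

# Vectorized mean adjusted R^2 of original-vs-perturbed fits for one profile
# at one noise amplitude. `r` is the raw ratio vector. Perturbed draws are
# made on the ratio scale; nonpositive draws are omitted from that
# replicate's fit (log10 undefined) and the adjusted R^2 uses the remaining
# point count. Replicates with fewer than 3 positive points are dropped.
mean_adj_rsq_at_e <- function(r, e, n_reps) {
  n <- length(r)
  centers <- rep(r, each = n_reps)
  perturbed <- matrix(runif(n_reps * n, centers - e, centers + e),
                      nrow = n_reps, ncol = n)
  x <- matrix(log10(r), nrow = n_reps, ncol = n, byrow = TRUE)
  if (all(perturbed > 0)) {
    y <- log10(perturbed)
    m <- n
    xc <- x - rowMeans(x)
    yc <- y - rowMeans(y)
    sxx <- rowSums(xc^2)
    syy <- rowSums(yc^2)
    sxy <- rowSums(xc * yc)
  } else {
    ok <- perturbed > 0
    y <- suppressWarnings(log10(perturbed))
    y[!ok] <- NA_real_
    x[!ok] <- NA_real_
    m <- rowSums(ok)
    keep <- m >= 3
    x <- x[keep, , drop = FALSE]
    y <- y[keep, , drop = FALSE]
    m <- m[keep]
    xc <- x - rowMeans(x, na.rm = TRUE)
    yc <- y - rowMeans(y, na.rm = TRUE)
    sxx <- rowSums(xc^2, na.rm = TRUE)
    syy <- rowSums(yc^2, na.rm = TRUE)
    sxy <- rowSums(xc * yc, na.rm = TRUE)
  }
  r2 <- sxy^2 / (sxx * syy)
  adj <- 1 - (1 - r2) * (m - 1) / (m - 2)
  mean(adj)
}

#' Average adjusted R-squared versus noise amplitude
#'
#' For each noise amplitude `e`, draws `n_reps` perturbed copies of the
#' profile ([perturb_profile()]'s noise model), fits the original log10
#' profile against each perturbed one, and averages the adjusted R-squared.
#' At `e = 0` the perturbed copy equals the original and the average is
#' exactly 1.
#'
#' @param profile a single-series profile table with a raw `value` column
#'   (the perturbation acts on the ratio scale).
#' @param e_grid nonnegative, sorted noise amplitudes; must contain 0.
#' @param n_reps repetitions per amplitude.
#' @param seed optional integer seed (`set.seed()`), for a reproducible curve.
#' @return a tibble with columns `name`, `e`, `avg_rsq`.
#' @export
#' @examples
#' cd11b <- dplyr::filter(example_profiles(), name == "CD11b")
#' average_rsq_curve(cd11b, n_reps = 100, seed = 1)
average_rsq_curve <- function(profile, e_grid = seq(0, 1, by = 0.1),
                              n_reps = 1000, seed = NULL) {
  check_e_grid(e_grid)
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  validate_profiles(profile)
  if (length(unique(profile$name)) != 1) {
    abort("`average_rsq_curve()` expects a single series; see `calibrate_rsq_threshold()` for panels.")
  }
  r <- profile$value
  tibble(
    name = profile$name[[1]],
    e = e_grid,
    avg_rsq = vapply(e_grid, function(e) mean_adj_rsq_at_e(r, e, n_reps),
                     numeric(1))
  )
}

check_e_grid <- function(e_grid) {
  if (length(e_grid) < 1 || anyNA(e_grid) || any(e_grid < 0) ||
      is.unsorted(e_grid, strictly = TRUE) || e_grid[1] != 0) {
    abort("`e_grid` must be sorted, nonnegative, distinct, and start at 0.")
  }
}

#' Exact one-dimensional k-means
#'
#' Globally optimal k-means partition of scalar values, computed by dynamic
#' programming on the sorted values (optimal 1-D clusters are contiguous in
#' sorted order). Deterministic, unlike Lloyd-style iterations.
#'
#' @param x numeric values.
#' @param k number of clusters, at most the number of distinct values.
#' @return a list with `cluster` (integer labels, 1 = lowest-valued cluster),
#'   `centers` (cluster means, increasing) and `tot_withinss`.
#' @export
#' @examples
#' kmeans_1d(c(0, 0.1, 0.9, 1), k = 2)
kmeans_1d <- function(x, k) {
  if (anyNA(x) || !is.numeric(x)) abort("`x` must be numeric without NA.")
  n_distinct_x <- length(unique(x))
  if (k < 1 || k > n_distinct_x) {
    abort(paste0("`k` must be between 1 and the number of distinct values (",
                 n_distinct_x, ")."))
  }
  o <- order(x)
  s <- x[o]
  n <- length(s)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  # within-sum-of-squares of the sorted slice i..j
  ssq <- function(i, j) {
    su <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    max(s2 - su^2 / (j - i + 1), 0)
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- ssq(1, j)
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        for (i in q:j) {
          v <- cost[q - 1, i - 1] + ssq(i, j)
          if (v < cost[q, j]) {
            cost[q, j] <- v
            back[q, j] <- i
          }
        }
      }
    }
  }
  labels <- integer(n)
  j <- n
  for (q in k:1) {
    i <- if (q == 1) 1L else back[q, j]
    labels[o[i:j]] <- q
    j <- i - 1L
  }
  list(
    cluster = labels,
    centers = as.numeric(tapply(x, labels, mean)),
    tot_withinss = cost[k, n]
  )
}

#' Mean silhouette score of a scalar clustering
#'
#' Average silhouette width over all points, using Euclidean distance on the
#' scalar values (via [cluster::silhouette()]). Used to confirm the number of
#' clusters when extracting the RSQ threshold.
#'
#' @param x numeric values.
#' @param labels integer cluster labels, at least two nonempty clusters.
#' @return the mean silhouette width, in `[-1, 1]`.
#' @export
silhouette_mean <- function(x, labels) {
  if (length(labels) != length(x)) {
    abort("`labels` must match `x` in length.")
  }
  sizes <- table(labels)
  if (length(sizes) < 2) abort("Need at least 2 clusters.")
  if (all(sizes == 1)) {
    abort("All clusters are singletons; the silhouette is undefined.")
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), dist(x))
  mean(sil[, "sil_width"])
}

# threshold = smallest averaged-RSQ value in the cluster with the highest
# center: the boundary of the "high RSQ" group toward the "low RSQ" group.
threshold_from_values <- function(values, k = 2) {
  km <- kmeans_1d(values, k)
  hi <- which.max(km$centers)
  list(threshold = min(values[km$cluster == hi]), kmeans = km)
}

#' Calibrate the adjusted R-squared acceptance threshold
#'
#' Monte-Carlo recipe for deciding how large an adjusted R-squared must be to
#' call two kinetic profiles "matching". Each input profile is perturbed on
#' the raw ratio scale with uniform noise of half-width `e` (for every `e` in
#' `e_grid`, `n_reps` times), the original log10 profile is fitted against
#' each perturbed copy, and the adjusted R-squared is averaged per
#' (profile, e). The per-`e` means across profiles form the average-RSQ
#' versus-amplitude curve; exact 1-D k-means splits that curve into a "high
#' RSQ" and a "low RSQ" group, and the threshold is the boundary (smallest)
#' element of the high-center group. A silhouette analysis over `k_range`
#' confirms the choice of two clusters.
#'
#' @param profiles a profile table (both kinds together is fine); every
#'   series is perturbed individually.
#' @param e_grid noise amplitudes; must start at 0 (where the average RSQ is
#'   exactly 1).
#' @param n_reps perturbation repetitions per (profile, e).
#' @param k number of clusters used for threshold extraction.
#' @param k_range cluster counts scored by silhouette.
#' @param seed optional integer seed; the random stream is consumed in a
#'   fixed order (profiles in input order, amplitudes ascending), so a seeded
#'   calibration is bit-for-bit reproducible.
#' @return an `rsq_calibration` object: list with `threshold`, `curves`
#'   (per-profile tibble `name`, `e`, `avg_rsq`), `pooled` (per-`e` means
#'   with cluster labels), `centers`, `silhouette_by_k`, `best_k`, and the
#'   configuration. [tidy()] returns the per-profile curves, [glance()] a
#'   one-row summary, [autoplot()] the calibration plot.
#' @export
#' @examples
#' cal <- calibrate_rsq_threshold(example_profiles(), n_reps = 50, seed = 1)
#' glance(cal)
calibrate_rsq_threshold <- function(profiles, e_grid = seq(0, 1, by = 0.1),
                                    n_reps = 1000, k = 2, k_range = 2:10,
                                    seed = NULL) {
  check_e_grid(e_grid)
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  if (k < 2) abort("`k` must be at least 2.")
  validate_profiles(profiles)
  series <- split_series(profiles)
  if (length(series) < 2) abort("Need at least 2 profiles to calibrate.")
  if (!is.null(seed)) set.seed(seed)

  curves <- series |>
    map(function(s) {
      tibble(name = s$name[[1]], e = e_grid,
             avg_rsq = vapply(e_grid,
                              function(e) mean_adj_rsq_at_e(s$value, e, n_reps),
                              numeric(1)))
    }) |>
    list_rbind()

  pooled <- curves |>
    group_by(.data$e) |>
    summarise(avg_rsq = mean(.data$avg_rsq)) |>
    arrange(.data$e)

  thr <- threshold_from_values(pooled$avg_rsq, k = k)
  pooled$cluster <- thr$kmeans$cluster

  k_range <- k_range[k_range >= 2 & k_range <= length(pooled$avg_rsq) - 1]
  silhouette_by_k <- tibble(
    k = k_range,
    score = vapply(k_range, function(kk) {
      silhouette_mean(pooled$avg_rsq, kmeans_1d(pooled$avg_rsq, kk)$cluster)
    }, numeric(1))
  )
  best_k <- if (nrow(silhouette_by_k) > 0) {
    silhouette_by_k$k[which.max(silhouette_by_k$score)]
  } else {
    NA_integer_
  }

  structure(
    list(threshold = thr$threshold, curves = curves, pooled = pooled,
         centers = thr$kmeans$centers, silhouette_by_k = silhouette_by_k,
         best_k = best_k,
         config = list(e_grid = e_grid, n_reps = n_reps, k = k,
                       k_range = k_range, seed = seed)),
    class = "rsq_calibration"
  )
}

#' @export
print.rsq_calibration <- function(x, ...) {
  cat("<rsq_calibration>\n")
  cat(sprintf("  %d profiles x %d amplitudes, %d reps each\n",
              length(unique(x$curves$name)), length(x$config$e_grid),
              x$config$n_reps))
  cat(sprintf("  adjusted RSQ threshold: %.4f (k = %d; silhouette best k = %s)\n",
              x$threshold, x$config$k, x$best_k))
  invisible(x)
}

#' @describeIn calibrate_rsq_threshold per-profile average-RSQ curves.
#' @param x an `rsq_calibration`.
#' @param ... unused.
#' @method tidy rsq_calibration
#' @export
tidy.rsq_calibration <- function(x, ...) x$curves

#' @describeIn calibrate_rsq_threshold one-row summary.
#' @method glance rsq_calibration
#' @export
glance.rsq_calibration <- function(x, ...) {
  tibble(
    threshold = x$threshold,
    n_profiles = length(unique(x$curves$name)),
    n_amplitudes = length(x$config$e_grid),
    n_reps = x$config$n_reps,
    k = x$config$k,
    best_k = x$best_k,
    best_silhouette = if (nrow(x$silhouette_by_k) > 0) {
      max(x$silhouette_by_k$score)
    } else {
      NA_real_
    }
  )
}

#' @describeIn calibrate_rsq_threshold average-RSQ curves against the noise
#'   amplitude with the derived threshold; thin grey lines are the individual
#'   profiles, points the pooled per-`e` means coloured by cluster.
#' @param object an `rsq_calibration`.
#' @method autoplot rsq_calibration
#' @export
autoplot.rsq_calibration <- function(object, ...) {
  ggplot(object$pooled, aes(x = .data$e, y = .data$avg_rsq)) +
    geom_line(data = object$curves,
              aes(group = .data$name), colour = "grey70", linewidth = 0.3) +
    geom_line() +
    geom_point(aes(colour = factor(.data$cluster)), size = 2) +
    geom_hline(yintercept = object$threshold, linetype = "dashed") +
    annotate("text", x = max(object$pooled$e), y = object$threshold,
             label = sprintf("threshold = %.3f", object$threshold),
             vjust = -0.6, hjust = 1, size = 3) +
    labs(x = "Perturbation amplitude e", y = "Average adjusted RSQ",
         colour = "Cluster") +
    theme_minimal()
}
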