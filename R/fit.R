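#' Fit one cytokine-marker pair
#'
#' Ordinary least squares of the cytokine log10 profile (response) on the
#' marker log10 profile (predictor), with intercept. The slope is the
#' proportionality factor between the two kinetic profiles on the log scale;
#' the overall F test against the intercept-only null model gives the p value,
#' and the adjusted R-squared `1 - (1 - R^2) (n - 1) / (n - 2)` measures
#' proximity to the linear fit. A constant (zero-variance) profile on either
#' side yields a degenerate sentinel fit (`p_value = 1`, `adj_rsq = -Inf`,
#' `degenerate = TRUE`) rather than an error, so panel-wide fitting never
#' aborts.
#'
#' @param cytokine,marker single-series profile tables on a shared timepoint
#'   grid; a raw `value` column is log10-normalized automatically.
#' @return a one-row tibble with columns `cytokine`, `marker`, `slope`,
#'   `intercept`, `adj_rsq`, `p_value`, `n_points`, `degenerate`.
#' @seealso [fit_all_pairs()] for a whole panel.
#' @export
#' @examples
#' panel <- example_profiles()
#' fit_pair(
#'   dplyr::filter(panel, name == "IL8"),
#'   dplyr::filter(panel, name == "CD11b")
#' )
fit_pair <- function(cytokine, marker) {
  cy <- ensure_normalized(cytokine)
  mk <- ensure_normalized(marker)
  if (length(unique(cy$name)) != 1 || length(unique(mk$name)) != 1) {
    abort("`fit_pair()` expects exactly one series on each side; use `fit_all_pairs()` for panels.")
  }
  shared_grid(cy, mk)
  fit_pair_values(cy$log_value, mk$log_value,
                  cytokine = cy$name[[1]], marker = mk$name[[1]])
}

# Core OLS on two numeric log10 vectors; returns the one-row PairFit tibble.
fit_pair_values <- function(y, x, cytokine = "cytokine", marker = "marker") {
  n <- length(y)
  degenerate <- function() {
    tibble(cytokine = cytokine, marker = marker,
           slope = NA_real_, intercept = mean(y),
           adj_rsq = -Inf, p_value = 1, n_points = n, degenerate = TRUE)
  }
  if (var(x) == 0 || var(y) == 0) {
    return(degenerate())
  }
  m <- lm(y ~ x)
  # exactly collinear inputs (e.g. noiseless synthetic pairs) trigger lm's
  # "essentially perfect fit" precision warning; the fit itself is valid
  s <- suppressWarnings(summary(m))
  fstat <- s$fstatistic
  if (is.null(fstat)) {
    return(degenerate())
  }
  p <- unname(pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]],
                 lower.tail = FALSE))
  tibble(
    cytokine = cytokine, marker = marker,
    slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
    adj_rsq = s$adj.r.squared, p_value = p,
    n_points = n, degenerate = FALSE
  )
}

#' Fit every cytokine against every granule marker
#'
#' Builds the full regression panel: one [fit_pair()] record per
#' (cytokine, marker) combination. All series must share one timepoint grid;
#' there is no interpolation.
#'
#' @param cytokines a profile table of cytokine series, or a combined table
#'   holding both kinds (then `markers` may be omitted and the split is made
#'   on the `kind` column).
#' @param markers a profile table of granule-marker series, or `NULL`.
#' @return a tibble of pair fits, `n_cytokines * n_markers` rows, in cytokine-
#'   major order.
#' @export
#' @examples
#' fits <- fit_all_pairs(example_profiles())
#' nrow(fits) # 10 cytokines x 8 markers
fit_all_pairs <- function(cytokines, markers = NULL) {
  if (is.null(markers)) {
    panel <- ensure_normalized(cytokines)
    cytokines <- filter(panel, .data$kind == "cytokine")
    markers <- filter(panel, .data$kind == "granule_marker")
  } else {
    cytokines <- ensure_normalized(cytokines)
    markers <- ensure_normalized(markers)
  }
  empty <- tibble(cytokine = character(), marker = character(),
                  slope = double(), intercept = double(),
                  adj_rsq = double(), p_value = double(),
                  n_points = integer(), degenerate = logical())
  if (nrow(cytokines) == 0 || nrow(markers) == 0) {
    return(empty)
  }
  shared_grid(cytokines, markers)
  cy <- split_series(cytokines)
  mk <- split_series(markers)
  tidyr::crossing(cytokine = names(cy), marker = names(mk)) |>
    arrange(match(.data$cytokine, names(cy)), match(.data$marker, names(mk))) |>
    pmap(function(cytokine, marker) {
      fit_pair_values(cy[[cytokine]]$log_value, mk[[marker]]$log_value,
                      cytokine = cytokine, marker = marker)
    }) |>
    list_rbind()
}

#' Filter pair fits by significance and adjusted R-squared
#'
#' Keeps fits that are significantly better than the intercept-only null
#' model (`p_value <= alpha`) and whose adjusted R-squared clears the
#' threshold (`adj_rsq >= rsq_min`); both comparisons are inclusive.
#' Degenerate fits never pass. No multiple-testing correction is applied by
#' default, matching the method's use of per-pair tests on a small panel; set
#' `p_adjust = "BH"` for a Benjamini-Hochberg corrected screen.
#'
#' @param fits a tibble of pair fits from [fit_all_pairs()].
#' @param alpha significance cut-off for the overall F test, in (0, 1).
#' @param rsq_min minimum adjusted R-squared; see
#'   [calibrate_rsq_threshold()] and [rsq_threshold_presets()].
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return the accepted subset of `fits`.
#' @export
filter_fits <- function(fits, alpha = 0.05, rsq_min = 0.82,
                        p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single probability in (0, 1).")
  }
  p <- fits$p_value
  if (p_adjust == "BH") {
    p <- p.adjust(p, method = "BH")
  }
  fits[!fits$degenerate & p <= alpha & fits$adj_rsq >= rsq_min, , drop = FALSE]
}

#' Group accepted fits into per-marker cytokine clusters
#'
#' Each granule marker's cluster is the set of cytokines whose secretion
#' profile was accepted against it, ordered by descending adjusted R-squared
#' (ties broken alphabetically). A cytokine may appear in several clusters.
#'
#' @param accepted accepted fits, e.g. from [filter_fits()].
#' @return a tibble with columns `marker`, `cytokine`, `adj_rsq`, `rank`
#'   (1 = best fit within the marker).
#' @export
build_clusters <- function(accepted) {
  accepted |>
    select("marker", "cytokine", "adj_rsq") |>
    arrange(.data$marker, desc(.data$adj_rsq), .data$cytokine) |>
    group_by(.data$marker) |>
    mutate(rank = row_number()) |>
    ungroup()
}

#' Rescale a cytokine profile by its fitted slope
#'
#' Divides the cytokine's log10 values by the slope of its pair fit, mapping
#' the cytokine series onto the marker's scale so the two kinetic profiles
#' can be overlaid in one panel.
#'
#' @param cytokine a single-series profile table (log10-normalized
#'   automatically if raw).
#' @param fit a one-row pair-fit tibble with a nonzero `slope`.
#' @return a tibble with columns `name`, `time`, `overlay`.
#' @export
slope_normalize <- function(cytokine, fit) {
  cy <- ensure_normalized(cytokine)
  slope <- fit$slope[[1]]
  if (is.na(slope) || slope == 0) {
    abort("Cannot slope-normalize: the fitted slope is zero or undefined.")
  }
  tibble(name = cy$name, time = cy$time, overlay = cy$log_value / slope)
}

#' Run the full linkage pipeline
#'
#' Normalizes the panel, fits every cytokine-marker pair, filters by the
#' overall F test and the adjusted R-squared threshold, groups cytokines into
#' per-marker clusters, and computes slope-normalized overlay series for each
#' accepted pair.
#'
#' @param profiles a profile table containing both cytokine and
#'   granule-marker series (see [example_profiles()]).
#' @param alpha significance cut-off for the F test.
#' @param rsq_threshold either a number, the string `"calibrate"` (run
#'   [calibrate_rsq_threshold()] on this panel), or a preset name from
#'   [rsq_threshold_presets()].
#' @param p_adjust passed to [filter_fits()].
#' @param e_grid,n_reps,seed forwarded to [calibrate_rsq_threshold()] when
#'   `rsq_threshold = "calibrate"`.
#' @return a `linkage_report` object: a list with tibbles `fits` (all fits,
#'   with an `accepted` flag), `clusters`, `overlays`, the thresholds used,
#'   and the calibration result when one was run. Use [tidy()] for the fit
#'   table, [glance()] for a one-row summary, [autoplot()] for overlay plots,
#'   and [write_linkage_report()] to serialize.
#' @export
#' @examples
#' report <- link_profiles(example_profiles(), rsq_threshold = 0.82)
#' glance(report)
link_profiles <- function(profiles, alpha = 0.05, rsq_threshold = 0.82,
                          p_adjust = c("none", "BH"),
                          e_grid = seq(0, 1, by = 0.1), n_reps = 1000,
                          seed = NULL) {
  p_adjust <- match.arg(p_adjust)
  calibration <- NULL
  if (is.character(rsq_threshold)) {
    if (identical(rsq_threshold, "calibrate")) {
      calibration <- calibrate_rsq_threshold(profiles, e_grid = e_grid,
                                             n_reps = n_reps, seed = seed)
      rsq_min <- calibration$threshold
      threshold_source <- "calibrated"
    } else {
      presets <- rsq_threshold_presets()
      if (!rsq_threshold %in% names(presets)) {
        abort(paste0("Unknown threshold preset '", rsq_threshold,
                     "'. Available: ", paste(names(presets), collapse = ", "),
                     ", or 'calibrate', or a number."))
      }
      rsq_min <- unname(presets[rsq_threshold])
      threshold_source <- rsq_threshold
    }
  } else {
    rsq_min <- rsq_threshold
    threshold_source <- "numeric"
  }

  normalized <- ensure_normalized(profiles)
  fits <- fit_all_pairs(normalized)
  accepted <- filter_fits(fits, alpha = alpha, rsq_min = rsq_min,
                          p_adjust = p_adjust)
  fits <- fits |>
    mutate(accepted = paste(.data$cytokine, .data$marker) %in%
             paste(accepted$cytokine, accepted$marker))
  clusters <- build_clusters(accepted)

  series <- split_series(normalized)
  overlays <- accepted |>
    pmap(function(cytokine, marker, slope, ...) {
      cy <- series[[cytokine]]
      mk <- series[[marker]]
      tibble(cytokine = cytokine, marker = marker, time = cy$time,
             marker_log = mk$log_value,
             cytokine_scaled = cy$log_value / slope)
    }) |>
    list_rbind()
  if (nrow(accepted) == 0) {
    overlays <- tibble(cytokine = character(), marker = character(),
                       time = double(), marker_log = double(),
                       cytokine_scaled = double())
  }

  structure(
    list(fits = fits, clusters = clusters, overlays = overlays,
         alpha = alpha, rsq_min = rsq_min,
         threshold_source = threshold_source, p_adjust = p_adjust,
         calibration = calibration),
    class = "linkage_report"
  )
}

#' @export
print.linkage_report <- function(x, ...) {
  cat("<linkage_report>\n")
  cat(sprintf("  %d pair fits, %d accepted (alpha = %g, adj RSQ >= %g [%s])\n",
              nrow(x$fits), sum(x$fits$accepted), x$alpha, x$rsq_min,
              x$threshold_source))
  if (nrow(x$clusters) > 0) {
    cl <- x$clusters |>
      group_by(.data$marker) |>
      summarise(cytokines = paste(.data$cytokine, collapse = ", "))
    for (i in seq_len(nrow(cl))) {
      cat(sprintf("  %s: %s\n", cl$marker[i], cl$cytokines[i]))
    }
  } else {
    cat("  no accepted links\n")
  }
  invisible(x)
}

#' @describeIn link_profiles the full fit table with the `accepted` flag.
#' @param x a `linkage_report`.
#' @param ... unused.
#' @method tidy linkage_report
#' @export
tidy.linkage_report <- function(x, ...) x$fits

#' @describeIn link_profiles one-row summary (counts and thresholds).
#' @method glance linkage_report
#' @export
glance.linkage_report <- function(x, ...) {
  tibble(
    n_fits = nrow(x$fits),
    n_accepted = sum(x$fits$accepted),
    n_linked_markers = length(unique(x$clusters$marker)),
    alpha = x$alpha,
    rsq_min = x$rsq_min,
    threshold_source = x$threshold_source
  )
}

#' @describeIn link_profiles overlay plot of accepted pairs, one facet per
#'   marker: the marker log10 profile with each linked cytokine rescaled by
#'   its fitted slope.
#' @param object a `linkage_report`.
#' @method autoplot linkage_report
#' @export
autoplot.linkage_report <- function(object, ...) {
  ov <- object$overlays
  if (nrow(ov) == 0) {
    abort("No accepted pairs to plot.")
  }
  marker_lines <- ov |> distinct(.data$marker, .data$time, .data$marker_log)
  ggplot(ov, aes(x = .data$time)) +
    geom_line(data = marker_lines,
              aes(y = .data$marker_log, linetype = "marker"),
              colour = "black") +
    geom_line(aes(y = .data$cytokine_scaled, colour = .data$cytokine)) +
    geom_point(aes(y = .data$cytokine_scaled, colour = .data$cytokine)) +
    facet_wrap(~marker) +
    labs(x = "Time after stimulation (h)",
         y = "log10 relative ratio (cytokines slope-rescaled)",
         colour = "Cytokine", linetype = NULL) +
    theme_minimal()
}
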