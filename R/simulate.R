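#' Simulate a granule-marker kinetic profile
#'
#' Deterministic base shapes on the log10 ratio scale, mimicking the kinetics
#' of LPS-induced degranulation markers: ratio 1 (log 0) before stimulation,
#' a peak at an interior timepoint for `"rise_fall"` (like CD11b, which peaks
#' at 12 h), a saturating increase for `"monotone"`, or a flat (no effect)
#' profile.
#'
#' @param shape one of `"rise_fall"`, `"monotone"`, `"flat"`.
#' @param timepoints sampling hours, default the 0/2/4/6/12/24 h design of
#'   the bundled panel.
#' @param amplitude peak log10 ratio (0.4 corresponds to a peak ratio of
#'   about 2.5).
#' @param peak_time hour of the maximum for `"rise_fall"`.
#' @param name series name.
#' @return a normalized profile table (`name`, `kind`, `time`, `log_value`).
#' @export
#' @examples
#' simulate_marker_profile("rise_fall")
simulate_marker_profile <- function(shape = c("rise_fall", "monotone", "flat"),
                                    timepoints = c(0, 2, 4, 6, 12, 24),
                                    amplitude = 0.4, peak_time = 12,
                                    name = "marker_1") {
  shape <- match.arg(shape)
  if (length(timepoints) < 3 || any(diff(timepoints) <= 0)) {
    abort("`timepoints` must be at least 3 strictly increasing hours.")
  }
  log_value <- switch(
    shape,
    flat = rep(0, length(timepoints)),
    monotone = amplitude * (timepoints / max(timepoints))^0.7,
    rise_fall = {
      up <- amplitude * (pmin(timepoints, peak_time) / peak_time)^0.7
      fall <- ifelse(timepoints > peak_time,
                     amplitude * (1 - 0.25 * (timepoints - peak_time) /
                                    (max(timepoints) - peak_time)),
                     up)
      fall
    }
  )
  tibble(name = name, kind = "granule_marker",
         time = as.numeric(timepoints), log_value = log_value)
}

#' Simulate a linked cytokine-marker pair
#'
#' Generates a marker profile and a cytokine profile that is exactly
#' log-proportional to it up to uniform noise:
#' `cytokine[i] = intercept + slope * marker[i] + U(-noise_e, +noise_e)`,
#' the generative counterpart of the noise model used in threshold
#' calibration.
#'
#' @param slope true proportionality factor on the log10 scale.
#' @param intercept true log10-scale offset.
#' @param noise_e uniform noise half-width on the log10 scale; 0 gives an
#'   exact linear relation.
#' @param shape,timepoints,amplitude,peak_time passed to
#'   [simulate_marker_profile()].
#' @param seed optional integer seed.
#' @return a normalized profile table with two series, `marker_1`
#'   (`granule_marker`) and `cytokine_1` (`cytokine`); ready for
#'   [fit_all_pairs()].
#' @export
#' @examples
#' pair <- simulate_linked_pair(slope = 2, noise_e = 0.05, seed = 1)
#' fit_all_pairs(pair)
simulate_linked_pair <- function(slope = 2, intercept = 0, noise_e = 0.05,
                                 shape = "rise_fall",
                                 timepoints = c(0, 2, 4, 6, 12, 24),
                                 amplitude = 0.4, peak_time = 12,
                                 seed = NULL) {
  if (noise_e < 0) abort("`noise_e` must be nonnegative.")
  if (!is.null(seed)) set.seed(seed)
  marker <- simulate_marker_profile(shape, timepoints, amplitude, peak_time,
                                    name = "marker_1")
  n <- nrow(marker)
  cytokine <- tibble(
    name = "cytokine_1", kind = "cytokine", time = marker$time,
    log_value = intercept + slope * marker$log_value +
      runif(n, -noise_e, noise_e)
  )
  bind_rows(marker, cytokine)
}

#' Simulate a panel of independent null profiles
#'
#' Profiles with no built-in linkage: every log10 value is drawn
#' independently and uniformly from `[-amplitude, +amplitude]`. Fitting any
#' two of them (or one of them against anything else) probes the false-accept
#' behaviour of the filtering step.
#'
#' @param n_profiles number of series, at least 1.
#' @param kind profile kind assigned to all series.
#' @param timepoints sampling hours.
#' @param amplitude half-width of the uniform log10 values.
#' @param seed optional integer seed.
#' @return a normalized profile table with series `null_1 ... null_n`.
#' @export
#' @examples
#' simulate_null_panel(2, seed = 1)
simulate_null_panel <- function(n_profiles, kind = "cytokine",
                                timepoints = c(0, 2, 4, 6, 12, 24),
                                amplitude = 0.5, seed = NULL) {
  if (!is.numeric(n_profiles) || length(n_profiles) != 1 || n_profiles < 1) {
    abort("`n_profiles` must be at least 1.")
  }
  kind <- match.arg(kind, profile_kinds)
  if (!is.null(seed)) set.seed(seed)
  n <- length(timepoints)
  purrr::map(seq_len(n_profiles), function(i) {
    tibble(name = paste0("null_", i), kind = kind,
           time = as.numeric(timepoints),
           log_value = runif(n, -amplitude, amplitude))
  }) |>
    list_rbind()
}
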