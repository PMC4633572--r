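#' Profile tables
#'
#' A profile table is a long tibble with one row per series and timepoint:
#' columns `name` (series identifier), `kind` (`"cytokine"` or
#' `"granule_marker"`), `time` (hours), `value` (relative ratio,
#' stimulated / time-matched control, strictly positive) and optionally `sem`
#' (per-point standard error, carried along for reporting only). A normalized
#' profile table carries `log_value` (log10 of the ratio) instead of, or in
#' addition to, `value`.
#'
#' @name profile-tables
#' @keywords internal
NULL

profile_kinds <- c("cytokine", "granule_marker")

# ASCII aliases for the Greek-lettered series names used in the bundled panel
greek_aliases <- c(
  TNFa  = "TNF\u03b1",
  IL1a  = "IL1\u03b1",
  IL1b  = "IL1\u03b2",
  IL12b = "IL12\u03b2"
)

#' Canonicalize series names
#'
#' Maps ASCII aliases of Greek-lettered series names (`"TNFa"`, `"IL1a"`,
#' `"IL1b"`, `"IL12b"`) to their UTF-8 forms; all other names pass through
#' unchanged.
#'
#' @param x character vector of series names.
#' @return character vector of the same length.
#' @export
#' @examples
#' canonical_profile_names(c("IL1b", "IL8"))
canonical_profile_names <- function(x) {
  hit <- x %in% names(greek_aliases)
  x[hit] <- greek_aliases[x[hit]]
  x
}

#' Validate a profile table
#'
#' Checks the invariants every downstream operation relies on: required
#' columns, at least three timepoints per series, strictly increasing times,
#' strictly positive finite ratios, and unique (name, time) rows.
#'
#' @param profiles a profile table (see [profile-tables]).
#' @param normalized if `TRUE`, expect a `log_value` column (finite values)
#'   instead of a positive `value` column.
#' @return the input, invisibly, after validation.
#' @export
validate_profiles <- function(profiles, normalized = FALSE) {
  if (!is.data.frame(profiles)) {
    abort("`profiles` must be a data frame.")
  }
  value_col <- if (normalized) "log_value" else "value"
  needed <- c("name", "kind", "time", value_col)
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols) > 0) {
    abort(paste0("`profiles` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  bad_kind <- setdiff(unique(profiles$kind), profile_kinds)
  if (length(bad_kind) > 0) {
    abort(paste0("Unknown profile kind(s): ", paste(bad_kind, collapse = ", "),
                 ". Use 'cytokine' or 'granule_marker'."))
  }
  by_series <- split(profiles, profiles$name)
  for (s in by_series) {
    nm <- s$name[[1]]
    if (nrow(s) < 3) {
      abort(paste0("Series '", nm, "' has fewer than 3 timepoints."))
    }
    if (anyDuplicated(s$time) || any(diff(sort(s$time)) <= 0)) {
      abort(paste0("Series '", nm, "' has duplicated timepoints."))
    }
    if (any(diff(s$time) <= 0)) {
      abort(paste0("Series '", nm, "' timepoints are not strictly increasing."))
    }
    v <- s[[value_col]]
    if (anyNA(v) || any(!is.finite(v))) {
      t_bad <- s$time[which(!is.finite(v) | is.na(v))[1]]
      abort(paste0("Series '", nm, "' has a missing or non-finite ", value_col,
                   " at t = ", t_bad, " h."))
    }
    if (!normalized && any(v <= 0)) {
      t_bad <- s$time[which(v <= 0)[1]]
      abort(paste0("Series '", nm, "' has a nonpositive ratio at t = ",
                   t_bad, " h; ratios must be > 0."))
    }
  }
  invisible(profiles)
}

#' Compute relative ratio profiles from paired measurements
#'
#' Divides each stimulated measurement by the control measurement from the
#' same timepoint, the normalization that puts cytokine concentrations
#' (pg/mL) and marker MFI values on a common dimensionless scale where 1.0
#' means "no effect of stimulation".
#'
#' @param data a data frame with columns `name`, `time`, and the two
#'   measurement columns.
#' @param stimulated,control column names (unquoted) holding the stimulated
#'   and time-matched control measurements; both must be strictly positive.
#' @param kind profile kind assigned to every series, `"cytokine"` or
#'   `"granule_marker"`.
#' @return a profile table with columns `name`, `kind`, `time`, `value`.
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   name = "IL8", time = c(0, 2, 4),
#'   stim = c(10, 40, 90), ctrl = c(10, 10, 10)
#' )
#' relative_profiles(raw, stim, ctrl)
relative_profiles <- function(data, stimulated, control,
                              kind = c("cytokine", "granule_marker")) {
  kind <- match.arg(kind)
  stim <- dplyr::pull(data, {{ stimulated }})
  ctrl <- dplyr::pull(data, {{ control }})
  if (length(stim) != length(ctrl)) {
    abort("`stimulated` and `control` must have equal length.")
  }
  check_pos <- function(x, label) {
    bad <- which(is.na(x) | x <= 0)
    if (length(bad) > 0) {
      abort(paste0(label, " measurement is missing or nonpositive for series '",
                   data$name[bad[1]], "' at t = ", data$time[bad[1]], " h."))
    }
  }
  check_pos(ctrl, "Control")
  check_pos(stim, "Stimulated")
  out <- data |>
    mutate(kind = kind, value = stim / ctrl) |>
    select("name", "kind", "time", "value")
  validate_profiles(out)
  out
}

#' Log10-normalize ratio profiles
#'
#' Applies the scale normalization used throughout the method: each relative
#' ratio is replaced by its base-10 logarithm, so that a ratio of 1 (no
#' effect) maps to 0 and multiplicative effects become additive. Nonpositive
#' ratios are a domain error, never clipped.
#'
#' @param profiles a profile table with a positive `value` column.
#' @return a tibble with columns `name`, `kind`, `time`, `log_value`.
#' @export
#' @examples
#' example_profiles("granule_marker") |> log10_normalize()
log10_normalize <- function(profiles) {
  validate_profiles(profiles)
  profiles |>
    mutate(log_value = log10(.data$value)) |>
    select("name", "kind", "time", "log_value")
}

# Accept either a raw or an already normalized profile table and return the
# normalized form; used by the fitting and calibration front ends.
ensure_normalized <- function(profiles) {
  if ("log_value" %in% names(profiles)) {
    validate_profiles(profiles, normalized = TRUE)
    as_tibble(profiles[, c("name", "kind", "time", "log_value")])
  } else {
    log10_normalize(profiles)
  }
}

# Split a normalized panel into a named list of per-series tibbles,
# preserving input order.
split_series <- function(profiles) {
  split(profiles, factor(profiles$name, levels = unique(profiles$name)))
}

format_grid <- function(t) paste(t, collapse = ", ")

# Error unless all series in both panels share one timepoint grid; returns it.
shared_grid <- function(a, b = NULL) {
  grids <- lapply(split_series(if (is.null(b)) a else bind_rows(a, b)),
                  function(s) s$time)
  ref <- grids[[1]]
  for (nm in names(grids)) {
    if (!isTRUE(all.equal(grids[[nm]], ref))) {
      abort(paste0("Timepoint grids differ: series '", names(grids)[1],
                   "' has [", format_grid(ref), "] h but series '", nm,
                   "' has [", format_grid(grids[[nm]]), "] h."))
    }
  }
  ref
}
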