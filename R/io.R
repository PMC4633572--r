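#' Read a profile table from CSV/TSV
#'
#' Reads a wide profile table: one row per series, a first column of series
#' names, and one column per timepoint with headers like `"0h", "2h", ...`
#' (a trailing `h` is optional). Cells may be plain numbers or carry a
#' standard-error annotation in the form `"2.57 \u00b1 0.29"` (an ASCII `+/-` is
#' also accepted); the SEM is parsed into the `sem` column and carried along
#' for reporting, but plays no role in the fitting, which uses the mean
#' ratios. ASCII aliases of Greek series names are canonicalized (see
#' [canonical_profile_names()]).
#'
#' @param path file path; comma- or tab-delimited by file extension
#'   (`.tsv`/`.tab` means tab).
#' @param kind profile kind assigned to all series in the file.
#' @return a profile table with columns `name`, `kind`, `time`, `value`,
#'   `sem` (`NA` where absent).
#' @export
#' @examples
#' path <- system.file("extdata", "lps_degranulation.csv",
#'                     package = "granulink")
#' read_profile_table(path, kind = "granule_marker")
read_profile_table <- function(path, kind = c("cytokine", "granule_marker")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path))
  }
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), trim_ws = TRUE, progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort(paste0("Profile table '", path,
                 "' is empty or has no timepoint columns."))
  }
  time_labels <- names(raw)[-1]
  time_match <- stringr::str_match(time_labels, "^\\s*([0-9]+\\.?[0-9]*)\\s*h?\\s*$")
  if (anyNA(time_match[, 2])) {
    bad <- time_labels[is.na(time_match[, 2])][1]
    abort(paste0("Cannot parse timepoint header '", bad, "' in ", path,
                 "; expected hour labels like '12h'."))
  }
  times <- as.numeric(time_match[, 2])
  names_col <- canonical_profile_names(raw[[1]])
  dup <- names_col[duplicated(names_col)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate series name '", dup[1], "' in ", path, "."))
  }

  parse_cell <- function(cell, row, col) {
    m <- stringr::str_match(
      cell,
      "^\\s*([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s*(?:(?:\u00b1|\\+/-)\\s*([0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?))?\\s*$"
    )
    if (is.na(m[1, 2])) {
      abort(paste0("Malformed numeric cell '", cell, "' at row ", row,
                   " ('", names_col[row], "'), column '", time_labels[col],
                   "' of ", path, "."))
    }
    c(value = as.numeric(m[1, 2]), sem = as.numeric(m[1, 3]))
  }

  out <- purrr::map(seq_len(nrow(raw)), function(i) {
    parsed <- purrr::map(seq_along(times), function(j) {
      parse_cell(raw[[j + 1]][i], i, j)
    })
    tibble(
      name = names_col[i], kind = kind, time = times,
      value = purrr::map_dbl(parsed, "value"),
      sem = purrr::map_dbl(parsed, "sem")
    )
  }) |>
    list_rbind() |>
    arrange(match(.data$name, names_col), .data$time)
  validate_profiles(out)
  out
}

#' Write a profile table to CSV/TSV
#'
#' Inverse of [read_profile_table()]: writes the wide dialect with hour
#' headers. When the table is normalized-only (a `log_value` column and no
#' `value`), ratios `10^log_value` are written, so simulated panels
#' round-trip through the same format as measured ones. SEM values, when
#' present, are written as `"value ± sem"` cells.
#'
#' @param profiles a profile table.
#' @param path output path; delimiter chosen by extension as in
#'   [read_profile_table()].
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  if (!"value" %in% names(profiles) && "log_value" %in% names(profiles)) {
    profiles <- mutate(profiles, value = 10^.data$log_value)
  }
  validate_profiles(profiles)
  has_sem <- "sem" %in% names(profiles) && any(!is.na(profiles$sem))
  cell <- if (has_sem) {
    ifelse(is.na(profiles$sem),
           format_num(profiles$value),
           paste0(format_num(profiles$value), " \u00b1 ",
                  format_num(profiles$sem)))
  } else {
    format_num(profiles$value)
  }
  wide <- profiles |>
    mutate(cell = cell, time_label = paste0(format_num(.data$time), "h")) |>
    select("name", "time_label", "cell") |>
    tidyr::pivot_wider(names_from = "time_label", values_from = "cell")
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(wide, path, delim = delim)
  invisible(path)
}

format_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                               trim = TRUE),
         character(1))
}

#' Bundled LPS-stimulation example panel
#'
#' The relative secretion ratios of ten cytokines and the relative
#' degranulation (MFI) ratios of eight granule-specific CD markers measured
#' in LPS-stimulated human neutrophils at 0, 2, 4, 6, 12 and 24 h, each
#' expressed as stimulated over time-matched nonstimulated control and
#' bundled as plain-text fixtures under `inst/extdata/`.
#'
#' @param kind `"both"` (default), `"cytokine"`, or `"granule_marker"`.
#' @return a profile table (18 series when `"both"`).
#' @export
#' @examples
#' example_profiles() |> dplyr::count(kind)
example_profiles <- function(kind = c("both", "cytokine", "granule_marker")) {
  kind <- match.arg(kind)
  cyt <- function() {
    read_profile_table(
      system.file("extdata", "lps_cytokine_secretion.csv",
                  package = "granulink"),
      kind = "cytokine"
    )
  }
  mrk <- function() {
    read_profile_table(
      system.file("extdata", "lps_degranulation.csv", package = "granulink"),
      kind = "granule_marker"
    )
  }
  switch(kind,
         both = bind_rows(cyt(), mrk()),
         cytokine = cyt(),
         granule_marker = mrk())
}

#' Serialize a linkage report
#'
#' Writes `report.json` (the full report: parameters, fits, clusters,
#' overlays — losslessly re-readable with [read_linkage_report()]),
#' `fits.tsv` (one row per pair fit with the accepted flag) and
#' `clusters.tsv`. When the report carries a calibration, also writes
#' `calibration.tsv` (profile, e, avg_rsq), `silhouette.tsv` and
#' `threshold.txt`.
#'
#' @param report a `linkage_report` from [link_profiles()].
#' @param outdir output directory, created if missing.
#' @return `outdir`, invisibly.
#' @export
write_linkage_report <- function(report, outdir) {
  if (!inherits(report, "linkage_report")) {
    abort("`report` must be a linkage_report.")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) {
    abort(paste0("Cannot create output directory: ", outdir))
  }
  readr::write_tsv(report$fits, file.path(outdir, "fits.tsv"))
  readr::write_tsv(report$clusters, file.path(outdir, "clusters.tsv"))

  # JSON has no -Inf: degenerate sentinel adj_rsq serializes as null and is
  # restored by read_linkage_report()
  json_fits <- report$fits
  json_fits$adj_rsq[!is.finite(json_fits$adj_rsq)] <- NA_real_
  payload <- list(
    alpha = report$alpha,
    rsq_min = report$rsq_min,
    threshold_source = report$threshold_source,
    p_adjust = report$p_adjust,
    fits = json_fits,
    clusters = report$clusters,
    overlays = report$overlays
  )
  jsonlite::write_json(payload, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  if (!is.null(report$calibration)) {
    cal <- report$calibration
    readr::write_tsv(cal$curves, file.path(outdir, "calibration.tsv"))
    readr::write_tsv(cal$silhouette_by_k, file.path(outdir, "silhouette.tsv"))
    writeLines(format_num(cal$threshold), file.path(outdir, "threshold.txt"))
  }
  invisible(outdir)
}

#' Read back a serialized linkage report
#'
#' Reconstructs the `linkage_report` object from the `report.json` written by
#' [write_linkage_report()] (calibration curves, which have their own TSV
#' files, are not part of the JSON round trip).
#'
#' @param path the output directory, or the `report.json` path itself.
#' @return a `linkage_report`.
#' @export
read_linkage_report <- function(path) {
  json_path <- if (dir.exists(path)) file.path(path, "report.json") else path
  if (!file.exists(json_path)) {
    abort(paste0("No report.json found at ", path))
  }
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  retype <- function(df, template) {
    df <- as_tibble(df)
    if (nrow(df) == 0 && length(df) == 0) {
      return(template)
    }
    for (col in names(template)) {
      if (!col %in% names(df)) df[[col]] <- template[[col]][0]
      mode_fun <- switch(class(template[[col]])[1],
                         integer = as.integer,
                         numeric = as.numeric,
                         logical = as.logical,
                         as.character)
      df[[col]] <- mode_fun(df[[col]])
    }
    df[, names(template), drop = FALSE]
  }
  fits_tmpl <- tibble(cytokine = character(), marker = character(),
                      slope = double(), intercept = double(),
                      adj_rsq = double(), p_value = double(),
                      n_points = integer(), degenerate = logical(),
                      accepted = logical())
  clusters_tmpl <- tibble(marker = character(), cytokine = character(),
                          adj_rsq = double(), rank = integer())
  overlays_tmpl <- tibble(cytokine = character(), marker = character(),
                          time = double(), marker_log = double(),
                          cytokine_scaled = double())
  fits <- retype(payload$fits, fits_tmpl)
  # JSON has no -Inf: degenerate fits serialize adj_rsq as null
  fits$adj_rsq[fits$degenerate & is.na(fits$adj_rsq)] <- -Inf
  structure(
    list(
      fits = fits,
      clusters = retype(payload$clusters, clusters_tmpl),
      overlays = retype(payload$overlays, overlays_tmpl),
      alpha = payload$alpha,
      rsq_min = payload$rsq_min,
      threshold_source = payload$threshold_source,
      p_adjust = payload$p_adjust %||% "none",
      calibration = NULL
    ),
    class = "linkage_report"
  )
}
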