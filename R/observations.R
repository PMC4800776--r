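#' @keywords internal
obs_key_cols <- c("species", "colony", "ramet", "temperature", "light", "day")

#' @keywords internal
obs_metric_cols <- c("fvfm", "qm", "rho", "chla", "r_h", "npq")

#' Construct an observation table
#'
#' An observation table is a long ("tidy") tibble with one row per
#' ramet x treatment x day and one column per bleaching metric. Keys are
#' `species`, `colony`, `ramet`, `temperature` (`CT`/`HT`), `light`
#' (`CL`/`HL`) and `day` (integer days relative to stress onset, negative =
#' baseline). Metric columns (all optional per row, `NA` = missing):
#' `fvfm` (dark-adapted PSII yield, 0--1), `qm` (maximum excitation pressure
#' over PSII), `rho` (pigment or cell areal density, unit recorded in
#' metadata), `chla` (chlorophyll *a*, ug cm^-2), `r_h` (holobiont
#' reflectance relative to a white standard) and `npq` (steady-state
#' non-photochemical quenching yield, an extension column used by the
#' synthetic generator's quenching trajectories).
#'
#' Units and the experiment day window are carried as attributes
#' (`"units"`, `"window"`) so downstream operations stay unit-agnostic but
#' unit-aware.
#'
#' @param data A data frame containing the key columns and at least one
#'   metric column.
#' @param units Named character vector of units per metric, e.g.
#'   `c(rho = "ug Chl a cm^-2")`.
#' @param window Length-2 integer vector, inclusive day range of the
#'   experiment (default `c(-10, 11)`: ten baseline days, eleven stress days).
#' @return A tibble with class `coraloptics_obs`.
#' @export
observation_table <- function(data,
                              units = default_units(),
                              window = c(-10L, 11L)) {
  missing_keys <- setdiff(obs_key_cols, names(data))
  if (length(missing_keys)) {
    stop_schema(sprintf("Missing mandatory columns: %s",
                        paste(missing_keys, collapse = ", ")))
  }
  if (!any(obs_metric_cols %in% names(data))) {
    stop_schema("At least one metric column is required.")
  }
  out <- tibble::as_tibble(data)
  attr(out, "units") <- units
  attr(out, "window") <- as.integer(window)
  class(out) <- unique(c("coraloptics_obs", class(out)))
  out
}

#' @rdname observation_table
#' @export
default_units <- function() {
  c(fvfm = "dimensionless", qm = "dimensionless",
    rho = "ug Chl a cm^-2", chla = "ug cm^-2",
    r_h = "fraction of white standard", npq = "dimensionless")
}

#' Read and write observation tables as delimited text
#'
#' Reads a comma-separated observation table (UTF-8, header row). Malformed
#' numeric cells are never coerced silently: every parsing problem is
#' reported with its line number in a warning and the affected cells are
#' `NA`. Duplicate keys that repeat a metric raise an integrity error, and
#' days outside `window` raise a validation warning listing the offending
#' rows.
#'
#' @param path File path to a CSV with columns
#'   `species, colony, ramet, temperature, light, day` plus any of
#'   `fvfm, qm, rho, chla, r_h, npq` (empty cell = missing).
#' @param units,window Passed to [observation_table()].
#' @return A validated observation table tibble.
#' @export
read_observations <- function(path,
                              units = default_units(),
                              window = c(-10L, 11L)) {
  if (!file.exists(path)) stop_schema(sprintf("No such file: %s", path))
  # every column is read as text and converted with strtod so that decimal
  # values round-trip bit-exactly; vroom's fast float path can be 1 ulp off
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  numeric_cols <- intersect(c("day", obs_metric_cols), names(raw))
  bad_lines <- integer()
  for (col in numeric_cols) {
    txt <- raw[[col]]
    val <- suppressWarnings(as.numeric(txt))
    malformed <- which(!is.na(txt) & txt != "" & is.na(val))
    bad_lines <- c(bad_lines, malformed)
    raw[[col]] <- val
  }
  if (length(bad_lines)) {
    rlang::warn(sprintf(
      "%d unparseable cell(s) set to NA (lines %s).",
      length(bad_lines), paste(sort(unique(bad_lines)), collapse = ", ")
    ))
  }
  tab <- observation_table(raw, units = units, window = window)
  check_duplicate_metrics(tab)
  out_of_window <- which(tab$day < window[1] | tab$day > window[2])
  if (length(out_of_window)) {
    rlang::warn(sprintf(
      "%d observation(s) outside day window [%d, %d] (rows %s).",
      length(out_of_window), window[1], window[2],
      paste(out_of_window, collapse = ", ")
    ))
  }
  tab
}

#' @rdname read_observations
#' @param table An observation table.
#' @export
write_observations <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

# integrity: a (species, colony, ramet, treatment, day) key may not carry
# the same metric twice
check_duplicate_metrics <- function(table) {
  metrics <- intersect(obs_metric_cols, names(table))
  dup <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(obs_key_cols))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metrics), ~ sum(!is.na(.x))),
      .groups = "drop"
    ) |>
    dplyr::filter(dplyr::if_any(dplyr::all_of(metrics), ~ .x > 1L))
  if (nrow(dup)) {
    key <- paste(unlist(dup[1, obs_key_cols]), collapse = " / ")
    stop_integrity(sprintf(
      "Duplicate metric values for %d key(s); first offending key: %s",
      nrow(dup), key
    ))
  }
  invisible(table)
}

#' Validate an observation table
#'
#' Pure, report-only validation: the table is never altered. Checks value
#' ranges (yields in 0--1, densities and reflectance non-negative), that
#' every row carries at least one metric, that treatment levels are drawn
#' from the CT/HT x CL/HL factorial, day-window membership, and key
#' uniqueness per metric.
#'
#' @param table An observation table (see [observation_table()]).
#' @param window Day window; defaults to the table's `"window"` attribute.
#' @return A tibble report with columns `rule`, `rows` (comma-separated row
#'   numbers) and `message`; zero rows iff every invariant holds.
#' @export
validate_observations <- function(table, window = attr(table, "window")) {
  window <- window %||% c(-10L, 11L)
  metrics <- intersect(obs_metric_cols, names(table))
  report <- list()
  note <- function(rule, rows, message) {
    tibble::tibble(rule = rule,
                   rows = paste(rows, collapse = ","),
                   message = message)
  }

  rng <- list(
    fvfm = c(0, 1), qm = c(0, 1), npq = c(0, 1),
    rho = c(0, Inf), chla = c(0, Inf), r_h = c(0, Inf)
  )
  for (m in metrics) {
    bad <- which(!is.na(table[[m]]) &
                   (table[[m]] < rng[[m]][1] | table[[m]] > rng[[m]][2]))
    if (length(bad)) {
      report <- c(report, list(note(
        "range", bad,
        sprintf("`%s` outside [%g, %g]", m, rng[[m]][1], rng[[m]][2])
      )))
    }
  }

  no_metric <- which(rowSums(!is.na(table[, metrics, drop = FALSE])) == 0)
  if (length(no_metric)) {
    report <- c(report, list(note("no_metric", no_metric,
                                  "no metric present")))
  }

  bad_t <- which(!table$temperature %in% c("CT", "HT"))
  if (length(bad_t)) {
    report <- c(report, list(note("treatment", bad_t,
                                  "temperature level not CT/HT")))
  }
  bad_l <- which(!table$light %in% c("CL", "HL"))
  if (length(bad_l)) {
    report <- c(report, list(note("treatment", bad_l,
                                  "light level not CL/HL")))
  }

  out_win <- which(table$day < window[1] | table$day > window[2])
  if (length(out_win)) {
    report <- c(report, list(note(
      "window", out_win,
      sprintf("day outside [%d, %d]", window[1], window[2])
    )))
  }

  dup <- tryCatch({
    check_duplicate_metrics(table)
    NULL
  }, coraloptics_integrity_error = function(e) conditionMessage(e))
  if (!is.null(dup)) {
    report <- c(report, list(note("uniqueness", integer(0), dup)))
  }

  if (length(report)) dplyr::bind_rows(report) else {
    tibble::tibble(rule = character(), rows = character(),
                   message = character())
  }
}
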