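#' Temporal rate of a bleaching metric (PE)
#'
#' The photochemical-efficiency rate PE is the temporal slope of a metric
#' (conventionally Fv/Fm) against day, estimated by ordinary least squares
#' within a day window. Standard error and the two-sided p-value come from
#' the usual slope t-test.
#'
#' @param days Numeric day stamps.
#' @param values Metric values matched to `days`.
#' @param window Inclusive day range used for the fit (default the stress
#'   window, days 0--11).
#' @return A one-row tibble: `slope` (per day), `se`, `n`, `p`,
#'   `day_start`, `day_end`.
#' @export
#' @examples
#' pe_slope(c(0, 2, 4, 6), c(0.60, 0.54, 0.48, 0.42)) # slope -0.03
pe_slope <- function(days, values, window = c(0, 11)) {
  keep <- !is.na(values) & !is.na(days) &
    days >= window[1] & days <= window[2]
  days <- days[keep]
  values <- values[keep]
  if (length(days) < 2L || length(unique(days)) < 2L) {
    stop_domain("Need >= 2 points at distinct days inside the window.")
  }
  fit <- lm(values ~ days)
  # noiseless trajectories are a legitimate oracle case; summary.lm warns
  # about "essentially perfect fit" there
  sm <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(
    slope = unname(sm["days", "Estimate"]),
    se = unname(sm["days", "Std. Error"]),
    n = length(days),
    p = unname(sm["days", "Pr(>|t|)"]),
    day_start = window[1], day_end = window[2]
  )
}

#' Per-ramet PE slopes for a whole observation table
#'
#' Applies [pe_slope()] to every ramet x treatment trajectory of one
#' metric.
#'
#' @param table An observation table.
#' @param metric Metric column name (default `"fvfm"`).
#' @param window Day window passed to [pe_slope()].
#' @return A tibble with key columns `species`, `colony`, `ramet`,
#'   `temperature`, `light` plus the [pe_slope()] columns.
#' @export
pe_table <- function(table, metric = "fvfm", window = c(0, 11)) {
  if (!metric %in% names(table)) {
    stop_schema(sprintf("No `%s` column in the table.", metric))
  }
  tibble::as_tibble(table) |>
    dplyr::group_by(.data$species, .data$colony, .data$ramet,
                    .data$temperature, .data$light) |>
    dplyr::filter(sum(!is.na(.data[[metric]]) &
                        .data$day >= window[1] &
                        .data$day <= window[2]) >= 2L) |>
    dplyr::group_modify(~ pe_slope(.x$day, .x[[metric]], window)) |>
    dplyr::ungroup()
}

#' Light- or temperature-isolated rate differences (Delta PE)
#'
#' Subtracting PE between treatment cells cancels, to first order, every
#' additive confounder that does not depend on the manipulated factor
#' (localized flow, tissue thickness, and any other ramet- or
#' species-specific offset). PE per species x treatment cell is the mean of
#' ramet-level slopes; the light basis contrasts HL - CL at each fixed
#' temperature, the temperature basis HT - CT at each fixed light level.
#'
#' @param pe A per-ramet PE table from [pe_table()] (or any tibble with
#'   `species`, `temperature`, `light`, `slope`).
#' @param basis `"light"` or `"temperature"`.
#' @return A tibble: `species`, `basis`, `conditioning` (the level held
#'   fixed: `CT`/`HT` for the light basis, `CL`/`HL` for the temperature
#'   basis) and `value` (day^-1). Species missing a required cell are
#'   dropped with a warning.
#' @export
delta_pe <- function(pe, basis = c("light", "temperature")) {
  basis <- match.arg(basis)
  cells <- pe |>
    dplyr::group_by(.data$species, .data$temperature, .data$light) |>
    dplyr::summarise(pe = mean(.data$slope), .groups = "drop")
  wide <- cells |>
    tidyr::pivot_wider(names_from = c("temperature", "light"),
                       values_from = "pe", names_sep = "_")
  need <- c("CT_CL", "CT_HL", "HT_CL", "HT_HL")
  for (col in setdiff(need, names(wide))) wide[[col]] <- NA_real_

  out <- if (basis == "light") {
    dplyr::bind_rows(
      tibble::tibble(species = wide$species, basis = "light",
                     conditioning = "CT", value = wide$CT_HL - wide$CT_CL),
      tibble::tibble(species = wide$species, basis = "light",
                     conditioning = "HT", value = wide$HT_HL - wide$HT_CL)
    )
  } else {
    dplyr::bind_rows(
      tibble::tibble(species = wide$species, basis = "temperature",
                     conditioning = "CL", value = wide$HT_CL - wide$CT_CL),
      tibble::tibble(species = wide$species, basis = "temperature",
                     conditioning = "HL", value = wide$HT_HL - wide$CT_HL)
    )
  }
  if (anyNA(out$value)) {
    skipped <- unique(out$species[is.na(out$value)])
    rlang::warn(sprintf("Species skipped for missing treatment cells: %s",
                        paste(skipped, collapse = ", ")))
    out <- out[!is.na(out$value), , drop = FALSE]
  }
  out
}

#' Regress Delta PE on microscopic skeletal scattering
#'
#' Species-level OLS of the isolated rate difference on `mu_sm`, the
#' central susceptibility regression: a positive slope with Delta PE
#' approaching zero at high scattering indicates that densely scattering
#' skeletons buffer their symbionts against light-driven loss of
#' photochemical efficiency.
#'
#' @param depe A [delta_pe()] tibble, typically filtered to one
#'   conditioning level.
#' @param profiles An optical-profile table with `species` and `mu_sm`.
#' @return A one-row tibble: `slope`, `intercept`, `r2`, `p` (slope
#'   t-test), `n`.
#' @export
regress_depe <- function(depe, profiles) {
  depe <- tibble::as_tibble(depe)
  depe$mu_sm <- NULL  # always taken from `profiles`
  dat <- dplyr::inner_join(depe,
                           tibble::as_tibble(profiles)[c("species", "mu_sm")],
                           by = "species")
  dat <- dat[!is.na(dat$value) & !is.na(dat$mu_sm), , drop = FALSE]
  if (nrow(dat) < 3L) {
    stop_domain("Need >= 3 species with both Delta PE and mu_sm.")
  }
  fit <- lm(value ~ mu_sm, data = dat)
  sm <- suppressWarnings(summary(fit))
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = sm$r.squared,
    p = unname(sm$coefficients["mu_sm", "Pr(>|t|)"]),
    n = nrow(dat)
  )
}
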