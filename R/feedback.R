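#' Per-species optical feedback analysis
#'
#' Runs the absorption side of the pipeline on an observation table: for
#' each species, the holobiont-reflectance and pigment trajectories of the
#' two thermal arms (HT-HL and HT-CL) are reduced to species x day means,
#' inverted with [infer_absorption()] (lower-bound parameters by default),
#' formed into skeleton-dependent absorption per unit pigment
#' (`I_a2 / rho`), and differenced HL minus CL at matched days; the
#' [feedback_rate()] of each species is the rate at which that excess grows
#' as pigment declines, using the HT-HL pigment trajectory as the pigment
#' axis.
#'
#' @param table An observation table with `r_h` and `rho` columns.
#' @param profiles Optical profiles supplying `r_s` and `mu_sm` per
#'   species.
#' @param params [absorption_params()] used for the inversion.
#' @param window Stress-day window over which trajectories are formed.
#' @return A tibble: `species`, `mu_sm`, `rate` (per unit rho), `n_days`.
#' @export
feedback_by_species <- function(table, profiles,
                                params = absorption_params(),
                                window = c(0, 11)) {
  prof <- tibble::as_tibble(profiles)
  arms <- tibble::as_tibble(table) |>
    dplyr::filter(.data$temperature == "HT",
                  .data$day >= window[1], .data$day <= window[2],
                  !is.na(.data$r_h), !is.na(.data$rho)) |>
    dplyr::group_by(.data$species, .data$light, .data$day) |>
    dplyr::summarise(r_h = mean(.data$r_h), rho = mean(.data$rho),
                     .groups = "drop") |>
    dplyr::left_join(prof[c("species", "r_s", "mu_sm")], by = "species")
  if (anyNA(arms$r_s)) {
    stop_schema("Every species needs an `r_s` in `profiles`.")
  }
  abs_res <- infer_absorption(arms$r_h, arms$r_s, params)
  arms$ratio <- abs_res$i_a2 / arms$rho

  wide <- arms |>
    dplyr::select("species", "mu_sm", "light", "day", "rho", "ratio") |>
    tidyr::pivot_wider(names_from = "light",
                       values_from = c("rho", "ratio")) |>
    dplyr::filter(!is.na(.data$ratio_HL), !is.na(.data$ratio_CL))

  wide |>
    dplyr::group_by(.data$species, .data$mu_sm) |>
    dplyr::summarise(
      rate = if (dplyr::n() >= 2L) {
        as.numeric(feedback_rate(.data$ratio_HL, .data$ratio_CL,
                                 .data$rho_HL))
      } else NA_real_,
      n_days = dplyr::n(),
      .groups = "drop"
    )
}

#' Fit the feedback-rate power law across species
#'
#' Regresses per-species feedback rates (from [feedback_by_species()])
#' against microscopic skeletal scattering as an inverse power law in
#' log-log space. Species with non-positive rates cannot enter the log fit
#' and are dropped with a warning.
#'
#' @param feedback A tibble with `species`, `mu_sm` and `rate`.
#' @return A `coraloptics_powerlaw` object (see
#'   [fit_inverse_power_law()]).
#' @export
fit_feedback_power_law <- function(feedback) {
  ok <- !is.na(feedback$rate) & feedback$rate > 0
  if (any(!ok)) {
    rlang::warn(sprintf(
      "%d species dropped from the power-law fit (non-positive rate): %s",
      sum(!ok), paste(feedback$species[!ok], collapse = ", ")
    ))
  }
  fb <- feedback[ok, , drop = FALSE]
  fit_inverse_power_law(setNames(fb$mu_sm, fb$species),
                        setNames(fb$rate, fb$species))
}
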