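#' Default configuration of the synthetic bleaching experiment
#'
#' Builds the full parameterization of the simulated heat/light stress
#' experiment: ten species (see [species_profiles()]), the 2 x 2 factorial
#' of control/high temperature (26.2 / 32.3 C) crossed with control/high
#' light (83 / 328 umol photons m^-2 s^-1), eight ramets per species per
#' treatment cell, sampling every second day over a ten-day baseline and an
#' eleven-day stress window (days -10, -8, ..., 10 plus a terminal day 11).
#'
#' Trajectory model: photophysiological yields decline piecewise-linearly
#' (flat baseline, linear slope from stress onset) with additive Gaussian
#' noise; pigment and chlorophyll densities decay exponentially with
#' multiplicative log-normal noise; holobiont reflectance is produced
#' through the forward optical model with first-pass absorption linked to
#' pigment density by `i_a1 = 1 - exp(-sigma * rho)`, so the analysis-side
#' inversion is exercised against known ground truth. Per-species pigment
#' decay under thermal stress scales inversely with microscopic scattering
#' (`mu_sm^-1`, the optical-feedback structure the generator emulates) with
#' log-normal species dispersion.
#'
#' Default group-level yield slopes under combined stress are the
#' calibration the clustered model is expected to recover
#' (Fv/Fm: -0.0319 / -0.0144 day^-1 and Qm: 0.043 / 0.011 day^-1 for the
#' low / high scattering groups); the species-level Delta-PE calibrations
#' (intercept, slope and noise sd against `mu_sm` per basis) are chosen so
#' the expected coefficients of determination of the susceptibility
#' regressions are 0.62 (light basis at high temperature), 0.35 (light
#' basis at control temperature) and 0.18 (temperature basis); the noise
#' sds were solved once by simulation for the default fixture and are
#' frozen here.
#'
#' @param ... Named overrides of any default element (checked against the
#'   known names).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    profiles = species_profiles(),
    treatments = tibble::tibble(
      temperature = c("CT", "CT", "HT", "HT"),
      light = c("CL", "HL", "CL", "HL"),
      temp_c = c(26.2, 26.2, 32.3, 32.3),
      light_umol = c(83, 328, 83, 328)
    ),
    n_ramets_per_cell = 8L,
    days = c(seq(-10L, 10L, by = 2L), 11L),
    stress_window = c(0L, 11L),
    # group x treatment linear slopes (day^-1)
    rate_params = tibble::tibble(
      temperature = c("CT", "CT", "CT", "CT", "HT", "HT", "HT", "HT"),
      light = c("CL", "CL", "HL", "HL", "CL", "CL", "HL", "HL"),
      group = rep(c("low", "high"), 4),
      fvfm_slope = c(0, 0, -0.008, -0.003, -0.018, -0.010, -0.0319, -0.0144),
      qm_slope = c(0, 0, 0.010, 0.004, 0.025, 0.007, 0.043, 0.011)
    ),
    baseline_params = tibble::tibble(
      group = c("low", "high"),
      fvfm0 = c(0.62, 0.56),
      qm0 = c(0.30, 0.25),
      rho0 = c(5, 8),       # ug Chl a cm^-2
      chla0 = c(9, 7),      # ug cm^-2
      npq0 = c(0.20, 0.20)
    ),
    # treatment-level pigment decay scale (day^-1 at mu_sm = mu_ref)
    pigment_decay = tibble::tibble(
      temperature = c("CT", "CT", "HT", "HT"),
      light = c("CL", "HL", "CL", "HL"),
      decay_scale = c(0, 0.004, 0.06, 0.11)
    ),
    chla_decay_factor = 0.8,
    mu_ref = 3.552,              # fixture mean mu_sm, mm^-1
    feedback_disp = 0.23,        # lognormal sd of species optical dispersion
    species_slope_sd = c(fvfm = 0.002, qm = 0.003),
    noise_sd = c(fvfm = 0.02, qm = 0.03, npq = 0.02, r_h = 0.01),
    density_sdlog = 0.08,
    sigma = 0.2,                 # cm^2 per ug: i_a1 = 1 - exp(-sigma_s * rho)
    sigma_mu_exp = 1,            # sigma_s = sigma * (mu_ref / mu_sm)^exp
    npq_fold = c(low = 1.8, high = 1.2),
    depe_calibration = list(
      light_ht = list(intercept = -0.0213300, slope = 0.0036965,
                      sd = 0.004413),
      light_ct = list(intercept = -0.0119105, slope = 0.0019455,
                      sd = 0.004300),
      temperature = list(intercept = -0.0242568, slope = 0.0031128,
                         sd = 0.014138)
    ),
    necrosis_rate = 0.013,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    rlang::abort(sprintf("Unknown config field(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "coraloptics_config_error")
  }
  cfg <- modifyList(cfg, overrides)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_ramets_per_cell < 1L) {
    rlang::abort("`n_ramets_per_cell` must be >= 1.",
                 class = "coraloptics_config_error")
  }
  if (any(cfg$noise_sd < 0) || cfg$density_sdlog < 0) {
    rlang::abort("Noise parameters must be >= 0.",
                 class = "coraloptics_config_error")
  }
  if (!is_number(cfg$sigma) || cfg$sigma <= 0) {
    rlang::abort("`sigma` must be > 0.",
                 class = "coraloptics_config_error")
  }
  if (!all(is.finite(cfg$rate_params$fvfm_slope)) ||
      !all(is.finite(cfg$rate_params$qm_slope))) {
    rlang::abort("All rate parameters must be finite.",
                 class = "coraloptics_config_error")
  }
  invisible(cfg)
}

# species x treatment mean-structure table: slopes, decays, baselines
generator_truth <- function(cfg) {
  prof <- cfg$profiles
  grid <- tidyr::expand_grid(
    species = prof$species,
    cfg$treatments[c("temperature", "light")]
  ) |>
    dplyr::left_join(prof[c("species", "mu_sm", "r_s", "group")],
                     by = "species") |>
    dplyr::left_join(cfg$rate_params,
                     by = c("temperature", "light", "group")) |>
    dplyr::left_join(cfg$pigment_decay, by = c("temperature", "light")) |>
    dplyr::left_join(cfg$baseline_params, by = "group")
  grid
}

#' Generate a complete synthetic bleaching experiment
#'
#' Simulates the full observation table (see [observation_table()]) under
#' the configured study conditions. The holobiont reflectance of every
#' record is produced by the forward optical model from that record's
#' realized pigment density, so inverting the noisy reflectances with
#' [infer_absorption()] recovers a known ground truth. The steady-state
#' non-photochemical quenching yield (`npq`) sits at its group baseline
#' until stress onset and at `npq_fold` times baseline on post-onset days
#' under thermal stress.
#'
#' Identical `(config, seed)` pairs give bit-identical tables. Yields are
#' clipped to [0, 1]; the number of clipped values is recorded in the
#' `"clip_count"` attribute. Ground truth (per-row noiseless `i_a1`,
#' `i_a2`, `rho_mean` and the per-species-by-treatment mean structure) is
#' attached as the `"truth"` attribute.
#'
#' @param config A [generator_config()].
#' @param seed Integer RNG seed (default the config's).
#' @return An observation table tibble with attributes `"truth"` and
#'   `"clip_count"`.
#' @export
generate_experiment <- function(config = generator_config(),
                                seed = config$seed) {
  validate_generator_config(config)
  set.seed(seed)
  truth <- generator_truth(config)

  # species-level effects: slope jitter (per species x treatment) and one
  # optical dispersion factor per species perturbing its absorption
  # cross-section (shared across treatments and days)
  n_sp <- nrow(config$profiles)
  disp <- stats::setNames(
    exp(rnorm(n_sp, 0, config$feedback_disp)), config$profiles$species
  )
  truth <- truth |>
    dplyr::mutate(
      fvfm_slope_sp = .data$fvfm_slope +
        rnorm(dplyr::n(), 0, config$species_slope_sd[["fvfm"]]),
      qm_slope_sp = .data$qm_slope +
        rnorm(dplyr::n(), 0, config$species_slope_sd[["qm"]]),
      decay_sp = .data$decay_scale * (config$mu_ref / .data$mu_sm)
    )

  ramets <- sprintf("r%02d", seq_len(config$n_ramets_per_cell))
  grid <- tidyr::expand_grid(
    truth,
    ramet = ramets,
    day = config$days
  ) |>
    dplyr::mutate(
      colony = paste0(.data$species, " colony"),
      stress_day = pmax(.data$day, 0)
    )

  n <- nrow(grid)
  nsd <- config$noise_sd
  fold <- config$npq_fold[as.character(grid$group)]
  hot <- grid$temperature == "HT"

  fvfm_mean <- grid$fvfm0 + grid$fvfm_slope_sp * grid$stress_day
  qm_mean <- grid$qm0 + grid$qm_slope_sp * grid$stress_day
  npq_mean <- unname(grid$npq0 * ifelse(hot & grid$day > 0, fold, 1))
  rho_mean <- grid$rho0 * exp(-grid$decay_sp * grid$stress_day)
  chla_mean <- grid$chla0 *
    exp(-config$chla_decay_factor * grid$decay_sp * grid$stress_day)

  rho <- unname(rho_mean * exp(rnorm(n, 0, config$density_sdlog)))
  chla <- unname(chla_mean * exp(rnorm(n, 0, config$density_sdlog)))
  # per-pigment absorption cross-section grows as microscopic scattering
  # falls: weakly scattering skeletons return more light per unit pigment;
  # `disp` carries species-level lognormal dispersion around that relation
  sigma_s <- config$sigma *
    (config$mu_ref / grid$mu_sm)^config$sigma_mu_exp *
    disp[grid$species]
  i_a1 <- unname(1 - exp(-sigma_s * rho))
  r_h_clean <- forward_reflectance(i_a1, grid$r_s)
  r_h <- pmax(r_h_clean + rnorm(n, 0, nsd[["r_h"]]), 0)

  clip01 <- function(x) pmin(pmax(x, 0), 1)
  fvfm_raw <- fvfm_mean + rnorm(n, 0, nsd[["fvfm"]])
  qm_raw <- qm_mean + rnorm(n, 0, nsd[["qm"]])
  npq_raw <- npq_mean + rnorm(n, 0, nsd[["npq"]])
  clip_count <- sum(fvfm_raw < 0 | fvfm_raw > 1) +
    sum(qm_raw < 0 | qm_raw > 1) + sum(npq_raw < 0 | npq_raw > 1) +
    sum(r_h_clean + (r_h - r_h_clean) < 0)

  tab <- tibble::tibble(
    species = grid$species,
    colony = grid$colony,
    ramet = grid$ramet,
    temperature = grid$temperature,
    light = grid$light,
    day = grid$day,
    fvfm = clip01(fvfm_raw),
    qm = clip01(qm_raw),
    rho = rho,
    chla = chla,
    r_h = r_h,
    npq = clip01(npq_raw)
  )
  out <- observation_table(tab)
  i_a2_true <- (1 - i_a1) * i_a1 * grid$r_s  # lower-bound params
  attr(out, "truth") <- list(
    per_row = tibble::tibble(
      i_a1 = i_a1, i_a2 = i_a2_true, rho_mean = rho_mean,
      r_h_clean = r_h_clean
    ),
    mean_structure = truth
  )
  attr(out, "clip_count") <- clip_count
  out
}

#' Remove ramets by simulated necrosis
#'
#' Each ramet is independently removed with probability `rate`; a removed
#' ramet loses all observations from a uniformly drawn necrosis day (one of
#' its scheduled days) onward, mimicking mid-experiment removal of necrotic
#' replicates.
#'
#' @param table An observation table.
#' @param rate Removal probability per ramet, in [0, 1).
#' @param seed Integer RNG seed.
#' @return A list: `table` (reduced observation table) and `removals`
#'   (log tibble: `species`, `colony`, `ramet`, `temperature`, `light`,
#'   `necrosis_day`).
#' @export
apply_necrosis_dropout <- function(table, rate = 0.013, seed = 1L) {
  if (!is_number(rate) || rate < 0 || rate >= 1) {
    stop_domain("`rate` must lie in [0, 1).")
  }
  empty_log <- tibble::tibble(
    species = character(), colony = character(), ramet = character(),
    temperature = character(), light = character(),
    necrosis_day = numeric()
  )
  if (rate == 0) return(list(table = table, removals = empty_log))
  set.seed(seed)
  key <- c("species", "colony", "ramet", "temperature", "light")
  units <- dplyr::distinct(tibble::as_tibble(table)[key])
  hit <- runif(nrow(units)) < rate
  if (!any(hit)) return(list(table = table, removals = empty_log))
  removed <- units[hit, , drop = FALSE]
  removed$necrosis_day <- purrr::pmap_dbl(removed, function(...) {
    u <- list(...)
    days <- sort(unique(table$day[
      table$species == u$species & table$ramet == u$ramet &
        table$temperature == u$temperature & table$light == u$light
    ]))
    days[sample.int(length(days), 1L)]
  })
  reduced <- tibble::as_tibble(table) |>
    dplyr::left_join(removed, by = key) |>
    dplyr::filter(is.na(.data$necrosis_day) |
                    .data$day < .data$necrosis_day) |>
    dplyr::select(-"necrosis_day")
  out <- observation_table(reduced,
                           units = attr(table, "units") %||% default_units(),
                           window = attr(table, "window") %||% c(-10L, 11L))
  list(table = out, removals = removed)
}

#' Simulate species-level Delta-PE datasets from the default calibration
#'
#' Draws one Delta-PE value per species around the configured linear
#' relation with `mu_sm` (`value = intercept + slope * mu_sm + N(0, sd)`),
#' for use in susceptibility-regression recovery studies.
#'
#' @param config A [generator_config()].
#' @param basis Which calibration: `"light_ht"` (light basis at high
#'   temperature), `"light_ct"` (light basis at control temperature) or
#'   `"temperature"` (temperature basis).
#' @param seed Optional integer seed (set only when non-NULL).
#' @return A tibble: `species`, `mu_sm`, `value`.
#' @export
simulate_depe <- function(config = generator_config(),
                          basis = c("light_ht", "light_ct", "temperature"),
                          seed = NULL) {
  basis <- match.arg(basis)
  if (!is.null(seed)) set.seed(seed)
  cal <- config$depe_calibration[[basis]]
  prof <- config$profiles
  tibble::tibble(
    species = prof$species,
    mu_sm = prof$mu_sm,
    value = cal$intercept + cal$slope * prof$mu_sm +
      rnorm(nrow(prof), 0, cal$sd)
  )
}

#' Generate white-standard-paired reflectance spectra
#'
#' Emits smooth synthetic spectra on a 400--800 nm grid whose visible-band
#' (400--700 nm) mean equals each scalar target exactly before noise. An
#' optional chlorophyll-like absorption dip centred at 675 nm can be added;
#' the dip is compensated by a constant offset inside the visible band so
#' the band mean is preserved while the 675 nm value drops below it. Each
#' spectrum is paired with white-standard and dark counts such that
#' [normalize_spectrum()] reproduces the (noisy) reflectance exactly.
#'
#' @param scalar_targets Numeric vector of target band-mean reflectances,
#'   each in (0, 1.2).
#' @param n_replicates Replicate spectra per target (e.g. 10 measurement
#'   spots).
#' @param dip_depth Depth of the 675 nm absorption dip (reflectance units).
#' @param noise_cov Multiplicative replicate noise as a coefficient of
#'   variation in percent (log-normal).
#' @param step_nm Wavelength grid step.
#' @param seed Optional integer seed.
#' @return A long tibble: `measurement_id`, `replicate`, `wavelength_nm`,
#'   `sample`, `standard`, `dark`.
#' @export
generate_reflectance_spectra <- function(scalar_targets, n_replicates = 1L,
                                         dip_depth = 0, noise_cov = 0,
                                         step_nm = 5, seed = NULL) {
  if (any(scalar_targets <= 0) || any(scalar_targets >= 1.2)) {
    stop_domain("Scalar targets must lie in (0, 1.2).")
  }
  if (!is.null(seed)) set.seed(seed)
  wl <- seq(400, 800, by = step_nm)
  vis <- wl >= 400 & wl <= 700
  dip <- dip_depth * exp(-((wl - 675)^2) / (2 * 12^2))
  comp <- mean(dip[vis])  # restores the band mean after the dip
  sdlog <- sqrt(log(1 + (noise_cov / 100)^2))
  standard <- 1000
  dark <- 30

  purrr::imap(scalar_targets, function(target, id) {
    base <- target + comp - dip
    base[wl > 700] <- target + 0.15 * (wl[wl > 700] - 700) / 100  # NIR rise
    if (any(base[vis] < 0)) {
      stop_domain("Dip too deep for this target: negative reflectance.")
    }
    purrr::map(seq_len(n_replicates), function(rep_i) {
      refl <- base * if (noise_cov > 0) exp(rnorm(1, 0, sdlog)) else 1
      tibble::tibble(
        measurement_id = sprintf("m%03d", id),
        replicate = rep_i,
        wavelength_nm = wl,
        sample = dark + refl * (standard - dark),
        standard = standard,
        dark = dark
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
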