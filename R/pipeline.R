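#' Run the full bleaching analysis pipeline
#'
#' Orchestrates the stages of the analysis behind one call, with every
#' stage communicating through delimited-text artifacts in `outdir` so any
#' stage's input can be replaced by real experimental data with the same
#' schema:
#' \describe{
#'   \item{simulate}{generate the synthetic experiment, apply necrosis
#'     dropout, write `observations.csv`, `removals.csv`, `profiles.csv`.}
#'   \item{absorb}{invert reflectance into absorbed-light fractions per
#'     observation (`absorption.csv`).}
#'   \item{rates}{per-ramet PE slopes for Fv/Fm and Qm (`pe_fvfm.csv`,
#'     `pe_qm.csv`).}
#'   \item{depe}{light- and temperature-basis Delta-PE per species and
#'     their regressions on `mu_sm` (`depe.csv`, `depe_regression.csv`).}
#'   \item{stats}{clustered rate models under combined stress, marginal
#'     per-day comparisons, baseline tests (`rates_by_group.csv`,
#'     `marginal_days.csv`, `baseline.csv`).}
#'   \item{feedback}{per-species feedback rates and the inverse power-law
#'     fit (`feedback.csv`, `powerlaw.csv`).}
#'   \item{report}{trajectory and regression figures (`fig_*.png`).}
#' }
#'
#' A YAML run manifest (`manifest.yaml`) records the config hash, seed,
#' package version, per-stage wall time and every artifact written;
#' rerunning with the same config and seed reproduces stochastic stages
#' bit-identically.
#'
#' @param outdir Output directory (created if missing).
#' @param config A [generator_config()].
#' @param seed Integer seed for the stochastic stages.
#' @param stages Character vector of stages to run (dependency order is
#'   enforced; missing upstream artifacts raise a dependency error naming
#'   the stage).
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(outdir,
                         config = generator_config(),
                         seed = config$seed,
                         stages = c("simulate", "absorb", "rates", "depe",
                                    "stats", "feedback", "report")) {
  all_stages <- c("simulate", "absorb", "rates", "depe", "stats",
                  "feedback", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  need <- function(f, stage) {
    if (!file.exists(pth(f))) {
      rlang::abort(sprintf(
        "Stage `%s` needs artifact `%s`; run its upstream stage first.",
        stage, f
      ), class = "coraloptics_dependency_error")
    }
    pth(f)
  }
  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("coraloptics")),
    stages = list()
  )
  artifacts <- character()
  log_stage <- function(name, outputs, elapsed, notes = NULL) {
    manifest$stages[[name]] <<- list(
      outputs = outputs, seconds = round(elapsed, 3),
      notes = notes
    )
    artifacts <<- c(artifacts, outputs)
  }

  if ("simulate" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    tab <- generate_experiment(config, seed = seed)
    drop <- apply_necrosis_dropout(tab, rate = config$necrosis_rate,
                                   seed = seed + 1L)
    write_observations(drop$table, pth("observations.csv"))
    readr::write_csv(drop$removals, pth("removals.csv"), progress = FALSE)
    write_optical_profiles(config$profiles, pth("profiles.csv"))
    log_stage("simulate",
              c("observations.csv", "removals.csv", "profiles.csv"),
              proc.time()[["elapsed"]] - t0,
              notes = sprintf("%d ramets removed by necrosis; %d clips",
                              nrow(drop$removals),
                              attr(tab, "clip_count")))
  }

  obs <- NULL
  prof <- NULL
  load_inputs <- function(stage) {
    if (is.null(obs)) {
      obs <<- read_observations(need("observations.csv", stage))
      prof <<- read_optical_profiles(need("profiles.csv", stage))
    }
  }

  if ("absorb" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    load_inputs("absorb")
    dat <- tibble::as_tibble(obs) |>
      dplyr::left_join(tibble::as_tibble(prof)[c("species", "r_s")],
                       by = "species") |>
      dplyr::filter(!is.na(.data$r_h))
    inv <- infer_absorption(dat$r_h, dat$r_s)
    out <- dplyr::bind_cols(
      dat[c("species", "colony", "ramet", "temperature", "light", "day")],
      inv[c("i_a1", "i_a2", "i_a", "r_prime", "flag")]
    )
    readr::write_csv(out, pth("absorption.csv"), progress = FALSE)
    log_stage("absorb", "absorption.csv", proc.time()[["elapsed"]] - t0,
              notes = sprintf("%d over-bright observation(s) clamped",
                              sum(inv$flag == "over-bright")))
  }

  if ("rates" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    load_inputs("rates")
    readr::write_csv(pe_table(obs, "fvfm"), pth("pe_fvfm.csv"),
                     progress = FALSE)
    readr::write_csv(pe_table(obs, "qm"), pth("pe_qm.csv"),
                     progress = FALSE)
    log_stage("rates", c("pe_fvfm.csv", "pe_qm.csv"),
              proc.time()[["elapsed"]] - t0)
  }

  if ("depe" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    load_inputs("depe")
    pe <- readr::read_csv(need("pe_fvfm.csv", "depe"),
                          show_col_types = FALSE, progress = FALSE)
    depe <- dplyr::bind_rows(delta_pe(pe, "light"),
                             delta_pe(pe, "temperature"))
    readr::write_csv(depe, pth("depe.csv"), progress = FALSE)
    reg <- depe |>
      dplyr::group_by(.data$basis, .data$conditioning) |>
      dplyr::group_modify(~ regress_depe(.x, prof)) |>
      dplyr::ungroup()
    readr::write_csv(reg, pth("depe_regression.csv"), progress = FALSE)
    log_stage("depe", c("depe.csv", "depe_regression.csv"),
              proc.time()[["elapsed"]] - t0)
  }

  if ("stats" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    load_inputs("stats")
    stress <- tibble::as_tibble(obs) |>
      dplyr::filter(.data$temperature == "HT", .data$light == "HL")
    cla <- purrr::map(c(fvfm = "fvfm", qm = "qm"), function(m) {
      clustered_rate_model(stress, m, profiles = prof)
    })
    by_group <- purrr::imap(cla, function(fit, m) {
      dplyr::mutate(fit$slopes, metric = m,
                    interaction_p = fit$interaction_p, .before = 1)
    }) |> dplyr::bind_rows()
    readr::write_csv(by_group, pth("rates_by_group.csv"), progress = FALSE)

    post_days <- sort(unique(obs$day[obs$day >= 0]))
    marg <- purrr::map(post_days, function(d) {
      dplyr::bind_rows(
        dplyr::mutate(
          marginal_day_comparison(stress, "fvfm", d,
                                  normalize_to_initial = TRUE,
                                  profiles = prof),
          metric = "fvfm", .before = 1
        ),
        dplyr::mutate(
          marginal_day_comparison(stress, "qm", d, profiles = prof),
          metric = "qm", .before = 1
        )
      )
    }) |> dplyr::bind_rows()
    readr::write_csv(marg, pth("marginal_days.csv"), progress = FALSE)

    base <- purrr::map(
      c(fvfm = "fvfm", qm = "qm", rho = "rho", chla = "chla"),
      function(m) baseline_compare(obs, m, profiles = prof)
    ) |> dplyr::bind_rows(.id = "metric")
    readr::write_csv(base, pth("baseline.csv"), progress = FALSE)
    log_stage("stats",
              c("rates_by_group.csv", "marginal_days.csv", "baseline.csv"),
              proc.time()[["elapsed"]] - t0)
  }

  if ("feedback" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    load_inputs("feedback")
    fb <- feedback_by_species(obs, prof)
    readr::write_csv(fb, pth("feedback.csv"), progress = FALSE)
    pl <- fit_feedback_power_law(fb)
    readr::write_csv(
      dplyr::bind_cols(glance(pl),
                       tidyr::pivot_wider(tidy(pl), names_from = "term",
                                          values_from = "estimate")),
      pth("powerlaw.csv"), progress = FALSE
    )
    log_stage("feedback", c("feedback.csv", "powerlaw.csv"),
              proc.time()[["elapsed"]] - t0)
  }

  if ("report" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    load_inputs("report")
    p1 <- plot_trajectories(obs, "fvfm", profiles = prof)
    ggplot2::ggsave(pth("fig_trajectories_fvfm.png"), p1,
                    width = 8, height = 5, dpi = 150)
    p2 <- plot_trajectories(obs, "r_h", profiles = prof)
    ggplot2::ggsave(pth("fig_trajectories_rh.png"), p2,
                    width = 8, height = 5, dpi = 150)
    if (file.exists(pth("depe.csv"))) {
      depe <- readr::read_csv(pth("depe.csv"), show_col_types = FALSE,
                              progress = FALSE)
      p3 <- plot_depe(dplyr::filter(depe, .data$basis == "light"), prof)
      ggplot2::ggsave(pth("fig_depe.png"), p3,
                      width = 6, height = 5, dpi = 150)
    }
    log_stage("report",
              c("fig_trajectories_fvfm.png", "fig_trajectories_rh.png"),
              proc.time()[["elapsed"]] - t0)
  }

  yaml::write_yaml(manifest, pth("manifest.yaml"))
  invisible(manifest)
}
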