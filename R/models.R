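#' Clustered longitudinal model of group-specific temporal rates
#'
#' Fits `metric ~ group + day + group:day` over the stress window with
#' colony-level clustering, estimating one temporal slope per scattering
#' group and a p-value for the group x day interaction (whether the groups
#' bleach at different rates). Two engines share the same mean structure
#' and agree on point estimates for balanced clusters:
#' \describe{
#'   \item{`"lmm"`}{reference implementation -- random intercept per
#'     cluster via \pkg{lme4}, interaction p from the Satterthwaite t-test
#'     (\pkg{lmerTest}).}
#'   \item{`"robust"`}{OLS point estimates with cluster-robust (CR0)
#'     standard errors via \pkg{sandwich}, t-tests on
#'     `n_clusters - rank` degrees of freedom.}
#' }
#'
#' @param table An observation table with a `group` column, or one joined
#'   against profiles via `profiles`.
#' @param metric Metric column name (e.g. `"fvfm"`, `"qm"`).
#' @param profiles Optional optical-profile table supplying `group` per
#'   species when the table lacks one.
#' @param window Inclusive day window (default stress days 0--11).
#' @param engine `"lmm"` or `"robust"`.
#' @param cluster Clustering unit, `"colony"` (default) or `"species"`.
#' @return An object of class `coraloptics_cla`: list with `slopes`
#'   (tibble: `group`, `slope`, `se`, `p`), `interaction_p`, `engine`,
#'   `cluster`, `n_clusters`, `n_obs`, `unreliable` (TRUE when any group
#'   has a single cluster) and the underlying `fit`.
#' @export
clustered_rate_model <- function(table, metric = "fvfm", profiles = NULL,
                                 window = c(0, 11),
                                 engine = c("lmm", "robust"),
                                 cluster = c("colony", "species")) {
  engine <- match.arg(engine)
  cluster <- match.arg(cluster)
  dat <- tibble::as_tibble(table)
  if (!"group" %in% names(dat)) {
    if (is.null(profiles)) {
      stop_schema("Supply a `group` column or a `profiles` table.")
    }
    dat <- dplyr::left_join(
      dat, tibble::as_tibble(profiles)[c("species", "group")], by = "species"
    )
  }
  if (!metric %in% names(dat)) {
    stop_schema(sprintf("No `%s` column in the table.", metric))
  }
  dat <- dat |>
    dplyr::filter(.data$day >= window[1], .data$day <= window[2],
                  !is.na(.data[[metric]]), .data$group %in% c("low", "high"))
  dat$group <- factor(as.character(dat$group), levels = c("low", "high"))
  dat$value <- dat[[metric]]
  dat$cl <- factor(dat[[cluster]])

  per_group_cl <- dat |>
    dplyr::distinct(.data$group, .data$cl) |>
    dplyr::count(.data$group)
  if (nrow(per_group_cl) < 2L) {
    stop_domain("Both scattering groups must be observed in the window.")
  }
  unreliable <- any(per_group_cl$n < 2L)
  if (unreliable) {
    rlang::warn("A group has a single cluster: inference is unreliable.")
  }

  if (engine == "lmm") {
    fit <- lmerTest::lmer(value ~ group * day + (1 | cl), data = dat,
                          REML = TRUE)
    sm <- summary(fit)$coefficients
    vc <- as.matrix(stats::vcov(fit))
    slope_low <- sm["day", "Estimate"]
    se_low <- sm["day", "Std. Error"]
    p_low <- sm["day", "Pr(>|t|)"]
    slope_high <- slope_low + sm["grouphigh:day", "Estimate"]
    se_high <- sqrt(vc["day", "day"] + vc["grouphigh:day", "grouphigh:day"] +
                      2 * vc["day", "grouphigh:day"])
    df_high <- sm["grouphigh:day", "df"]
    p_high <- 2 * pt(abs(slope_high / se_high), df_high, lower.tail = FALSE)
    interaction_p <- sm["grouphigh:day", "Pr(>|t|)"]
  } else {
    fit <- lm(value ~ group * day, data = dat)
    vc <- sandwich::vcovCL(fit, cluster = dat$cl)
    cf <- coef(fit)
    g <- nlevels(droplevels(dat$cl))
    dfree <- max(g - length(cf), 1L)
    slope_low <- unname(cf["day"])
    se_low <- sqrt(vc["day", "day"])
    p_low <- 2 * pt(abs(slope_low / se_low), dfree, lower.tail = FALSE)
    slope_high <- slope_low + unname(cf["grouphigh:day"])
    se_high <- sqrt(vc["day", "day"] + vc["grouphigh:day", "grouphigh:day"] +
                      2 * vc["day", "grouphigh:day"])
    p_high <- 2 * pt(abs(slope_high / se_high), dfree, lower.tail = FALSE)
    int_se <- sqrt(vc["grouphigh:day", "grouphigh:day"])
    interaction_p <- 2 * pt(abs(unname(cf["grouphigh:day"]) / int_se),
                            dfree, lower.tail = FALSE)
  }

  structure(
    list(
      slopes = tibble::tibble(
        group = c("low", "high"),
        slope = c(slope_low, slope_high),
        se = c(se_low, se_high),
        p = c(p_low, p_high)
      ),
      interaction_p = unname(interaction_p),
      metric = metric,
      engine = engine,
      cluster = cluster,
      n_clusters = nlevels(droplevels(dat$cl)),
      n_obs = nrow(dat),
      unreliable = unreliable,
      fit = fit
    ),
    class = "coraloptics_cla"
  )
}

#' @export
print.coraloptics_cla <- function(x, ...) {
  cat(sprintf(
    "Clustered longitudinal model of `%s` (%s engine, %d %s clusters)\n",
    x$metric, x$engine, x$n_clusters, x$cluster
  ))
  print(x$slopes)
  cat(sprintf("group x day interaction p = %.4g\n", x$interaction_p))
  invisible(x)
}

#' @method tidy coraloptics_cla
#' @export
tidy.coraloptics_cla <- function(x, ...) {
  dplyr::mutate(x$slopes, term = paste0("day[", .data$group, "]"),
                .before = 1)
}

#' @method glance coraloptics_cla
#' @export
glance.coraloptics_cla <- function(x, ...) {
  tibble::tibble(interaction_p = x$interaction_p, engine = x$engine,
                 n_clusters = x$n_clusters, nobs = x$n_obs,
                 unreliable = x$unreliable)
}

#' Marginal between-group comparison at a single day
#'
#' Compares the scattering groups at one post-stress day, optionally after
#' normalizing each ramet to its own baseline (its day-0 value, or the
#' latest earlier baseline day available) -- normalization makes the
#' comparison sensitive to relative change when groups differ in absolute
#' baseline. The p-value comes from a two-sided t-test on the group
#' contrast with colony-cluster-robust variance.
#'
#' @param table Observation table with a `group` column (or supply
#'   `profiles`).
#' @param metric Metric column name.
#' @param day The post-stress day to compare.
#' @param normalize_to_initial Divide each ramet by its own baseline first?
#' @param profiles Optional profile table supplying `group`.
#' @return A one-row tibble: `day`, `difference` (mean high - mean low),
#'   `p`, `n_low`, `n_high`, `n_excluded` (ramets lacking a baseline).
#' @export
marginal_day_comparison <- function(table, metric, day,
                                    normalize_to_initial = FALSE,
                                    profiles = NULL) {
  dat <- tibble::as_tibble(table)
  if (!"group" %in% names(dat)) {
    if (is.null(profiles)) {
      stop_schema("Supply a `group` column or a `profiles` table.")
    }
    dat <- dplyr::left_join(
      dat, tibble::as_tibble(profiles)[c("species", "group")], by = "species"
    )
  }
  dat$value <- dat[[metric]]
  ramet_key <- c("species", "colony", "ramet", "temperature", "light")

  at_day <- dat |>
    dplyr::filter(.data$day == !!day, !is.na(.data$value))
  n_excluded <- 0L
  if (normalize_to_initial) {
    baseline <- dat |>
      dplyr::filter(.data$day <= 0, !is.na(.data$value)) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(ramet_key))) |>
      dplyr::arrange(dplyr::desc(.data$day), .by_group = TRUE) |>
      dplyr::summarise(baseline = dplyr::first(.data$value),
                       .groups = "drop")
    before <- nrow(at_day)
    at_day <- dplyr::inner_join(at_day, baseline, by = ramet_key)
    n_excluded <- before - nrow(at_day)
    if (n_excluded > 0) {
      rlang::warn(sprintf("%d ramet(s) excluded: no baseline value.",
                          n_excluded))
    }
    at_day$value <- at_day$value / at_day$baseline
  }
  groups_present <- unique(as.character(at_day$group))
  if (!all(c("low", "high") %in% groups_present)) {
    stop_domain(sprintf("Both groups must be observed at day %d.", day))
  }
  at_day$group <- factor(as.character(at_day$group),
                         levels = c("low", "high"))
  fit <- lm(value ~ group, data = at_day)
  cl <- factor(at_day$colony)
  vc <- sandwich::vcovCL(fit, cluster = cl)
  est <- unname(coef(fit)["grouphigh"])
  se <- sqrt(vc["grouphigh", "grouphigh"])
  dfree <- max(nlevels(droplevels(cl)) - 2L, 1L)
  tibble::tibble(
    day = day,
    difference = est,
    p = 2 * pt(abs(est / se), dfree, lower.tail = FALSE),
    n_low = sum(at_day$group == "low"),
    n_high = sum(at_day$group == "high"),
    n_excluded = n_excluded
  )
}

#' Baseline (pre-stress) group comparison
#'
#' Two-sample two-sided t-test (Welch) on ramet-level baseline means of a
#' metric between scattering groups, using days before stress onset
#' (day < 0).
#'
#' @inheritParams marginal_day_comparison
#' @return A one-row tibble: `difference` (mean low - mean high, positive
#'   when the low-scattering group starts higher), `t`, `p`, `n_low`,
#'   `n_high`.
#' @export
baseline_compare <- function(table, metric, profiles = NULL) {
  dat <- tibble::as_tibble(table)
  if (!"group" %in% names(dat)) {
    if (is.null(profiles)) {
      stop_schema("Supply a `group` column or a `profiles` table.")
    }
    dat <- dplyr::left_join(
      dat, tibble::as_tibble(profiles)[c("species", "group")], by = "species"
    )
  }
  dat$value <- dat[[metric]]
  base <- dat |>
    dplyr::filter(.data$day < 0, !is.na(.data$value)) |>
    dplyr::group_by(.data$species, .data$colony, .data$ramet,
                    .data$temperature, .data$light, .data$group) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  lo <- base$value[base$group == "low"]
  hi <- base$value[base$group == "high"]
  if (!length(lo) || !length(hi)) {
    stop_domain("Baseline data required in both groups.")
  }
  tt <- stats::t.test(lo, hi)
  tibble::tibble(
    difference = mean(lo) - mean(hi),
    t = unname(tt$statistic),
    p = tt$p.value,
    n_low = length(lo),
    n_high = length(hi)
  )
}
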