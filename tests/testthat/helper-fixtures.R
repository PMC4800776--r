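# shared fixture builders; everything is generated in code, nothing on disk

tiny_observations <- function() {
  tibble::tibble(
    species = rep("A", 6),
    colony = rep("A colony", 6),
    ramet = rep(c("r1", "r2"), each = 3),
    temperature = "HT",
    light = "HL",
    day = rep(c(0, 2, 4), 2),
    fvfm = c(0.60, 0.54, 0.48, 0.62, 0.56, 0.50),
    r_h = 0.1
  )
}

# two-group balanced table with exact linear trajectories and no noise
noiseless_group_table <- function(slope_low = -0.03, slope_high = -0.01,
                                  n_colonies = 3, n_ramets = 4,
                                  days = seq(0, 10, 2),
                                  baseline = 0.6) {
  grid <- expand.grid(
    group = c("low", "high"), colony_i = seq_len(n_colonies),
    ramet = sprintf("r%d", seq_len(n_ramets)), day = days,
    stringsAsFactors = FALSE
  )
  slope <- ifelse(grid$group == "low", slope_low, slope_high)
  tibble::tibble(
    species = paste0(grid$group, grid$colony_i),
    colony = paste0(grid$group, grid$colony_i),
    ramet = grid$ramet,
    temperature = "HT", light = "HL",
    day = grid$day,
    group = grid$group,
    fvfm = baseline + slope * grid$day
  )
}

# simulated null experiment for interaction-test calibration: no group
# effect, genuine colony-level random intercepts
null_cla_table <- function(n_colonies_per_group = 3, n_ramets = 4,
                           days = seq(0, 10, 2),
                           colony_sd = 0.02, noise_sd = 0.03) {
  tab <- noiseless_group_table(slope_low = -0.02, slope_high = -0.02,
                               n_colonies = n_colonies_per_group,
                               n_ramets = n_ramets, days = days)
  eff <- stats::rnorm(length(unique(tab$colony)), 0, colony_sd)
  names(eff) <- unique(tab$colony)
  tab$fvfm <- tab$fvfm + eff[tab$colony] +
    stats::rnorm(nrow(tab), 0, noise_sd)
  tab
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
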