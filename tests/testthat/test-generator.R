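test_that("the default design has the full factorial shape", {
  cfg <- generator_config()
  tab <- generate_experiment(cfg, seed = 1)
  ramets <- dplyr::distinct(tibble::as_tibble(tab), species, temperature,
                            light, ramet)
  expect_equal(nrow(ramets), 10 * 4 * 8)
  per_ramet_days <- dplyr::count(tibble::as_tibble(tab), species,
                                 temperature, light, ramet)
  expect_true(all(per_ramet_days$n == length(cfg$days)))
  expect_equal(cfg$days, c(seq(-10, 10, 2), 11))
})

test_that("identical seeds give identical tables, different seeds differ", {
  cfg <- generator_config()
  a <- generate_experiment(cfg, seed = 42)
  b <- generate_experiment(cfg, seed = 42)
  c <- generate_experiment(cfg, seed = 43)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_false(identical(a$fvfm, c$fvfm))
})

test_that("the noiseless limit reproduces closed-form trajectories exactly", {
  cfg <- generator_config(
    noise_sd = c(fvfm = 0, qm = 0, npq = 0, r_h = 0),
    density_sdlog = 0,
    species_slope_sd = c(fvfm = 0, qm = 0),
    feedback_disp = 0
  )
  tab <- generate_experiment(cfg, seed = 2)
  prof <- cfg$profiles

  # slope recovery is exact per ramet
  pe <- pe_table(tab, "fvfm")
  cells <- pe |>
    dplyr::left_join(prof[c("species", "group")], by = "species") |>
    dplyr::group_by(group, temperature, light) |>
    dplyr::summarise(slope = mean(slope), .groups = "drop")
  hthl_low <- cells$slope[cells$group == "low" &
                            cells$temperature == "HT" & cells$light == "HL"]
  expect_equal(hthl_low, -0.0319, tolerance = 1e-9)

  # the absorption inversion recovers the generator's ground truth
  truth <- attr(tab, "truth")$per_row
  dat <- dplyr::left_join(tibble::as_tibble(tab),
                          prof[c("species", "r_s")], by = "species")
  inv <- infer_absorption(dat$r_h, dat$r_s)
  expect_lt(max(abs(inv$i_a1 - truth$i_a1)), 1e-9)
  expect_lt(max(abs(inv$i_a2 - truth$i_a2)), 1e-9)
})

test_that("necrosis dropout removes ramets at the configured rate", {
  cfg <- generator_config()
  tab <- generate_experiment(cfg, seed = 3)

  untouched <- apply_necrosis_dropout(tab, rate = 0, seed = 1)
  expect_identical(tibble::as_tibble(untouched$table),
                   tibble::as_tibble(tab))
  expect_equal(nrow(untouched$removals), 0L)

  n_removed <- vapply(1:400, function(s) {
    nrow(apply_necrosis_dropout(tab, rate = 0.013, seed = s)$removals)
  }, numeric(1))
  expect_lt(abs(mean(n_removed) - 320 * 0.013), 0.35)

  one <- apply_necrosis_dropout(tab, rate = 0.013, seed = 9)
  if (nrow(one$removals) > 0) {
    gone <- one$removals[1, ]
    left <- dplyr::filter(tibble::as_tibble(one$table),
                          species == gone$species, ramet == gone$ramet,
                          temperature == gone$temperature,
                          light == gone$light)
    expect_true(all(left$day < gone$necrosis_day))
  }
  expect_error(apply_necrosis_dropout(tab, rate = 1),
               class = "coraloptics_domain_error")
})

test_that("species-level Delta PE simulation is seeded and calibrated in mean", {
  cfg <- generator_config()
  a <- simulate_depe(cfg, "light_ht", seed = 5)
  b <- simulate_depe(cfg, "light_ht", seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 10L)

  # the configured line passes through the group means
  cal <- cfg$depe_calibration$light_ht
  expect_equal(cal$intercept + cal$slope * 2.01, -0.0139, tolerance = 1e-4)
  expect_equal(cal$intercept + cal$slope * 4.58, -0.0044, tolerance = 1e-4)
})

test_that("invalid configurations are rejected before generation", {
  expect_error(generator_config(n_ramets_per_cell = 0),
               class = "coraloptics_config_error")
  expect_error(generator_config(sigma = -1),
               class = "coraloptics_config_error")
  expect_error(generator_config(not_a_field = 1),
               class = "coraloptics_config_error")
})

test_that("holobiont reflectance rises toward bare skeleton as pigment is lost", {
  cfg <- generator_config(noise_sd = c(fvfm = 0, qm = 0, npq = 0, r_h = 0),
                          density_sdlog = 0)
  tab <- generate_experiment(cfg, seed = 4)
  prof <- cfg$profiles
  hthl <- tibble::as_tibble(tab) |>
    dplyr::filter(temperature == "HT", light == "HL") |>
    dplyr::left_join(prof[c("species", "r_s", "group")], by = "species") |>
    dplyr::group_by(species, r_s) |>
    dplyr::summarise(r_h_start = mean(r_h[day == 0]),
                     r_h_end = mean(r_h[day == 11]), .groups = "drop")
  expect_true(all(hthl$r_h_end > hthl$r_h_start))
  expect_true(all(hthl$r_h_end <= hthl$r_s + 1e-9))
})
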