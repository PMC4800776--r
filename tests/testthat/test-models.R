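test_that("scattering groups split at the species mean with ties going high", {
  out <- classify_scattering_group(
    data.frame(species = c("a", "b", "c"), mu_sm = c(2, 3, 4))
  )
  expect_equal(as.character(out$group), c("low", "high", "high"))
  expect_equal(attr(out, "mu_sm_threshold"), 3)

  expect_warning(
    single <- classify_scattering_group(
      data.frame(species = "a", mu_sm = 2)
    ),
    "unassigned"
  )
  expect_equal(as.character(single$group), "unassigned")
})

test_that("the default fixture reproduces the expected species grouping", {
  prof <- species_profiles()
  low <- sort(prof$species[prof$group == "low"])
  expect_equal(low, sort(c("Merulina sp.", "Pocillopora damicornis",
                           "Seriatopora hystrix", "Stylophora pistillata")))
  expect_true(all(c("Montipora digitata", "Montipora foliosa",
                    "Goniopora sp.", "Favia favus",
                    "Diploria labyrinthiformis") %in%
                    prof$species[prof$group == "high"]))
})

test_that("clustered model recovers exact slopes on noiseless balanced data", {
  tab <- noiseless_group_table(slope_low = -0.03, slope_high = -0.01)
  m <- clustered_rate_model(tab, "fvfm")
  expect_equal(m$slopes$slope[m$slopes$group == "low"], -0.03,
               tolerance = 1e-8)
  expect_equal(m$slopes$slope[m$slopes$group == "high"], -0.01,
               tolerance = 1e-8)

  r <- clustered_rate_model(tab, "fvfm", engine = "robust")
  expect_equal(r$slopes$slope, m$slopes$slope, tolerance = 1e-8)
  expect_lt(r$interaction_p, 1e-6)
})

test_that("lmm and cluster-robust engines agree on balanced point estimates", {
  set.seed(55)
  tab <- null_cla_table()
  m <- clustered_rate_model(tab, "fvfm")
  r <- clustered_rate_model(tab, "fvfm", engine = "robust")
  expect_equal(m$slopes$slope, r$slopes$slope, tolerance = 1e-6)
})

test_that("single-cluster groups are flagged as unreliable", {
  tab <- noiseless_group_table(n_colonies = 1)
  expect_warning(m <- clustered_rate_model(tab, "fvfm", engine = "robust"),
                 "unreliable")
  expect_true(m$unreliable)
})

test_that("marginal day comparisons difference the groups with optional normalization", {
  tab <- noiseless_group_table(slope_low = 0, slope_high = 0)
  same <- marginal_day_comparison(tab, "fvfm", day = 4)
  expect_equal(same$difference, 0, tolerance = 1e-12)

  # low group at 0.9x baseline, high at 1.0x: normalized difference is 0.1
  tab2 <- noiseless_group_table(slope_low = 0, slope_high = 0)
  tab2$fvfm[tab2$group == "low" & tab2$day == 4] <-
    0.9 * tab2$fvfm[tab2$group == "low" & tab2$day == 4]
  norm <- marginal_day_comparison(tab2, "fvfm", day = 4,
                                  normalize_to_initial = TRUE)
  expect_equal(norm$difference, 0.1, tolerance = 1e-12)

  expect_error(
    marginal_day_comparison(dplyr::filter(tab, group == "low"),
                            "fvfm", day = 4),
    class = "coraloptics_domain_error"
  )
})

test_that("baseline comparison tests pre-stress group differences", {
  tab <- noiseless_group_table(days = seq(-10, 4, 2))
  tab$fvfm[tab$group == "low" & tab$day < 0] <- 0.65
  tab$fvfm[tab$group == "high" & tab$day < 0] <- 0.55
  set.seed(8)
  tab$fvfm <- tab$fvfm + rnorm(nrow(tab), 0, 0.01)
  res <- baseline_compare(tab, "fvfm")
  expect_gt(res$difference, 0.05)
  expect_lt(res$p, 0.001)

  expect_error(
    baseline_compare(dplyr::filter(tab, group == "low"), "fvfm"),
    class = "coraloptics_domain_error"
  )
})

test_that("the generator's baseline ordering flows through to the test", {
  tab <- generate_experiment(generator_config(), seed = 13)
  res <- baseline_compare(tab, "fvfm", profiles = species_profiles())
  expect_gt(res$difference, 0)  # low group configured with higher baseline
  expect_lt(res$p, 0.001)
})

test_that("tidy and glance expose CLA slopes and interaction p", {
  tab <- noiseless_group_table()
  m <- clustered_rate_model(tab, "fvfm", engine = "robust")
  td <- generics::tidy(m)
  expect_setequal(td$term, c("day[low]", "day[high]"))
  expect_true(is.numeric(generics::glance(m)$interaction_p))
})
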