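make_spectrum <- function(reflectance, wl = seq(400, 700, 10),
                          standard = 1100, dark = 100) {
  tibble::tibble(
    wavelength_nm = wl,
    sample = dark + rep_len(reflectance, length(wl)) * (standard - dark),
    standard = standard,
    dark = dark
  )
}

test_that("white-standard normalization is exact and pointwise", {
  s <- make_spectrum(1)
  expect_true(all(normalize_spectrum(s)$reflectance == 1))
  s2 <- make_spectrum(0.5)[, c("wavelength_nm", "sample", "standard")]
  s2$sample <- 0.5 * s2$standard
  expect_true(all(normalize_spectrum(s2)$reflectance == 0.5))
  one <- tibble::tibble(wavelength_nm = c(500, 510), sample = 600,
                        standard = 1100, dark = 100)
  expect_equal(normalize_spectrum(one)$reflectance, c(0.5, 0.5))

  # no smoothing: perturbing one wavelength changes only that wavelength
  s3 <- make_spectrum(0.4)
  s3$sample[7] <- s3$sample[7] + 50
  r0 <- normalize_spectrum(make_spectrum(0.4))$reflectance
  r1 <- normalize_spectrum(s3)$reflectance
  expect_true(all((r1 != r0) == (seq_along(r0) == 7)))

  bad <- make_spectrum(0.4)
  bad$standard[3] <- bad$dark[3]
  expect_error(normalize_spectrum(bad),
               class = "coraloptics_measurement_error")
})

test_that("scalar reflectance is the closed-band mean", {
  flat <- tibble::tibble(wavelength_nm = seq(400, 700, 5), reflectance = 0.3)
  expect_equal(scalar_reflectance(flat), 0.3)

  step <- tibble::tibble(
    wavelength_nm = c(seq(400, 549, length.out = 50),
                      seq(551, 700, length.out = 50)),
    reflectance = rep(c(0.2, 0.4), each = 50)
  )
  expect_equal(scalar_reflectance(step), 0.3)
  expect_error(scalar_reflectance(flat, band = c(800, 900)),
               class = "coraloptics_domain_error")
})

test_that("replicate aggregation yields mean, SEM and COV", {
  a <- aggregate_replicates(c(0.2, 0.3))
  expect_equal(a$value, 0.25)
  expect_equal(a$sem, 0.05)
  expect_equal(a$cov, 100 * sd(c(0.2, 0.3)) / 0.25)
  expect_equal(round(a$cov, 2), 28.28)

  single <- aggregate_replicates(0.4)
  expect_equal(single$value, 0.4)
  expect_equal(single$sem, 0)
  expect_true(single$flagged)

  equal10 <- aggregate_replicates(rep(0.5, 10))
  expect_equal(equal10$sem, 0)
  expect_equal(equal10$cov, 0)
  expect_error(aggregate_replicates(numeric(0)),
               class = "coraloptics_domain_error")
})

test_that("scaling replicates scales mean and SEM, leaves COV fixed", {
  set.seed(3)
  vals <- runif(10, 0.2, 0.6)
  a <- aggregate_replicates(vals)
  b <- aggregate_replicates(3 * vals)
  expect_equal(b$value, 3 * a$value)
  expect_equal(b$sem, 3 * a$sem)
  expect_equal(b$cov, a$cov)
})

test_that("synthetic spectra hit their band-mean targets through the reader", {
  sp <- generate_reflectance_spectra(0.5)
  r <- normalize_spectrum(sp[c("wavelength_nm", "sample", "standard", "dark")])
  expect_lt(abs(scalar_reflectance(r) - 0.5), 1e-6)

  # a pigment dip lowers 675 nm below the band mean without moving it
  dip <- generate_reflectance_spectra(0.5, dip_depth = 0.1)
  rd <- normalize_spectrum(dip[c("wavelength_nm", "sample", "standard",
                                 "dark")])
  expect_lt(abs(scalar_reflectance(rd) - 0.5), 1e-6)
  expect_lt(rd$reflectance[rd$wavelength_nm == 675], scalar_reflectance(rd))
  expect_error(generate_reflectance_spectra(1.5),
               class = "coraloptics_domain_error")
})

test_that("replicate noise at COV 38% is recovered and sets ~24% resolvability", {
  set.seed(9)
  covs <- replicate(40, {
    sp <- generate_reflectance_spectra(0.3, n_replicates = 10,
                                       noise_cov = 38)
    vals <- vapply(split(sp, sp$replicate), function(s) {
      scalar_reflectance(normalize_spectrum(
        s[c("wavelength_nm", "sample", "standard", "dark")]
      ))
    }, numeric(1))
    aggregate_replicates(vals)
  }, simplify = FALSE)
  covs <- dplyr::bind_rows(covs)
  expect_lt(abs(mean(covs$cov) - 38), 6)
  # 2 * sem / mean with n = 10 puts the resolvable change near 24 percent
  expect_gt(mean(covs$resolvable_pct), 12)
  expect_lt(mean(covs$resolvable_pct), 36)
})
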