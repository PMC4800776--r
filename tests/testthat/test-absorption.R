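test_that("flat lower-bound inversion matches the closed form", {
  res <- infer_absorption(0.25, 1)
  expect_equal(res$i_a1, 0.5)
  expect_equal(res$i_a2, 0.25)
  expect_equal(res$i_a, 0.75)
  # no-reentry limit at r_s = 1: i_a = 1 - R'
  expect_equal(res$i_a, 1 - res$r_prime)

  # printed-range extremes under lower-bound parameters
  ext <- infer_absorption(0.26, 0.71)
  expect_equal(ext$i_a1, 1 - sqrt(0.26 / 0.71), tolerance = 1e-12)
  expect_equal(round(ext$i_a1, 5), 0.39486)
  expect_equal(round(ext$i_a2, 5), 0.16965)
})

test_that("general-parameter inversion is the exact inverse of the forward model", {
  p <- absorption_params(alpha = 1.5, beta = 1.2, gamma = 0.8)
  res <- infer_absorption(0.30, 0.60, p)
  expect_equal(round(res$i_a1, 5), 0.17929)
  expect_equal(round(res$i_a2, 5), 0.17601)
  expect_equal(round(res$i_a, 5), 0.35530)
  expect_equal(res$r_1, 0.5)
  expect_equal(res$a_2, 1.5 * res$i_a1)
  # forward substitution reproduces the measured reflectance
  expect_equal(forward_reflectance(res$i_a1, 0.60, p), 0.30,
               tolerance = 1e-10)
})

test_that("zero absorption cases and degenerate inputs behave", {
  res <- infer_absorption(0.5, 0.5)
  expect_equal(res$i_a1, 0)
  expect_equal(res$i_a2, 0)
  expect_equal(res$i_a, 0)
  expect_equal(forward_reflectance(0, 0.8), 0.8)  # R_1 at no absorption
  expect_error(infer_absorption(0.2, 0), class = "coraloptics_domain_error")
  expect_error(forward_reflectance(0.9, 1, absorption_params(alpha = 2)),
               class = "coraloptics_domain_error")

  over <- infer_absorption(0.9, 0.8)
  expect_equal(over$i_a1, 0)
  expect_equal(over$flag, "over-bright")
})

test_that("forward/inverse round trip and balance identities hold on random tuples", {
  set.seed(101)
  for (i in 1:500) {
    al <- runif(1, 1, 2.5)
    be <- runif(1, 1, 2)
    ga <- runif(1, 0.5, 1)
    r_s <- runif(1, 0.2, 1)
    i1 <- runif(1, 0, min(1, 1 / al))
    p <- absorption_params(al, be, ga)
    r_h <- forward_reflectance(i1, r_s, p)
    res <- infer_absorption(r_h, r_s, p)
    expect_lt(abs(res$i_a1 - i1), 1e-10)
    expect_lt(abs(res$i_a - (res$i_a1 + res$i_a2)), 1e-12)
    # radicand identity keeps the root real
    expect_gte((1 - al)^2 + 4 * al * be * res$r_prime, 0)
  }
  # flat-skeleton closed form i_a1 = 1 - sqrt(R')
  set.seed(102)
  r_prime <- runif(50, 0, 1)
  flat <- infer_absorption(r_prime * 0.7, 0.7)
  expect_true(all(abs(flat$i_a1 - (1 - sqrt(r_prime))) < 1e-12))
})

test_that("the all-ones setting is a lower bound for i_a2 across the grid", {
  pairs <- expand.grid(r_h = c(0.02, 0.1, 0.26), r_s = c(0.24, 0.5, 0.71))
  pairs <- pairs[pairs$r_h < pairs$r_s, ]
  violations <- purrr::pmap_int(pairs, function(r_h, r_s) {
    g <- sweep_absorption(r_h, r_s,
                          alpha = seq(1, 2.5, by = 0.25),
                          beta = seq(1, 2, by = 0.25),
                          gamma = seq(0.5, 1, by = 0.25))
    base <- g$i_a2[g$alpha == 1 & g$beta == 1 & g$gamma == 1]
    sum(g$i_a2 < base - 1e-12)
  })
  # any counter-example must surface loudly, not silently pass
  expect_identical(sum(violations), 0L)
})

test_that("per-pigment dynamics computes ratio series and rates", {
  d <- per_pigment_dynamics(c(0.1, 0.2), c(10, 5), c(0, 2))
  expect_equal(d$series$ratio, c(0.01, 0.04))
  expect_equal(d$rate, 0.015)
  expect_equal(
    per_pigment_dynamics(c(0.1, 0.2), c(10, 5), c(0, 2),
                         method = "endpoint")$rate, 0.015
  )
  expect_equal(per_pigment_dynamics(c(0.2, 0.2, 0.2), c(4, 4, 4),
                                    c(0, 2, 4))$rate, 0)
  expect_error(per_pigment_dynamics(c(0.1, 0.2), c(10, 0), c(0, 2)),
               class = "coraloptics_domain_error")
})

test_that("feedback rate is minus the slope of the excess against pigment", {
  expect_equal(as.numeric(feedback_rate(c(0, 0.02), c(0, 0), c(10, 5))),
               0.004)
  expect_equal(as.numeric(feedback_rate(c(0.1, 0.2), c(0.1, 0.2),
                                        c(10, 5))), 0)
  expect_error(feedback_rate(c(0, 0.02), c(0, 0), c(5, 5)),
               class = "coraloptics_domain_error")
  expect_error(feedback_rate(0.1, 0.1, 5),
               class = "coraloptics_domain_error")
})

test_that("inverse power-law fitting recovers noiseless and noisy exponents", {
  mu <- c(1.5, 2, 3, 4.5, 6)
  f <- fit_inverse_power_law(mu, 2 * mu^-1.5)
  expect_equal(f$a, 2, tolerance = 1e-9)
  expect_equal(f$b, 1.5, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)

  const <- fit_inverse_power_law(mu, rep(2, 5))
  expect_equal(const$b, 0)
  expect_equal(const$r2, 0)
  expect_true(const$flagged)
  expect_error(fit_inverse_power_law(mu, c(1, 2, -1, 4, 5)),
               class = "coraloptics_domain_error")

  # log-normal noise leaves the exponent unbiased
  set.seed(7)
  mu10 <- seq(1.5, 6, length.out = 10)
  b_hat <- replicate(500, {
    fit_inverse_power_law(mu10, 2 * mu10^-1.5 * exp(rnorm(10, 0, 0.3)))$b
  })
  expect_lt(abs(mean(b_hat) - 1.5), 0.1)
})

test_that("tidy and glance summarise power-law fits", {
  f <- fit_inverse_power_law(c(1.5, 2, 3), 2 * c(1.5, 2, 3)^-1)
  td <- generics::tidy(f)
  expect_equal(td$estimate[td$term == "exponent"], 1, tolerance = 1e-9)
  expect_equal(generics::glance(f)$nobs, 3L)
})
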