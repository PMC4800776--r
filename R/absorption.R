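#' Light-transport parameters of the absorption model
#'
#' The two-pass absorption model is governed by three morphology-dependent
#' coefficients: `alpha` (>= 1), the amplification of absorption due to the
#' elongation of light paths when unabsorbed downwelling light is diffusely
#' reflected by the skeleton back through the tissue (alpha grows as
#' absorbing pigment density falls); `beta` (>= 1), the ratio R_S / R_1
#' of bare-skeleton reflectance to the fraction of unabsorbed light leaving
#' the holobiont after skeletal reflection including all reentries
#' (non-flatness); and `gamma` (in (0, 1]), scaling absorption by processes
#' other than the first pass and the pigment absorption of reflected light.
#' The flat-coral special case is `beta = gamma = 1` with `1 < alpha <= 2`;
#' `alpha = beta = gamma = 1` yields a conservative lower bound on the
#' skeleton-dependent absorbed fraction and is the default analysis
#' setting.
#'
#' @param alpha,beta,gamma Model coefficients (defaults all 1).
#' @return A list of class `absorption_params`.
#' @export
absorption_params <- function(alpha = 1, beta = 1, gamma = 1) {
  if (!is_number(alpha) || alpha < 1) stop_domain("`alpha` must be >= 1.")
  if (!is_number(beta) || beta < 1) stop_domain("`beta` must be >= 1.")
  if (!is_number(gamma) || gamma <= 0 || gamma > 1) {
    stop_domain("`gamma` must be in (0, 1].")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "absorption_params")
}

#' @export
print.absorption_params <- function(x, ...) {
  cat(sprintf("absorption params: alpha = %g, beta = %g, gamma = %g\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Invert holobiont/skeleton reflectance into absorbed-light fractions
#'
#' Solves the two-pass light-absorption balance for the fraction of
#' incident light absorbed by symbiont pigments. With R' = R_H / R_S, the
#' first-pass fraction `i_a1` is the negative root of the quadratic
#' `alpha * i^2 - (1 + alpha) * i + (1 - beta * R') = 0`:
#' \deqn{I_{a1} = \frac{1}{2\alpha}\left(1 + \alpha -
#'   \sqrt{(1+\alpha)^2 - 4\alpha(1 - \beta R')}\right),}
#' the skeleton-dependent fraction is
#' \deqn{I_{a2} = (1 - I_{a1})\left(\frac{\alpha}{\beta} I_{a1} +
#'   \gamma\frac{\beta - 1}{\beta}\right) R_S,}
#' and the total is `i_a = i_a1 + i_a2`, cross-checked against the
#' independent balance
#' `I_a = I_a1 + (1 - I_a1) R_1 a_2 + (1 - I_a1) gamma (R_S - R_1)`
#' with `R_1 = R_S / beta` and `a_2 = alpha * I_a1`. The radicand equals
#' `(1 - alpha)^2 + 4 alpha beta R'` and is therefore never negative for
#' admissible inputs.
#'
#' When `beta * R' > 1` the holobiont is brighter than the no-absorption
#' limit `R_1` (possible for nearly bare skeleton under measurement noise);
#' `i_a1` is then clamped to 0 and the row flagged `"over-bright"` rather
#' than erroring.
#'
#' @param r_h Holobiont reflectance(s), >= 0. Vectorised.
#' @param r_s Skeletal reflectance(s) in (0, 1]. Vectorised (recycled).
#' @param params An [absorption_params()] object; default is the
#'   lower-bound setting `alpha = beta = gamma = 1`.
#' @return A tibble with one row per input: `r_h`, `r_s`, `r_prime`,
#'   `i_a1`, `i_a2`, `i_a`, `r_1`, `a_2`, `flag` (`"ok"` or
#'   `"over-bright"`).
#' @export
#' @examples
#' infer_absorption(0.25, 1) # flat lower bound: i_a1 = 0.5, i_a = 0.75
infer_absorption <- function(r_h, r_s, params = absorption_params()) {
  stopifnot(inherits(params, "absorption_params"))
  if (any(!is.finite(r_h)) || any(r_h < 0)) {
    stop_domain("`r_h` must be finite and >= 0.")
  }
  if (any(!is.finite(r_s)) || any(r_s <= 0) || any(r_s > 1)) {
    stop_domain("`r_s` must lie in (0, 1].")
  }
  n <- max(length(r_h), length(r_s))
  r_h <- rep_len(r_h, n)
  r_s <- rep_len(r_s, n)
  al <- params$alpha; be <- params$beta; ga <- params$gamma

  r_prime <- r_h / r_s
  radicand <- (1 - al)^2 + 4 * al * be * r_prime
  stopifnot(all(radicand >= 0))
  i_a1 <- ((1 + al) - sqrt(radicand)) / (2 * al)
  over_bright <- be * r_prime > 1
  i_a1[over_bright] <- 0

  a_2 <- al * i_a1
  if (any(a_2 > 1 + 1e-12)) {
    stop_domain(
      "Inferred a_2 = alpha * i_a1 exceeds 1: inconsistent parameters.",
      class = "coraloptics_parameter_error"
    )
  }
  r_1 <- r_s / be
  i_a2 <- (1 - i_a1) * ((al / be) * i_a1 + ga * (be - 1) / be) * r_s
  i_a <- i_a1 + i_a2

  # independent total-absorption balance must agree
  i_a_balance <- i_a1 + (1 - i_a1) * r_1 * a_2 + (1 - i_a1) * ga * (r_s - r_1)
  stopifnot(all(abs(i_a - i_a_balance) < 1e-10))
  # forward model must reproduce the measured reflectance
  ok <- !over_bright
  if (any(ok)) {
    stopifnot(all(abs(
      forward_reflectance(i_a1[ok], r_s[ok], params) - r_h[ok]
    ) < 1e-10))
  }

  tibble::tibble(
    r_h = r_h, r_s = r_s, r_prime = r_prime,
    i_a1 = i_a1, i_a2 = i_a2, i_a = i_a,
    r_1 = r_1, a_2 = a_2,
    flag = ifelse(over_bright, "over-bright", "ok")
  )
}

#' Forward reflectance model
#'
#' The exact inverse of [infer_absorption()]: holobiont reflectance from a
#' first-pass absorbed fraction,
#' `R_H = R_1 (1 - I_a1)(1 - a_2) = (R_S / beta)(1 - I_a1)(1 - alpha I_a1)`.
#'
#' @param i_a1 First-pass absorbed fraction(s), in `[0, min(1, 1/alpha)]`.
#' @param r_s Skeletal reflectance(s) in (0, 1].
#' @param params An [absorption_params()] object.
#' @return Numeric vector of holobiont reflectances.
#' @export
#' @examples
#' forward_reflectance(0.5, 1) # 0.25
forward_reflectance <- function(i_a1, r_s, params = absorption_params()) {
  stopifnot(inherits(params, "absorption_params"))
  al <- params$alpha; be <- params$beta
  if (any(!is.finite(i_a1)) || any(i_a1 < 0) ||
      any(i_a1 > min(1, 1 / al) + 1e-12)) {
    stop_domain("`i_a1` must lie in [0, min(1, 1/alpha)].")
  }
  if (any(r_s <= 0) || any(r_s > 1)) stop_domain("`r_s` must lie in (0, 1].")
  (r_s / be) * (1 - i_a1) * (1 - al * i_a1)
}

#' Sensitivity sweep of the absorption inversion over (alpha, beta, gamma)
#'
#' Evaluates [infer_absorption()] for one (R_H, R_S) pair over a parameter
#' grid, e.g. to verify that the `alpha = beta = gamma = 1` setting is a
#' lower bound on `i_a2`.
#'
#' @param r_h,r_s Scalar reflectances.
#' @param alpha,beta,gamma Numeric vectors of grid values.
#' @return A tibble with columns `alpha`, `beta`, `gamma`, `i_a1`, `i_a2`,
#'   `i_a`, `flag`.
#' @export
sweep_absorption <- function(r_h, r_s, alpha = 1, beta = 1, gamma = 1) {
  grid <- tidyr::expand_grid(alpha = alpha, beta = beta, gamma = gamma)
  purrr::pmap(grid, function(alpha, beta, gamma) {
    res <- infer_absorption(r_h, r_s,
                            absorption_params(alpha, beta, gamma))
    tibble::tibble(alpha = alpha, beta = beta, gamma = gamma,
                   i_a1 = res$i_a1, i_a2 = res$i_a2, i_a = res$i_a,
                   flag = res$flag)
  }) |> dplyr::bind_rows()
}

#' Skeleton-dependent light absorbed per unit pigment and its temporal rate
#'
#' Forms the pointwise series `I_a2 / rho` and estimates its temporal rate
#' over the series, either as the least-squares slope against day (default;
#' robust to noise) or as the endpoint difference quotient.
#'
#' @param i_a2 Skeleton-dependent absorbed fractions (length >= 2).
#' @param rho Matched pigment areal densities (> 0).
#' @param days Matched day stamps.
#' @param method `"slope"` (OLS against day) or `"endpoint"`
#'   (difference quotient between first and last points).
#' @return A list with `series` (tibble: `day`, `ratio`) and `rate`
#'   (per day).
#' @export
#' @examples
#' per_pigment_dynamics(c(0.1, 0.2), c(10, 5), c(0, 2))$rate # 0.015
per_pigment_dynamics <- function(i_a2, rho, days,
                                 method = c("slope", "endpoint")) {
  method <- match.arg(method)
  if (length(i_a2) < 2L || length(rho) != length(i_a2) ||
      length(days) != length(i_a2)) {
    stop_domain("`i_a2`, `rho`, `days` must be equal length >= 2.")
  }
  if (any(rho <= 0)) stop_domain("`rho` must be > 0 at all points.")
  ratio <- i_a2 / rho
  rate <- if (method == "slope") {
    unname(coef(lm(ratio ~ days))[2])
  } else {
    (ratio[length(ratio)] - ratio[1]) / (days[length(days)] - days[1])
  }
  list(series = tibble::tibble(day = days, ratio = ratio), rate = rate)
}

#' Optical feedback rate per unit pigment
#'
#' The rate at which the light-minus-control excess in skeleton-dependent
#' absorption per unit pigment grows as pigment declines:
#' `-d(I_a2/rho|HL - I_a2/rho|CL) / d(rho)`, estimated as minus the
#' least-squares slope of the difference series against the matched pigment
#' series. Positive values mean remaining symbionts absorb progressively
#' more skeleton-derived excess light as bleaching proceeds.
#'
#' @param ratio_hl `I_a2 / rho` series under the high-light arm.
#' @param ratio_cl Matched series under the control-light arm (same time
#'   points).
#' @param rho Matched pigment series (conventionally the high-light arm's
#'   declining trajectory).
#' @return A scalar rate (per unit rho) with attribute
#'   `"rho_nonmonotone"` set when `rho` is not strictly decreasing.
#' @export
#' @examples
#' feedback_rate(c(0, 0.02), c(0, 0), c(10, 5)) # 0.004
feedback_rate <- function(ratio_hl, ratio_cl, rho) {
  n <- length(ratio_hl)
  if (n < 2L || length(ratio_cl) != n || length(rho) != n) {
    stop_domain("Need >= 2 aligned points across all three series.")
  }
  if (diff(range(rho)) == 0) {
    stop_domain("`rho` is constant: feedback slope undefined.")
  }
  d <- ratio_hl - ratio_cl
  rate <- -unname(coef(lm(d ~ rho))[2])
  attr(rate, "rho_nonmonotone") <- any(diff(rho) >= 0)
  rate
}

#' Fit an inverse power law y = a * x^(-b)
#'
#' Ordinary least squares of `log(y)` on `log(x)`; `b` is minus the
#' log-log slope, `a = exp(intercept)`, and `r2` is the coefficient of
#' determination in log-log space. Log-normal multiplicative noise makes
#' this estimator unbiased for `b`.
#'
#' @param mu Positive predictor values (e.g. per-species microscopic
#'   scattering, mm^-1), optionally named by species.
#' @param y Positive response values (e.g. per-species feedback rates).
#' @return An object of class `coraloptics_powerlaw`: list with `a`, `b`,
#'   `r2`, `n`, `p` (slope test), `flagged` (TRUE when the response is
#'   degenerate and r2 undefined, reported as 0) and the underlying `fit`.
#' @export
#' @examples
#' f <- fit_inverse_power_law(c(1.5, 2, 3, 4.5, 6),
#'                            2 * c(1.5, 2, 3, 4.5, 6)^-1.5)
#' c(f$a, f$b, f$r2)
fit_inverse_power_law <- function(mu, y) {
  if (length(mu) != length(y) || length(mu) < 3L) {
    stop_domain("Need matched `mu` and `y` of length >= 3.")
  }
  if (any(mu <= 0)) stop_domain("`mu` must be positive.")
  if (any(y <= 0)) {
    offenders <- if (!is.null(names(y))) {
      paste(names(y)[y <= 0], collapse = ", ")
    } else {
      paste(which(y <= 0), collapse = ", ")
    }
    stop_domain(sprintf("Non-positive response for: %s (cannot take logs).",
                        offenders))
  }
  fit <- lm(log(y) ~ log(mu))
  degenerate <- stats::sd(log(y)) == 0
  if (degenerate) {
    # constant response: exponent 0 and r2 undefined (reported as 0)
    a <- exp(mean(log(y))); b <- 0; r2 <- 0; p <- NA_real_
  } else {
    sm <- summary(fit)
    a <- exp(unname(coef(fit)[1]))
    b <- -unname(coef(fit)[2])
    r2 <- sm$r.squared
    p <- unname(sm$coefficients[2, 4])
    if (!is.finite(r2)) {
      degenerate <- TRUE
      r2 <- 0
    }
  }
  structure(
    list(a = a, b = b, r2 = r2, n = length(mu), p = p,
         flagged = degenerate, fit = fit,
         data = tibble::tibble(mu = mu, y = y)),
    class = "coraloptics_powerlaw"
  )
}

#' @export
print.coraloptics_powerlaw <- function(x, ...) {
  cat(sprintf("Inverse power law: y = %.4g * x^(-%.4g)  (r2 = %.3f, n = %d)\n",
              x$a, x$b, x$r2, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy coraloptics_powerlaw
#' @export
tidy.coraloptics_powerlaw <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "exponent"),
    estimate = c(x$a, x$b)
  )
}

#' @method glance coraloptics_powerlaw
#' @export
glance.coraloptics_powerlaw <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, p.value = x$p, nobs = x$n,
                 flagged = x$flagged)
}
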