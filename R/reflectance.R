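#' Normalise a raw spectrum to its white standard
#'
#' Converts detector counts to diffuse reflectance relative to an adjacent
#' white standard, wavelength by wavelength:
#' `reflectance = (sample - dark) / (standard - dark)` with `dark = 0` when
#' no dark spectrum was recorded. No smoothing or filtering of any kind is
#' applied: the output at each wavelength depends only on that wavelength's
#' inputs.
#'
#' @param spectrum A data frame with columns `wavelength_nm` (strictly
#'   increasing), `sample`, `standard` and optionally `dark` (all detector
#'   counts).
#' @return A tibble with columns `wavelength_nm` and `reflectance`.
#' @export
#' @examples
#' s <- data.frame(wavelength_nm = c(400, 500), sample = c(600, 600),
#'                 standard = c(1100, 1100), dark = c(100, 100))
#' normalize_spectrum(s) # reflectance 0.5 at both wavelengths
normalize_spectrum <- function(spectrum) {
  need <- c("wavelength_nm", "sample", "standard")
  if (!all(need %in% names(spectrum))) {
    stop_schema(sprintf("Spectrum needs columns: %s",
                        paste(need, collapse = ", ")))
  }
  if (nrow(spectrum) < 2L) stop_domain("Spectrum needs at least 2 points.")
  wl <- spectrum$wavelength_nm
  if (any(diff(wl) <= 0)) {
    stop_domain("`wavelength_nm` must be strictly increasing.")
  }
  dark <- if ("dark" %in% names(spectrum)) spectrum$dark else 0
  denom <- spectrum$standard - dark
  if (any(denom <= 0)) {
    stop_domain("Standard signal must exceed dark at every wavelength.",
                class = "coraloptics_measurement_error")
  }
  tibble::tibble(
    wavelength_nm = wl,
    reflectance = (spectrum$sample - dark) / denom
  )
}

#' Reduce a reflectance spectrum to a scalar band mean
#'
#' The scalar reflectance of a spectrum is its unweighted mean over a
#' closed wavelength band, by default the visible band 400--700 nm.
#'
#' @param spectrum A tibble from [normalize_spectrum()] (columns
#'   `wavelength_nm`, `reflectance`).
#' @param band Length-2 numeric, inclusive band limits in nm.
#' @return A single dimensionless reflectance.
#' @export
scalar_reflectance <- function(spectrum, band = c(400, 700)) {
  if (!all(c("wavelength_nm", "reflectance") %in% names(spectrum))) {
    stop_schema("Spectrum needs `wavelength_nm` and `reflectance` columns.")
  }
  sel <- spectrum$wavelength_nm >= band[1] & spectrum$wavelength_nm <= band[2]
  if (!any(sel)) {
    stop_domain(sprintf("No wavelengths inside band [%g, %g] nm.",
                        band[1], band[2]))
  }
  mean(spectrum$reflectance[sel])
}

#' Aggregate replicate scalar reflectances
#'
#' Replicate spot measurements (typically ten per ramet, spread across its
#' geometry) are reduced to mean, standard error of the mean (sample sd,
#' n - 1 denominator) and coefficient of variation (100 * sd / mean).
#' For a single replicate, sd is defined as 0 and the result is flagged.
#'
#' @param values Numeric vector of replicate scalar reflectances (n >= 1).
#' @param role Optional label, e.g. `"R_H"` or `"R_S"`.
#' @return A one-row tibble: `value` (mean), `n`, `sem`, `cov` (percent),
#'   `resolvable_pct` (minimal resolvable relative change, `2 * sem/mean`
#'   in percent -- an operational detectability figure), `role`, `flagged`.
#' @export
#' @examples
#' aggregate_replicates(c(0.2, 0.3))
aggregate_replicates <- function(values, role = NA_character_) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop_domain("At least one replicate value is required.")
  m <- mean(values)
  s <- if (n > 1L) stats::sd(values) else 0
  sem <- s / sqrt(n)
  cv <- if (m > 0) 100 * s / m else NA_real_
  tibble::tibble(
    value = m, n = n, sem = sem, cov = cv,
    resolvable_pct = if (m > 0) 2 * sem / m * 100 else NA_real_,
    role = role, flagged = n == 1L
  )
}

#' Read spectra in long delimited format
#'
#' Long CSV with a `measurement_id` column plus `wavelength_nm`, `sample`,
#' `standard` and optional `dark`; one measurement per id.
#'
#' @param path CSV path.
#' @return A named list of per-measurement tibbles.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("No such file: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("measurement_id", "wavelength_nm", "sample", "standard")
  if (!all(need %in% names(raw))) {
    stop_schema(sprintf("Spectra file needs columns: %s",
                        paste(need, collapse = ", ")))
  }
  split(tibble::as_tibble(raw[setdiff(names(raw), "measurement_id")]),
        raw$measurement_id)
}
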