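#' Dark-adapted maximum quantum yield of PSII
#'
#' Computes Fv/Fm = (Fm - F0)/Fm from dark-adapted minimal and maximal
#' fluorescence. Both inputs are arbitrary fluorescence units; the result is
#' dimensionless in [0, 1).
#'
#' @param f0 Minimal dark-adapted fluorescence (> 0). Vectorised.
#' @param fm Maximal dark-adapted fluorescence (>= `f0`). Vectorised.
#' @return Numeric vector of Fv/Fm values.
#' @export
#' @examples
#' dark_yield(200, 500) # 0.6
dark_yield <- function(f0, fm) {
  if (any(!is.finite(f0)) || any(!is.finite(fm))) {
    stop_domain("Fluorescence values must be finite.")
  }
  if (any(f0 <= 0) || any(fm <= 0)) {
    stop_domain("Fluorescence values must be positive.")
  }
  if (any(f0 > fm)) stop_domain("`f0` must not exceed `fm`.")
  (fm - f0) / fm
}

#' Steady-state quantum-yield partition from an induction curve
#'
#' Reduces a PAM induction curve (typically 13 saturation-pulse cycles) to
#' its steady-state light-adapted fluorescence and partitions the absorbed
#' excitation into photochemistry, regulated non-photochemical quenching
#' and non-regulated dissipation:
#' \deqn{\Phi_{PSII} = (F_m' - F')/F_m',\quad
#'       \Phi_{NPQ} = F'/F_m' - F'/F_m,\quad
#'       \Phi_{NO} = F'/F_m,}
#' which sum to 1 identically. Steady-state F' and Fm' are the means over
#' the final `steady_cycles` cycles; how many cycles constitute "steady
#' state" is an acquisition choice, so it is a parameter (default 3), not a
#' constant.
#'
#' @param induction A data frame with columns `f_prime` and `fm_prime`
#'   (one row per cycle, in acquisition order); a `time_s` column is allowed
#'   and ignored.
#' @param fm Dark-adapted maximal fluorescence Fm (> 0).
#' @param steady_cycles Number of terminal cycles averaged (default 3).
#' @return A one-row tibble with columns `phi_psii`, `phi_npq`, `phi_no`,
#'   `f_prime`, `fm_prime` (the steady-state values) and `n_cycles`.
#' @export
#' @examples
#' ind <- data.frame(f_prime = rep(150, 13), fm_prime = rep(300, 13))
#' induction_yields(ind, fm = 500)
induction_yields <- function(induction, fm, steady_cycles = 3L) {
  if (!all(c("f_prime", "fm_prime") %in% names(induction))) {
    stop_schema("`induction` needs `f_prime` and `fm_prime` columns.")
  }
  n <- nrow(induction)
  if (steady_cycles < 1L || steady_cycles > n) {
    stop_domain("`steady_cycles` must be between 1 and the cycle count.")
  }
  if (any(induction$f_prime <= 0) || any(induction$fm_prime <= 0)) {
    stop_domain("Fluorescence values must be positive.")
  }
  if (!is_number(fm) || fm <= 0) stop_domain("`fm` must be a positive number.")
  idx <- seq.int(n - steady_cycles + 1L, n)
  fp <- mean(induction$f_prime[idx])
  fmp <- mean(induction$fm_prime[idx])
  if (fmp < fp) {
    stop_domain("Steady-state Fm' < F': invalid induction window.")
  }
  phi_psii <- (fmp - fp) / fmp
  phi_no <- fp / fm
  phi_npq <- fp / fmp - fp / fm
  tibble::tibble(
    phi_psii = phi_psii, phi_npq = phi_npq, phi_no = phi_no,
    f_prime = fp, fm_prime = fmp, n_cycles = n
  )
}

#' Maximum excitation pressure over PSII
#'
#' Qm = 1 - Phi_PSII(peak light) / (Fv/Fm at dawn). Values near 0 indicate
#' light limitation; values near 1 indicate photoinhibition. Out-of-range
#' results (possible when the peak-light yield exceeds the dawn yield under
#' measurement noise) are flagged via the `"flagged"` attribute, never
#' clamped.
#'
#' @param phi_psii_peak Effective PSII quantum yield at peak light.
#'   Vectorised.
#' @param fvfm_dawn Dark-adapted Fv/Fm measured at dawn (> 0). Vectorised.
#' @return Numeric vector of Qm values with attribute `"flagged"`, a logical
#'   vector marking elements outside [0, 1].
#' @export
#' @examples
#' excitation_pressure(0.3, 0.6) # 0.5
excitation_pressure <- function(phi_psii_peak, fvfm_dawn) {
  if (any(!is.finite(fvfm_dawn)) || any(fvfm_dawn <= 0)) {
    stop_domain("`fvfm_dawn` must be positive.")
  }
  if (any(!is.finite(phi_psii_peak)) || any(phi_psii_peak < 0)) {
    stop_domain("`phi_psii_peak` must be non-negative.")
  }
  qm <- 1 - phi_psii_peak / fvfm_dawn
  attr(qm, "flagged") <- qm < 0 | qm > 1
  qm
}

#' Read a PAM induction-curve file
#'
#' Delimited-text dialect: a CSV whose first two data rows carry the
#' dark-adapted pair as `cycle = 0` rows with columns
#' `cycle, time_s, f_prime, fm_prime` -- row `cycle 0` stores F0 in
#' `f_prime` and Fm in `fm_prime`; rows `cycle >= 1` are the induction
#' cycles in order.
#'
#' @param path CSV path.
#' @return A list with elements `f0`, `fm` and `induction` (tibble of
#'   cycles).
#' @export
read_induction_curve <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("No such file: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cycle", "f_prime", "fm_prime")
  if (!all(need %in% names(raw))) {
    stop_schema(sprintf("Induction file needs columns: %s",
                        paste(need, collapse = ", ")))
  }
  dark <- raw[raw$cycle == 0, , drop = FALSE]
  if (nrow(dark) != 1L) {
    stop_schema("Exactly one `cycle = 0` row (F0/Fm) is required.")
  }
  f0 <- dark$f_prime
  fm <- dark$fm_prime
  if (f0 <= 0 || fm < f0) stop_domain("Require Fm >= F0 > 0.")
  list(
    f0 = f0, fm = fm,
    induction = tibble::as_tibble(raw[raw$cycle > 0, , drop = FALSE])
  )
}
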