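#' Default ten-species skeletal optical profile fixture
#'
#' A synthetic per-species table of skeletal optical properties emulating a
#' ten-species experimental panel. Microscopic reduced scattering
#' (`mu_sm`, mm^-1) spans 1.53--5.8 mm^-1 and is constructed so that the
#' below-mean ("low") group of four species averages 2.01 mm^-1 and the
#' above-mean ("high") group averages 4.58 mm^-1. Per-species values are
#' synthetic: only the range endpoints and group means are constrained;
#' *Turbinaria reniformis* is assigned the high-group mean so that threshold
#' classification places it in the high group without moving that group's
#' mean. Skeletal reflectance `r_s` (fraction of a white standard) spans
#' 0.24--0.71 and tissue thickness 0.1--2.8 mm, both synthetic within the
#' observed ranges.
#'
#' @return A tibble with columns `species`, `mu_sm` (mm^-1), `mu_s_bulk`
#'   (mm^-1), `r_s` (dimensionless), `tissue_thickness_mm` (mm) and `group`
#'   (factor: `low`/`high`), one row per species.
#' @export
#' @examples
#' species_profiles()
species_profiles <- function() {
  profiles <- tibble::tibble(
    species = c(
      "Seriatopora hystrix", "Pocillopora damicornis", "Stylophora pistillata",
      "Merulina sp.", "Diploria labyrinthiformis", "Favia favus",
      "Goniopora sp.", "Turbinaria reniformis", "Montipora foliosa",
      "Montipora digitata"
    ),
    mu_sm = c(1.53, 1.87, 2.10, 2.54, 3.85, 4.05, 4.30, 4.58, 4.90, 5.80),
    mu_s_bulk = c(3.1, 2.4, 4.2, 5.0, 3.6, 4.8, 2.9, 3.3, 5.5, 4.1),
    r_s = c(0.43, 0.38, 0.40, 0.24, 0.52, 0.47, 0.55, 0.58, 0.63, 0.71),
    tissue_thickness_mm = c(0.1, 0.5, 1.2, 1.8, 2.8, 2.0, 2.5, 0.7, 0.6, 1.5)
  )
  classify_scattering_group(profiles)
}

#' Classify species into low- and high-scattering groups
#'
#' Assigns each species to the `low` or `high` microscopic-scattering group
#' by comparing its `mu_sm` against the arithmetic mean of the species
#' panel. Values strictly below the mean are `low`; values at or above the
#' mean are `high` (ties go high). Species with missing `mu_sm` are left
#' `unassigned` with a warning.
#'
#' @param profiles A data frame with at least `species` and `mu_sm` columns.
#' @return The input as a tibble with a `group` factor column
#'   (`low`/`high`/`unassigned`) and the threshold recorded in the
#'   `"mu_sm_threshold"` attribute.
#' @export
#' @examples
#' classify_scattering_group(data.frame(species = c("a", "b", "c"),
#'                                      mu_sm = c(2, 3, 4)))
classify_scattering_group <- function(profiles) {
  if (!all(c("species", "mu_sm") %in% names(profiles))) {
    stop_schema("`profiles` must have `species` and `mu_sm` columns.")
  }
  profiles <- tibble::as_tibble(profiles)
  known <- profiles$mu_sm[!is.na(profiles$mu_sm)]
  if (length(known) < 2L) {
    rlang::warn("Fewer than 2 species with `mu_sm`; all left unassigned.")
    profiles$group <- factor(rep("unassigned", nrow(profiles)),
                             levels = c("low", "high", "unassigned"))
    attr(profiles, "mu_sm_threshold") <- NA_real_
    return(profiles)
  }
  if (anyNA(profiles$mu_sm)) {
    rlang::warn(sprintf(
      "%d species missing `mu_sm`; left unassigned.", sum(is.na(profiles$mu_sm))
    ))
  }
  threshold <- mean(known)
  grp <- ifelse(is.na(profiles$mu_sm), "unassigned",
                ifelse(profiles$mu_sm < threshold, "low", "high"))
  profiles$group <- factor(grp, levels = c("low", "high", "unassigned"))
  attr(profiles, "mu_sm_threshold") <- threshold
  profiles
}

#' Read or write optical profile tables
#'
#' Delimited-text (CSV) IO for per-species skeletal optics: columns
#' `species`, `mu_sm`, optional `mu_s_bulk`, `r_s`, optional
#' `tissue_thickness_mm`. Values are validated on read: `mu_sm` must be
#' positive, `r_s` in (0, 1], tissue thickness positive when present.
#'
#' @param path File path.
#' @param profiles A profile data frame (for writing).
#' @return `read_optical_profiles()` returns a validated tibble with a
#'   `group` column assigned by [classify_scattering_group()];
#'   `write_optical_profiles()` returns `path` invisibly.
#' @export
read_optical_profiles <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("No such file: %s", path))
  prof <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("species", "mu_sm", "r_s")
  missing_cols <- setdiff(required, names(prof))
  if (length(missing_cols)) {
    stop_schema(sprintf("Missing mandatory columns: %s",
                        paste(missing_cols, collapse = ", ")))
  }
  bad_mu <- !is.na(prof$mu_sm) & prof$mu_sm <= 0
  bad_rs <- !is.na(prof$r_s) & (prof$r_s <= 0 | prof$r_s > 1)
  if (any(bad_mu)) stop_domain("`mu_sm` must be > 0 for all species.")
  if (any(bad_rs)) stop_domain("`r_s` must lie in (0, 1].")
  if ("tissue_thickness_mm" %in% names(prof) &&
      any(!is.na(prof$tissue_thickness_mm) & prof$tissue_thickness_mm <= 0)) {
    stop_domain("`tissue_thickness_mm` must be > 0 when present.")
  }
  classify_scattering_group(prof)
}

#' @rdname read_optical_profiles
#' @export
write_optical_profiles <- function(profiles, path) {
  readr::write_csv(tibble::as_tibble(profiles), path, progress = FALSE)
  invisible(path)
}
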