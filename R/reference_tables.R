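# Bundled reference tables: the published composite-intake percentile rows,
# hazard-index exceedance percentages, contribution-to-variance shares and
# per-goitrogen attribution for the six U.S. age groups, on both PEC bases.
# These are the calibration targets and held-out validation surfaces
# distributed with the package; the underlying survey inputs are not.

#' @noRd
reference_file <- function(name) {
  path <- system.file("extdata", name, package = "goitrisk")
  if (!nzchar(path))
    gr_abort(sprintf("bundled reference table '%s' not found", name),
             "goitrisk_io_error")
  path
}

#' Bundled reference tables
#'
#' Accessors for the reference surfaces shipped with the package:
#' composite PEC intake percentiles by age group and basis
#' (`reference_percentiles`), hazard-index exceedance percentages per
#' reference-dose approach (`reference_exceedance`), contribution-to-
#' variance shares over the eight input factors (`reference_cv_shares`),
#' and per-goitrogen attribution of exceedance (`reference_attribution`).
#' The water-route share constants of mean intake are 4% for perchlorate,
#' 6% for nitrate and 0% for thiocyanate on either basis
#' (`reference_route_shares`).
#'
#' @return A data frame (or named numeric for the route shares).
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
reference_percentiles <- function() {
  utils::read.csv(reference_file("reference_adri_percentiles.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_exceedance <- function() {
  utils::read.csv(reference_file("reference_exceedance.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_cv_shares <- function() {
  utils::read.csv(reference_file("reference_cv_shares.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_attribution <- function() {
  utils::read.csv(reference_file("reference_attribution.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_route_shares <- function() {
  c(perchlorate = 4, nitrate = 6, thiocyanate = 0)
}

#' Build the bundled calibration target for one age group and basis
#'
#' Assembles a [calibration_target()] from the bundled reference tables:
#' the percentile row for the requested basis, the matching
#' contribution-to-variance shares, and the water-route share constants.
#'
#' @param age_group One of [age_group_roster()].
#' @param basis `"serum"`, `"halflife"`, or `"both"` for a joint target.
#' @return A `calibration_target`.
#' @export
reference_target <- function(age_group, basis = "serum") {
  pct <- reference_percentiles()
  cv <- reference_cv_shares()
  grab_pct <- function(b) {
    row <- pct[pct$age_group == age_group & pct$basis == b, ]
    if (nrow(row) != 1)
      gr_abort(sprintf("no reference percentile row for '%s' (%s)", age_group, b),
               "goitrisk_lookup_error")
    vals <- unlist(row[grep("^p", names(row))])
    stats::setNames(as.numeric(vals), sub("^p", "", names(vals)))
  }
  grab_cv <- function(b) {
    row <- cv[cv$age_group == age_group & cv$basis == b, ]
    if (nrow(row) != 1) return(NULL)
    stats::setNames(as.numeric(unlist(row[cv_factor_names()])), cv_factor_names())
  }
  bases <- if (basis == "both") c("serum", "halflife") else basis
  calibration_target(
    age_group = age_group,
    percentiles_serum = if ("serum" %in% bases) grab_pct("serum") else NULL,
    percentiles_halflife = if ("halflife" %in% bases) grab_pct("halflife") else NULL,
    cv_serum = if ("serum" %in% bases) grab_cv("serum") else NULL,
    cv_halflife = if ("halflife" %in% bases) grab_cv("halflife") else NULL,
    route_shares = reference_route_shares()
  )
}
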