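#' Goitrogen agents and potency-equivalence divisors
#'
#' The three goitrogens share a mode of action (inhibition of thyroidal
#' iodide uptake via the sodium-iodide symporter), so their intakes are
#' expressed on a common perchlorate-equivalent (PEC) scale, a
#' toxicity-equivalence weighting. Intake of agent g is divided by its
#' potency divisor: the mass of g equivalent to one mass unit of
#' perchlorate. Two bases are provided: equivalent serum concentration
#' (perchlorate : thiocyanate : nitrate = 1 : 8.8 : 150) and serum
#' half-life-corrected ingested mass (1 : 0.5 : 240).
#'
#' @return A data frame with columns `name`, `pec_divisor_serum`,
#'   `pec_divisor_halflife`.
#' @export
goitrogen_agents <- function() {
  data.frame(
    name = c("perchlorate", "nitrate", "thiocyanate"),
    pec_divisor_serum = c(1, 150, 8.8),
    pec_divisor_halflife = c(1, 240, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Reference-dose approaches
#'
#' Alternative PEC reference doses (ug/kg-day) used as the hazard-index
#' denominator: `A3` derives from a no-observed-effect level with the
#' background goitrogen contribution included; `A4` from an
#' exposure-response curve with a 50% iodide-uptake-inhibition threshold;
#' `A4b` from the same curve with a 0-5% inhibition threshold. Each carries
#' a value without (`rfd_no_correction`) and with (`rfd_with_correction`)
#' serum half-life correction.
#'
#' @return A data frame with columns `name`, `rfd_no_correction`,
#'   `rfd_with_correction`.
#' @export
rfd_approaches <- function() {
  data.frame(
    name = c("A3", "A4", "A4b"),
    rfd_no_correction = c(13.5, 29.5, 14.5),
    rfd_with_correction = c(22.9, 38.9, 23.9),
    stringsAsFactors = FALSE
  )
}

#' Percentile grid for composite intake tables
#'
#' @return The nine reporting percentiles `c(1, 5, 10, 30, 50, 70, 90, 95, 99)`.
#' @export
adri_percentile_grid <- function() c(1, 5, 10, 30, 50, 70, 90, 95, 99)

#' Default age-group roster
#'
#' @return Character vector of the six modelled population groups.
#' @export
age_group_roster <- function() {
  c("1-3 months", "2-3 years", "6-11 years", "18-21 years", ">21 years",
    "pregnant women")
}

#' All default domain constants
#'
#' Convenience bundle of [goitrogen_agents()], [rfd_approaches()] and
#' [adri_percentile_grid()].
#'
#' @return A list with elements `agents`, `approaches`, `percentile_grid`.
#' @export
default_constants <- function() {
  list(agents = goitrogen_agents(), approaches = rfd_approaches(),
       percentile_grid = adri_percentile_grid())
}

#' @noRd
pec_divisors <- function(basis) {
  ag <- goitrogen_agents()
  col <- switch(basis,
    serum = "pec_divisor_serum",
    halflife = "pec_divisor_halflife",
    gr_abort(sprintf("unknown basis '%s' (use 'serum' or 'halflife')", basis),
             "goitrisk_lookup_error")
  )
  stats::setNames(ag[[col]], ag$name)
}

#' Construct an exposure scenario
#'
#' A scenario fully specifies one simulatable population: the agent roster
#' with PEC divisors, per-age-group water and food exposure factors
#' (intake per kg body mass per day, combining intake rate and body mass
#' because the two are correlated), per-agent concentration distributions
#' in water (ug/L) and in the effective food basket (ug/kg), an optional
#' food-basket composition, and the deterministic endogenous-nitrate
#' coefficient (endogenously produced nitrate per unit exogenous nitrate
#' intake; effective nitrate intake is exogenous * (1 + coeff)).
#'
#' Thiocyanate in drinking water is negligible and defaults to the
#' degenerate zero distribution when omitted.
#'
#' @param age_groups Named list; each element a list with fields `name`,
#'   `ef_water` and `ef_food` ([trunc_lognormal()] objects; L/kg-day and
#'   kg/kg-day).
#' @param conc_water,conc_food Named lists mapping each agent to a
#'   [trunc_lognormal()] concentration distribution.
#' @param basket_shares Optional named numeric of food-category shares
#'   summing to 1.
#' @param endo_nitrate_coeff Non-negative scalar, default 0.
#' @param trunc Default truncation half-width recorded with the scenario.
#' @param agents Agent table, default [goitrogen_agents()].
#' @return An object of class `goitrogen_scenario`.
#' @export
new_scenario <- function(age_groups, conc_water, conc_food,
                         basket_shares = NULL, endo_nitrate_coeff = 0,
                         trunc = 3, agents = goitrogen_agents()) {
  if (is.null(conc_water$thiocyanate))
    conc_water$thiocyanate <- trunc_lognormal(0, 1.5, trunc)
  s <- structure(
    list(agents = agents, age_groups = age_groups, conc_water = conc_water,
         conc_food = conc_food, basket_shares = basket_shares,
         endo_nitrate_coeff = endo_nitrate_coeff, trunc = trunc),
    class = "goitrogen_scenario"
  )
  validate_scenario(s)
  s
}

#' Validate a scenario
#'
#' Checks structural integrity; raises a schema error naming the offending
#' key on the first violation.
#'
#' @param s A `goitrogen_scenario`.
#' @return `s`, invisibly, when valid.
#' @export
validate_scenario <- function(s) {
  schema <- function(key, msg) {
    gr_abort(sprintf("scenario field '%s': %s", key, msg), "goitrisk_schema_error")
  }
  if (!inherits(s, "goitrogen_scenario")) schema("(root)", "not a goitrogen_scenario")
  if (!is.data.frame(s$agents) || nrow(s$agents) == 0) schema("agents", "empty roster")
  if (length(s$age_groups) == 0) schema("age_groups", "empty roster")
  for (g in s$age_groups) {
    if (is.null(g$name)) schema("age_groups", "missing group name")
    for (f in c("ef_water", "ef_food")) {
      d <- g[[f]]
      if (!inherits(d, "trunc_lognormal"))
        schema(paste0("age_groups$", g$name, "$", f), "not a trunc_lognormal")
      if (d$median <= 0)
        schema(paste0("age_groups$", g$name, "$", f), "median must be positive")
    }
  }
  for (side in c("conc_water", "conc_food")) {
    for (a in s$agents$name) {
      d <- s[[side]][[a]]
      if (is.null(d)) schema(paste0(side, "$", a), "missing distribution")
      if (!inherits(d, "trunc_lognormal")) schema(paste0(side, "$", a), "not a trunc_lognormal")
    }
  }
  if (!is.null(s$basket_shares)) {
    if (is.null(names(s$basket_shares)) || any(s$basket_shares < 0))
      schema("basket_shares", "must be a named non-negative vector")
    if (abs(sum(s$basket_shares) - 1) > 1e-9)
      schema("basket_shares", sprintf("shares sum to %.12f, not 1", sum(s$basket_shares)))
  }
  if (!is.numeric(s$endo_nitrate_coeff) || s$endo_nitrate_coeff < 0)
    schema("endo_nitrate_coeff", "must be a non-negative number")
  invisible(s)
}

#' @export
print.goitrogen_scenario <- function(x, ...) {
  cat(sprintf("<goitrogen_scenario: %d agents, %d age group(s), endo-nitrate %.3g>\n",
              nrow(x$agents), length(x$age_groups), x$endo_nitrate_coeff))
  invisible(x)
}

# ---- serialisation ---------------------------------------------------------

#' @noRd
tln_to_list <- function(d) list(median = d$median, gsd = d$gsd, trunc = d$trunc)

#' @noRd
tln_from_list <- function(x, key) {
  need <- c("median", "gsd", "trunc")
  if (!all(need %in% names(x)))
    gr_abort(sprintf("scenario field '%s': distribution needs fields %s", key,
                     paste(setdiff(need, names(x)), collapse = ", ")),
             "goitrisk_schema_error")
  tryCatch(
    trunc_lognormal(x$median, x$gsd, x$trunc),
    goitrisk_invalid_distribution = function(e)
      gr_abort(sprintf("scenario field '%s': %s", key, conditionMessage(e)),
               "goitrisk_schema_error")
  )
}

#' Save a scenario to a YAML configuration file
#'
#' Serialisation is stable: two saves of the same scenario are
#' byte-identical.
#'
#' @param s A `goitrogen_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(s, path) {
  validate_scenario(s)
  doc <- list(
    agents = lapply(seq_len(nrow(s$agents)), function(i) as.list(s$agents[i, ])),
    age_groups = lapply(unname(s$age_groups), function(g)
      list(name = g$name, ef_water = tln_to_list(g$ef_water),
           ef_food = tln_to_list(g$ef_food))),
    conc_water = lapply(s$conc_water, tln_to_list),
    conc_food = lapply(s$conc_food, tln_to_list),
    basket_shares = if (is.null(s$basket_shares)) NULL else as.list(s$basket_shares),
    endo_nitrate_coeff = s$endo_nitrate_coeff,
    trunc = s$trunc
  )
  txt <- yaml::as.yaml(doc, precision = 15)
  writeLines(txt, path)
  invisible(path)
}

#' Load a scenario from a YAML configuration file
#'
#' Unknown top-level keys are rejected; a missing thiocyanate water entry
#' is accepted and becomes the degenerate zero distribution.
#'
#' @param path Path to a file written by [save_scenario()] (or hand-written
#'   to the same schema).
#' @return A `goitrogen_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path))
    gr_abort(sprintf("scenario file not found: %s", path), "goitrisk_io_error")
  doc <- yaml::read_yaml(path)
  known <- c("agents", "age_groups", "conc_water", "conc_food",
             "basket_shares", "endo_nitrate_coeff", "trunc")
  extra <- setdiff(names(doc), known)
  if (length(extra) > 0)
    gr_abort(sprintf("unknown scenario key(s): %s", paste(extra, collapse = ", ")),
             "goitrisk_schema_error")
  for (key in c("age_groups", "conc_water", "conc_food")) {
    if (is.null(doc[[key]]))
      gr_abort(sprintf("scenario field '%s': missing", key), "goitrisk_schema_error")
  }
  agents <- if (is.null(doc$agents)) goitrogen_agents() else
    do.call(rbind, lapply(doc$agents, function(a) as.data.frame(a, stringsAsFactors = FALSE)))
  age_groups <- lapply(doc$age_groups, function(g) {
    if (is.null(g$name))
      gr_abort("scenario field 'age_groups': missing group name", "goitrisk_schema_error")
    list(name = g$name,
         ef_water = tln_from_list(g$ef_water, paste0("age_groups$", g$name, "$ef_water")),
         ef_food = tln_from_list(g$ef_food, paste0("age_groups$", g$name, "$ef_food")))
  })
  names(age_groups) <- vapply(age_groups, `[[`, "", "name")
  trunc <- doc$trunc %||% 3
  conc_water <- lapply(stats::setNames(nm = names(doc$conc_water)), function(a)
    tln_from_list(doc$conc_water[[a]], paste0("conc_water$", a)))
  conc_food <- lapply(stats::setNames(nm = names(doc$conc_food)), function(a)
    tln_from_list(doc$conc_food[[a]], paste0("conc_food$", a)))
  basket <- if (is.null(doc$basket_shares)) NULL else unlist(doc$basket_shares)
  new_scenario(age_groups, conc_water, conc_food, basket_shares = basket,
               endo_nitrate_coeff = doc$endo_nitrate_coeff %||% 0,
               trunc = trunc, agents = agents)
}
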