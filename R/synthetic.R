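#' Default parameters for the synthetic scenario generator
#'
#' Centre values emulate the structure of U.S. dietary exposure data for
#' the three goitrogens: drinking-water perchlorate around 1.5 ug/L,
#' water nitrate around 4 mg/L, negligible water thiocyanate; effective
#' food-basket concentrations around 23 ug/kg (perchlorate), 42 mg/kg
#' (nitrate) and 0.9 mg/kg (thiocyanate); age-group exposure factors
#' declining from infancy to adulthood. Concentration GSDs default to 1.5,
#' the measured spread of the goitrogen concentration distributions, and
#' every distribution is truncated at 3 GSDs. `jitter_gsd` controls how far
#' the generator perturbs the centre medians (lognormal jitter), so two
#' seeds give distinct but structurally identical scenarios.
#'
#' @return A list of generator parameters (see source for fields).
#' @export
synthetic_defaults <- function() {
  ef <- data.frame(
    age_group = age_group_roster(),
    ef_water_median = c(0.100, 0.035, 0.025, 0.015, 0.016, 0.018),
    ef_water_gsd    = c(1.35, 1.35, 1.30, 1.30, 1.30, 1.30),
    ef_food_median  = c(0.090, 0.065, 0.045, 0.024, 0.024, 0.028),
    ef_food_gsd     = c(1.25, 1.25, 1.25, 1.25, 1.25, 1.25),
    stringsAsFactors = FALSE
  )
  list(
    conc_gsd = 1.5,
    trunc = 3,
    jitter_gsd = 1.15,
    # water concentration centre medians, ug/L (thiocyanate negligible)
    conc_water_median = c(perchlorate = 1.5, nitrate = 4000, thiocyanate = 0),
    # per-category food concentration centre medians, ug/kg
    basket_shares = c(vegetables = 0.30, grains = 0.25, dairy = 0.20,
                      fruits = 0.15, meats = 0.10),
    conc_food_median = list(
      perchlorate = c(vegetables = 35, grains = 15, dairy = 25, fruits = 20, meats = 10),
      nitrate     = c(vegetables = 110000, grains = 12000, dairy = 8000,
                      fruits = 25000, meats = 9000),
      thiocyanate = c(vegetables = 1800, grains = 500, dairy = 900,
                      fruits = 400, meats = 300)
    ),
    ef_table = ef,
    endo_nitrate_coeff = 0
  )
}

#' Generate a synthetic exposure scenario
#'
#' Stands in for exposure-survey inputs that are not distributed with the
#' package: draws per-category food concentrations and water concentrations
#' by jittering the centre medians of `params`, collapses the food basket
#' to one effective concentration per agent (every individual consumes the
#' same basket composition; only total food mass varies between
#' individuals), and assembles a full multi-age-group scenario.
#' Reproducible: the same seed yields an identical scenario.
#'
#' @param seed Integer seed.
#' @param params Generator parameters, default [synthetic_defaults()].
#' @param collapse_basket Collapse per-category food concentrations to the
#'   effective basket concentration (default `TRUE`; the per-category table
#'   is attached as attribute `"basket_detail"` either way).
#' @return A `goitrogen_scenario`.
#' @export
synthetic_scenario <- function(seed = 1, params = synthetic_defaults(),
                               collapse_basket = TRUE) {
  if (length(params$conc_water_median) == 0 || is.null(params$ef_table) ||
      nrow(params$ef_table) == 0)
    gr_abort("generator parameters need a non-empty agent and age-group roster",
             "goitrisk_invalid_spec")
  if (abs(sum(params$basket_shares) - 1) > 1e-9)
    gr_abort("basket_shares must sum to 1", "goitrisk_invalid_spec")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  jit <- function(centre) {
    centre * exp(log(params$jitter_gsd) * stats::rnorm(length(centre)))
  }
  agents <- names(params$conc_water_median)
  conc_water <- lapply(stats::setNames(nm = agents), function(a) {
    m <- params$conc_water_median[[a]]
    trunc_lognormal(if (m > 0) jit(m) else 0, params$conc_gsd, params$trunc)
  })
  basket <- params$basket_shares
  detail <- lapply(stats::setNames(nm = agents), function(a)
    jit(params$conc_food_median[[a]][names(basket)]))
  conc_food <- lapply(detail, function(cats)
    trunc_lognormal(sum(basket * cats), params$conc_gsd, params$trunc))

  ef <- params$ef_table
  age_groups <- lapply(seq_len(nrow(ef)), function(i) {
    list(name = ef$age_group[i],
         ef_water = trunc_lognormal(jit(ef$ef_water_median[i]),
                                    ef$ef_water_gsd[i], params$trunc),
         ef_food = trunc_lognormal(jit(ef$ef_food_median[i]),
                                   ef$ef_food_gsd[i], params$trunc))
  })
  names(age_groups) <- ef$age_group

  s <- new_scenario(age_groups, conc_water, conc_food,
                    basket_shares = if (collapse_basket) basket else NULL,
                    endo_nitrate_coeff = params$endo_nitrate_coeff,
                    trunc = params$trunc)
  attr(s, "basket_detail") <- detail
  attr(s, "seed") <- as.integer(seed)
  s
}
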