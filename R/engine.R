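#' @noRd
component_names <- function() {
  c("perchlorate_water", "nitrate_water", "thiocyanate_water",
    "perchlorate_food", "nitrate_food", "thiocyanate_food")
}

#' @noRd
cv_factor_names <- function() {
  c("perchlorate_water_conc", "nitrate_water_conc", "thiocyanate_water_conc",
    "perchlorate_food_conc", "nitrate_food_conc", "thiocyanate_food_conc",
    "water_EF", "food_EF")
}

#' Simulate per-individual goitrogen intake for one age group
#'
#' The Monte Carlo core. For each simulated individual one water exposure
#' factor and one food exposure factor are drawn and shared across all
#' agents (one person has one water intake), while concentration draws are
#' independent across agents and routes and treated as perfectly correlated
#' across days within an individual — a deliberately health-protective
#' over-dispersion. The intake of agent g via route r is
#' `EF_r * C_{g,r}`, nitrate intake is multiplied by
#' `(1 + endo_nitrate_coeff)` for endogenous production, and the result is
#' divided by the agent's PEC potency divisor for the chosen basis. The
#' six components are summed to the composite PEC intake (total average
#' daily rate of intake, ug/kg-day PEC).
#'
#' Random streams are derived deterministically per (age group, component)
#' from the root seed, so every component's draws are reproducible
#' independently of evaluation order, and the raw draws are identical
#' across the two bases (which differ only in divisors).
#'
#' @param scenario A `goitrogen_scenario`.
#' @param age_group Name of an age group present in the scenario.
#' @param basis `"serum"` or `"halflife"`.
#' @param n Number of simulated individuals.
#' @param seed Integer root seed.
#' @return An object of class `adri_samples` with fields `components`
#'   (per-component PEC intakes), `conc_draws` (raw concentration draws),
#'   `ef_draws` (water and food exposure-factor draws), `total`, and
#'   bookkeeping (`age_group`, `basis`, `n`, `seed`).
#' @export
simulate_adri <- function(scenario, age_group, basis = "serum", n = 50000L,
                          seed = 1L) {
  validate_scenario(scenario)
  if (!(age_group %in% names(scenario$age_groups)))
    gr_abort(sprintf("unknown age group '%s'", age_group), "goitrisk_lookup_error")
  div <- pec_divisors(basis) # also validates basis
  if (!(is.numeric(n) && length(n) == 1 && is.finite(n) && n >= 1))
    gr_abort("`n` must be a positive integer", "goitrisk_domain_error")
  n <- as.integer(n)
  grp <- scenario$age_groups[[age_group]]
  gidx <- match(age_group, names(scenario$age_groups))

  agents <- scenario$agents$name
  routes <- c(water = "conc_water", food = "conc_food")
  comp <- list(); conc <- list()
  k <- 0L
  for (route in names(routes)) {
    for (a in agents) {
      k <- k + 1L
      d <- scenario[[routes[[route]]]][[a]]
      conc[[paste0(a, "_", route)]] <- tln_sample(d, n, seed = gr_child_seed(seed, gidx, k))
    }
  }
  ef_draws <- list(
    water = tln_sample(grp$ef_water, n, seed = gr_child_seed(seed, gidx, 101L)),
    food = tln_sample(grp$ef_food, n, seed = gr_child_seed(seed, gidx, 102L))
  )
  endo <- 1 + scenario$endo_nitrate_coeff
  for (route in names(routes)) {
    for (a in agents) {
      nm <- paste0(a, "_", route)
      intake <- ef_draws[[route]] * conc[[nm]]
      if (a == "nitrate") intake <- intake * endo
      comp[[nm]] <- intake / div[[a]]
    }
  }
  comp <- comp[component_names()]
  conc <- conc[component_names()]
  total <- Reduce(`+`, comp)
  structure(
    list(age_group = age_group, basis = basis, n = n, seed = as.integer(seed),
         components = comp, conc_draws = conc, ef_draws = ef_draws,
         total = total),
    class = "adri_samples"
  )
}

#' @export
print.adri_samples <- function(x, ...) {
  cat(sprintf("<adri_samples: %s, %s basis, n=%d, median total %.3g ug/kg-day PEC>\n",
              x$age_group, x$basis, x$n, stats::median(x$total)))
  invisible(x)
}

#' Empirical percentile table of composite intake
#'
#' Empirical quantiles of the composite PEC intake at the requested
#' percentiles, using the inclusive linear-interpolation definition
#' (`stats::quantile` type 7).
#'
#' @param samples An `adri_samples` object (or any object with a `total`
#'   numeric field).
#' @param grid Percentiles in (0, 100); default [adri_percentile_grid()].
#' @return Named numeric vector, monotone in percentile.
#' @export
percentile_table <- function(samples, grid = adri_percentile_grid()) {
  total <- samples$total
  if (length(total) == 0)
    gr_abort("empty sample set", "goitrisk_empty_input")
  q <- stats::quantile(total, probs = grid / 100, type = 7, names = FALSE)
  stats::setNames(q, as.character(grid))
}

#' Fraction of the population with Hazard Index above 1
#'
#' With a common reference dose for all agents sharing the mode of action,
#' the Hazard Index of individual i is `total[i] / rfd`, and the reported
#' quantity is the percentage with HI strictly above 1.
#'
#' @param samples An `adri_samples` object.
#' @param rfd Reference dose, ug/kg-day PEC, positive.
#' @return Percentage in \[0, 100\].
#' @export
exceedance_fraction <- function(samples, rfd) {
  if (!(is.numeric(rfd) && length(rfd) == 1 && is.finite(rfd) && rfd > 0))
    gr_abort("`rfd` must be a positive number", "goitrisk_domain_error")
  100 * mean(samples$total / rfd > 1)
}

#' Attribute hazard-index exceedance to individual goitrogens
#'
#' Partitions the exceeding individuals among the agents: each individual
#' with HI > 1 is assigned to exactly one agent, the one with the largest
#' summed (water + food) PEC contribution for that individual, so the
#' per-agent percentages sum exactly to [exceedance_fraction()]. The
#' alternative `rule = "single_agent"` reports, for each agent, the
#' percentage whose HI would exceed 1 from that agent alone (not a
#' partition; provided for sensitivity exploration).
#'
#' @param samples An `adri_samples` object.
#' @param rfd Reference dose, ug/kg-day PEC, positive.
#' @param rule `"partition"` (default) or `"single_agent"`.
#' @return Named numeric vector of percentages, one per agent.
#' @export
attribute_exceedance <- function(samples, rfd, rule = c("partition", "single_agent")) {
  rule <- match.arg(rule)
  if (!(is.numeric(rfd) && length(rfd) == 1 && is.finite(rfd) && rfd > 0))
    gr_abort("`rfd` must be a positive number", "goitrisk_domain_error")
  agents <- unique(sub("_(water|food)$", "", names(samples$components)))
  per_agent <- vapply(agents, function(a) {
    samples$components[[paste0(a, "_water")]] + samples$components[[paste0(a, "_food")]]
  }, numeric(samples$n))
  if (rule == "single_agent") {
    return(stats::setNames(100 * colMeans(per_agent / rfd > 1), agents))
  }
  exceed <- samples$total / rfd > 1
  winner <- max.col(per_agent, ties.method = "first")
  out <- vapply(seq_along(agents), function(j) {
    100 * sum(exceed & winner == j) / samples$n
  }, numeric(1))
  stats::setNames(out, agents)
}

#' Route split of an agent's intake
#'
#' Mean PEC contribution through water and through food, as percentages of
#' the agent's total mean contribution.
#'
#' @param samples An `adri_samples` object.
#' @param agent Agent name.
#' @return Named numeric `c(water = , food = )`, summing to 100.
#' @export
route_shares <- function(samples, agent) {
  w <- samples$components[[paste0(agent, "_water")]]
  f <- samples$components[[paste0(agent, "_food")]]
  if (is.null(w) || is.null(f))
    gr_abort(sprintf("agent '%s' not present in sample set", agent),
             "goitrisk_lookup_error")
  mw <- mean(w); mf <- mean(f)
  if (mw + mf <= 0)
    gr_abort(sprintf("agent '%s' has zero total contribution; route share undefined",
                     agent), "goitrisk_undefined_share")
  c(water = 100 * mw / (mw + mf), food = 100 * mf / (mw + mf))
}

#' Sample size for a stable upper-percentile estimate
#'
#' Doubles the sample size from `start_n` until the 95th-percentile
#' estimate of the composite intake changes by less than 1% relative to
#' the previous stage, and returns the first stable stage's n. Because all
#' component streams are seeded per component, enlarging n extends each
#' stream: the first `start_n` draws of every stage coincide.
#'
#' @param scenario A `goitrogen_scenario`.
#' @param age_group Age-group name.
#' @param basis `"serum"` or `"halflife"`.
#' @param start_n First stage size (default 1000).
#' @param seed Integer root seed.
#' @param rel_tol Relative stability tolerance (default 0.01).
#' @param cap Largest n attempted (default 1e6); reaching it without
#'   stability raises a non-convergence error carrying the trace.
#' @return Integer n, with the stagewise estimates attached as attribute
#'   `"trace"`.
#' @export
stability_n <- function(scenario, age_group, basis = "serum", start_n = 1000L,
                        seed = 1L, rel_tol = 0.01, cap = 1e6) {
  if (start_n < 1) gr_abort("start_n must be >= 1", "goitrisk_domain_error")
  q95 <- function(n) {
    s <- simulate_adri(scenario, age_group, basis, n = n, seed = seed)
    unname(stats::quantile(s$total, 0.95, type = 7))
  }
  n <- as.integer(start_n)
  trace <- data.frame(n = n, q95 = q95(n))
  repeat {
    n_next <- n * 2L
    if (n_next > cap) {
      gr_abort(sprintf("95th percentile not stable within cap n=%g", cap),
               "goitrisk_non_convergence", data = trace)
    }
    qn <- q95(n_next)
    trace <- rbind(trace, data.frame(n = n_next, q95 = qn))
    prev <- trace$q95[nrow(trace) - 1L]
    if (prev == 0 || abs(qn - prev) / abs(prev) < rel_tol) {
      return(structure(n, trace = trace))
    }
    n <- n_next
  }
}

#' Summarise a sample set against the default reference-dose approaches
#'
#' Bundles the percentile table, the per-approach exceedance percentages
#' and the per-approach attribution partition into one object.
#'
#' @param samples An `adri_samples` object.
#' @param approaches Approach table, default [rfd_approaches()].
#' @param grid Percentile grid.
#' @return A list of class `risk_summary` with fields `percentiles`,
#'   `exceedance`, `attribution`, `hi_values`.
#' @export
risk_summary <- function(samples, approaches = rfd_approaches(),
                         grid = adri_percentile_grid()) {
  rfd_col <- if (samples$basis == "serum") "rfd_no_correction" else "rfd_with_correction"
  rfds <- stats::setNames(approaches[[rfd_col]], approaches$name)
  exc <- vapply(rfds, function(r) exceedance_fraction(samples, r), numeric(1))
  attr_tab <- lapply(rfds, function(r) attribute_exceedance(samples, r))
  hi <- samples$total / rfds[["A3"]]
  structure(
    list(age_group = samples$age_group, basis = samples$basis, n = samples$n,
         percentiles = percentile_table(samples, grid), exceedance = exc,
         attribution = attr_tab,
         hi_values = c(min = min(hi), median = stats::median(hi),
                       mean = mean(hi), max = max(hi))),
    class = "risk_summary"
  )
}
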