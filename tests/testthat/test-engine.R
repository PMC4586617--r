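test_that("point-mass scenario reproduces hand-computed PEC totals on both bases", {
  scn <- degenerate_scenario()
  sim <- simulate_adri(scn, "adult", "serum", n = 25, seed = 1)
  # 0.05 * 1 / 1 + 0.02 * 15000 / 150
  expect_equal(unique(sim$total), 2.05, tolerance = 1e-12)
  simh <- simulate_adri(scn, "adult", "halflife", n = 25, seed = 1)
  # 0.05 * 1 / 1 + 0.02 * 15000 / 240
  expect_equal(unique(simh$total), 1.30, tolerance = 1e-12)
  # all-zero concentrations give an identically zero composite
  zero <- degenerate_scenario(c_pw = 0, c_nf = 0)
  expect_equal(unique(simulate_adri(zero, "adult", "serum", n = 10, seed = 1)$total), 0)
  expect_gr_error(simulate_adri(scn, "nobody", "serum", 10, 1), "goitrisk_lookup_error")
  expect_gr_error(simulate_adri(scn, "adult", "plasma", 10, 1), "goitrisk_lookup_error")
})

test_that("composite conserves the component sum exactly and shares EF draws", {
  scn <- synthetic_scenario(seed = 4)
  sim <- simulate_adri(scn, "2-3 years", "serum", n = 5000, seed = 9)
  expect_identical(sim$total, Reduce(`+`, sim$components))
  # one water draw per individual, shared across agents
  div <- c(perchlorate = 1, nitrate = 150, thiocyanate = 8.8)
  for (a in c("perchlorate", "nitrate")) {
    implied_ef <- sim$components[[paste0(a, "_water")]] * div[[a]] /
      sim$conc_draws[[paste0(a, "_water")]]
    expect_equal(implied_ef, sim$ef_draws$water, tolerance = 1e-12)
  }
  implied_ef_food <- sim$components$nitrate_food * 150 / sim$conc_draws$nitrate_food
  expect_equal(implied_ef_food, sim$ef_draws$food, tolerance = 1e-12)
})

test_that("switching basis rescales each agent by its divisor ratio, draw by draw", {
  scn <- synthetic_scenario(seed = 8)
  s1 <- simulate_adri(scn, ">21 years", "serum", n = 4000, seed = 13)
  s2 <- simulate_adri(scn, ">21 years", "halflife", n = 4000, seed = 13)
  ratio <- c(perchlorate = 1, nitrate = 150 / 240, thiocyanate = 8.8 / 0.5)
  for (comp in names(s1$components)) {
    agent <- sub("_(water|food)$", "", comp)
    expect_equal(s2$components[[comp]], s1$components[[comp]] * ratio[[agent]],
                 tolerance = 1e-12, label = comp)
  }
})

test_that("percentile tables use inclusive linear interpolation and stay monotone", {
  fake <- structure(list(total = as.numeric(1:100)), class = "adri_samples")
  expect_equal(unname(percentile_table(fake, 50)), 50.5)
  expect_equal(unname(percentile_table(fake, c(1, 50, 99))),
               unname(quantile(1:100, c(0.01, 0.5, 0.99), type = 7)))
  scn <- single_component_scenario(median_pec = 13.5)
  sim <- simulate_adri(scn, "adult", "serum", n = 50000, seed = 2)
  tab <- percentile_table(sim)
  expect_equal(unname(tab["50"]), 13.5, tolerance = 0.01)
  expect_true(all(diff(tab) > 0))
  expect_gr_error(percentile_table(structure(list(total = numeric(0)),
                                             class = "adri_samples")),
                  "goitrisk_empty_input")
})

test_that("exceedance matches the closed-form tail and is monotone in the dose", {
  scn <- single_component_scenario(median_pec = 10, gsd = 1.5, trunc = 3)
  sim <- simulate_adri(scn, "adult", "serum", n = 50000, seed = 3)
  d <- trunc_lognormal(10, 1.5, 3)
  for (rfd in c(7, 10, 15, 20)) {
    p_true <- 100 * (1 - tln_cdf(d, rfd))
    se <- 100 * sqrt(p_true / 100 * (1 - p_true / 100) / 50000)
    expect_lt(abs(exceedance_fraction(sim, rfd) - p_true), 3 * se)
  }
  expect_lt(abs(exceedance_fraction(sim, 10) - 50), 1)
  expect_equal(exceedance_fraction(sim, 35), 0) # above the truncated ceiling
  rfds <- seq(2, 40, by = 0.5)
  exc <- vapply(rfds, function(r) exceedance_fraction(sim, r), numeric(1))
  expect_true(all(diff(exc) <= 0))
  expect_gr_error(exceedance_fraction(sim, -1), "goitrisk_domain_error")
})

test_that("attribution partitions exceeders by largest contribution, summing exactly", {
  # only one live agent: everything lands on it
  scn <- single_component_scenario(median_pec = 12)
  sim <- simulate_adri(scn, "adult", "serum", n = 20000, seed = 5)
  att <- attribute_exceedance(sim, 10)
  expect_equal(unname(att["nitrate"]), exceedance_fraction(sim, 10))
  expect_equal(unname(att["perchlorate"]), 0)
  # partition property on a full scenario, at several doses
  sim2 <- simulate_adri(synthetic_scenario(seed = 10), "2-3 years", "serum",
                        n = 30000, seed = 6)
  for (rfd in c(5, 13.5, 29.5)) {
    att2 <- attribute_exceedance(sim2, rfd)
    expect_equal(sum(att2), exceedance_fraction(sim2, rfd), tolerance = 1e-12)
  }
  # largest-contribution rule on a hand-built sample set
  hand <- structure(list(
    n = 2L,
    total = c(1.2, 1.2) * 10,
    components = list(perchlorate_water = c(0, 0), nitrate_water = c(0, 0),
                      thiocyanate_water = c(0, 0),
                      perchlorate_food = c(9, 3), nitrate_food = c(3, 9),
                      thiocyanate_food = c(0, 0))
  ), class = "adri_samples")
  att3 <- attribute_exceedance(hand, 10)
  expect_equal(unname(att3[c("perchlorate", "nitrate")]), c(50, 50))
  # single-agent thresholding rule is not a partition
  att4 <- attribute_exceedance(hand, 10, rule = "single_agent")
  expect_equal(unname(att4[c("perchlorate", "nitrate")]), c(0, 0))
})

test_that("route shares split an agent's mean intake and flag degenerate agents", {
  sim <- simulate_adri(synthetic_scenario(seed = 3), ">21 years", "serum",
                       n = 20000, seed = 4)
  rs <- route_shares(sim, "nitrate")
  expect_equal(sum(rs), 100)
  expect_true(rs[["water"]] > 0 && rs[["water"]] < 50)
  expect_equal(route_shares(sim, "thiocyanate"), c(water = 0, food = 100))
  # a single-route agent gets (0, 100)
  sim1 <- simulate_adri(single_component_scenario(), "adult", "serum", 1000, 2)
  expect_equal(route_shares(sim1, "nitrate"), c(water = 0, food = 100))
  expect_gr_error(route_shares(sim1, "perchlorate"), "goitrisk_undefined_share")
})

test_that("the stability rule returns the first doubling stage with a stable 95th", {
  scn <- degenerate_scenario()
  st <- stability_n(scn, "adult", "serum", start_n = 1000, seed = 1)
  expect_equal(as.integer(st), 1000L)
  expect_s3_class(attr(st, "trace"), "data.frame")
  syn <- synthetic_scenario(seed = 3)
  st2 <- stability_n(syn, ">21 years", "serum", start_n = 2000, seed = 5)
  st3 <- stability_n(syn, ">21 years", "serum", start_n = 2000, seed = 5)
  expect_identical(as.integer(st2), as.integer(st3))
  expect_lte(as.integer(st2), 1e6)
  # a cap below the first doubling cannot converge and must say so
  err <- tryCatch(stability_n(syn, ">21 years", "serum", start_n = 1000,
                              seed = 5, cap = 1500),
                  error = identity)
  expect_s3_class(err, "goitrisk_non_convergence")
  expect_s3_class(err$data, "data.frame")
})

test_that("risk summaries order the approaches by their reference doses", {
  sim <- simulate_adri(synthetic_scenario(seed = 6), "2-3 years", "serum",
                       n = 20000, seed = 7)
  rs <- risk_summary(sim)
  # 29.5 > 14.5 > 13.5 implies exceedance(A4) <= exceedance(A4b) <= exceedance(A3)
  expect_lte(rs$exceedance[["A4"]], rs$exceedance[["A4b"]])
  expect_lte(rs$exceedance[["A4b"]], rs$exceedance[["A3"]])
  expect_true(all(diff(rs$percentiles) > 0))
  for (ap in names(rs$attribution)) {
    expect_equal(sum(rs$attribution[[ap]]), rs$exceedance[[ap]])
  }
})
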