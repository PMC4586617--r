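test_that("calibration targets validate their surfaces", {
  expect_gr_error(calibration_target("x"), "goitrisk_schema_error")
  expect_gr_error(
    calibration_target("x", percentiles_serum = c("50" = 10, "95" = 9)),
    "goitrisk_inconsistent_targets"
  )
  expect_gr_error(
    calibration_target("x", percentiles_serum = c("50" = 10, "95" = 20),
                       cv_serum = c(a = 50, b = 50)),
    "goitrisk_schema_error"
  )
  tg <- calibration_target("x", percentiles_serum = c("50" = 10, "95" = 20))
  expect_s3_class(tg, "calibration_target")
})

test_that("bundled reference targets are complete and coherent", {
  for (b in c("serum", "halflife")) {
    tg <- reference_target("2-3 years", b)
    pct <- tg[[paste0("percentiles_", b)]]
    expect_length(pct, 9)
    expect_true(all(diff(pct) > 0))
    cv <- tg[[paste0("cv_", b)]]
    expect_equal(sum(cv), 100, tolerance = 2)
    expect_equal(unname(tg$route_shares), c(4, 6, 0))
  }
  expect_gr_error(reference_target("nobody", "serum"), "goitrisk_lookup_error")
  # both-bases target carries both rows
  tgb <- reference_target(">21 years", "both")
  expect_false(is.null(tgb$percentiles_serum))
  expect_false(is.null(tgb$percentiles_halflife))
})

test_that("component splits are refused without identifying surfaces", {
  tg <- calibration_target("x", percentiles_serum = c("50" = 10, "95" = 20),
                           route_shares = NULL)
  expect_gr_error(calibrate(tg), "goitrisk_underdetermined")
})

test_that("variance targets on structurally degenerate factors fail fast", {
  cv_bad <- setNames(c(0, 0, 100, 0, 0, 0, 0, 0),
                     c("perchlorate_water_conc", "nitrate_water_conc",
                       "thiocyanate_water_conc", "perchlorate_food_conc",
                       "nitrate_food_conc", "thiocyanate_food_conc",
                       "water_EF", "food_EF"))
  tg <- calibration_target("x", percentiles_serum = c("50" = 10, "95" = 20),
                           cv_serum = cv_bad)
  expect_gr_error(calibrate(tg, seed = 1), "goitrisk_calibration_failure")
})

test_that("calibration recovers a known synthetic scenario", {
  # boost the minor agent so every component carries an identifiable
  # variance share; sub-percent shares sit below the rank-correlation
  # identifiability floor at any practical sample size
  params <- synthetic_defaults()
  params$conc_food_median$perchlorate <- params$conc_food_median$perchlorate * 6
  params$conc_water_median[["perchlorate"]] <-
    params$conc_water_median[["perchlorate"]] * 6
  scn <- synthetic_scenario(seed = 42, params = params)
  g <- ">21 years"
  sim <- simulate_adri(scn, g, "serum", n = 200000, seed = 5)
  pct <- percentile_table(sim)
  cv <- contribution_to_variance(sim)$shares
  rsh <- vapply(c("perchlorate", "nitrate", "thiocyanate"), function(a)
    route_shares(sim, a)[["water"]], numeric(1))
  tg <- calibration_target(g,
                           percentiles_serum = setNames(as.numeric(pct), names(pct)),
                           cv_serum = cv, route_shares = rsh)
  cal <- calibrate(tg, seed = 3, perchlorate_prior_weight = 0, n = 20000L,
                   cv_weight = 0.05, n_starts = 6L,
                   percentile_weights = setNames(rep(1, 9), names(pct)))
  ags <- goitrogen_agents()
  ef_food <- scn$age_groups[[g]]$ef_food$median
  truth <- vapply(ags$name, function(a)
    scn$conc_food[[a]]$median * ef_food /
      ags$pec_divisor_serum[ags$name == a], numeric(1))
  expect_lt(max(abs(cal$fitted$pec_food_medians / truth - 1)), 0.05)
  # and the calibrated scenario reproduces the target percentiles within 1%
  sim2 <- simulate_adri(cal$scenario, g, "serum", n = 200000, seed = 6)
  expect_lt(max(abs(percentile_table(sim2) / pct - 1)), 0.01)
  # exposure-factor spreads come back too
  expect_lt(abs(cal$fitted$ef_gsds[["food"]] - scn$age_groups[[g]]$ef_food$gsd), 0.05)
})

test_that("the accepted objective trajectory is non-increasing", {
  cal <- calibrate(reference_target("2-3 years", "serum"), seed = 2,
                   n = 4000L, n_starts = 4L, maxit = 150L)
  expect_true(all(diff(cal$trace) <= 0))
  expect_equal(min(cal$trace), cal$objective_value, tolerance = 1e-9)
})

test_that("joint two-basis calibration fits both rows with shared draws", {
  scn <- synthetic_scenario(seed = 17)
  g <- "2-3 years"
  sims <- lapply(c(serum = "serum", halflife = "halflife"), function(b)
    simulate_adri(scn, g, b, n = 100000, seed = 5))
  tg <- calibration_target(
    g,
    percentiles_serum = {
      p <- percentile_table(sims$serum); setNames(as.numeric(p), names(p))
    },
    percentiles_halflife = {
      p <- percentile_table(sims$halflife); setNames(as.numeric(p), names(p))
    },
    cv_serum = contribution_to_variance(sims$serum)$shares,
    route_shares = vapply(c("perchlorate", "nitrate", "thiocyanate"), function(a)
      route_shares(sims$serum, a)[["water"]], numeric(1))
  )
  cal <- calibrate(tg, seed = 4, perchlorate_prior_weight = 0, n = 10000L,
                   percentile_weights = setNames(rep(1, 9), names(percentile_table(sims$serum))))
  expect_setequal(cal$bases, c("serum", "halflife"))
  for (b in c("serum", "halflife")) {
    sim2 <- simulate_adri(cal$scenario, g, b, n = 100000, seed = 9)
    expect_lt(max(abs(percentile_table(sim2) / percentile_table(sims[[b]]) - 1)),
              0.03)
  }
})

test_that("verification reports signed errors only for supplied printed entries", {
  cal <- calibrate(reference_target(">21 years", "serum"), seed = 6,
                   n = 4000L, n_starts = 3L, maxit = 150L)
  empty <- verify_calibration(cal, exceedance_rows = NULL, attribution_rows = NULL,
                              n = 2000)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("age_group", "basis", "approach", "metric", "agent",
                        "predicted", "printed", "error"))
  rep <- verify_calibration(cal, exceedance_rows = reference_exceedance(),
                            attribution_rows = reference_attribution(),
                            n = 20000, seed = 3)
  expect_equal(nrow(rep), 3 + 9) # 3 approaches + 3 approaches x 3 agents
  expect_equal(rep$error, rep$predicted - rep$printed)
  a3 <- rep[rep$approach == "A3" & rep$metric == "exceedance", ]
  expect_lt(abs(a3$error), 2.5)
})
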