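# Shared fixtures built in code.

# Point-mass scenario: perchlorate 1 ug/L in water, nitrate 15,000 ug/kg in
# food, fixed exposure factors. Serum-basis composite is exactly
# 0.05 * 1 / 1 + 0.02 * 15000 / 150 = 2.05 ug/kg-day PEC.
degenerate_scenario <- function(ef_water = 0.05, ef_food = 0.02,
                                c_pw = 1, c_nf = 15000) {
  ag <- list(adult = list(
    name = "adult",
    ef_water = trunc_lognormal(ef_water, 1),
    ef_food = trunc_lognormal(ef_food, 1)
  ))
  cw <- list(perchlorate = trunc_lognormal(c_pw, 1),
             nitrate = trunc_lognormal(0, 1),
             thiocyanate = trunc_lognormal(0, 1))
  cf <- list(perchlorate = trunc_lognormal(0, 1),
             nitrate = trunc_lognormal(c_nf, 1),
             thiocyanate = trunc_lognormal(0, 1))
  new_scenario(ag, cw, cf)
}

# One-component stochastic scenario: only nitrate in food varies.
single_component_scenario <- function(median_pec = 10, gsd = 1.5, trunc = 3) {
  ag <- list(adult = list(
    name = "adult",
    ef_water = trunc_lognormal(0.05, 1),
    ef_food = trunc_lognormal(1, 1)
  ))
  cw <- list(perchlorate = trunc_lognormal(0, 1),
             nitrate = trunc_lognormal(0, 1),
             thiocyanate = trunc_lognormal(0, 1))
  cf <- list(perchlorate = trunc_lognormal(0, 1),
             nitrate = trunc_lognormal(median_pec * 150, gsd, trunc),
             thiocyanate = trunc_lognormal(0, 1))
  new_scenario(ag, cw, cf, trunc = trunc)
}

expect_gr_error <- function(expr, class) {
  expect_error(expr, class = class)
}
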