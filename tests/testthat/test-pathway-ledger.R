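# Cofactor ledger: flux resolution, NADH/ferredoxin budget, branch
# equations and ATP yields.

fx <- builtin_table1_fixtures()
net_rha <- net_changes(fx$rhamnose)
net_glc <- net_changes(fx$glucose)

test_that("demand-driven fluxes reconstruct the rhamnose culture", {
  fl <- solve_fluxes("rhamnose", net_rha)
  flux <- stats::setNames(fl$flux, fl$reaction)
  # 43.2 mM of lactaldehyde reduced: all 1,2-propanediol-derived products
  expect_equal(unname(flux["lactaldehyde_reductase"]), 17.2 + 18.2 + 7.8)
  # 42.6 mM DHAP-equivalents oxidized: acetate + 2 x butyrate
  expect_equal(unname(flux["emp_dhap"]), 19.2 + 2 * 11.7)
  expect_equal(unname(flux["pfor"]), 42.6)
  expect_equal(unname(flux["c4_reduction"]), 11.7)
  expect_equal(unname(flux["propanol_dehydrogenase"]), 18.2)
  expect_equal(unname(flux["propionaldehyde_dehydrogenase"]), 7.8)
})

test_that("observed-mode NADH budget balances the measured product spectrum", {
  led <- nadh_ledger(net_rha, "rhamnose")
  expect_equal(led$nadh_glycolytic, 42.6)
  expect_equal(led$fd_red_produced, 42.6)
  expect_equal(led$nadh_other_produced, 7.8)   # propionaldehyde oxidation
  # sinks: 43.2 (propanediol) + 18.2 (propanol) + 2 x 11.7 (C4 reduction)
  expect_equal(led$nadh_consumed, 43.2 + 18.2 + 23.4)
  expect_equal(led$nadh_deficit, 34.4)
  expect_equal(unname(led$branch_inputs["lactaldehyde"]), 43.2)
  expect_equal(unname(led$branch_inputs["dhap"]), 42.6)
  # C4-branch NADH sink is 2 NADH per butyrate at each reduction step
  c4 <- led$fluxes[led$fluxes$reaction == "c4_reduction", ]
  expect_equal(-c4$nadh, 2 * 11.7)
})

test_that("discussion convention yields the 92.8 mM total NADH figure", {
  led <- nadh_ledger(net_rha, "rhamnose", mode = "discussion")
  expect_equal(led$nadh_glycolytic, 46.4)
  expect_equal(led$fd_red_produced, 46.4)
  expect_equal(led$nadh_available, 92.8)
})

test_that("a culture with no products gives an all-zero ledger", {
  ds <- fermentation_dataset("e", c(0, 24), cbind(rhamnose = c(100, 90)),
                             substrates = "rhamnose", biomass_end_mM = 0)
  led <- nadh_ledger(net_changes(ds), "rhamnose")
  expect_equal(led$nadh_produced, 0)
  expect_equal(led$nadh_consumed, 0)
  expect_equal(led$fd_red_produced, 0)
  expect_true(all(led$fluxes$flux == 0))
})

test_that("ledger totals are linear in the product amounts", {
  ds <- fx$rhamnose
  doubled <- fermentation_dataset(ds$culture_id, ds$time_h,
                                  ds$conc * 2,
                                  substrates = ds$substrates,
                                  biomass_end_mM = ds$biomass_end_mM * 2)
  l1 <- nadh_ledger(net_changes(ds), "rhamnose")
  l2 <- nadh_ledger(net_changes(doubled), "rhamnose")
  expect_equal(l2$fluxes$flux, 2 * l1$fluxes$flux)
  expect_equal(l2$nadh_consumed, 2 * l1$nadh_consumed)
  expect_equal(l2$atp_produced, 2 * l1$atp_produced)
})

test_that("acetate reassimilation is pinned to its measured consumption", {
  fl <- solve_fluxes("glucose", net_glc)
  flux <- stats::setNames(fl$flux, fl$reaction)
  expect_equal(unname(flux["acetate_coa_transferase"]), 30.7)
  expect_equal(unname(flux["acetate_kinase"]), 0)
  # acetyl-CoA demand 377.2 minus reassimilated 30.7 comes from pyruvate
  expect_equal(unname(flux["pfor"]), 346.5)
  expect_equal(unname(flux["emp_glucose"]), (346.5 + 7.5) / 2)
})

test_that("mixture pyruvate is fed by capped DHAP supply then glucose", {
  fl <- solve_fluxes("mixture", net_changes(fx$mixture))
  flux <- stats::setNames(fl$flux, fl$reaction)
  # all rhamnose-derived DHAP (one per propanediol formed) is used first
  expect_equal(unname(flux["emp_dhap"]), 78.4)
  expect_gt(unname(flux["emp_glucose"]), 0)
  led <- nadh_ledger(net_changes(fx$mixture), "mixture")
  expect_equal(led$nadh_glycolytic,
               unname(flux["emp_dhap"] + 2 * flux["emp_glucose"]))
})

test_that("branch equations reproduce the published coefficients on basis 44.3", {
  be <- branch_equations(net_rha)
  expect_equal(be$basis_mM, 44.3)
  expect_equal(round(unname(be$lactaldehyde), 2),
               c(0.39, 0.41, 0.18))   # propanediol, propanol, propionate
  expect_equal(round(unname(be$dhap), 2), c(0.43, 0.26))
  # acetyl-CoA units per pyruvate: acetate + 2 x butyrate <= basis
  expect_lte(be$dhap[["acetate"]] + 2 * be$dhap[["butyrate"]], 1)
  # round trip: coefficients times basis regenerate the observed products
  expect_equal(unname(be$lactaldehyde * be$basis_mM), c(17.2, 18.2, 7.8))
  expect_equal(unname(be$dhap * be$basis_mM), c(19.2, 11.7))
  expect_error(branch_equations(net_glc), "rhamnose")
})

test_that("branch coefficients survive a generator round trip", {
  m <- 1 - 5 * 0.045 / 6
  spec <- simulation_spec(
    substrates = c(rhamnose = 243.4), consumed = c(rhamnose = 46.4),
    product_coeffs = list(rhamnose = c(propanediol = 0.5, propanol = 0.3,
                                       propionate = 0.2, acetate = 0.5,
                                       butyrate = 0.25) * m),
    biomass_yield = c(rhamnose = 0.045))
  sim <- simulate_fermentation(spec)
  be <- branch_equations(net_changes(sim$dataset))
  basis_per_sugar <- be$basis_mM / 46.4   # 1 - biomass drain
  expect_equal(unname(be$lactaldehyde * basis_per_sugar),
               c(0.5, 0.3, 0.2) * m, tolerance = 1e-12)
})

test_that("ATP yields land at ~0.9 on rhamnose and ~2 on glucose", {
  expect_equal(atp_yield(net_rha, "rhamnose"), 0.874, tolerance = 0.001)
  expect_equal(round(atp_yield(net_rha, "rhamnose"), 1), 0.9)
  expect_equal(atp_yield(net_glc, "glucose"), 2.01, tolerance = 0.005)
  # zero acid production on rhamnose: -1 uptake - 1 kinase + 2 EMP = 0
  ds <- fermentation_dataset("pd", c(0, 24),
                             cbind(rhamnose = c(100, 60),
                                   propanediol = c(0, 38)),
                             substrates = "rhamnose", biomass_end_mM = 0)
  expect_equal(atp_yield(net_changes(ds), "rhamnose"), 0)
})

test_that("carbon-unbalanced reactions are rejected at pathway assembly", {
  bad <- reaction("bad", consumes = c(pyruvate = 1),
                  produces = c(butyrate = 1))
  expect_error(pathway("x", list(bad), species_order = "butyrate",
                       sugars = "glucose", atp_uptake_cost = 0,
                       atp_slp_per_sugar = 2, acid_products = "butyrate"),
               "not carbon balanced")
})
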