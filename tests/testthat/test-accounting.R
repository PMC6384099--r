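# Net-change accounting, biomass conversion and molar yields.

test_that("net_changes assigns substrate/product roles from the sign of the delta", {
  fx <- builtin_table1_fixtures()
  ng <- net_changes(fx$glucose)
  expect_equal(ng$net[ng$compound == "acetate"], 30.7)
  expect_equal(ng$role[ng$compound == "acetate"], "substrate")

  nr <- net_changes(fx$rhamnose)
  expect_equal(nr$net[nr$compound == "acetate"], 19.2)
  expect_equal(nr$role[nr$compound == "acetate"], "product")

  # roles are exclusive and exhaustive for nonzero changes
  for (net in list(ng, nr)) {
    expect_false(anyDuplicated(net$compound) > 0)
    expect_true(all(net$role %in% c("substrate", "product")))
    expect_true(all(net$net > 0))
  }
})

test_that("compounds with zero net change are omitted", {
  ds <- fermentation_dataset("z", c(0, 24),
                             conc = cbind(glucose = c(100, 40),
                                          ethanol = c(5, 5)),
                             substrates = "glucose", biomass_end_mM = 0)
  net <- net_changes(ds)
  expect_false("ethanol" %in% net$compound)
})

test_that("a single time point is insufficient for accounting", {
  ds <- fermentation_dataset("one", 0, conc = cbind(glucose = 100),
                             biomass_end_mM = 0)
  expect_error(net_changes(ds), "insufficient")
})

test_that("OD600 calibration is linear with the published coefficients", {
  expect_equal(biomass_from_od(0), 0.13)
  expect_equal(biomass_from_od(11.1), 3.238)
  expect_error(biomass_from_od(-1), "non-negative")
})

test_that("cdw converts to mM of 5-C biomass units through the unit mass", {
  expect_equal(biomass_millimolar(0), 0)
  expect_equal(biomass_millimolar(3.238), 26.3, tolerance = 0.01)
  expect_equal(biomass_millimolar(0.2583), 2.1, tolerance = 0.01)
  expect_error(biomass_millimolar(-0.1), "non-negative")
})

test_that("biomass resolution prefers direct mM, then cdw, then OD", {
  base <- cbind(glucose = c(100, 40))
  ds1 <- fermentation_dataset("a", c(0, 24), base, od600 = c(0.1, 10),
                              cdw_end = 1.2313, biomass_end_mM = 26.6)
  expect_equal(dataset_biomass_mM(ds1), 26.6)
  ds2 <- fermentation_dataset("b", c(0, 24), base, od600 = c(0.1, 10),
                              cdw_end = 1.23131)
  expect_equal(dataset_biomass_mM(ds2), 10, tolerance = 1e-4)
  ds3 <- fermentation_dataset("c", c(0, 24), base, od600 = c(0.1, 10))
  expect_equal(dataset_biomass_mM(ds3), biomass_millimolar(biomass_from_od(10)))
  ds4 <- fermentation_dataset("d", c(0, 24), base)
  expect_warning(b4 <- dataset_biomass_mM(ds4), "no biomass")
  expect_equal(b4, 0)
})

test_that("yields reproduce the printed mol/mol values", {
  fx <- builtin_table1_fixtures()
  yg <- yields(net_changes(fx$glucose))
  pick <- function(y, p, b) y$yield[y$product == p & y$basis == b]
  expect_equal(round(pick(yg, "butanol", "glucose"), 2), 0.52)
  expect_equal(round(pick(yg, "biomass", "sugar"), 2), 0.12)

  yr <- yields(net_changes(fx$rhamnose))
  expect_equal(round(pick(yr, "propanediol", "rhamnose"), 2), 0.37)
  expect_equal(round(pick(yr, "propanol", "rhamnose"), 2), 0.39)
  expect_equal(round(pick(yr, "propionate", "rhamnose"), 2), 0.17)
  expect_equal(round(pick(yr, "biomass", "sugar"), 3), 0.045)

  ym <- yields(net_changes(fx$mixture))
  expect_equal(round(pick(ym, "butanol", "glucose"), 2), 0.53)
  expect_equal(round(pick(ym, "propanediol", "rhamnose"), 3), 0.904)
  # mixture biomass basis is the summed sugar consumption
  expect_equal(round(pick(ym, "biomass", "sugar"), 3),
               round(11.7 / (111.2 + 86.7), 3))
})

test_that("yields are invariant under uniform scaling of concentrations", {
  fx <- table1_replay("rhamnose")
  scaled <- fermentation_dataset(fx$culture_id, fx$time_h, fx$conc * 3,
                                 substrates = fx$substrates,
                                 biomass_end_mM = fx$biomass_end_mM * 3)
  expect_equal(yields(net_changes(scaled))$yield,
               yields(net_changes(fx))$yield)
})

test_that("a basis without net consumption is an error", {
  ds <- fermentation_dataset("z", c(0, 24),
                             conc = cbind(glucose = c(100, 40),
                                          ethanol = c(0, 20)),
                             substrates = "glucose", biomass_end_mM = 0)
  net <- net_changes(ds)
  expect_error(yields(net, bases = "rhamnose"), "undefined yield")
})

test_that("noiseless synthetic data return the generating coefficients exactly", {
  spec <- table1_like_rhamnose_spec(noise_sd = 0, seed = NULL)
  sim <- simulate_fermentation(spec)
  truth <- sim$truth$coeffs$rhamnose
  net <- net_changes(sim$dataset)
  y <- yields(net, bases = "rhamnose", products = names(truth))
  expect_equal(stats::setNames(y$yield, y$product), truth, tolerance = 1e-12)
  # regression-based recovery over the full trajectory agrees too
  rec <- recover_yields(sim$dataset, "rhamnose", names(truth))
  expect_equal(rec, truth, tolerance = 1e-12)
})
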