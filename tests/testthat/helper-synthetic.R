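# Synthetic-culture builders shared across tests.

# A fully carbon- and electron-closed rhamnose-type split: the
# lactaldehyde-branch coefficients sum to 1 and the DHAP branch satisfies
# acetate + 2 x butyrate = 1 (per mol of triose), scaled down by the
# biomass carbon drain, so recoveries are 100% by construction.
balanced_rhamnose_spec <- function(noise_sd = 0, seed = NULL,
                                   biomass_yield = 0.045,
                                   times = seq(0, 56, length.out = 15)) {
  m <- 1 - 5 * biomass_yield / 6   # catabolized fraction of substrate moles
  coeffs <- c(propanediol = 0.5, propanol = 0.3, propionate = 0.2,
              acetate = 0.5, butyrate = 0.25) * m
  simulation_spec(substrates = c(rhamnose = 243.4),
                  consumed = c(rhamnose = 46.4),
                  product_coeffs = list(rhamnose = coeffs),
                  biomass_yield = c(rhamnose = biomass_yield),
                  times = times, noise_sd = noise_sd, seed = seed)
}

# Coefficients of the reference l-rhamnose culture (per mol sugar consumed):
# realistic, not fully closed (carbon recovery ~96%).
table1_like_rhamnose_spec <- function(noise_sd = 1, seed = 1,
                                      times = seq(0, 56, length.out = 15)) {
  simulation_spec(
    substrates = c(rhamnose = 243.4), consumed = c(rhamnose = 46.4),
    product_coeffs = list(rhamnose = c(propanediol = 17.2, propanol = 18.2,
                                       propionate = 7.8, acetate = 19.2,
                                       butyrate = 11.7) / 46.4),
    biomass_yield = c(rhamnose = 0.045),
    times = times, noise_sd = noise_sd, seed = seed)
}

# The classic homoacetate fermentation, glucose + 2 H2O -> 2 acetate +
# 2 CO2 + 4 H2, as a synthetic culture.
homoacetate_spec <- function(consumed = 50) {
  simulation_spec(substrates = c(glucose = 100),
                  consumed = c(glucose = consumed),
                  product_coeffs = list(glucose = c(acetate = 2)))
}
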