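# Synthetic batch fermentations with known ground-truth stoichiometry.
#
# The generator emulates a batch culture in which products accumulate in
# fixed molar proportion to substrate consumed (the behaviour of the
# reference cultures): per mole of substrate, a coefficient vector routes
# carbon to products and biomass, and the generator closes the elemental
# balance itself -- CO2 takes the residual carbon, H2 the residual
# electrons, water the residual O/H -- so every simulated culture is
# balanced by construction and the ground truth is exact.

#' Specify a synthetic fermentation
#'
#' @param substrates named numeric vector of initial concentrations (mM).
#' @param consumed named numeric vector: total consumption per substrate
#'   over the run (mM); must not exceed the initial amount.
#' @param product_coeffs named list (one element per substrate) of named
#'   coefficient vectors: mol product formed per mol substrate consumed.
#' @param biomass_yield named numeric: mol of 5-C biomass units per mol
#'   substrate consumed.
#' @param times sampling times (h), strictly increasing, starting at 0.
#' @param logistic_rate,logistic_mid rate (1/h) and midpoint (h) of the
#'   logistic progress curve that the cumulative consumption follows
#'   (growth-coupled consumption: fast around the midpoint, saturating as
#'   the culture arrests).
#' @param noise_sd additive Gaussian measurement noise per concentration
#'   reading, sd in mM (HPLC-type error); applied to concentrations, never
#'   to the underlying truth, and clipped at 0 (detection limit).
#' @param seed integer; fixes the full trajectory.
#' @param registry a `compound_registry`.
#' @return A `simulation_spec` with the derived per-substrate closure
#'   coefficients `co2`, `h2`, `water` attached.
#' @export
simulation_spec <- function(substrates, consumed, product_coeffs,
                            biomass_yield = NULL,
                            times = seq(0, 56, length.out = 15),
                            logistic_rate = 0.25, logistic_mid = NULL,
                            noise_sd = 0, seed = NULL,
                            registry = default_registry()) {
  stopifnot(is.numeric(substrates), !is.null(names(substrates)),
            is.numeric(consumed), !is.null(names(consumed)))
  if (!all(names(consumed) %in% names(substrates))) {
    stop("simulation spec: 'consumed' names must be substrates", call. = FALSE)
  }
  if (any(consumed < 0) || any(consumed > substrates[names(consumed)] + 1e-9)) {
    stop("simulation spec: consumption must lie in [0, initial]",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("simulation spec: noise sd must be a single non-negative number",
         call. = FALSE)
  }
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE)) {
    stop("simulation spec: times must be strictly increasing", call. = FALSE)
  }
  if (is.null(biomass_yield)) {
    biomass_yield <- stats::setNames(rep(0, length(consumed)), names(consumed))
  }
  unit <- biomass_unit()
  closure <- list()
  for (s in names(consumed)) {
    cf <- product_coeffs[[s]] %||% stats::setNames(numeric(0), character(0))
    if (any(cf < 0)) {
      stop("simulation spec: negative product coefficient for ", s,
           call. = FALSE)
    }
    by <- biomass_yield[s]
    if (is.na(by)) by <- 0
    c_s <- compound_carbon(s, registry)
    g_s <- compound_gamma(s, registry)
    c_p <- if (length(cf)) sum(compound_carbon(names(cf), registry) * cf) else 0
    g_p <- if (length(cf)) sum(compound_gamma(names(cf), registry) * cf) else 0
    co2 <- c_s - c_p - unit$carbon * by
    if (co2 < -1e-9) {
      stop("simulation spec: carbon-inconsistent split for ", s,
           " (products + biomass draw ", c_p + unit$carbon * by,
           " C from a ", c_s, "-C substrate)", call. = FALSE)
    }
    h2 <- (g_s - g_p - unit$gamma * by) / 2
    if (h2 < -1e-9) {
      stop("simulation spec: electron-inconsistent split for ", s,
           call. = FALSE)
    }
    o_s <- unclass(parse_formula_or_fail(
      registry$formula[match(s, registry$name)]))[["O"]]
    o_p <- if (length(cf)) {
      sum(vapply(names(cf), function(p) {
        unclass(parse_formula(registry$formula[match(p, registry$name)]))[["O"]]
      }, numeric(1)) * cf)
    } else 0
    water <- o_s - o_p - 2.5 * by - 2 * co2   # can be negative: water consumed
    closure[[s]] <- list(coeffs = cf, biomass = unname(by),
                         co2 = max(0, co2), h2 = max(0, h2), water = water)
  }
  structure(list(substrates = substrates, consumed = consumed,
                 closure = closure, times = as.numeric(times),
                 logistic_rate = logistic_rate,
                 logistic_mid = logistic_mid %||% (max(times) / 3),
                 noise_sd = noise_sd, seed = seed, registry = registry),
            class = "simulation_spec")
}

# normalized logistic progress: 0 at t[1], 1 at t[end]
logistic_progress <- function(times, rate, mid) {
  l <- 1 / (1 + exp(-rate * (times - mid)))
  (l - l[1L]) / (l[length(l)] - l[1L])
}

#' Simulate a batch fermentation time course
#'
#' Substrate depletion follows the spec's logistic progress curve; each
#' product (and biomass) accumulates as coefficient x substrate consumed;
#' the generator's own CO2, H2 and water closures are tracked in the ground
#' truth; measurement noise is applied last.  The same seed always yields a
#' bit-identical dataset.
#'
#' @param spec a `simulation_spec`.
#' @return A list of class `fermentation_simulation`: `dataset` (a
#'   `fermentation_dataset` of the noisy observations) and `truth` (true
#'   consumed amounts, product coefficients, biomass, CO2/H2 series, number
#'   of noise values clipped at the detection floor).
#' @export
simulate_fermentation <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
  }
  times <- spec$times
  prog <- logistic_progress(times, spec$logistic_rate, spec$logistic_mid)
  products <- unique(unlist(lapply(spec$closure,
                                   function(cl) names(cl$coeffs))))
  compounds <- c(names(spec$substrates), products)
  true_conc <- matrix(0, length(times), length(compounds),
                      dimnames = list(NULL, compounds))
  true_conc[, names(spec$substrates)] <-
    rep(spec$substrates, each = length(times))
  biomass <- co2 <- h2 <- numeric(length(times))
  for (s in names(spec$consumed)) {
    cons_t <- spec$consumed[[s]] * prog
    true_conc[, s] <- true_conc[, s] - cons_t
    cl <- spec$closure[[s]]
    for (p in names(cl$coeffs)) {
      true_conc[, p] <- true_conc[, p] + cl$coeffs[[p]] * cons_t
    }
    biomass <- biomass + cl$biomass * cons_t
    co2 <- co2 + cl$co2 * cons_t
    h2 <- h2 + cl$h2 * cons_t
  }
  obs <- true_conc
  n_clipped <- 0L
  if (spec$noise_sd > 0) {
    noise <- matrix(stats::rnorm(length(obs), sd = spec$noise_sd),
                    nrow(obs), ncol(obs))
    obs <- obs + noise
    n_clipped <- sum(obs < 0)
    obs[obs < 0] <- 0
  }
  ds <- fermentation_dataset(
    culture_id = "synthetic", time_h = times, conc = obs,
    substrates = names(spec$substrates),
    biomass_end_mM = biomass[length(biomass)],
    registry = spec$registry)
  structure(list(
    dataset = ds,
    truth = list(consumed = spec$consumed,
                 coeffs = lapply(spec$closure, `[[`, "coeffs"),
                 biomass_mM = biomass[length(biomass)],
                 biomass_series = biomass,
                 co2_mM = co2[length(co2)], co2_series = co2,
                 h2_mM = h2[length(h2)], h2_series = h2,
                 true_conc = true_conc,
                 n_clipped = n_clipped)),
    class = "fermentation_simulation")
}
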