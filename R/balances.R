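# Carbon recovery, CO2 estimation, H2 estimation by redox closure, and
# degree-of-reduction electron recovery.

#' Estimate CO2 release from the product spectrum
#'
#' Applies the class rule: every mole of acetate or ethanol formed releases
#' 1 mol CO2, butyrate or butanol 2 mol, acetone or isopropanol 3 mol; all
#' other products none.  Compounds consumed (role = substrate) contribute
#' nothing -- consumed acetate never generates CO2.
#'
#' @param net a `net_change_table`.
#' @param registry a `compound_registry`; defaults to the table's.
#' @return Estimated CO2 in mM.
#' @export
estimate_co2 <- function(net, registry = attr(net, "registry")) {
  prods <- net[net$role == "product", , drop = FALSE]
  if (!nrow(prods)) return(0)
  sum(co2_per_mole(prods$compound, registry) * prods$net)
}

#' Carbon recovery
#'
#' Percentage of substrate carbon recovered in measured products, biomass
#' (5 C-mol per formula unit) and estimated CO2:
#' 100 x (sum C x product + 5 x biomass + CO2) / (sum C x substrate).
#'
#' @param net a `net_change_table`.
#' @param biomass_mM biomass formed, mM of 5-C units (default: the table's
#'   attribute).
#' @param registry a `compound_registry`.
#' @param co2_mM CO2 to count, mM; default [estimate_co2()].
#' @return Recovery in percent (numeric scalar), with a `terms` attribute
#'   holding the C-mmol/L totals (`substrate_C`, `product_C`, `biomass_C`,
#'   `co2_C`).
#' @export
carbon_recovery <- function(net, biomass_mM = attr(net, "biomass_mM"),
                            registry = attr(net, "registry"),
                            co2_mM = estimate_co2(net, registry)) {
  subs <- net[net$role == "substrate", , drop = FALSE]
  prods <- net[net$role == "product", , drop = FALSE]
  if (!nrow(subs)) stop("no substrates with net consumption", call. = FALSE)
  substrate_C <- sum(compound_carbon(subs$compound, registry) * subs$net)
  product_C <- if (nrow(prods)) {
    sum(compound_carbon(prods$compound, registry) * prods$net)
  } else 0
  biomass_C <- biomass_unit()$carbon * (biomass_mM %||% 0)
  pct <- 100 * (product_C + biomass_C + co2_mM) / substrate_C
  structure(pct, terms = c(substrate_C = substrate_C, product_C = product_C,
                           biomass_C = biomass_C, co2_C = co2_mM))
}

#' Estimate H2 production by redox closure
#'
#' H2 cannot usually be quantified during the fermentation, so it is
#' inferred from the stoichiometry: pyruvate oxidation to acetyl-CoA
#' reduces 1 ferredoxin per pyruvate, and reduced ferredoxin either covers
#' the NADH deficit of the product spectrum (via transhydrogenation) or is
#' vented as H2 by the hydrogenase.  Surplus NADH, when the products
#' consume less than glycolysis delivers, is likewise vented:
#' `H2 = max(0, Fd_red + NADH_produced - NADH_consumed)`.
#' Electron-bifurcating reactions are not modeled.
#'
#' @param net a `net_change_table`.
#' @param pathway a `pathway` or shipped pathway id.
#' @return Estimated H2 in mM, with the `pathway_ledger` used attached as
#'   attribute `ledger`.
#' @export
estimate_h2 <- function(net, pathway) {
  led <- nadh_ledger(net, pathway, mode = "observed")
  h2 <- max(0, led$fd_red_produced + led$nadh_produced - led$nadh_consumed)
  structure(h2, ledger = led)
}

#' Electron recovery
#'
#' Percentage of substrate electron equivalents (degree-of-reduction
#' weighted) recovered in products, biomass (21 electrons per 5-C unit) and
#' H2 (2 electrons/mol): 100 x (sum gamma x product + 21 x biomass +
#' 2 x H2) / (sum gamma x substrate).  CO2 carries zero electrons, so the
#' result is independent of the CO2 estimate.
#'
#' @inheritParams carbon_recovery
#' @param h2_mM H2 to count, mM (e.g. from [estimate_h2()]).
#' @return Recovery in percent, with a `terms` attribute
#'   (electron-mmol/L totals).
#' @export
electron_recovery <- function(net, biomass_mM = attr(net, "biomass_mM"),
                              h2_mM = 0, registry = attr(net, "registry")) {
  subs <- net[net$role == "substrate", , drop = FALSE]
  prods <- net[net$role == "product", , drop = FALSE]
  if (!nrow(subs)) stop("no substrates with net consumption", call. = FALSE)
  substrate_e <- sum(compound_gamma(subs$compound, registry) * subs$net)
  product_e <- if (nrow(prods)) {
    sum(compound_gamma(prods$compound, registry) * prods$net)
  } else 0
  biomass_e <- biomass_unit()$gamma * (biomass_mM %||% 0)
  h2_e <- 2 * h2_mM
  pct <- 100 * (product_e + biomass_e + h2_e) / substrate_e
  structure(pct, terms = c(substrate_e = substrate_e, product_e = product_e,
                           biomass_e = biomass_e, h2_e = h2_e))
}

#' H2 required to close the electron balance
#'
#' Diagnostic companion to [estimate_h2()]: the H2 that would make the
#' electron recovery reach `target_pct`.  Useful where the closure
#' convention is under-determined (the d-glucose IBE culture).
#'
#' @inheritParams electron_recovery
#' @param target_pct electron recovery to close to (default 100).
#' @return H2 in mM (can be negative if products already exceed the
#'   target).
#' @export
required_h2 <- function(net, biomass_mM = attr(net, "biomass_mM"),
                        target_pct = 100, registry = attr(net, "registry")) {
  base <- electron_recovery(net, biomass_mM, h2_mM = 0, registry = registry)
  terms <- attr(base, "terms")
  (target_pct / 100 * terms[["substrate_e"]] -
     terms[["product_e"]] - terms[["biomass_e"]]) / 2
}

# Integer display of recovery percentages: truncated toward zero, a
# conservative convention that never overstates how much of the balance
# closed (95.1 -> 95, 96.2 -> 96, 88.7 -> 88).
report_percent <- function(x) trunc(x + 1e-9)

#' Full balance report for a culture
#'
#' Assembles net changes, yields, CO2 and H2 estimates, carbon and electron
#' recovery with all intermediate terms, and the cofactor ledger.
#'
#' @param dataset a `fermentation_dataset`.
#' @param pathway a `pathway`, shipped pathway id, or `NULL` to take the
#'   dataset's `pathway_id` attribute (set on the packaged fixtures).
#'   Without a pathway the H2 closure is skipped (H2 = 0).
#' @param end_time passed to [net_changes()].
#' @return A `balance_report` list.
#' @export
balance_report <- function(dataset, pathway = NULL, end_time = NULL) {
  if (is.null(pathway)) pathway <- attr(dataset, "pathway_id")
  net <- net_changes(dataset, end_time = end_time)
  biomass_mM <- attr(net, "biomass_mM")
  co2 <- estimate_co2(net)
  h2 <- if (!is.null(pathway)) estimate_h2(net, pathway) else 0
  ledger <- attr(h2, "ledger")
  crec <- carbon_recovery(net, co2_mM = co2)
  erec <- electron_recovery(net, h2_mM = as.numeric(h2))
  erec0 <- electron_recovery(net, h2_mM = 0)
  yt <- yields(net)
  structure(list(
    culture_id = attr(net, "culture_id"),
    net = net,
    yields = yt,
    biomass_mM = biomass_mM,
    co2_mM = co2,
    h2_mM = as.numeric(h2),
    h2_required_for_100 = required_h2(net),
    carbon_recovery = as.numeric(crec),
    carbon_terms = attr(crec, "terms"),
    electron_recovery = as.numeric(erec),
    electron_recovery_no_h2 = as.numeric(erec0),
    electron_terms = attr(erec, "terms"),
    carbon_recovery_pct = report_percent(as.numeric(crec)),
    electron_recovery_pct = report_percent(as.numeric(erec)),
    ledger = ledger),
    class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance report> culture ", x$culture_id, "\n", sep = "")
  n <- x$net
  for (role in c("substrate", "product")) {
    rows <- n[n$role == role, , drop = FALSE]
    if (!nrow(rows)) next
    cat("  ", role, "s (net mM): ",
        paste(sprintf("%s %.1f", rows$compound, rows$net), collapse = ", "),
        "\n", sep = "")
  }
  cat(sprintf("  biomass %.1f mM (5-C units); CO2 est. %.1f mM; H2 est. %.1f mM\n",
              x$biomass_mM, x$co2_mM, x$h2_mM))
  cat(sprintf("  carbon recovery   %d%% (%.2f%%)\n",
              x$carbon_recovery_pct, x$carbon_recovery))
  cat(sprintf("  electron recovery %d%% (%.2f%%; %.2f%% without H2; H2 for 100%%: %.1f mM)\n",
              x$electron_recovery_pct, x$electron_recovery,
              x$electron_recovery_no_h2, x$h2_required_for_100))
  invisible(x)
}
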