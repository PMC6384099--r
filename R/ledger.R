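# Cofactor ledger over a resolved pathway: NADH and reduced-ferredoxin
# budget, branch fermentation equations, and ATP yield per mole of sugar.

#' NADH / ferredoxin / ATP ledger for a culture
#'
#' Resolves pathway fluxes from the measured net changes (see
#' [solve_fluxes()]) and totals the cofactor turnover.  Two conventions are
#' exposed:
#' \describe{
#'   \item{`"observed"`}{triose and pyruvate fluxes are demand-driven from
#'     the measured products (pyruvate oxidized = acetate + 2 x butyrate
#'     etc.).  This is the convention used for the H2 redox closure.}
#'   \item{`"discussion"`}{the glycolytic and pyruvate-oxidation fluxes are
#'     set to the full sugar consumption (every mole of rhamnose assumed to
#'     deliver its DHAP to pyruvate), the approximation used when quoting
#'     the total NADH made available by sugar catabolism.}
#' }
#' NADH available assumes complete transhydrogenation of reduced ferredoxin
#' to NAD: `nadh_available = nadh_glycolytic + fd_red_produced`.
#'
#' @param net a `net_change_table`.
#' @param pathway a `pathway` or shipped pathway id.
#' @param mode ledger convention, see Details.
#' @return A `pathway_ledger`: list with the per-reaction `fluxes` table,
#'   per-branch totals (`branches`), and the scalar summary terms (all mM):
#'   `nadh_glycolytic`, `fd_red_produced`, `nadh_available`,
#'   `nadh_other_produced`, `nadh_produced`, `nadh_consumed`,
#'   `nadh_deficit`, `atp_produced`, `atp_consumed`, `branch_inputs`.
#' @export
nadh_ledger <- function(net, pathway, mode = c("observed", "discussion")) {
  mode <- match.arg(mode)
  pathway <- as_pathway(pathway)
  fx <- solve_fluxes(pathway, net)
  if (mode == "discussion") {
    sugar_mM <- sum(vapply(pathway$sugars, function(s) {
      net_amount(net, s, role = "substrate")
    }, numeric(1)))
    for (nm in c("emp_dhap", "emp_glucose", "pfor")) {
      i <- match(nm, fx$reaction)
      if (is.na(i)) next
      r <- pathway$reactions[[nm]]
      f <- if (nm == "emp_glucose") sugar_mM / r$produces[["pyruvate"]] else sugar_mM
      fx$flux[i] <- f
      fx$nadh[i] <- f * r$nadh
      fx$fdred[i] <- f * r$fdred
      fx$atp[i] <- f * r$atp
      fx$co2[i] <- f * r$co2
    }
  }
  branch_inputs <- c(
    lactaldehyde = if ("rha_uptake_aldolase" %in% fx$reaction)
      fx$flux[fx$reaction == "rha_uptake_aldolase"] else 0,
    dhap = sum(fx$flux[fx$reaction %in% c("emp_dhap")]))
  branches <- do.call(rbind, lapply(split(fx, fx$branch), function(b) {
    data.frame(branch = b$branch[1L],
               nadh_produced = sum(pmax(b$nadh, 0)),
               nadh_consumed = -sum(pmin(b$nadh, 0)),
               fd_red = sum(b$fdred),
               atp_produced = sum(pmax(b$atp, 0)),
               atp_consumed = -sum(pmin(b$atp, 0)),
               stringsAsFactors = FALSE)
  }))
  rownames(branches) <- NULL
  glyc <- sum(fx$nadh[fx$glycolytic & fx$nadh > 0])
  other <- sum(fx$nadh[!fx$glycolytic & fx$nadh > 0])
  consumed <- -sum(fx$nadh[fx$nadh < 0])
  structure(list(
    pathway_id = pathway$id, mode = mode, fluxes = fx, branches = branches,
    branch_inputs = branch_inputs,
    nadh_glycolytic = glyc,
    fd_red_produced = sum(fx$fdred),
    nadh_available = glyc + sum(fx$fdred),
    nadh_other_produced = other,
    nadh_produced = glyc + other,
    nadh_consumed = consumed,
    nadh_deficit = consumed - (glyc + other),
    atp_produced = sum(pmax(fx$atp, 0)),
    atp_consumed = -sum(pmin(fx$atp, 0)),
    sugar_demand = attr(fx, "sugar_demand")),
    class = "pathway_ledger")
}

#' @export
print.pathway_ledger <- function(x, ...) {
  cat("<pathway ledger> ", x$pathway_id, " (", x$mode, " convention)\n",
      sep = "")
  cat(sprintf("  NADH: glycolytic %.1f + Fd_red %.1f = %.1f mM available",
              x$nadh_glycolytic, x$fd_red_produced, x$nadh_available),
      "(full Fd->NAD transfer)\n")
  cat(sprintf("  NADH produced %.1f / consumed %.1f mM (deficit %.1f)\n",
              x$nadh_produced, x$nadh_consumed, x$nadh_deficit))
  cat(sprintf("  ATP produced %.1f / consumed %.1f mM\n",
              x$atp_produced, x$atp_consumed))
  cat(sprintf("  branch inputs: lactaldehyde %.1f mM, DHAP %.1f mM\n",
              x$branch_inputs[["lactaldehyde"]], x$branch_inputs[["dhap"]]))
  invisible(x)
}

#' Normalized branch fermentation equations
#'
#' Expresses the products of each half of rhamnose catabolism per mole of
#' branch input.  The basis is the sugar consumed minus the biomass drain
#' (mM of 5-C units subtracted mole-for-mole): from 46.4 mM rhamnose and
#' 2.1 mM biomass, 44.3 mM of lactaldehyde and of DHAP are available, and
#' each product coefficient is its net amount over that basis.
#'
#' @param net a `net_change_table` from a rhamnose-consuming culture.
#' @param biomass_mM biomass drain in mM of 5-C units; defaults to the
#'   table's `biomass_mM` attribute.
#' @return A `branch_equations` object: list with `basis_mM` and the two
#'   coefficient vectors `lactaldehyde` (1,2-propanediol, propanol,
#'   propionate) and `dhap` (acetate, butyrate).
#' @export
branch_equations <- function(net, biomass_mM = attr(net, "biomass_mM")) {
  stopifnot(inherits(net, "net_change_table"))
  rha <- net_amount(net, "rhamnose", role = "substrate")
  if (rha <= 0) {
    stop("branch equations need a culture that consumed rhamnose",
         call. = FALSE)
  }
  basis <- rha - (biomass_mM %||% 0)
  if (basis <= 0) stop("non-positive branch basis", call. = FALSE)
  coefs <- function(compounds) {
    v <- vapply(compounds, function(p) net_amount(net, p, "product"),
                numeric(1)) / basis
    v[v > 0]
  }
  structure(list(basis_mM = basis,
                 lactaldehyde = coefs(c("propanediol", "propanol",
                                        "propionate")),
                 dhap = coefs(c("acetate", "butyrate"))),
            class = "branch_equations")
}

#' @export
print.branch_equations <- function(x, ...) {
  eq <- function(basis, v) {
    cat("  1 ", basis, " -> ",
        paste(sprintf("%.2f %s", v, names(v)), collapse = " + "),
        "\n", sep = "")
  }
  cat("<branch equations> basis ", format(x$basis_mM), " mM\n", sep = "")
  eq("lactaldehyde", x$lactaldehyde)
  eq("DHAP", x$dhap)
  invisible(x)
}

#' Net ATP yield per mole of sugar
#'
#' Substrate-level phosphorylation is the only ATP source: the ledger
#' charges the pathway's uptake/priming cost per mol sugar, credits the
#' glycolytic phosphorylations of the sugar's triose flux assuming complete
#' 1 sugar -> 1 DHAP conversion (+2/mol), and credits +1 per mole of acid
#' (acetate, butyrate, propionate) formed per mole of basis -- the
#' biomass-corrected basis of [branch_equations()].  For rhamnose this is
#' -1 (uptake) - 1 (rhamnulokinase) + 2 + 0.43 + 0.26 + 0.18 = 0.87; for
#' glucose, +2 plus the small butyrate-kinase term, about 2.
#'
#' @param net a `net_change_table`.
#' @param pathway a `pathway` or shipped pathway id.
#' @param biomass_mM biomass drain (mM of 5-C units) used for the basis;
#'   defaults to the table's attribute.
#' @return mol ATP per mol sugar (numeric scalar).
#' @export
atp_yield <- function(net, pathway, biomass_mM = attr(net, "biomass_mM")) {
  pathway <- as_pathway(pathway)
  sugar_mM <- sum(vapply(pathway$sugars, function(s) {
    net_amount(net, s, role = "substrate")
  }, numeric(1)))
  if (sugar_mM <= 0) stop("no sugar consumed", call. = FALSE)
  basis <- sugar_mM - (biomass_mM %||% 0)
  if (basis <= 0) stop("non-positive sugar basis", call. = FALSE)
  acids <- sum(vapply(pathway$acid_products, function(p) {
    net_amount(net, p, role = "product")
  }, numeric(1)))
  -pathway$atp_uptake_cost + pathway$atp_slp_per_sugar + acids / basis
}
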