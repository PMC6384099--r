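# Declarative pathway definitions and a demand-driven flux solver.
#
# A pathway is a small reaction network (a DAG from sugars through
# intermediates to the measured end products) in which each reaction
# carries cofactor coefficients per unit flux: NADH (positive = produced),
# reduced ferredoxin, and ATP.  Fluxes are resolved by back-propagating the
# measured net product amounts through the network ("pull" semantics):
# intermediates are at steady state, so the producer of each intermediate
# runs at exactly the rate its consumers plus any measured accumulation
# demand.  Secondary producers can be pinned to a measured consumption
# (acetate reassimilated via CoA transferase) or capped by upstream supply
# (DHAP from the rhamnulose-phosphate aldolase in mixed-sugar cultures);
# the single balancing producer takes the remainder.

# Carbon counts for pathway intermediates not present in the compound
# registry (CoA thioesters are counted as their acyl moiety).
.INTERMEDIATE_CARBON <- c(
  lactaldehyde = 3, dhap = 3, pyruvate = 3, acetyl_coa = 2,
  butyryl_coa = 4, propionyl_coa = 3, propionaldehyde = 3
)

#' Define a pathway reaction
#'
#' @param name reaction identifier.
#' @param consumes,produces named numeric vectors of stoichiometric
#'   coefficients per unit flux (compound registry names or pathway
#'   intermediates).
#' @param nadh,fdred,atp signed cofactor coefficients per unit flux
#'   (positive = produced).
#' @param co2 mol CO2 released per unit flux (used only for the carbon
#'   closure check; CO2 accounting in balances uses the registry rule).
#' @param branch branch tag: `"lactaldehyde"`, `"dhap"` or `"common"`.
#' @param kind `"balancing"` (flux set by demand for its driver product),
#'   `"pinned_substrate"` (flux equals the measured net consumption of
#'   `pin`), or `"capped_supply"` (flux covers remaining demand up to the
#'   available supply of its input).
#' @param pin compound whose measured consumption pins the flux
#'   (for `kind = "pinned_substrate"`).
#' @param driver species whose demand sets a balancing reaction's flux;
#'   defaults to the first produced species.  A reaction with several
#'   products (the aldolase) is resolved once, at its driver.
#' @param glycolytic logical: does the reaction's NADH production count as
#'   glycolytic (GAPDH-type) in ledger summaries?
#' @return A `pathway_reaction` list.
#' @export
reaction <- function(name, consumes, produces, nadh = 0, fdred = 0, atp = 0,
                     co2 = 0, branch = "common",
                     kind = c("balancing", "pinned_substrate", "capped_supply"),
                     pin = NULL, driver = NULL, glycolytic = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(consumes), !is.null(names(consumes)),
            is.numeric(produces), !is.null(names(produces)))
  structure(list(name = name, consumes = consumes, produces = produces,
                 nadh = nadh, fdred = fdred, atp = atp, co2 = co2,
                 branch = branch, kind = kind, pin = pin,
                 driver = driver %||% names(produces)[1L],
                 glycolytic = glycolytic),
            class = "pathway_reaction")
}

species_carbon <- function(sp, registry) {
  if (sp %in% names(.INTERMEDIATE_CARBON)) {
    .INTERMEDIATE_CARBON[[sp]]
  } else {
    unname(compound_carbon(sp, registry))
  }
}

#' Assemble a pathway
#'
#' Checks every reaction for carbon balance (consumed C = produced C +
#' declared CO2) and stores the species resolution order used by the
#' flux solver (terminal products first, sugars last).
#'
#' @param id pathway identifier.
#' @param reactions list of [reaction()] objects.
#' @param species_order character vector: reverse-topological species order.
#' @param sugars sugar substrate(s) of the pathway.
#' @param atp_uptake_cost ATP spent on sugar uptake and priming kinases per
#'   mol sugar (2 for l-rhamnose: MFS uptake 1 + rhamnulokinase 1; 0 for
#'   d-glucose, whose net +2 is already encoded in the EMP reaction).
#' @param atp_slp_per_sugar substrate-level phosphorylation per mol sugar on
#'   complete conversion of the sugar's triose flux (2 for both pathways).
#' @param acid_products products whose kinases yield +1 ATP/mol.
#' @param registry a `compound_registry`.
#' @return A `pathway` object.
#' @export
pathway <- function(id, reactions, species_order, sugars,
                    atp_uptake_cost, atp_slp_per_sugar,
                    acid_products, registry = default_registry()) {
  names(reactions) <- vapply(reactions, `[[`, character(1), "name")
  for (r in reactions) {
    c_in <- sum(vapply(names(r$consumes),
                       function(s) species_carbon(s, registry) * r$consumes[[s]],
                       numeric(1)))
    c_out <- sum(vapply(names(r$produces),
                        function(s) species_carbon(s, registry) * r$produces[[s]],
                        numeric(1))) + r$co2
    if (abs(c_in - c_out) > 1e-9) {
      stop("reaction ", sQuote(r$name), " is not carbon balanced (",
           c_in, " C in vs ", c_out, " C out)", call. = FALSE)
    }
  }
  structure(list(id = id, reactions = reactions,
                 species_order = species_order, sugars = sugars,
                 atp_uptake_cost = atp_uptake_cost,
                 atp_slp_per_sugar = atp_slp_per_sugar,
                 acid_products = acid_products),
            class = "pathway")
}

# ---- shipped pathway definitions -------------------------------------------

rhamnose_branch_reactions <- function() {
  list(
    reaction("rha_uptake_aldolase",
             consumes = c(rhamnose = 1),
             produces = c(lactaldehyde = 1, dhap = 1),
             atp = -2, branch = "common"),
    reaction("lactaldehyde_reductase",
             consumes = c(lactaldehyde = 1),
             produces = c(propanediol = 1),
             nadh = -1, branch = "lactaldehyde"),
    reaction("propanediol_dehydratase",
             consumes = c(propanediol = 1),
             produces = c(propionaldehyde = 1),
             branch = "lactaldehyde"),
    reaction("propanol_dehydrogenase",
             consumes = c(propionaldehyde = 1),
             produces = c(propanol = 1),
             nadh = -1, branch = "lactaldehyde"),
    reaction("propionaldehyde_dehydrogenase",
             consumes = c(propionaldehyde = 1),
             produces = c(propionyl_coa = 1),
             nadh = 1, branch = "lactaldehyde"),
    reaction("propionate_kinase",
             consumes = c(propionyl_coa = 1),
             produces = c(propionate = 1),
             atp = 1, branch = "lactaldehyde")
  )
}

acetyl_coa_reactions <- function() {
  list(
    reaction("pfor",
             consumes = c(pyruvate = 1),
             produces = c(acetyl_coa = 1),
             fdred = 1, co2 = 1, branch = "dhap"),
    reaction("acetate_kinase",
             consumes = c(acetyl_coa = 1),
             produces = c(acetate = 1),
             atp = 1, branch = "dhap"),
    reaction("c4_reduction",   # thiolase + 3-HB-CoA DH + crotonase + BCD
             consumes = c(acetyl_coa = 2),
             produces = c(butyryl_coa = 1),
             nadh = -2, branch = "dhap"),
    reaction("butyrate_kinase",
             consumes = c(butyryl_coa = 1),
             produces = c(butyrate = 1),
             atp = 1, branch = "dhap")
  )
}

solvent_reactions <- function() {
  list(
    reaction("lactate_dehydrogenase",
             consumes = c(pyruvate = 1),
             produces = c(lactate = 1),
             nadh = -1, branch = "dhap"),
    reaction("acetate_coa_transferase",
             consumes = c(acetate = 1),
             produces = c(acetyl_coa = 1),
             kind = "pinned_substrate", pin = "acetate", branch = "dhap"),
    reaction("ethanol_dehydrogenase",
             consumes = c(acetyl_coa = 1),
             produces = c(ethanol = 1),
             nadh = -2, branch = "dhap"),
    reaction("butanol_dehydrogenase",
             consumes = c(butyryl_coa = 1),
             produces = c(butanol = 1),
             nadh = -2, branch = "dhap"),
    reaction("acetone_synthesis",  # CoAT + acetoacetate decarboxylase
             consumes = c(acetyl_coa = 2),
             produces = c(acetone = 1),
             co2 = 1, branch = "dhap"),
    reaction("isopropanol_dehydrogenase",
             consumes = c(acetone = 1),
             produces = c(isopropanol = 1),
             nadh = -1, branch = "dhap")
  )
}

#' Shipped pathway definitions
#'
#' Three pathways are shipped: `"rhamnose"` (rhamnulose-phosphate route
#' splitting into the lactaldehyde branch -- 1,2-propanediol, propanol,
#' propionate inside the bacterial microcompartment -- and the DHAP/EMP
#' branch to acetate and butyrate), `"glucose"` (EMP glycolysis with the
#' IBE solvent reactions), and `"mixture"` (their union, with DHAP supply
#' capped by the aldolase flux and glucose balancing the remaining pyruvate
#' demand).
#'
#' @param registry a `compound_registry`.
#' @return Named list of `pathway` objects.
#' @export
default_pathways <- function(registry = default_registry()) {
  emp_dhap <- reaction("emp_dhap",
                       consumes = c(dhap = 1),
                       produces = c(pyruvate = 1),
                       nadh = 1, atp = 2, branch = "dhap",
                       glycolytic = TRUE)
  emp_dhap_capped <- reaction("emp_dhap",
                              consumes = c(dhap = 1),
                              produces = c(pyruvate = 1),
                              nadh = 1, atp = 2, branch = "dhap",
                              kind = "capped_supply", glycolytic = TRUE)
  emp_glc <- reaction("emp_glucose",
                      consumes = c(glucose = 1),
                      produces = c(pyruvate = 2),
                      nadh = 2, atp = 2, branch = "common",
                      glycolytic = TRUE)

  rha <- pathway(
    "rhamnose",
    c(rhamnose_branch_reactions(), list(emp_dhap), acetyl_coa_reactions()),
    species_order = c("propanol", "propionate", "propionyl_coa",
                      "propionaldehyde", "propanediol", "lactaldehyde",
                      "acetate", "butyrate", "butyryl_coa", "acetyl_coa",
                      "pyruvate", "dhap", "rhamnose"),
    sugars = "rhamnose", atp_uptake_cost = 2, atp_slp_per_sugar = 2,
    acid_products = c("acetate", "butyrate", "propionate"),
    registry = registry)

  glc <- pathway(
    "glucose",
    c(list(emp_glc), acetyl_coa_reactions(), solvent_reactions()),
    species_order = c("lactate", "ethanol", "butanol", "butyrate",
                      "isopropanol", "acetone", "butyryl_coa", "acetate",
                      "acetyl_coa", "pyruvate", "glucose"),
    sugars = "glucose", atp_uptake_cost = 0, atp_slp_per_sugar = 2,
    acid_products = c("acetate", "butyrate"),
    registry = registry)

  mix <- pathway(
    "mixture",
    c(rhamnose_branch_reactions(), list(emp_dhap_capped, emp_glc),
      acetyl_coa_reactions(), solvent_reactions()),
    species_order = c("propanol", "propionate", "propionyl_coa",
                      "propionaldehyde", "propanediol", "lactaldehyde",
                      "lactate", "ethanol", "butanol", "butyrate",
                      "isopropanol", "acetone", "butyryl_coa", "acetate",
                      "acetyl_coa", "pyruvate", "dhap", "glucose",
                      "rhamnose"),
    sugars = c("glucose", "rhamnose"),
    atp_uptake_cost = 1, atp_slp_per_sugar = 2,
    acid_products = c("acetate", "butyrate", "propionate"),
    registry = registry)

  list(rhamnose = rha, glucose = glc, mixture = mix)
}

#' Look up a shipped pathway, or accept one supplied directly
#' @param x a `pathway` or the id of a shipped one.
#' @return A `pathway`.
#' @export
as_pathway <- function(x) {
  if (inherits(x, "pathway")) return(x)
  pw <- default_pathways()
  if (is.character(x) && length(x) == 1L && x %in% names(pw)) return(pw[[x]])
  stop("unknown pathway: ", deparse(x), call. = FALSE)
}

# ---- flux solver ------------------------------------------------------------

#' Resolve reaction fluxes from measured net changes
#'
#' Demand-driven resolution in the pathway's stored species order: each
#' species' demand is its measured net accumulation plus the consumption by
#' already-resolved downstream reactions; pinned producers contribute their
#' fixed flux, capped producers cover remaining demand up to their input
#' supply, and the balancing producer takes the rest.  Sugar endpoints
#' accumulate an implied catabolic demand (which can fall short of the
#' measured consumption -- the gap is the carbon not recovered in measured
#' products or biomass).
#'
#' @param pathway a `pathway`.
#' @param net a `net_change_table`.
#' @return A data.frame of per-reaction fluxes (mM) with cofactor totals
#'   per reaction, plus attribute `sugar_demand` (implied sugar
#'   consumption, mM).
#' @export
solve_fluxes <- function(pathway, net) {
  pathway <- as_pathway(pathway)
  rxns <- pathway$reactions
  flux <- stats::setNames(numeric(length(rxns)), names(rxns))
  resolved <- stats::setNames(logical(length(rxns)), names(rxns))
  avail <- stats::setNames(numeric(0), character(0))
  add_avail <- function(sp, x) {
    avail[sp] <<- (if (sp %in% names(avail)) avail[[sp]] else 0) + x
  }
  get_avail <- function(sp) if (sp %in% names(avail)) avail[[sp]] else 0
  settle <- function(r, f) {
    flux[r$name] <<- f
    resolved[r$name] <<- TRUE
    for (sp in names(r$produces)) add_avail(sp, f * r$produces[[sp]])
    for (sp in names(r$consumes)) add_avail(sp, -f * r$consumes[[sp]])
  }

  prod_of <- function(sp) Filter(function(r) sp %in% names(r$produces), rxns)
  cons_of <- function(sp) Filter(function(r) sp %in% names(r$consumes), rxns)

  measured_prod <- function(sp) net_amount(net, sp, role = "product")
  measured_cons <- function(sp) net_amount(net, sp, role = "substrate")

  # pinned reactions run at the measured consumption of their pin compound,
  # drawn from the medium pool (they create no internal demand)
  for (nm in names(rxns)) {
    r <- rxns[[nm]]
    if (r$kind == "pinned_substrate") settle(r, measured_cons(r$pin))
  }

  sugar_demand <- stats::setNames(numeric(length(pathway$sugars)),
                                  pathway$sugars)
  for (sp in pathway$species_order) {
    downstream <- sum(vapply(cons_of(sp), function(r) {
      if (r$kind == "pinned_substrate") 0 else flux[[r$name]] * r$consumes[[sp]]
    }, numeric(1)))
    demand <- max(0, measured_prod(sp)) + downstream
    if (sp %in% pathway$sugars) {
      sugar_demand[[sp]] <- demand
      next
    }
    producers <- prod_of(sp)
    if (!length(producers)) next
    supplied <- sum(vapply(producers, function(r) {
      if (resolved[[r$name]]) flux[[r$name]] * r$produces[[sp]] else 0
    }, numeric(1)))
    remaining <- demand - supplied
    for (r in Filter(function(r) r$kind == "capped_supply" &&
                       !resolved[[r$name]], producers)) {
      inp <- names(r$consumes)[1L]
      f <- min(get_avail(inp) / r$consumes[[inp]],
               max(0, remaining) / r$produces[[sp]])
      settle(r, f)
      remaining <- remaining - f * r$produces[[sp]]
    }
    balancing <- Filter(function(r) r$kind == "balancing" &&
                          !resolved[[r$name]] && identical(r$driver, sp),
                        producers)
    if (length(balancing) > 1L) {
      stop("species ", sQuote(sp), " has multiple balancing producers",
           call. = FALSE)
    }
    if (length(balancing)) {
      settle(balancing[[1L]], max(0, remaining) / balancing[[1L]]$produces[[sp]])
    }
  }

  out <- data.frame(
    reaction = names(rxns),
    branch = vapply(rxns, `[[`, character(1), "branch"),
    flux = unname(flux),
    nadh = unname(flux * vapply(rxns, `[[`, numeric(1), "nadh")),
    fdred = unname(flux * vapply(rxns, `[[`, numeric(1), "fdred")),
    atp = unname(flux * vapply(rxns, `[[`, numeric(1), "atp")),
    co2 = unname(flux * vapply(rxns, `[[`, numeric(1), "co2")),
    glycolytic = vapply(rxns, `[[`, logical(1), "glycolytic"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sugar_demand") <- sugar_demand
  out
}
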