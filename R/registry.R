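# Compound registry: each measurable species with its elemental formula,
# CO2 class and role hint.  The CO2 class encodes the accounting rule that
# producing 1 mol of acetate or ethanol, butyrate or butanol, and acetone or
# isopropanol releases 1, 2 and 3 mol CO2 respectively; everything else
# (including 1,2-propanediol, propanol, propionate and lactate) releases
# none.  Acids are registered as the undissociated species -- only then do
# the conventional printed degrees of reduction (acetate 8, butyrate 20,
# propionate 14, lactate 12) follow from gamma = 4C + H - 2O - 3N.

.DEFAULT_COMPOUNDS <- list(
  #        name          display             formula         co2 sugar role
  list("glucose",      "d-Glucose",        "C6H12O6",        0L, TRUE,  "substrate"),
  list("rhamnose",     "l-Rhamnose",       "C6H12O5",        0L, TRUE,  "substrate"),
  list("xylose",       "d-Xylose",         "C5H10O5",        0L, TRUE,  "substrate"),
  list("acetate",      "Acetate",          "C2H4O2",         1L, FALSE, "either"),
  list("ethanol",      "Ethanol",          "C2H6O1",         1L, FALSE, "product"),
  list("butyrate",     "Butyrate",         "C4H8O2",         2L, FALSE, "either"),
  list("butanol",      "Butanol",          "C4H10O1",        2L, FALSE, "product"),
  list("acetone",      "Acetone",          "C3H6O1",         3L, FALSE, "product"),
  list("isopropanol",  "Isopropanol",      "C3H8O1",         3L, FALSE, "product"),
  list("lactate",      "Lactate",          "C3H6O3",         0L, FALSE, "product"),
  list("propanediol",  "1,2-Propanediol",  "C3H8O2",         0L, FALSE, "product"),
  list("propanol",     "Propanol",         "C3H8O1",         0L, FALSE, "product"),
  list("propionate",   "Propionate",       "C3H6O2",         0L, FALSE, "product"),
  list("hydrogen",     "H2",               "H2",             0L, FALSE, "product"),
  list("co2",          "CO2",              "C1O2",           0L, FALSE, "product"),
  list("water",        "H2O",              "H2O1",           0L, FALSE, "either"),
  list("ammonia",      "NH3",              "H3N1",           0L, FALSE, "substrate"),
  list("biomass",      "Biomass (5-C unit)", "C5H9O2.5N1",   0L, FALSE, "product")
)

# Compounds whose CO2 class is fixed by the accounting rule; user registries
# may extend the table but not reassign these.
.CO2_RULE <- c(acetate = 1L, ethanol = 1L, butyrate = 2L, butanol = 2L,
               acetone = 3L, isopropanol = 3L)

#' Default compound registry
#'
#' The registry ships every species measured in the reference cultures plus
#' the bookkeeping species (H2, CO2, H2O, NH3) and the 5-carbon biomass
#' formula unit.  Each row carries the elemental formula (from which the
#' degree of reduction and carbon count derive), the CO2 class, whether the
#' compound counts as a sugar for "per mol of sugar" yield bases, and a role
#' hint.
#'
#' @return A `data.frame` of class `compound_registry` with columns `name`,
#'   `display`, `formula`, `co2_class`, `sugar`, `role_hint`, `gamma`,
#'   `carbon`.
#' @export
default_registry <- function() {
  rows <- do.call(rbind, lapply(.DEFAULT_COMPOUNDS, function(x) {
    data.frame(name = x[[1]], display = x[[2]], formula = x[[3]],
               co2_class = x[[4]], sugar = x[[5]], role_hint = x[[6]],
               stringsAsFactors = FALSE)
  }))
  as_compound_registry(rows)
}

as_compound_registry <- function(df) {
  required <- c("name", "formula", "co2_class")
  if (!all(required %in% names(df))) {
    stop("registry must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("registry has duplicated compound names", call. = FALSE)
  }
  if (is.null(df$display)) df$display <- df$name
  if (is.null(df$sugar)) df$sugar <- FALSE
  if (is.null(df$role_hint)) df$role_hint <- "either"
  df$co2_class <- as.integer(df$co2_class)
  if (any(is.na(df$co2_class)) || any(!df$co2_class %in% 0:3)) {
    stop("co2_class must be 0, 1, 2 or 3", call. = FALSE)
  }
  fixed <- intersect(df$name, names(.CO2_RULE))
  bad <- fixed[df$co2_class[match(fixed, df$name)] != .CO2_RULE[fixed]]
  if (length(bad)) {
    stop("co2_class inconsistent with the accounting rule for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  forms <- lapply(df$formula, parse_formula)     # validates every formula
  df$gamma <- vapply(forms, degree_of_reduction, numeric(1))
  df$carbon <- vapply(forms, carbon_count, numeric(1))
  if (any(df$gamma < 0)) {
    stop("registry entries must have non-negative degree of reduction",
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("compound_registry", "data.frame")
  df
}

#' Read a compound registry from a YAML config
#'
#' The config maps compound names to a formula string and optional fields
#' `co2_class`, `display`, `sugar`, `role_hint`, e.g.
#' \preformatted{
#' glycerol:
#'   formula: C3H8O3
#'   co2_class: 0
#' }
#' Entries extend (or, except for the CO2-rule compounds, override) the
#' defaults.  A compound without a formula is rejected.
#'
#' @param path YAML file path.
#' @param base registry to extend; defaults to [default_registry()].
#' @return A `compound_registry`.
#' @export
read_registry <- function(path, base = default_registry()) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg)) return(base)
  rows <- lapply(names(cfg), function(nm) {
    entry <- cfg[[nm]]
    if (is.character(entry) && length(entry) == 1L) entry <- list(formula = entry)
    if (is.null(entry$formula)) {
      stop("registry entry ", sQuote(nm), " has no formula", call. = FALSE)
    }
    data.frame(name = nm, display = entry$display %||% nm,
               formula = entry$formula,
               co2_class = as.integer(entry$co2_class %||% 0L),
               sugar = isTRUE(entry$sugar),
               role_hint = entry$role_hint %||% "either",
               stringsAsFactors = FALSE)
  })
  extra <- do.call(rbind, rows)
  keep <- base[!base$name %in% extra$name,
               c("name", "display", "formula", "co2_class", "sugar", "role_hint")]
  as_compound_registry(rbind(keep, extra))
}

registry_lookup <- function(registry, names, field) {
  idx <- match(names, registry$name)
  if (anyNA(idx)) {
    stop("compound(s) not in registry: ",
         paste(unique(names[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(registry[[field]][idx], names)
}

#' Degree of reduction for registered compounds
#'
#' @param names character vector of compound names.
#' @param registry a `compound_registry`.
#' @return Named numeric vector of electrons/mol.
#' @export
compound_gamma <- function(names, registry = default_registry()) {
  registry_lookup(registry, names, "gamma")
}

#' Carbon counts for registered compounds
#'
#' @inheritParams compound_gamma
#' @return Named numeric vector of C-mol/mol.
#' @export
compound_carbon <- function(names, registry = default_registry()) {
  registry_lookup(registry, names, "carbon")
}

#' CO2 released per mole of product formed
#'
#' Implements the accounting rule: 1 mol CO2 per mol acetate or ethanol,
#' 2 per mol butyrate or butanol, 3 per mol acetone or isopropanol, 0 for
#' every other compound.
#'
#' @inheritParams compound_gamma
#' @return Named integer vector, mol CO2 per mol.
#' @export
co2_per_mole <- function(names, registry = default_registry()) {
  registry_lookup(registry, names, "co2_class")
}

#' The biomass formula unit
#'
#' Biomass is accounted as a 5-carbon formula unit C5H9O2.5N, i.e. five
#' monomers of the standard elemental cell composition CH1.8O0.5N0.2.  The
#' unit size is chosen so that one "mole" of biomass carries 21 electrons
#' (5 x 4.2 electrons per C-mol), the per-mole degree of reduction used in
#' electron-recovery accounting.
#'
#' @return A list with `formula`, `molar_mass` (g/mol), `gamma`
#'   (electrons/mol, 21) and `carbon` (C-mol/mol, 5).
#' @export
biomass_unit <- function() {
  f <- parse_formula("C5H9O2.5N1")
  unit <- list(formula = f, molar_mass = molar_mass(f),
               gamma = degree_of_reduction(f), carbon = carbon_count(f))
  stopifnot(unit$gamma == 21, unit$carbon == 5)
  unit
}

`%||%` <- function(a, b) if (is.null(a)) b else a
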