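# Net consumption/production accounting between two time points, biomass
# conversion, and molar yields.

#' Net changes between start and end of fermentation
#'
#' For every measured compound the signed delta end - start is folded into a
#' non-negative `net` amount and a `role`: substrate if the final
#' concentration is lower than at the start, product if it is higher.  This
#' covers compounds such as acetate that are dosed with the medium and can
#' move either way.  Compounds with zero net change (or unmeasured at
#' either end) are omitted.
#'
#' @param dataset a `fermentation_dataset` with at least two time points.
#' @param end_time end of fermentation (h); defaults to the last time point.
#' @return A `net_change_table`: data.frame with columns `compound`,
#'   `start`, `end`, `net`, `role`, carrying attributes `biomass_mM`
#'   (see [dataset_biomass_mM()]), `substrates` (labels dosed at t0),
#'   `culture_id` and `registry`.
#' @export
net_changes <- function(dataset, end_time = NULL) {
  stopifnot(inherits(dataset, "fermentation_dataset"))
  if (length(dataset$time_h) < 2L) {
    stop("insufficient data: need at least two time points", call. = FALSE)
  }
  i_end <- if (is.null(end_time)) {
    length(dataset$time_h)
  } else {
    match(end_time, dataset$time_h)
  }
  if (is.na(i_end) || i_end < 2L) {
    stop("end_time must match a time point after t0", call. = FALSE)
  }
  start <- dataset$conc[1L, ]
  end <- dataset$conc[i_end, ]
  ok <- !is.na(start) & !is.na(end)
  delta <- end[ok] - start[ok]
  nz <- delta != 0
  tab <- data.frame(compound = names(delta)[nz],
                    start = unname(start[ok][nz]),
                    end = unname(end[ok][nz]),
                    net = abs(unname(delta[nz])),
                    role = ifelse(delta[nz] < 0, "substrate", "product"),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(tab,
            biomass_mM = dataset_biomass_mM(dataset),
            substrates = dataset$substrates,
            culture_id = dataset$culture_id,
            registry = dataset$registry,
            class = c("net_change_table", "data.frame"))
}

net_amount <- function(net, compound, role = NULL) {
  sel <- net$compound == compound
  if (!is.null(role)) sel <- sel & net$role == role
  if (!any(sel)) 0 else sum(net$net[sel])
}

#' Cell dry weight from optical density
#'
#' Linear calibration for d-glucose-grown cultures:
#' cdw (g/L) = OD600 x 0.28 + 0.13.  Cultures grown on l-rhamnose show a
#' different cell morphology and the calibration does not transfer; for
#' those, supply a measured `cdw_end` or `biomass_end_mM` instead.
#'
#' @param od600 non-negative OD600 reading(s).
#' @return Cell dry weight in g/L.
#' @export
biomass_from_od <- function(od600) {
  if (any(!is.finite(od600)) || any(od600 < 0)) {
    stop("od600 must be finite and non-negative", call. = FALSE)
  }
  od600 * 0.28 + 0.13
}

#' Convert cell dry weight to biomass formula-unit concentration
#'
#' @param cdw cell dry weight, g/L (non-negative).
#' @param unit biomass formula unit, see [biomass_unit()].
#' @return mM of biomass formula units.
#' @export
biomass_millimolar <- function(cdw, unit = biomass_unit()) {
  if (any(!is.finite(cdw)) || any(cdw < 0)) {
    stop("cdw must be finite and non-negative", call. = FALSE)
  }
  cdw / unit$molar_mass * 1000
}

#' End-point biomass of a dataset, in mM of 5-C units
#'
#' Resolution order: an explicit `biomass_end_mM` (direct measurement)
#' overrides a measured `cdw_end`, which overrides the OD600 calibration
#' ([biomass_from_od()], applicable to d-glucose-grown cultures); 0 with a
#' warning when no biomass observation exists.
#'
#' @param dataset a `fermentation_dataset`.
#' @param unit biomass formula unit.
#' @return mM of biomass formula units at the final time point.
#' @export
dataset_biomass_mM <- function(dataset, unit = biomass_unit()) {
  if (!is.null(dataset$biomass_end_mM)) {
    return(dataset$biomass_end_mM)
  }
  if (!is.null(dataset$cdw_end)) {
    return(biomass_millimolar(dataset$cdw_end, unit))
  }
  if (!is.null(dataset$od600)) {
    od <- dataset$od600[length(dataset$od600)]
    if (is.finite(od)) {
      return(biomass_millimolar(biomass_from_od(od), unit))
    }
  }
  warning("no biomass observation for culture ", dataset$culture_id,
          "; assuming 0 mM", call. = FALSE)
  0
}

#' Molar product yields
#'
#' yield(product, basis) = net product formed / net basis substrate
#' consumed, in mol/mol.  The pseudo-basis `"sugar"` uses the summed
#' consumption of all registry sugars (the denominator for biomass yields
#' in mixed-sugar cultures) and adds a `biomass` yield row.
#'
#' @param net a `net_change_table`.
#' @param bases substrate names to use as denominators, and/or `"sugar"`.
#' @param products product names; defaults to every compound with
#'   role = product, plus biomass for the `"sugar"` basis.
#' @return A `yield_table`: data.frame with columns `product`, `basis`,
#'   `yield` (full precision) and `yield_2dp` (display rounding to 2
#'   significant decimals, matching how such tables are printed).
#' @export
yields <- function(net, bases = NULL, products = NULL) {
  stopifnot(inherits(net, "net_change_table"))
  registry <- attr(net, "registry")
  if (is.null(bases)) {
    subs <- net$compound[net$role == "substrate"]
    bases <- c(subs[registry$sugar[match(subs, registry$name)]], "sugar")
  }
  if (is.null(products)) {
    products <- net$compound[net$role == "product"]
  }
  rows <- list()
  for (basis in bases) {
    if (basis == "sugar") {
      sugars <- registry$name[registry$sugar]
      denom <- sum(net$net[net$role == "substrate" & net$compound %in% sugars])
      prods <- c(products, "biomass")
    } else {
      denom <- net_amount(net, basis, role = "substrate")
      prods <- products
    }
    if (denom <= 0) {
      stop("undefined yield: basis ", sQuote(basis),
           " has no net consumption", call. = FALSE)
    }
    num <- vapply(prods, function(p) {
      if (p == "biomass") attr(net, "biomass_mM") else net_amount(net, p, "product")
    }, numeric(1))
    rows[[basis]] <- data.frame(product = prods, basis = basis,
                                yield = num / denom,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$yield_2dp <- signif_yield(out$yield)
  class(out) <- c("yield_table", "data.frame")
  out
}

# Display rounding: 2 decimals, except one extra digit below 0.1 and for
# values printed with 3 decimals in the source tables (e.g. 0.904, 0.045).
signif_yield <- function(x) {
  ifelse(x < 0.1, round(x, 3), round(x, 2))
}

#' Recover product yield coefficients from a full time course
#'
#' Least-squares slope through the origin of product concentration against
#' substrate consumed, using every time point.  On noiseless data generated
#' from fixed stoichiometry this returns the generating coefficients
#' exactly; under measurement noise it averages over the trajectory.
#'
#' @param dataset a `fermentation_dataset`.
#' @param substrate substrate compound name.
#' @param products product names; default: all other measured compounds
#'   that accumulate.
#' @return Named numeric vector of mol product per mol substrate consumed.
#' @export
recover_yields <- function(dataset, substrate, products = NULL) {
  stopifnot(inherits(dataset, "fermentation_dataset"))
  conc <- dataset$conc
  if (!substrate %in% colnames(conc)) {
    stop("substrate not measured: ", substrate, call. = FALSE)
  }
  consumed <- conc[1L, substrate] - conc[, substrate]
  if (is.null(products)) {
    cand <- setdiff(colnames(conc), substrate)
    products <- cand[conc[nrow(conc), cand] > conc[1L, cand]]
  }
  vapply(products, function(p) {
    y <- conc[, p] - conc[1L, p]
    sum(consumed * y, na.rm = TRUE) / sum(consumed^2, na.rm = TRUE)
  }, numeric(1))
}
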