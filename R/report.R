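# Run configuration, report assembly and serialization: the programmatic
# surface behind the command-line wrapper (inst/scripts/fermbal.R).

#' Run the full balance analysis for one culture
#'
#' @param config a list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{`fixture`}{id of a packaged culture (`"glucose"`,
#'       `"rhamnose"`, `"mixture"`), or}
#'     \item{`dataset`}{path to a delimited time-series table, with
#'       optional `culture_id`, `substrates`, `cdw_end`, `biomass_end_mM`;}
#'     \item{`registry`}{optional YAML registry extension
#'       ([read_registry()]);}
#'     \item{`pathway`}{shipped pathway id; default: the fixture's, else
#'       none (H2 closure skipped);}
#'     \item{`ledger_mode`}{`"observed"` (default) or `"discussion"`
#'       for the additionally reported ledger;}
#'     \item{`out`}{optional output directory: writes `report.json` and
#'       `report.md`.}
#'   }
#' @return A `fermentation_run` list: the `balance_report`, the yield
#'   table, the pathway ledger (both conventions where a pathway is set),
#'   branch equations and ATP yield where applicable, and the paths
#'   written.  Outputs are deterministic for fixed inputs.
#' @export
run_balance <- function(config) {
  config <- load_config(config)
  registry <- if (!is.null(config$registry)) {
    read_registry(config$registry)
  } else {
    default_registry()
  }
  if (!is.null(config$fixture)) {
    dataset <- table1_replay(config$fixture, registry = registry)
  } else if (!is.null(config$dataset)) {
    dataset <- read_dataset(config$dataset,
                            culture_id = config$culture_id,
                            substrates = config$substrates %||% character(),
                            cdw_end = config$cdw_end,
                            biomass_end_mM = config$biomass_end_mM,
                            registry = registry)
  } else {
    stop("config needs a 'fixture' id or a 'dataset' path", call. = FALSE)
  }
  pathway_id <- config$pathway %||% attr(dataset, "pathway_id")
  report <- balance_report(dataset, pathway = pathway_id)
  net <- report$net
  ledger2 <- branch_eq <- atp <- NULL
  if (!is.null(pathway_id)) {
    mode <- config$ledger_mode %||% "discussion"
    ledger2 <- nadh_ledger(net, pathway_id, mode = mode)
    atp <- tryCatch(atp_yield(net, pathway_id), error = function(e) NULL)
  }
  if (net_amount(net, "rhamnose", role = "substrate") > 0) {
    branch_eq <- branch_equations(net)
  }
  run <- structure(list(culture_id = report$culture_id,
                        pathway_id = pathway_id,
                        report = report, yields = report$yields,
                        ledger = report$ledger, ledger_alt = ledger2,
                        branch_equations = branch_eq, atp_yield = atp,
                        paths = character()),
                   class = "fermentation_run")
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    json_path <- file.path(config$out, "report.json")
    md_path <- file.path(config$out, "report.md")
    jsonlite::write_json(run_to_list(run), json_path, auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
    writeLines(run_to_markdown(run), md_path)
    run$paths <- c(json = json_path, md = md_path)
  }
  run
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

run_to_list <- function(run) {
  rep <- run$report
  net <- rep$net
  out <- list(
    culture_id = run$culture_id,
    pathway = run$pathway_id,
    net_changes = as.data.frame(net),
    biomass_mM = rep$biomass_mM,
    co2_mM = rep$co2_mM,
    h2_mM = rep$h2_mM,
    h2_required_for_100 = rep$h2_required_for_100,
    carbon_recovery = rep$carbon_recovery,
    carbon_recovery_pct = rep$carbon_recovery_pct,
    electron_recovery = rep$electron_recovery,
    electron_recovery_no_h2 = rep$electron_recovery_no_h2,
    electron_recovery_pct = rep$electron_recovery_pct,
    yields = as.data.frame(run$yields))
  if (!is.null(run$branch_equations)) {
    be <- run$branch_equations
    out$branch_equations <- list(basis_mM = be$basis_mM,
                                 lactaldehyde = as.list(be$lactaldehyde),
                                 dhap = as.list(be$dhap))
  }
  if (!is.null(run$atp_yield)) out$atp_yield_per_sugar <- run$atp_yield
  led <- run$ledger_alt %||% run$ledger
  if (!is.null(led)) {
    out$ledger <- list(mode = led$mode,
                       nadh_glycolytic = led$nadh_glycolytic,
                       fd_red_produced = led$fd_red_produced,
                       nadh_available = led$nadh_available,
                       nadh_produced = led$nadh_produced,
                       nadh_consumed = led$nadh_consumed,
                       atp_produced = led$atp_produced,
                       atp_consumed = led$atp_consumed,
                       branch_inputs = as.list(led$branch_inputs))
  }
  out
}

run_to_markdown <- function(run) {
  rep <- run$report
  net <- rep$net
  fmt <- function(x, d = 1) formatC(x, format = "f", digits = d)
  lines <- c(paste0("# Balance report: ", run$culture_id), "",
             "| Quantity | Value |", "| --- | --- |")
  row <- function(k, v) paste0("| ", k, " | ", v, " |")
  for (i in seq_len(nrow(net))) {
    lines <- c(lines, row(paste0(net$compound[i], " (", net$role[i], ")"),
                          paste0(fmt(net$net[i]), " mM")))
  }
  lines <- c(lines,
             row("Biomass", paste0(fmt(rep$biomass_mM), " mM (5-C units)")),
             row("CO2 (estimated)", paste0(fmt(rep$co2_mM), " mM")),
             row("H2 (redox closure)", paste0(fmt(rep$h2_mM), " mM")),
             row("Carbon recovery", paste0(rep$carbon_recovery_pct, "% (",
                                           fmt(rep$carbon_recovery, 2), "%)")),
             row("Electron recovery", paste0(rep$electron_recovery_pct, "% (",
                                             fmt(rep$electron_recovery, 2),
                                             "%)")),
             "", "## Yields (mol/mol)", "",
             "| Product | Basis | Yield |", "| --- | --- | --- |")
  yt <- run$yields
  for (i in seq_len(nrow(yt))) {
    lines <- c(lines, paste0("| ", yt$product[i], " | ", yt$basis[i], " | ",
                             yt$yield_2dp[i], " |"))
  }
  if (!is.null(run$atp_yield)) {
    lines <- c(lines, "",
               paste0("ATP yield: ", fmt(run$atp_yield, 2), " mol/mol sugar"))
  }
  lines
}

#' @export
print.fermentation_run <- function(x, ...) {
  print(x$report)
  if (!is.null(x$branch_equations)) print(x$branch_equations)
  if (!is.null(x$atp_yield)) {
    cat(sprintf("  ATP yield: %.2f mol/mol sugar\n", x$atp_yield))
  }
  invisible(x)
}

#' Simulate a fermentation and persist it
#'
#' @param config list (or YAML path) holding the [simulation_spec()]
#'   arguments plus an optional `out` directory; `substrates`, `consumed`
#'   and `biomass_yield` may be named lists (as parsed from YAML).
#' @return The `fermentation_simulation`, with `paths` to the written
#'   `dataset.csv` and `truth.json` when `out` is set.  Rerunning with the
#'   same seed reproduces the files byte-identically.
#' @export
run_simulate <- function(config) {
  config <- load_config(config)
  as_named <- function(x) if (is.list(x)) unlist(x) else x
  spec <- simulation_spec(
    substrates = as_named(config$substrates),
    consumed = as_named(config$consumed),
    product_coeffs = lapply(config$product_coeffs, as_named),
    biomass_yield = as_named(config$biomass_yield),
    times = config$times %||% seq(0, 56, length.out = 15),
    logistic_rate = config$logistic_rate %||% 0.25,
    logistic_mid = config$logistic_mid,
    noise_sd = config$noise_sd %||% 0,
    seed = config$seed)
  sim <- simulate_fermentation(spec)
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(config$out, "dataset.csv")
    tj <- file.path(config$out, "truth.json")
    write_dataset(sim$dataset, csv)
    truth <- sim$truth
    truth$true_conc <- NULL
    jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    sim$paths <- c(dataset = csv, truth = tj)
  }
  sim
}
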