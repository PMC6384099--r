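# Packaged reference cultures: the three bioreactor fermentations of
# C. beijerinckii DSM 6423 (d-glucose 56 h, l-rhamnose 56 h, and a
# d-glucose/l-rhamnose mixture 72 h) as two-point start/end datasets.

fixture_meta <- function() {
  yaml::read_yaml(system.file("extdata", "table1_cultures.yaml",
                              package = "fermstoich", mustWork = TRUE))
}

#' The packaged reference cultures
#'
#' Returns the three reference batch cultures (culture ids `"glucose"`,
#' `"rhamnose"`, `"mixture"`) as two-point datasets holding the start and
#' end concentrations of every measured compound, the end-point biomass in
#' mM of 5-C formula units, and the substrate labels (the sugars plus the
#' acetate dosed with the medium).
#'
#' @param registry a `compound_registry`.
#' @return Named list of three `fermentation_dataset` objects.
#' @export
builtin_table1_fixtures <- function(registry = default_registry()) {
  meta <- fixture_meta()
  out <- lapply(names(meta), function(id) {
    m <- meta[[id]]
    path <- system.file("extdata", m$file, package = "fermstoich",
                        mustWork = TRUE)
    ds <- read_dataset(path, culture_id = id,
                       substrates = unlist(m$substrates),
                       biomass_end_mM = m$biomass_end_mM,
                       registry = registry)
    attr(ds, "pathway_id") <- m$pathway
    ds
  })
  stats::setNames(out, names(meta))
}

#' Replay one reference culture
#'
#' Convenience passthrough to [builtin_table1_fixtures()] for a single
#' culture id.
#'
#' @param column one of `"glucose"`, `"rhamnose"`, `"mixture"`.
#' @param registry a `compound_registry`.
#' @return A `fermentation_dataset`.
#' @export
table1_replay <- function(column = c("glucose", "rhamnose", "mixture"),
                          registry = default_registry()) {
  column <- match.arg(column)
  builtin_table1_fixtures(registry)[[column]]
}
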