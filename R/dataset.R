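# Fermentation datasets: time-indexed extracellular concentration series
# (mM) per compound for one batch culture, plus optional biomass
# observations (OD600 series, end-point cell dry weight, or an end-point
# biomass concentration in mM of 5-C formula units).

#' Construct a fermentation dataset
#'
#' @param culture_id identifier for the culture.
#' @param time_h strictly increasing numeric vector of sampling times (h).
#' @param conc numeric matrix or data.frame, rows = time points, columns =
#'   registered compounds; concentrations in mM, `NA` = not measured.
#' @param substrates compound names dosed at t0 (yield denominators).
#' @param od600 optional numeric vector of OD600 readings, parallel to
#'   `time_h` (`NA` allowed).
#' @param cdw_end optional end-point cell dry weight (g/L).
#' @param biomass_end_mM optional end-point biomass in mM of 5-C units;
#'   takes precedence over `cdw_end` and the OD600 calibration.
#' @param nd optional logical matrix flagging cells that are
#'   below-detection ("ND"); such cells hold 0 mM in `conc` but remain
#'   distinguishable from true zeros.
#' @param registry a `compound_registry`; every concentration column must
#'   resolve in it.
#' @return An object of class `fermentation_dataset`.
#' @export
fermentation_dataset <- function(culture_id, time_h, conc,
                                 substrates = character(),
                                 od600 = NULL, cdw_end = NULL,
                                 biomass_end_mM = NULL, nd = NULL,
                                 registry = default_registry()) {
  time_h <- as.numeric(time_h)
  conc <- as.matrix(conc)
  storage.mode(conc) <- "double"
  if (length(time_h) == 0L || nrow(conc) == 0L) {
    stop("dataset validation: no time points", call. = FALSE)
  }
  if (nrow(conc) != length(time_h)) {
    stop("dataset validation: conc must have one row per time point",
         call. = FALSE)
  }
  if (is.null(colnames(conc)) || !ncol(conc)) {
    stop("dataset validation: conc needs compound column names", call. = FALSE)
  }
  if (anyNA(time_h) || is.unsorted(time_h, strictly = TRUE)) {
    stop("dataset validation: times must be strictly increasing", call. = FALSE)
  }
  compound_gamma(colnames(conc), registry)   # errors on unknown compounds
  if (any(conc < 0, na.rm = TRUE)) {
    stop("dataset validation: negative concentration", call. = FALSE)
  }
  if (is.null(nd)) {
    nd <- matrix(FALSE, nrow(conc), ncol(conc), dimnames = dimnames(conc))
  }
  stopifnot(identical(dim(nd), dim(conc)))
  if (!is.null(od600)) {
    od600 <- as.numeric(od600)
    stopifnot(length(od600) == length(time_h))
    if (any(od600 < 0, na.rm = TRUE)) {
      stop("dataset validation: negative OD600", call. = FALSE)
    }
  }
  missing_sub <- setdiff(substrates, colnames(conc))
  if (length(missing_sub)) {
    stop("substrate label(s) not among measured compounds: ",
         paste(missing_sub, collapse = ", "), call. = FALSE)
  }
  structure(list(culture_id = as.character(culture_id),
                 time_h = time_h, conc = conc, nd = nd,
                 substrates = substrates, od600 = od600,
                 cdw_end = cdw_end, biomass_end_mM = biomass_end_mM,
                 registry = registry),
            class = "fermentation_dataset")
}

#' Read a fermentation time series from a delimited text table
#'
#' The table must have a `time_h` column, optionally an `od600` column, and
#' one column per registered compound, concentrations in mM.  Cells reading
#' `ND` are below-detection and are recorded as 0 mM with the ND flag set;
#' empty cells are recorded as absent (`NA`), not zero.
#'
#' @param path CSV (`,`) or TSV (tab, for `.tsv`/`.txt`) file.
#' @param culture_id culture identifier; defaults to the file stem.
#' @param substrates,cdw_end,biomass_end_mM,registry passed to
#'   [fermentation_dataset()].
#' @return A `fermentation_dataset`.
#' @export
read_dataset <- function(path, culture_id = NULL, substrates = character(),
                         cdw_end = NULL, biomass_end_mM = NULL,
                         registry = default_registry()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  if (!nrow(raw)) stop("dataset validation: empty table", call. = FALSE)
  if (!"time_h" %in% names(raw)) {
    stop("table must have a 'time_h' column", call. = FALSE)
  }
  time_h <- as.numeric(raw[["time_h"]])
  od600 <- if ("od600" %in% names(raw)) {
    suppressWarnings(as.numeric(raw[["od600"]]))
  }
  compound_cols <- setdiff(names(raw), c("time_h", "od600"))
  if (!length(compound_cols)) {
    stop("table has no compound columns", call. = FALSE)
  }
  nd <- conc <- matrix(NA_real_, nrow(raw), length(compound_cols),
                       dimnames = list(NULL, compound_cols))
  nd[] <- FALSE
  for (cc in compound_cols) {
    cell <- raw[[cc]]
    is_nd <- toupper(cell) == "ND"
    is_empty <- !nzchar(cell)
    val <- suppressWarnings(as.numeric(cell))
    bad <- !is_nd & !is_empty & is.na(val)
    if (any(bad)) {
      stop("non-numeric cell in column ", sQuote(cc), call. = FALSE)
    }
    val[is_nd] <- 0
    val[is_empty] <- NA_real_
    conc[, cc] <- val
    nd[, cc] <- is_nd
  }
  mode(nd) <- "logical"
  fermentation_dataset(culture_id %||% sub("\\.[^.]*$", "", basename(path)),
                       time_h, conc, substrates = substrates, od600 = od600,
                       cdw_end = cdw_end, biomass_end_mM = biomass_end_mM,
                       nd = nd, registry = registry)
}

#' Write a fermentation dataset back to delimited text
#'
#' Inverse of [read_dataset()]: below-detection cells are written as `ND`,
#' absent cells as empty strings, values at full double precision so the
#' round trip is the identity on all fields.
#'
#' @param dataset a `fermentation_dataset`.
#' @param path output file; extension selects the delimiter as in
#'   [read_dataset()].
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "fermentation_dataset"))
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15,
                                                 scientific = FALSE,
                                                 trim = TRUE))
  out <- data.frame(time_h = fmt(dataset$time_h), check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(dataset$od600)) out$od600 <- fmt(dataset$od600)
  for (cc in colnames(dataset$conc)) {
    col <- fmt(dataset$conc[, cc])
    col[dataset$nd[, cc]] <- "ND"
    out[[cc]] <- col
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.fermentation_dataset <- function(x, ...) {
  cat("<fermentation dataset> ", x$culture_id, "\n", sep = "")
  cat("  ", length(x$time_h), " time points over [",
      x$time_h[1], ", ", x$time_h[length(x$time_h)], "] h; ",
      ncol(x$conc), " compounds\n", sep = "")
  if (length(x$substrates)) {
    cat("  substrates dosed at t0:", paste(x$substrates, collapse = ", "), "\n")
  }
  if (!is.null(x$biomass_end_mM)) {
    cat("  end-point biomass:", x$biomass_end_mM, "mM (5-C units)\n")
  } else if (!is.null(x$cdw_end)) {
    cat("  end-point cdw:", x$cdw_end, "g/L\n")
  }
  invisible(x)
}
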