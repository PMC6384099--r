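# Elemental formulas restricted to C, H, O, N -- the four elements that the
# degree-of-reduction convention (gamma = 4C + H - 2O - 3N, reference
# compounds CO2, H2O, NH3) assigns weights to.

.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)
.GAMMA_WEIGHTS <- c(C = 4, H = 1, O = -2, N = -3)

#' Construct an elemental formula
#'
#' An elemental formula is a named numeric vector of non-negative (possibly
#' fractional) element counts for C, H, O and N.  Fractional counts allow
#' biomass-type unit formulas such as CH1.8O0.5N0.2.
#'
#' @param C,H,O,N non-negative finite element counts; at least one must be
#'   positive.
#' @return An object of class `elemental_formula`.
#' @examples
#' elemental_formula(C = 6, H = 12, O = 6)        # d-glucose
#' elemental_formula(C = 1, H = 1.8, O = 0.5, N = 0.2)  # biomass monomer
#' @export
elemental_formula <- function(C = 0, H = 0, O = 0, N = 0) {
  counts <- c(C = as.numeric(C), H = as.numeric(H),
              O = as.numeric(O), N = as.numeric(N))
  if (any(!is.finite(counts))) {
    stop("invalid formula: element counts must be finite", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("invalid formula: negative element count", call. = FALSE)
  }
  if (all(counts == 0)) {
    stop("invalid formula: at least one element count must be > 0",
         call. = FALSE)
  }
  structure(counts, class = "elemental_formula")
}

#' Parse a formula string
#'
#' Accepts Hill-like notation over C, H, O, N with optional fractional
#' subscripts, e.g. `"C6H12O5"` (l-rhamnose) or `"C1H1.8O0.5N0.2"`.
#'
#' @param x a single formula string.
#' @return An `elemental_formula`.
#' @export
parse_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  s <- gsub("[[:space:]]", "", x)
  pat <- "([CHON])([0-9]*\\.?[0-9]*)"
  toks <- regmatches(s, gregexpr(pat, s))[[1]]
  if (length(toks) == 0L || paste(toks, collapse = "") != s) {
    stop("cannot parse formula string: ", sQuote(x), call. = FALSE)
  }
  counts <- c(C = 0, H = 0, O = 0, N = 0)
  for (tok in toks) {
    el <- substr(tok, 1L, 1L)
    num <- substring(tok, 2L)
    counts[[el]] <- counts[[el]] + if (nzchar(num)) as.numeric(num) else 1
  }
  elemental_formula(counts[["C"]], counts[["H"]], counts[["O"]], counts[["N"]])
}

#' Degree of reduction of a compound
#'
#' Electrons available per mole on full oxidation to CO2, H2O and NH3:
#' gamma = 4 C + H - 2 O - 3 N.  The reference compounds themselves have
#' gamma = 0; H2 has gamma = 2.  gamma is linear in the formula, so any
#' reaction balanced in C, H, O, N conserves total gamma.
#'
#' @param formula an `elemental_formula`, or a string parseable by
#'   [parse_formula()].
#' @return Electrons per mole (numeric scalar).
#' @examples
#' degree_of_reduction("C6H12O6")  # d-glucose: 24
#' degree_of_reduction("C6H12O5")  # l-rhamnose: 26
#' @export
degree_of_reduction <- function(formula) {
  f <- parse_formula_or_fail(formula)
  sum(.GAMMA_WEIGHTS * unclass(f))
}

#' Carbon count of a compound
#'
#' @inheritParams degree_of_reduction
#' @return C-mol per mol (numeric scalar).
#' @export
carbon_count <- function(formula) {
  f <- parse_formula_or_fail(formula)
  unname(unclass(f)[["C"]])
}

#' Molar mass of a formula
#'
#' @inheritParams degree_of_reduction
#' @return g/mol, from IUPAC standard atomic weights.
#' @export
molar_mass <- function(formula) {
  f <- parse_formula_or_fail(formula)
  sum(.ATOMIC_MASS * unclass(f))
}

parse_formula_or_fail <- function(formula) {
  if (inherits(formula, "elemental_formula")) {
    formula
  } else if (is.character(formula)) {
    parse_formula(formula)
  } else {
    stop("expected an elemental_formula or a formula string", call. = FALSE)
  }
}

#' @export
format.elemental_formula <- function(x, ...) {
  counts <- unclass(x)
  parts <- vapply(names(counts)[counts > 0], function(el) {
    n <- counts[[el]]
    paste0(el, if (n == 1) "" else format(n, digits = 10))
  }, character(1))
  paste(parts, collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental formula> ", format(x),
      "  (gamma = ", degree_of_reduction(x),
      ", C = ", carbon_count(x), ")\n", sep = "")
  invisible(x)
}
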