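# Monoisotopic element masses (Da) and derived adduct arithmetic.

#' @keywords internal
ELEMENT_MONO_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668
)

ELECTRON_MASS <- 0.00054857990907

# 13C - 12C spacing used for isotope envelopes of singly charged ions
ISOTOPE_SPACING <- 1.0033548

# phosphocholine head-group fragment of PC/SM in positive mode
PC_HEADGROUP_MZ <- 184.0733

#' Parse a molecular formula string
#'
#' Converts a Hill-style formula such as `"C39H74O5"` into a named integer
#' vector of element counts. Element symbols must be present in the bundled
#' monoisotopic mass table.
#'
#' @param formula character scalar, e.g. `"C45H88NO8P"`; an element without a
#'   following number counts once.
#' @return named integer vector of element counts (empty vector for `""`).
#' @examples
#' parse_formula("C39H74O5")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  formula <- trimws(formula)
  if (!nzchar(formula)) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  out <- tapply(counts, elems, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula a formula string (see [parse_formula()]) or a named numeric
#'   vector of element counts.
#' @return monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' monoisotopic_mass("C39H74O5") # DG(36:1), 622.55362
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L) return(0)
  if (is.null(names(formula)) || any(!nzchar(names(formula)))) {
    stop("formula counts must be named by element symbol")
  }
  unknown <- setdiff(names(formula), names(ELEMENT_MONO_MASS))
  if (length(unknown)) {
    stop("unknown element(s) in formula: ", paste(unknown, collapse = ", "))
  }
  if (any(formula < 0)) stop("element counts must be non-negative")
  sum(formula * ELEMENT_MONO_MASS[names(formula)])
}

#' Positive-mode adduct table
#'
#' The four singly charged adducts commonly observed for lipids in positive
#' mode MALDI and LC-MS: protonated, sodiated, potassiated and ammoniated
#' species. `delta_mass` is the mass of the attached cation minus one
#' electron, i.e. the shift from neutral monoisotopic mass to observed m/z.
#'
#' @param labels optional character vector restricting/ordering the adducts,
#'   e.g. `c("[M+K]+", "[M+NH4]+")`.
#' @return data.frame with columns `label`, `delta_mass`, `charge`.
#' @examples
#' default_adducts()
#' @export
default_adducts <- function(labels = NULL) {
  cation_formulas <- c(
    "[M+H]+"   = "H",
    "[M+Na]+"  = "Na",
    "[M+K]+"   = "K",
    "[M+NH4]+" = "NH4"
  )
  delta <- vapply(cation_formulas, function(f) {
    monoisotopic_mass(f) - ELECTRON_MASS
  }, numeric(1))
  out <- data.frame(
    label = names(cation_formulas),
    delta_mass = unname(delta),
    charge = 1L,
    stringsAsFactors = FALSE
  )
  if (!is.null(labels)) {
    missing <- setdiff(labels, out$label)
    if (length(missing)) {
      stop("unknown adduct label(s): ", paste(missing, collapse = ", "))
    }
    out <- out[match(labels, out$label), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Observed m/z of a neutral molecule under a positive adduct
#'
#' @param neutral_mass neutral monoisotopic mass in Da (>= 0).
#' @param adduct an adduct label (see [default_adducts()]) or a one-row
#'   adduct data.frame.
#' @return m/z in Da (charge +1).
#' @examples
#' adduct_mz(622.55362, "[M+K]+") # DG(36:1) potassiated, 661.51678
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass >= 0))
  delta <- adduct_delta(adduct)
  neutral_mass + delta
}

adduct_delta <- function(adduct) {
  if (is.character(adduct)) {
    default_adducts(adduct)$delta_mass
  } else if (is.data.frame(adduct)) {
    adduct$delta_mass
  } else if (is.numeric(adduct)) {
    adduct
  } else {
    stop("adduct must be a label, adduct data.frame, or numeric delta")
  }
}

#' Signed relative mass error in parts per million
#'
#' @param observed_mz observed m/z (Da).
#' @param theoretical_mz theoretical m/z (Da), > 0.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @examples
#' ppm_error(661.5175, adduct_mz(monoisotopic_mass("C39H74O5"), "[M+K]+"))
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  stopifnot(all(theoretical_mz > 0))
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Molecular formula of a lipid from class and total acyl composition
#'
#' Applies the standard formula rules for the lipid classes handled by the
#' package, with `carbons`/`double_bonds` the summed acyl-chain composition
#' (e.g. DG(36:1) -> `lipid_formula("DG", 36, 1)` -> C39H74O5). Sphingoid
#' classes (SM, CerPE) interpret the composition as the d-form long-chain
#' base plus N-acyl total.
#'
#' @param lipid_class one of `"DG"`, `"TG"`, `"PC"`, `"SM"`, `"PA"`, `"CerPE"`.
#' @param carbons total acyl/backbone carbons.
#' @param double_bonds total number of C=C double bonds.
#' @return formula string in Hill-ish order.
#' @examples
#' lipid_formula("DG", 36, 1) # "C39H74O5"
#' lipid_formula("PC", 34, 1) # "C42H82NO8P"
#' @export
lipid_formula <- function(lipid_class, carbons, double_bonds) {
  stopifnot(carbons > 0, double_bonds >= 0)
  cc <- as.integer(carbons)
  d <- as.integer(double_bonds)
  counts <- switch(lipid_class,
    DG    = c(C = cc + 3L, H = 2L * cc - 2L * d + 4L, O = 5L),
    TG    = c(C = cc + 3L, H = 2L * cc - 2L * d + 2L, O = 6L),
    PC    = c(C = cc + 8L, H = 2L * cc - 2L * d + 16L, N = 1L, O = 8L, P = 1L),
    PA    = c(C = cc + 3L, H = 2L * cc - 2L * d + 5L, O = 8L, P = 1L),
    SM    = c(C = cc + 5L, H = 2L * cc - 2L * d + 13L, N = 2L, O = 6L, P = 1L),
    CerPE = c(C = cc + 2L, H = 2L * cc - 2L * d + 7L, N = 2L, O = 6L, P = 1L),
    stop("no formula rule for lipid class: ", lipid_class)
  )
  format_formula(counts)
}

format_formula <- function(counts) {
  counts <- counts[counts > 0]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a free fatty acid CnH(2n-2d)O2
#'
#' @param carbons acyl carbon count.
#' @param double_bonds number of double bonds.
#' @return RCOOH monoisotopic mass in Da (e.g. 18:0 stearic acid, 284.27153).
#' @export
fatty_acid_mass <- function(carbons, double_bonds) {
  stopifnot(carbons >= 1, double_bonds >= 0)
  monoisotopic_mass(c(C = carbons, H = 2 * carbons - 2 * double_bonds, O = 2))
}
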