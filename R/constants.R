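#' Unit conversion constants
#'
#' All energy expressions are evaluated in atomic units (bohr, hartree,
#' electron charge) and converted to kcal/mol and Angstrom only at the I/O
#' boundary.
#'
#' @format Named numeric vector with elements `bohr_per_angstrom`,
#'   `angstrom_per_bohr`, `kcal_per_hartree`.
#' @export
sapt_units <- c(
  bohr_per_angstrom = 1 / 0.52917721,
  angstrom_per_bohr = 0.52917721,
  kcal_per_hartree  = 627.509
)

# Elements the model supports.
SUPPORTED_ELEMENTS <- c("C", "H", "N", "O", "S", "F", "Cl", "Br")

# Covalent radii (Angstrom), Cordero-type single-bond values, used only for
# bond perception.
COVALENT_RADII <- c(
  C = 0.76, H = 0.31, N = 0.71, O = 0.66,
  S = 1.05, F = 0.57, Cl = 1.02, Br = 1.20
)

#' The 17-label atom-species vocabulary
#'
#' Heavy atoms are labelled by element plus total bonded-neighbour count
#' (hydrogens included): C4/C3/C2, N3/N2/N1, O2/O1, S2/S1.  Hydrogens are
#' labelled by the element they are attached to (HC/HN/HO/HS) and halogens
#' by element alone (F/Cl/Br).  These labels index the global per-species
#' parameters of the energy model.
#'
#' @return Character vector of the 17 species labels.
#' @export
species_vocabulary <- function() {
  c("C4", "C3", "C2",
    "N3", "N2", "N1",
    "O2", "O1",
    "S2", "S1",
    "HC", "HN", "HO", "HS",
    "F", "Cl", "Br")
}

#' Free-atom reference constants
#'
#' Free-atom C6 dispersion coefficients (hartree bohr^6), static dipole
#' polarizabilities (bohr^3), the multipole expectation values <r^2>
#' (bohr^2) and <r^4> (bohr^4) of the free atomic density, and the nuclear
#' charge, for the eight supported elements.  Magnitudes are
#' literature-typical free-atom values; they are configuration for the
#' dispersion model (they set the scale of C6/C8/C10 before Hirshfeld
#' scaling), not fitted quantities.
#'
#' @param element Optional character vector of element symbols; if given,
#'   the subset of rows for those elements (errors on unsupported symbols).
#' @return data.frame with columns `element`, `c6_free`, `alpha_free`,
#'   `r2`, `r4`, `z_nuc`.
#' @export
free_atom_constants <- function(element = NULL) {
  tab <- data.frame(
    element    = c("C", "H", "N", "O", "S", "F", "Cl", "Br"),
    c6_free    = c(46.6, 6.5, 24.2, 15.6, 134.0, 9.5, 94.6, 162.0),
    alpha_free = c(12.0, 4.5, 7.4, 5.4, 19.6, 3.8, 14.6, 20.0),
    r2         = c(13.8, 3.0, 9.9, 7.6, 19.6, 6.0, 16.2, 19.3),
    r4         = c(113.0, 22.5, 61.0, 38.0, 210.0, 25.0, 150.0, 213.0),
    z_nuc      = c(6, 1, 7, 8, 16, 9, 17, 35),
    stringsAsFactors = FALSE
  )
  if (is.null(element)) return(tab)
  idx <- match(element, tab$element)
  if (anyNA(idx)) {
    stop("unsupported element(s): ",
         paste(unique(element[is.na(idx)]), collapse = ", "))
  }
  tab[idx, , drop = FALSE]
}

# Printed class composition of the 47-homodimer supplement drawn from the
# large diverse homodimer collection used to extend the training set.
SUPPLEMENT_CLASS_COUNTS <- c(
  "Ester" = 2, "Ether" = 4, "Nitrile" = 3, "Sulfide" = 5,
  "Disulfide" = 2, "Amine" = 5, "Cyclic Ether" = 1, "Haloalkane" = 3,
  "Cyclic Sulfide" = 1, "Non-Aromatic Ring" = 9, "Aromatic Ring" = 10,
  "Aromatic Secondary Amine" = 2
)

#' Class composition of the diverse-homodimer training supplement
#'
#' The per-class homodimer counts (12 functional-group classes, 47 dimers
#' in total) used to extend a functional-group training set so that all 17
#' atom species appear in training.
#'
#' @return Named integer vector of per-class dimer counts.
#' @export
supplement_class_counts <- function() SUPPLEMENT_CLASS_COUNTS

#' Expand class counts into a dimer-slot manifest
#'
#' Turns a named vector of per-class dimer counts into a manifest
#' data.frame with one row per dimer slot, in class order.
#'
#' @param counts Named non-negative integer vector (names = class labels).
#' @return data.frame with columns `slot`, `class`.
#' @export
class_manifest <- function(counts = supplement_class_counts()) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector of class counts")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  cls <- rep(names(counts), times = counts)
  data.frame(slot = seq_along(cls), class = cls, stringsAsFactors = FALSE)
}
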