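# Element tables shared across the package.

# Conventional (abridged) standard atomic weights. Three or more decimals,
# enough to reproduce vendor catalogue masses to 0.001 g/mol.
.ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974,
  S = 32.06, Cl = 35.453, K = 39.098, Ca = 40.078, Se = 78.971,
  Br = 79.904, I = 126.904, Ne = 20.180, He = 4.003, Ar = 39.948,
  Li = 6.94, Zn = 65.38, Fe = 55.845
)

# Single-bond covalent radii (Angstrom), used for idealized bond lengths
# during conformer embedding.
.COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Na = 1.66, Mg = 1.41, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  K = 2.03, Ca = 1.76, Se = 1.20, Br = 1.20, I = 1.39, Ne = 0.58,
  He = 0.28, Ar = 1.06, Li = 1.28, Zn = 1.22, Fe = 1.32
)

# Elements of the SMILES "organic subset": written without brackets,
# hydrogen counts implied by lowest consistent valence.
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# Allowed valence lists for implicit-hydrogen assignment (organic subset).
.DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Standard atomic weight of an element
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of atomic weights in g/mol.
#' @keywords internal
atomic_weight <- function(element) {
  w <- .ATOMIC_WEIGHTS[element]
  if (anyNA(w)) {
    bad <- unique(element[is.na(w)])
    stop("no tabulated atomic weight for element(s): ",
         paste(bad, collapse = ", "))
  }
  unname(w)
}
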