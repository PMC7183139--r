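# Molecule: an attributed molecular graph with optional 3D conformers.

#' Construct a Molecule
#'
#' Low-level constructor; most users will obtain molecules from
#' [parse_smiles()], [read_smi()] or [read_sdf()]. Atoms are rows of a
#' data frame with columns `element`, `charge`, `implicit_h`, `aromatic`;
#' bonds have `a`, `b`, `order` (single/double/triple/aromatic) and
#' `in_ring`. Conformers are matrices with one Cartesian row (Angstrom)
#' per atom.
#'
#' @param name Identifier string.
#' @param atoms Atom table.
#' @param bonds Bond table.
#' @param conformers List of `n_atoms x 3` coordinate matrices.
#' @param smiles Source SMILES, if any.
#' @return An object of class `Molecule`.
#' @export
new_molecule <- function(name, atoms, bonds, conformers = list(),
                         smiles = NULL) {
  mol <- structure(list(name = name, atoms = atoms, bonds = bonds,
                        conformers = conformers, smiles = smiles),
                   class = "Molecule")
  validate_molecule(mol)
  mol
}

#' Validate Molecule invariants
#'
#' Checks bond endpoints, unknown elements, negative hydrogen counts and
#' conformer dimensions. Called by the constructor; exported for use after
#' manual graph edits.
#'
#' @param mol A [Molecule].
#' @return `mol`, invisibly; errors on violation.
#' @export
validate_molecule <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  if (nrow(a) == 0L) stop("molecule has no atoms")
  if (!all(a$element %in% names(.ATOMIC_WEIGHTS)))
    stop("unknown element symbol(s): ",
         paste(setdiff(a$element, names(.ATOMIC_WEIGHTS)), collapse = ", "))
  if (any(a$implicit_h < 0L)) stop("negative implicit hydrogen count")
  if (nrow(b) > 0L) {
    if (any(b$a == b$b)) stop("bond with identical endpoints")
    if (any(b$a < 1L | b$a > nrow(a) | b$b < 1L | b$b > nrow(a)))
      stop("bond endpoint out of range")
  }
  for (cf in mol$conformers) {
    if (!is.matrix(cf) || nrow(cf) != nrow(a) || ncol(cf) != 3L)
      stop("conformer must be an n_atoms x 3 matrix")
    if (any(!is.finite(cf))) stop("non-finite conformer coordinates")
  }
  invisible(mol)
}

#' @export
print.Molecule <- function(x, ...) {
  cat(sprintf("<Molecule %s: %d heavy atoms, %d bonds, charge %+d, %d conformer(s)>\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds), net_charge(x),
              length(x$conformers)))
  invisible(x)
}

#' Net formal charge of a molecule
#' @param mol A [Molecule].
#' @return Integer net charge in units of e.
#' @export
net_charge <- function(mol) as.integer(sum(mol$atoms$charge))

# neighbor indices of atom i
.neighbors <- function(mol, i) {
  b <- mol$bonds
  c(b$b[b$a == i], b$a[b$b == i])
}

# count of heavy-atom neighbors for every atom
.heavy_degree <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- integer(n)
  if (nrow(mol$bonds) > 0L) {
    t1 <- tabulate(mol$bonds$a, n)
    t2 <- tabulate(mol$bonds$b, n)
    deg <- t1 + t2
  }
  deg
}

#' Molecular formula in Hill order
#'
#' Element counts include implicit hydrogens. Hill convention: carbon first,
#' then hydrogen, then remaining elements alphabetically; without carbon,
#' all elements (including H) are alphabetical. A net formal charge is
#' annotated as a trailing `+`/`-` (with magnitude when above 1).
#'
#' @param mol A [Molecule].
#' @return Formula string, e.g. `"C22H25N3O4"` or `"H4N+"`.
#' @export
molecular_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  counts <- stats::setNames(as.integer(counts), names(counts))
  nh <- sum(mol$atoms$implicit_h)
  counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + nh
  counts <- counts[counts > 0L]
  els <- names(counts)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", if ("H" %in% els) "H", rest)
  } else {
    ord <- sort(els)
  }
  part <- vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, "")
  q <- net_charge(mol)
  suffix <- if (q == 0L) "" else if (q == 1L) "+" else if (q == -1L) "-"
            else sprintf("%+d", q)
  paste0(paste(part, collapse = ""), suffix)
}

#' Molecular weight
#'
#' Sum of standard atomic weights over all atoms, including implicit
#' hydrogens, of the molecule exactly as drawn (charged species are not
#' neutralized first).
#'
#' @param mol A [Molecule].
#' @return Mass in g/mol.
#' @export
molecular_weight <- function(mol) {
  sum(atomic_weight(mol$atoms$element)) +
    sum(mol$atoms$implicit_h) * .ATOMIC_WEIGHTS[["H"]]
}

#' Neutralize protonation-state charges
#'
#' Removes one hydrogen from each positively charged N/O bearing at least
#' one hydrogen, and adds one hydrogen to each negatively charged N/O,
#' until the net charge is zero. Only hydrogen arithmetic is performed:
#' the heavy-atom skeleton is untouched. Charges that cannot be resolved
#' this way (e.g. a quaternary ammonium nitrogen) raise an error.
#'
#' @param mol A [Molecule].
#' @return A neutral [Molecule]; conformers are preserved (heavy-atom
#'   coordinates are unaffected by hydrogen arithmetic).
#' @export
neutralize <- function(mol) {
  a <- mol$atoms
  if (sum(a$charge) == 0L && all(a$charge == 0L)) return(mol)
  for (i in seq_len(nrow(a))) {
    if (a$charge[i] == 0L) next
    if (!a$element[i] %in% c("N", "O"))
      stop("atom ", i, " (", a$element[i], sprintf("%+d", a$charge[i]),
           "): charge not removable by hydrogen arithmetic")
    if (a$charge[i] > 0L) {
      if (a$implicit_h[i] < a$charge[i])
        stop("atom ", i, " (", a$element[i], sprintf("%+d", a$charge[i]),
             "): no removable hydrogen")
      a$implicit_h[i] <- a$implicit_h[i] - a$charge[i]
    } else {
      a$implicit_h[i] <- a$implicit_h[i] + abs(a$charge[i])
    }
    a$charge[i] <- 0L
  }
  out <- mol
  out$atoms <- a
  out$smiles <- NULL
  validate_molecule(out)
  out
}

# Total hydrogen count attached to atom i (implicit only in this model).
.h_count <- function(mol, i) mol$atoms$implicit_h[i]
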