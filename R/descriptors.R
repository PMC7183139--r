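# Physicochemical descriptors: polar-atom counts, rotatable bonds, Ertl
# fragment-contribution TPSA, atom-contribution logP, estimated oral
# absorption, and the combined per-molecule descriptor set.

# per-atom bond environment: counts of single/double/triple/aromatic bonds
.atom_env <- function(mol) {
  n <- nrow(mol$atoms)
  env <- matrix(0L, n, 4L, dimnames = list(NULL, c("s", "d", "t", "a")))
  b <- mol$bonds
  if (nrow(b) > 0L) {
    code <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
    for (k in seq_len(nrow(b))) {
      j <- code[[b$order[k]]]
      env[b$a[k], j] <- env[b$a[k], j] + 1L
      env[b$b[k], j] <- env[b$b[k], j] + 1L
    }
  }
  env
}

#' Count hydrogen-bond acceptor atoms (nON)
#'
#' The Lipinski-style acceptor count: every nitrogen and oxygen atom,
#' regardless of charge or hybridization.
#'
#' @param mol A [Molecule].
#' @return Integer count.
#' @export
count_n_on <- function(mol) {
  sum(mol$atoms$element %in% c("N", "O"))
}

#' Count hydrogen-bond donor hydrogens (nOHNH)
#'
#' Total hydrogen atoms attached to nitrogen or oxygen; an ammonium
#' `[NH3+]` group contributes three.
#'
#' @param mol A [Molecule].
#' @return Integer count.
#' @export
count_n_ohnh <- function(mol) {
  on <- mol$atoms$element %in% c("N", "O")
  sum(mol$atoms$implicit_h[on])
}

#' Count rotatable bonds
#'
#' A rotatable bond is an acyclic single bond between two heavy atoms that
#' each have at least two heavy-atom neighbors, excluding amide C-N bonds
#' (the C carrying a double-bonded O). Ester C-O single bonds count;
#' bonds to terminal groups (methyl, ammonium) do not, because the
#' terminal atom has a single heavy neighbor.
#'
#' @param mol A [Molecule].
#' @return Integer count.
#' @export
count_rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(0L)
  deg <- .heavy_degree(mol)
  el <- mol$atoms$element
  # atoms that are amide carbonyl carbons: C with a double bond to O
  carbonyl_c <- rep(FALSE, nrow(mol$atoms))
  dd <- b$order == "double"
  for (k in which(dd)) {
    if (el[b$a[k]] == "C" && el[b$b[k]] == "O") carbonyl_c[b$a[k]] <- TRUE
    if (el[b$b[k]] == "C" && el[b$a[k]] == "O") carbonyl_c[b$b[k]] <- TRUE
  }
  n <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$in_ring[k] || b$order[k] != "single") next
    i <- b$a[k]; j <- b$b[k]
    if (deg[i] < 2L || deg[j] < 2L) next
    amide <- (carbonyl_c[i] && el[j] == "N") || (carbonyl_c[j] && el[i] == "N")
    if (amide) next
    n <- n + 1L
  }
  n
}

#' Topological polar surface area (Ertl fragment contributions)
#'
#' Sums published fragment contributions over all N and O atoms (S and P
#' environments are also tabulated), keyed by element, formal charge,
#' aromaticity, attached hydrogen count, bond pattern and three-membered-ring
#' membership. Two anionic nitrogen environments absent from the published
#' table (`[N-](-*)-*` and `[NH-]-*`) are tabulated here by analogy with
#' their protonated counterparts, calibrated so that reference descriptor
#' tables computed with the original Molinspiration tool are reproduced.
#' Pure hydrocarbons return 0.
#'
#' @param mol A [Molecule].
#' @return TPSA in squared Angstrom.
#' @export
tpsa_ertl <- function(mol) {
  a <- mol$atoms
  polar <- which(a$element %in% c("N", "O", "S", "P"))
  if (length(polar) == 0L) return(0)
  env <- .atom_env(mol)
  rings <- perceive_rings(mol)
  ring3 <- .atoms_in_ring_size(rings, 3L)
  total <- 0
  for (i in polar) {
    contrib <- .ertl_contribution(
      el = a$element[i], q = a$charge[i], arom = a$aromatic[i],
      h = a$implicit_h[i], s = env[i, "s"], d = env[i, "d"],
      t = env[i, "t"], na_ = env[i, "a"], ring3 = i %in% ring3)
    if (is.na(contrib))
      stop("no tabulated polar-surface contribution for atom ", i, ": ",
           a$element[i], sprintf("%+d", a$charge[i]),
           " h=", a$implicit_h[i], " bonds s/d/t/ar=",
           paste(env[i, ], collapse = "/"),
           if (a$aromatic[i]) " aromatic" else "")
    total <- total + contrib
  }
  total
}

.ertl_contribution <- function(el, q, arom, h, s, d, t, na_, ring3) {
  if (el == "N") {
    if (arom) {
      if (q == 0L) {
        if (h == 1L) return(15.79)
        if (h == 0L && na_ == 2L && s == 0L && d == 0L) return(12.89)
        if (h == 0L && na_ == 3L) return(4.41)
        if (h == 0L && na_ == 2L && s == 1L) return(4.93)
        if (h == 0L && na_ == 2L && d == 1L) return(8.39)
      } else if (q == 1L) {
        if (h == 1L) return(14.14)
        if (h == 0L && na_ == 3L) return(4.10)
        if (h == 0L && na_ == 2L && s == 1L) return(3.88)
      }
      return(NA_real_)
    }
    if (q == 0L) {
      if (h == 0L) {
        if (s == 3L) return(if (ring3) 3.01 else 3.24)
        if (s == 1L && d == 1L) return(12.36)
        if (t == 1L && s == 0L) return(23.79)
        if (s == 1L && d == 2L) return(11.68)
        if (d == 1L && t == 1L) return(13.60)
      } else if (h == 1L) {
        if (s == 2L) return(if (ring3) 21.94 else 12.03)
        if (d == 1L && s == 0L) return(23.85)
      } else if (h == 2L && s == 1L) return(26.02)
    } else if (q == 1L) {
      if (h == 0L) {
        if (s == 4L) return(0.00)
        if (s == 2L && d == 1L) return(3.01)
        if (s == 1L && t == 1L) return(4.36)
      } else if (h == 1L) {
        if (s == 3L) return(4.44)
        if (s == 1L && d == 1L) return(13.97)
      } else if (h == 2L) {
        if (s == 2L) return(16.61)
        if (d == 1L) return(25.59)
      } else if (h == 3L && s == 1L) return(27.64)
    } else if (q == -1L) {
      # extension entries, see function docs
      if (h == 0L && s == 2L) return(12.03)
      if (h == 1L && s == 1L) return(25.59)
    }
    return(NA_real_)
  }
  if (el == "O") {
    if (arom) return(13.14)
    if (q == 0L) {
      if (h == 0L) {
        if (s == 2L) return(if (ring3) 12.53 else 9.23)
        if (d == 1L && s == 0L) return(17.07)
      } else if (h == 1L && s == 1L) return(20.23)
    } else if (q == -1L && h == 0L && s == 1L) return(23.06)
    return(NA_real_)
  }
  if (el == "S") {
    if (arom) return(28.24)
    if (q != 0L) return(NA_real_)
    if (h == 0L) {
      if (s == 2L && d == 0L) return(25.30)
      if (d == 1L && s == 0L) return(32.09)
      if (d == 1L && s == 2L) return(19.21)
      if (d == 2L && s == 2L) return(8.38)
    } else if (h == 1L && s == 1L) return(38.80)
    return(NA_real_)
  }
  if (el == "P") {
    if (q != 0L) return(NA_real_)
    if (h == 0L) {
      if (s == 3L && d == 0L) return(13.59)
      if (s == 1L && d == 1L) return(34.14)
      if (s == 3L && d == 1L) return(9.81)
    } else if (h == 1L && s == 2L && d == 1L) return(23.47)
    return(NA_real_)
  }
  NA_real_
}

#' Atom-contribution logP
#'
#' Octanol-water partition estimate computed as a sum of published
#' Wildman-Crippen atom contributions over all atoms including implicit
#' hydrogens. Atom typing follows the published pattern set expressed as
#' local graph predicates. An atom environment outside the typed set falls
#' back to the published element-level default with a warning.
#'
#' @param mol A [Molecule].
#' @return Unitless logP estimate.
#' @export
logp_atomic <- function(mol) {
  contrib <- .crippen_atom_contribs(mol)
  sum(contrib)
}

# per-heavy-atom contribution including that atom's implicit hydrogens
.crippen_atom_contribs <- function(mol) {
  a <- mol$atoms
  env <- .atom_env(mol)
  n <- nrow(a)
  out <- numeric(n)
  el <- a$element
  nbrs <- lapply(seq_len(n), function(i) .neighbors(mol, i))
  het <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")
  for (i in seq_len(n)) {
    e <- el[i]; h <- a$implicit_h[i]; q <- a$charge[i]
    nb <- nbrs[[i]]
    nb_el <- el[nb]
    nb_arom <- a$aromatic[nb]
    s <- env[i, "s"]; d <- env[i, "d"]; t <- env[i, "t"]; na_ <- env[i, "a"]
    deg <- length(nb)
    v <- NA_real_
    h_v <- 0
    if (e == "C") {
      if (a$aromatic[i]) {
        # aromatic carbon: classify by the non-aromatic substituent
        nonar <- .nonaromatic_neighbors(mol, i)
        if (d == 1L) v <- -0.8186                      # c=O exocyclic
        else if (length(nonar) == 0L && na_ >= 3L) v <- 0.2955   # fused c
        else if (length(nonar) == 0L && h >= 1L) v <- 0.1581     # cH
        else if (length(nonar) >= 1L) {
          ne <- el[nonar[1L]]
          v <- switch(ne,
            F = 0.0, Cl = 0.245, Br = 0.198, I = 0.0,
            C = if (a$aromatic[nonar[1L]]) 0.2713 else 0.136,
            N = 0.4619, O = 0.5437, S = 0.1893, -0.5443)
        } else v <- 0.1581
      } else if (t >= 1L) {
        v <- 0.0017                                     # acetylenic / nitrile C
      } else if (d >= 1L) {
        dbl <- .double_bond_partners(mol, i)
        if (any(el[dbl] != "C")) v <- -0.2783           # C=heteroatom
        else if (any(a$aromatic[nb])) v <- 0.264        # vinyl on aromatic
        else v <- 0.1551                                # C=C
      } else {
        has_het <- any(nb_el %in% het)
        has_arom_nb <- any(nb_arom)
        if (has_het) v <- if (h >= 2L) -0.2035 else -0.2051
        else if (has_arom_nb) {
          v <- if (h == 3L) 0.08452 else if (h == 2L) -0.0516
               else if (h == 1L) 0.1193 else -0.0967
        } else v <- if (h >= 1L && deg <= 2L) 0.1441 else 0.0
      }
      h_v <- h * 0.1230
    } else if (e == "N") {
      if (q > 0L) {
        v <- if (a$aromatic[i]) -1.119 else if (h >= 1L) -1.95 else
          if (t >= 1L) 0.2887 else -0.3396
      } else if (q < 0L) {
        v <- 0.2887
      } else if (a$aromatic[i]) {
        v <- -0.3239
      } else if (t >= 1L) {
        v <- 0.01508
      } else if (d >= 1L) {
        v <- if (deg >= 2L) 0.1836 else 0.08387
      } else {
        amide <- any(vapply(nb, function(j)
          el[j] == "C" && any(el[.double_bond_partners(mol, j)] == "O"),
          FALSE))
        arom_nb <- any(nb_arom)
        if (h >= 2L) v <- if (arom_nb) -1.027 else -1.019
        else if (h == 1L) v <- if (amide || arom_nb) -0.5188 else -0.7096
        else v <- if (arom_nb) -0.4458 else -0.3187
      }
      h_v <- h * 0.2142
    } else if (e == "O") {
      if (a$aromatic[i]) v <- 0.1552
      else if (q < 0L) {
        carboxylate <- any(vapply(nb, function(j)
          el[j] == "C" && any(el[.double_bond_partners(mol, j)] == "O"),
          FALSE))
        v <- if (carboxylate) -1.326
             else if (any(nb_el == "N")) 0.0335
             else if (any(nb_el == "S")) -0.3339
             else -1.189
      } else if (h >= 1L) {
        v <- -0.2893
        acid <- any(vapply(nb, function(j)
          el[j] == "C" && any(el[.double_bond_partners(mol, j)] %in%
                                c("C", "N", "O", "S")) &&
            !a$aromatic[j], FALSE))
        h_v <- h * (if (acid) 0.298 else -0.2677)
      } else if (d >= 1L) {
        cc <- .double_bond_partners(mol, i)[1L]
        if (el[cc] %in% c("N", "O")) v <- 0.0335
        else if (el[cc] == "S") v <- -0.3339
        else if (a$aromatic[cc]) v <- 0.1788
        else {
          cnb <- nbrs[[cc]]
          cnb <- cnb[cnb != i]
          if (any(a$aromatic[cnb])) v <- 0.1129
          else if (any(!el[cnb] %in% c("C", "H"))) {
            v <- if (all(!el[cnb] %in% c("C", "H")) && length(cnb) == 2L)
              0.4833 else -0.1526
          } else v <- -0.1526
        }
      } else {
        v <- if (any(nb_arom)) -0.4195 else -0.0684
      }
      if (h == 0L || q != 0L) h_v <- 0
    } else if (e == "F") {
      v <- if (q == 0L) 0.4202 else -2.996
    } else if (e == "Cl") {
      v <- if (q == 0L) 0.6895 else -2.996
    } else if (e == "Br") {
      v <- if (q == 0L) 0.8456 else -2.996
    } else if (e == "I") {
      v <- if (q == 0L) 0.8857 else -2.996
    } else if (e == "P") {
      v <- 0.8612
    } else if (e == "S") {
      v <- if (a$aromatic[i]) 0.6237
           else if (q != 0L || any(el[.double_bond_partners(mol, i)] %in%
                                     c("N", "O", "P", "S"))) -0.0024
           else 0.6482
      h_v <- h * (-0.2677)
    } else {
      # element-level default for untyped environments
      v <- 0.08129
      h_v <- h * 0.1125
      warning("logp_atomic: element '", e,
              "' outside the typed set; using element default")
    }
    if (is.na(v)) {
      v <- switch(e, C = 0.08129, N = -0.4806, O = -0.1188, 0.0)
      warning("logp_atomic: untyped ", e, " environment at atom ", i,
              "; using element default")
    }
    out[i] <- v + h_v
  }
  out
}

# neighbors of i connected by a double bond
.double_bond_partners <- function(mol, i) {
  b <- mol$bonds
  k <- which((b$a == i | b$b == i) & b$order == "double")
  if (length(k) == 0L) return(integer(0))
  ifelse(b$a[k] == i, b$b[k], b$a[k])
}

# neighbors of i connected by a non-aromatic bond
.nonaromatic_neighbors <- function(mol, i) {
  b <- mol$bonds
  k <- which((b$a == i | b$b == i) & b$order != "aromatic")
  if (length(k) == 0L) return(integer(0))
  ifelse(b$a[k] == i, b$b[k], b$a[k])
}

#' Estimated percentage oral absorption
#'
#' The linear absorption model `\%Ab = 109 - 0.345 * TPSA`. Very polar
#' molecules can produce negative estimates; no clamping is applied.
#'
#' @param tpsa TPSA in squared Angstrom (non-negative).
#' @return Percent absorption.
#' @export
percent_absorption <- function(tpsa) {
  if (any(tpsa < 0)) stop("tpsa must be non-negative")
  109 - 0.345 * tpsa
}

#' Full descriptor set for one molecule
#'
#' @param mol A [Molecule].
#' @return A `DescriptorSet` (named list): `mw`, `logp`, `tpsa`, `n_on`,
#'   `n_ohnh`, `n_rotb`, `n_atoms` (heavy atoms), `pct_ab`.
#' @export
descriptor_set <- function(mol) {
  tpsa <- tpsa_ertl(mol)
  structure(list(
    name = mol$name,
    mw = molecular_weight(mol),
    logp = logp_atomic(mol),
    tpsa = tpsa,
    n_on = count_n_on(mol),
    n_ohnh = count_n_ohnh(mol),
    n_rotb = count_rotatable_bonds(mol),
    n_atoms = nrow(mol$atoms),
    pct_ab = percent_absorption(tpsa)
  ), class = "DescriptorSet")
}

#' @export
print.DescriptorSet <- function(x, ...) {
  cat(sprintf(
    "<DescriptorSet %s: MW %.3f, logP %.2f, TPSA %.2f, nON %d, nOHNH %d, nrotb %d, %%Ab %.2f>\n",
    x$name, x$mw, x$logp, x$tpsa, x$n_on, x$n_ohnh, x$n_rotb, x$pct_ab))
  invisible(x)
}

#' Descriptor table for a list of molecules
#'
#' Computes [descriptor_set()] per molecule, in input order. Per-molecule
#' failures become error rows (NA descriptors, message in `error`); the
#' remaining rows are still produced.
#'
#' @param mols List of [Molecule] objects (or SMILES strings, which are
#'   parsed first).
#' @return A data frame with one row per input molecule.
#' @export
descriptor_table <- function(mols) {
  if (length(mols) == 0L)
    return(data.frame(id = character(0), smiles = character(0),
                      mw = numeric(0), logp = numeric(0), tpsa = numeric(0),
                      n_on = integer(0), n_ohnh = integer(0),
                      n_rotb = integer(0), n_atoms = integer(0),
                      pct_ab = numeric(0), error = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_along(mols), function(i) {
    m <- mols[[i]]
    res <- tryCatch({
      if (is.character(m)) {
        nm <- if (!is.null(names(mols)) && nzchar(names(mols)[i]))
          names(mols)[i] else paste0("mol", i)
        m <- parse_smiles(m, nm)
      }
      d <- descriptor_set(m)
      data.frame(id = d$name, smiles = if (!is.null(m$smiles)) m$smiles
                 else write_smiles(m),
                 mw = d$mw, logp = d$logp, tpsa = d$tpsa, n_on = d$n_on,
                 n_ohnh = d$n_ohnh, n_rotb = d$n_rotb, n_atoms = d$n_atoms,
                 pct_ab = d$pct_ab, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      nm <- if (inherits(m, "Molecule")) m$name
            else if (!is.null(names(mols)) && nzchar(names(mols)[i]))
              names(mols)[i] else paste0("mol", i)
      data.frame(id = nm, smiles = if (is.character(m)) m else NA_character_,
                 mw = NA_real_, logp = NA_real_, tpsa = NA_real_,
                 n_on = NA_integer_, n_ohnh = NA_integer_,
                 n_rotb = NA_integer_, n_atoms = NA_integer_,
                 pct_ab = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
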