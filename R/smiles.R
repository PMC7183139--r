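# SMILES reader: organic subset + bracket atoms, branches, ring closures,
# aromatic lowercase notation, charges, explicit H counts, disconnected
# components ('.'). Stereo marks (@, @@, /, \) are parsed and retained on the
# atom/bond records but play no role in any downstream computation.

#' Parse a SMILES string into a Molecule
#'
#' Builds an attributed molecular graph from a SMILES string: atoms with
#' element, formal charge, implicit hydrogen count and aromatic flag; bonds
#' with order and ring membership. Aromatic perception follows the lowercase
#' notation of the input; every lowercase atom must end up in a ring,
#' otherwise parsing fails. Implicit hydrogens on organic-subset atoms are
#' assigned from the lowest standard valence consistent with the explicit
#' bonds; bracket atoms carry exactly the hydrogen count written.
#'
#' @param smiles SMILES string (non-empty).
#' @param name Identifier attached to the molecule (default `""`).
#' @return A [Molecule] object.
#' @examples
#' m <- parse_smiles("CCO", "ethanol")
#' molecular_formula(m)
#' @export
parse_smiles <- function(smiles, name = "") {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("smiles must be a non-empty string")
  s <- smiles
  n <- nchar(s)
  atoms <- list()     # each: list(element, charge, h_explicit, aromatic, stereo, bracket)
  bonds <- list()     # each: list(a, b, order, explicit_order)
  prev <- NA_integer_ # index of previous atom
  pending_bond <- NULL   # bond symbol awaiting the next atom
  branch_stack <- integer(0)
  ring_open <- list()    # digit label -> list(atom, order)

  add_atom <- function(el, charge, h, aromatic, stereo, bracket) {
    atoms[[length(atoms) + 1L]] <<- list(element = el, charge = charge,
                                         h_explicit = h, aromatic = aromatic,
                                         stereo = stereo, bracket = bracket)
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- pending_bond
      add_bond(prev, idx, ord)
    }
    pending_bond <<- NULL
    prev <<- idx
    idx
  }
  add_bond <- function(a, b, sym) {
    if (a == b) stop("ring-bond closure onto the same atom near '", sym, "'")
    explicit <- !is.null(sym)
    ord <- if (is.null(sym)) "default" else switch(sym,
      "-" = "single", "=" = "double", "#" = "triple", ":" = "aromatic",
      "/" = "single", "\\" = "single",
      stop("unknown bond symbol '", sym, "'"))
    bonds[[length(bonds) + 1L]] <<- list(a = a, b = b, order = ord,
                                         explicit_order = explicit)
  }

  i <- 1L
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      if (is.na(prev)) stop("branch open '(' before any atom at position ", i)
      branch_stack <- c(branch_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(branch_stack) == 0L)
        stop("unmatched ')' at position ", i)
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      i <- i + 1L
    } else if (ch == ".") {
      if (!is.null(pending_bond)) stop("bond symbol before '.' at position ", i)
      prev <- NA_integer_
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (is.na(prev)) stop("ring-bond digit before any atom at position ", i)
      if (ch == "%") {
        lab <- substr(s, i + 1L, i + 2L)
        if (!grepl("^[0-9][0-9]$", lab))
          stop("malformed '%' ring label at position ", i)
        i <- i + 3L
      } else {
        lab <- ch
        i <- i + 1L
      }
      if (!is.null(ring_open[[lab]])) {
        op <- ring_open[[lab]]
        sym <- if (!is.null(pending_bond)) pending_bond else op$sym
        if (!is.null(pending_bond) && !is.null(op$sym) &&
            pending_bond != op$sym)
          stop("conflicting bond orders on ring closure '", lab, "'")
        add_bond(op$atom, prev, sym)
        ring_open[[lab]] <- NULL
        pending_bond <- NULL
      } else {
        ring_open[[lab]] <- list(atom = prev, sym = pending_bond)
        pending_bond <- NULL
      }
    } else if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unterminated bracket atom at position ", i)
      tok <- substr(s, i, i + j - 1L)
      at <- .parse_bracket_atom(tok)
      add_atom(at$element, at$charge, at$h, at$aromatic, at$stereo, TRUE)
      i <- i + j
    } else {
      # organic-subset atom (two-letter first)
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        add_atom(two, 0L, NA_integer_, FALSE, "", FALSE)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, 0L, NA_integer_, FALSE, "", FALSE)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), 0L, NA_integer_, TRUE, "", FALSE)
        i <- i + 1L
      } else {
        stop("unparsable token '", ch, "' at position ", i)
      }
    }
  }
  if (length(branch_stack) > 0L) stop("unclosed branch '(' in '", smiles, "'")
  if (length(ring_open) > 0L)
    stop("unclosed ring bond (label ", paste(names(ring_open), collapse = ","),
         ") in '", smiles, "'")
  if (length(atoms) == 0L) stop("no atoms parsed from '", smiles, "'")

  adf <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    implicit_h = vapply(atoms, `[[`, 0L, "h_explicit"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    stereo = vapply(atoms, `[[`, "", "stereo"),
    bracket = vapply(atoms, `[[`, FALSE, "bracket"),
    stringsAsFactors = FALSE
  )
  if (length(bonds) > 0L) {
    bdf <- data.frame(
      a = vapply(bonds, `[[`, 0L, "a"),
      b = vapply(bonds, `[[`, 0L, "b"),
      order = vapply(bonds, `[[`, "", "order"),
      explicit_order = vapply(bonds, `[[`, FALSE, "explicit_order"),
      stringsAsFactors = FALSE
    )
  } else {
    bdf <- data.frame(a = integer(0), b = integer(0), order = character(0),
                      explicit_order = logical(0), stringsAsFactors = FALSE)
  }

  # ring perception: a bond is in a ring iff it is not a bridge
  bdf$in_ring <- .ring_bond_flags(nrow(adf), bdf)

  # default-order bonds between two aromatic ring atoms become aromatic
  if (nrow(bdf) > 0L) {
    arom_bond <- bdf$order == "default" & bdf$in_ring &
      adf$aromatic[bdf$a] & adf$aromatic[bdf$b]
    bdf$order[arom_bond] <- "aromatic"
    bdf$order[bdf$order == "default"] <- "single"
  }

  # aromatic atoms must sit in a ring
  if (any(adf$aromatic)) {
    ring_atoms <- unique(c(bdf$a[bdf$in_ring], bdf$b[bdf$in_ring]))
    stray <- which(adf$aromatic & !(seq_len(nrow(adf)) %in% ring_atoms))
    if (length(stray) > 0L)
      stop("aromatic atom ", stray[1L], " ('",
           tolower(adf$element[stray[1L]]), "') is not in a ring")
  }

  # implicit hydrogens for organic-subset atoms + valence check
  adf$implicit_h <- .assign_implicit_h(adf, bdf)
  bdf$explicit_order <- NULL

  new_molecule(name = name, atoms = adf, bonds = bdf, smiles = smiles)
}

# Parse one bracket-atom token "[...]" into its fields.
.parse_bracket_atom <- function(tok) {
  body <- substr(tok, 2L, nchar(tok) - 1L)
  m <- regexec(
    "^([0-9]+)?([A-Za-z][a-z]?|\\*)(@@|@)?(H([0-9]+)?)?(\\+[0-9]+|-[0-9]+|\\++|-+)?(:[0-9]+)?$",
    body)
  g <- regmatches(body, m)[[1L]]
  if (length(g) == 0L) stop("unparsable bracket atom '", tok, "'")
  sym <- g[3L]
  if (sym == "*") stop("wildcard atom '*' is not supported: '", tok, "'")
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  el <- if (aromatic) {
    paste0(toupper(substr(sym, 1L, 1L)), substr(sym, 2L, nchar(sym)))
  } else sym
  if (!el %in% names(.ATOMIC_WEIGHTS))
    stop("unknown element '", sym, "' in bracket atom '", tok, "'")
  h <- if (g[5L] == "") 0L else if (g[6L] == "") 1L else as.integer(g[6L])
  chg_tok <- g[7L]
  charge <- if (chg_tok == "") {
    0L
  } else if (grepl("^[+-][0-9]+$", chg_tok)) {
    as.integer(chg_tok)
  } else {
    sgn <- if (substr(chg_tok, 1L, 1L) == "+") 1L else -1L
    sgn * nchar(chg_tok)
  }
  list(element = el, charge = charge, h = h, aromatic = aromatic,
       stereo = g[4L])
}

# Bridge detection via iterative DFS: ring bonds are the non-bridges.
.ring_bond_flags <- function(n_atoms, bonds) {
  nb <- nrow(bonds)
  if (nb == 0L) return(logical(0))
  adj <- vector("list", n_atoms)
  for (k in seq_len(nb)) {
    adj[[bonds$a[k]]] <- c(adj[[bonds$a[k]]], k)
    adj[[bonds$b[k]]] <- c(adj[[bonds$b[k]]], k)
  }
  disc <- integer(n_atoms); low <- integer(n_atoms)
  visited <- logical(n_atoms)
  is_bridge <- logical(nb)
  timer <- 0L
  for (root in seq_len(n_atoms)) {
    if (visited[root]) next
    # stack frames: (vertex, parent-bond, next-neighbor-pointer)
    stack <- list(list(v = root, pb = 0L, ptr = 1L))
    timer <- timer + 1L
    visited[root] <- TRUE; disc[root] <- timer; low[root] <- timer
    while (length(stack) > 0L) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$ptr <= length(adj[[v]])) {
        k <- adj[[v]][fr$ptr]
        stack[[length(stack)]]$ptr <- fr$ptr + 1L
        if (k == fr$pb) next
        w <- if (bonds$a[k] == v) bonds$b[k] else bonds$a[k]
        if (visited[w]) {
          low[v] <- min(low[v], disc[w])
        } else {
          timer <- timer + 1L
          visited[w] <- TRUE; disc[w] <- timer; low[w] <- timer
          stack[[length(stack) + 1L]] <- list(v = w, pb = k, ptr = 1L)
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (fr$pb > 0L) {
          k <- fr$pb
          u <- if (bonds$a[k] == v) bonds$b[k] else bonds$a[k]
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) is_bridge[k] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

# Implicit hydrogen assignment and valence sanity check.
# Aromatic bonds count 1.5 toward the bond-order sum; the sum is ceiled
# before comparison with the allowed valences.
.assign_implicit_h <- function(atoms, bonds) {
  n <- nrow(atoms)
  bsum <- numeric(n)
  bsigma <- numeric(n)  # aromatic bonds counted 1 (sigma skeleton)
  if (nrow(bonds) > 0L) {
    w <- c(single = 1, double = 2, triple = 3, aromatic = 1.5, default = 1)
    ws <- c(single = 1, double = 2, triple = 3, aromatic = 1, default = 1)
    for (k in seq_len(nrow(bonds))) {
      for (e in c(bonds$a[k], bonds$b[k])) {
        bsum[e] <- bsum[e] + w[[bonds$order[k]]]
        bsigma[e] <- bsigma[e] + ws[[bonds$order[k]]]
      }
    }
  }
  out <- atoms$implicit_h
  for (i in seq_len(n)) {
    el <- atoms$element[i]
    need <- as.integer(ceiling(bsum[i] - 1e-9))
    if (atoms$bracket[i]) {
      # bracket atoms: H count is exactly as written; only check valence.
      # Aromatic bracket atoms (e.g. pyrrole [nH]) are checked against the
      # sigma skeleton: their lone pair or half pi bond carries no H cost.
      tot <- (if (atoms$aromatic[i]) as.integer(bsigma[i]) else need) + out[i]
      vmax <- .max_valence(el, atoms$charge[i])
      if (!is.na(vmax) && tot > vmax)
        stop("impossible valence for atom ", i, " (", el,
             if (atoms$charge[i] != 0) sprintf("%+d", atoms$charge[i]) else "",
             "): ", tot, " > ", vmax)
      next
    }
    vals <- .DEFAULT_VALENCES[[el]]
    if (is.null(vals)) { out[i] <- 0L; next }
    if (atoms$aromatic[i]) vals <- vals[1L]  # no hypervalent aromatic atoms
    fit <- vals[vals >= need]
    if (length(fit) == 0L) {
      if (atoms$aromatic[i]) { out[i] <- 0L; next }
      stop("impossible valence for atom ", i, " (", el, "): bond order sum ",
           bsum[i], " exceeds ", max(vals))
    }
    out[i] <- as.integer(fit[1L] - need)
  }
  out
}

# Maximum total valence allowed for a (element, charge) pair; NA = no check.
.max_valence <- function(element, charge) {
  base <- switch(element,
    C = 4L, B = 3L, N = 3L, O = 2L, P = 5L, S = 6L,
    F = 1L, Cl = 7L, Br = 7L, I = 7L, NA_integer_)
  if (is.na(base)) return(NA_integer_)
  if (element == "N") return(base + as.integer(charge))   # N+: 4, N-: 2
  if (element == "O") return(base + as.integer(charge))   # O+: 3, O-: 1
  if (element == "C") return(base - abs(as.integer(charge)))
  base
}
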