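# SMILES output. Atom ordering is fixed by iterative neighborhood-invariant
# refinement (Morgan-style), so a given molecular graph always serializes
# identically. Stereochemistry is not emitted.

#' Write a molecule as a SMILES string
#'
#' Deterministic serialization of the molecular graph. Atoms are visited in
#' an order fixed by refined neighborhood invariants; implicit hydrogens are
#' re-derived by the reader, with bracket notation forced wherever the
#' organic-subset defaults would not reproduce the stored hydrogen count or
#' charge. Round-tripping preserves formula and net charge.
#'
#' @param mol A [Molecule].
#' @return SMILES string.
#' @export
write_smiles <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  n <- nrow(a)
  rk <- .canonical_ranks(mol)
  adj <- vector("list", n)  # rows: (neighbor, bond row)
  if (nrow(b) > 0L) {
    for (k in seq_len(nrow(b))) {
      adj[[b$a[k]]] <- rbind(adj[[b$a[k]]], c(b$b[k], k))
      adj[[b$b[k]]] <- rbind(adj[[b$b[k]]], c(b$a[k], k))
    }
  }
  for (i in seq_len(n)) {
    if (NROW(adj[[i]]) > 1L)
      adj[[i]] <- adj[[i]][order(rk[adj[[i]][, 1L]], adj[[i]][, 1L]), ,
                           drop = FALSE]
  }

  # --- pass A: spanning forest + ring-closure digit assignment ------------
  visited <- logical(n)
  children <- vector("list", n)      # bond rows of tree children
  ring_at <- vector("list", n)       # (digit, bond row) pairs per atom
  next_digit <- 1L
  roots <- integer(0)
  for (root in order(rk, seq_len(n))) {
    if (visited[root]) next
    roots <- c(roots, root)
    used <- logical(nrow(b))
    stack <- root
    visited[root] <- TRUE
    order_stack <- list(root)
    # explicit DFS keeping traversal order identical to emission order
    dfs <- function(v) {
      nb <- adj[[v]]
      for (r in seq_len(NROW(nb))) {
        k <- nb[r, 2L]
        if (used[k]) next
        w <- nb[r, 1L]
        if (visited[w]) {
          used[k] <<- TRUE
          d <- next_digit; next_digit <<- next_digit + 1L
          ring_at[[w]] <<- rbind(ring_at[[w]], c(d, k))
          ring_at[[v]] <<- rbind(ring_at[[v]], c(d, k))
        } else {
          used[k] <<- TRUE
          visited[w] <<- TRUE
          children[[v]] <<- c(children[[v]], k)
          dfs(w)
        }
      }
    }
    dfs(root)
  }

  # --- pass B: emission ----------------------------------------------------
  bond_sym <- function(k) {
    ord <- b$order[k]
    if (ord == "double") return("=")
    if (ord == "triple") return("#")
    if (ord == "aromatic") return("")
    if (a$aromatic[b$a[k]] && a$aromatic[b$b[k]]) return("-")
    ""
  }
  atom_token <- function(i) {
    el <- a$element[i]
    sym <- if (a$aromatic[i]) tolower(el) else el
    organic <- el %in% .ORGANIC_SUBSET
    need_bracket <- !organic || a$charge[i] != 0L ||
      a$implicit_h[i] != .implied_h(mol, i)
    if (!need_bracket) return(sym)
    h <- a$implicit_h[i]
    htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    q <- a$charge[i]
    qtok <- if (q == 0L) "" else if (q == 1L) "+" else if (q == -1L) "-"
            else sprintf("%+d", q)
    paste0("[", sym, htok, qtok, "]")
  }
  emitted <- logical(n)
  emit <- function(i, from_bond) {
    out <- if (is.na(from_bond)) "" else bond_sym(from_bond)
    out <- paste0(out, atom_token(i))
    emitted[i] <<- TRUE
    ra <- ring_at[[i]]
    for (r in seq_len(NROW(ra))) {
      k <- ra[r, 2L]
      other <- if (b$a[k] == i) b$b[k] else b$a[k]
      # bond symbol printed on the closing side only
      sym <- if (emitted[other]) bond_sym(k) else ""
      out <- paste0(out, sym, .digit_token(ra[r, 1L]))
    }
    ch <- children[[i]]
    if (length(ch) > 0L) {
      for (ci in seq_along(ch)) {
        k <- ch[[ci]]
        w <- if (b$a[k] == i) b$b[k] else b$a[k]
        sub <- emit(w, k)
        if (ci < length(ch)) sub <- paste0("(", sub, ")")
        out <- paste0(out, sub)
      }
    }
    out
  }
  paste(vapply(roots, function(r) emit(r, NA_integer_), ""), collapse = ".")
}

.digit_token <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)

# implicit H count the reader would assign to atom i without brackets
.implied_h <- function(mol, i) {
  el <- mol$atoms$element[i]
  vals <- .DEFAULT_VALENCES[[el]]
  if (is.null(vals)) return(-1L)
  if (mol$atoms$aromatic[i]) vals <- vals[1L]
  b <- mol$bonds
  w <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
  bs <- 0
  if (nrow(b) > 0L) {
    inc <- b$a == i | b$b == i
    bs <- sum(w[b$order[inc]])
  }
  need <- as.integer(ceiling(bs - 1e-9))
  fit <- vals[vals >= need]
  if (length(fit) == 0L) return(0L)
  as.integer(fit[1L] - need)
}

# Morgan-style iterative refinement; returns an integer rank per atom.
.canonical_ranks <- function(mol) {
  a <- mol$atoms
  n <- nrow(a)
  key <- paste(a$element, a$charge, a$implicit_h, a$aromatic,
               .heavy_degree(mol), sep = "|")
  rk <- as.integer(factor(key, levels = sort(unique(key))))
  b <- mol$bonds
  if (nrow(b) == 0L) return(rk)
  for (iter in seq_len(n)) {
    nbkey <- vapply(seq_len(n), function(i) {
      nb <- c(b$b[b$a == i], b$a[b$b == i])
      paste(sort(rk[nb]), collapse = ",")
    }, "")
    key2 <- paste(rk, nbkey, sep = ";")
    rk2 <- as.integer(factor(key2, levels = sort(unique(key2))))
    if (identical(rk2, rk)) break
    rk <- rk2
  }
  rk
}
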