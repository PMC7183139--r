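# Ring enumeration: smallest ring through each ring bond, deduplicated.
# Adequate as an SSSR stand-in for drug-sized molecules.

#' Enumerate smallest rings of a molecule
#'
#' For every ring bond, finds the smallest cycle containing it (breadth-first
#' search in the ring-bond subgraph) and deduplicates by atom set.
#'
#' @param mol A [Molecule].
#' @return List of integer vectors, each an atom-index cycle in ring order.
#' @export
perceive_rings <- function(mol) {
  b <- mol$bonds
  rb <- which(b$in_ring)
  if (length(rb) == 0L) return(list())
  n <- nrow(mol$atoms)
  # adjacency restricted to ring bonds
  adj <- vector("list", n)
  for (k in rb) {
    adj[[b$a[k]]] <- rbind(adj[[b$a[k]]], c(b$b[k], k))
    adj[[b$b[k]]] <- rbind(adj[[b$b[k]]], c(b$a[k], k))
  }
  rings <- list()
  seen <- character(0)
  for (k in rb) {
    s <- b$a[k]; t <- b$b[k]
    # BFS from s to t avoiding bond k
    parent <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0L && is.na(dist[t])) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      for (r in seq_len(NROW(nb))) {
        if (nb[r, 2L] == k) next
        w <- nb[r, 1L]
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          parent[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[t])) next
    path <- t
    while (path[length(path)] != s) path <- c(path, parent[path[length(path)]])
    key <- paste(sort(path), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

# indices of atoms that are members of any ring of the given size
.atoms_in_ring_size <- function(rings, size) {
  unique(unlist(rings[vapply(rings, length, 0L) == size], use.names = FALSE))
}

# rings whose atoms are all aromatic
.aromatic_rings <- function(mol, rings = perceive_rings(mol)) {
  rings[vapply(rings, function(r) all(mol$atoms$aromatic[r]), FALSE)]
}
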