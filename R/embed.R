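# Seeded 3D conformer embedding by distance-geometry stress minimization.
#
# Targets: idealized bond lengths (covalent radii scaled by bond order),
# 1-3 distances from idealized angles (law of cosines), and a lower-bound
# hinge on all remaining pairs. Coordinates are initialized from a seeded
# Gaussian cloud and minimized with BFGS, so identical (molecule, n, seed)
# inputs give bit-identical conformers while different seeds land in
# different torsional minima.

.BOND_ORDER_SCALE <- c(single = 1.00, double = 0.87, triple = 0.78,
                       aromatic = 0.91)

# ideal length of bond row k (Angstrom)
.ideal_bond_length <- function(mol, k) {
  b <- mol$bonds
  r <- .COVALENT_RADII[c(mol$atoms$element[b$a[k]],
                         mol$atoms$element[b$b[k]])]
  sum(r) * .BOND_ORDER_SCALE[[b$order[k]]]
}

# idealized bond angle (radians) at atom j: sp 180, sp2 120, sp3 109.47
.ideal_angle_at <- function(mol, j, env) {
  if (env[j, "t"] > 0L || env[j, "d"] >= 2L) return(pi)
  if (env[j, "d"] == 1L || env[j, "a"] > 0L) return(2 * pi / 3)
  109.47 * pi / 180
}

# distance-target table for the stress function
.dg_targets <- function(mol) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  env <- .atom_env(mol)
  blen <- vapply(seq_len(nrow(b)), function(k) .ideal_bond_length(mol, k), 0)
  ti <- b$a; tj <- b$b; tt <- blen; tw <- rep(10, nrow(b))
  hinge <- rep(FALSE, nrow(b))
  # 1-3 pairs through every central atom
  nbr <- lapply(seq_len(n), function(i) {
    k <- which(b$a == i | b$b == i)
    cbind(ifelse(b$a[k] == i, b$b[k], b$a[k]), k)
  })
  seen <- new.env(hash = TRUE)
  for (j in seq_len(n)) {
    nb <- nbr[[j]]
    if (NROW(nb) < 2L) next
    ang <- .ideal_angle_at(mol, j, env)
    for (p in seq_len(nrow(nb) - 1L)) {
      for (q in seq(p + 1L, nrow(nb))) {
        i <- nb[p, 1L]; k2 <- nb[q, 1L]
        key <- paste(min(i, k2), max(i, k2))
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        l1 <- blen[nb[p, 2L]]; l2 <- blen[nb[q, 2L]]
        d13 <- sqrt(l1^2 + l2^2 - 2 * l1 * l2 * cos(ang))
        ti <- c(ti, i); tj <- c(tj, k2); tt <- c(tt, d13)
        tw <- c(tw, 3); hinge <- c(hinge, FALSE)
      }
    }
  }
  # lower-bound hinges on all remaining pairs
  bonded_key <- paste(pmin(ti, tj), pmax(ti, tj))
  if (n >= 2L) {
    all_pairs <- utils::combn(n, 2L)
    keys <- paste(all_pairs[1L, ], all_pairs[2L, ])
    rest <- which(!keys %in% bonded_key)
    if (length(rest) > 0L) {
      ti <- c(ti, all_pairs[1L, rest]); tj <- c(tj, all_pairs[2L, rest])
      tt <- c(tt, rep(2.4, length(rest)))
      tw <- c(tw, rep(1, length(rest)))
      hinge <- c(hinge, rep(TRUE, length(rest)))
    }
  }
  list(i = ti, j = tj, target = tt, weight = tw, hinge = hinge)
}

.dg_stress <- function(x, tg, n) {
  X <- matrix(x, n, 3L)
  D <- X[tg$i, , drop = FALSE] - X[tg$j, , drop = FALSE]
  d <- sqrt(rowSums(D * D))
  r <- d - tg$target
  r[tg$hinge & r > 0] <- 0
  sum(tg$weight * r * r)
}

.dg_gradient <- function(x, tg, n) {
  X <- matrix(x, n, 3L)
  D <- X[tg$i, , drop = FALSE] - X[tg$j, , drop = FALSE]
  d <- sqrt(rowSums(D * D))
  r <- d - tg$target
  r[tg$hinge & r > 0] <- 0
  cf <- 2 * tg$weight * r / pmax(d, 1e-8)
  GD <- D * cf
  acc <- rowsum(rbind(GD, -GD), group = c(tg$i, tg$j))
  G <- matrix(0, n, 3L)
  G[as.integer(rownames(acc)), ] <- acc
  as.vector(G)
}

#' Embed seeded 3D conformers
#'
#' Generates `n` conformers by seeded distance-geometry stress minimization.
#' Conformer `k` depends only on (molecule, seed, k), so the first conformer
#' of an ensemble is identical regardless of `n`. Coordinates are in
#' Angstrom, one row per atom (hydrogens stay implicit).
#'
#' @param mol A [Molecule].
#' @param n Number of conformers (0 allowed, returning the molecule with an
#'   empty conformer list).
#' @param seed Integer random seed.
#' @return The molecule with `n` conformers attached.
#' @export
embed_conformers <- function(mol, n = 1L, seed = 42L) {
  if (n < 0L) stop("n must be >= 0")
  mol$conformers <- list()
  if (n == 0L) return(mol)
  na <- nrow(mol$atoms)
  tg <- .dg_targets(mol)
  for (k in seq_len(n)) {
    mol$conformers[[k]] <- .embed_one(mol, tg, na, seed, k)
  }
  mol
}

.embed_one <- function(mol, tg, na, seed, k) {
  base <- (as.integer(seed) %% 1000003L) * 1009L + k * 7919L
  for (attempt in 0:4) {
    sk <- (base + attempt * 104729L) %% 2147483647L
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(sk)
    X0 <- matrix(stats::rnorm(na * 3L, sd = 1.2 * max(1, na)^(1/3)), na, 3L)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    if (na == 1L) return(matrix(0, 1L, 3L))
    # stage 1: bonds and angles only
    tg1 <- lapply(tg, function(v) v[!tg$hinge])
    fit1 <- stats::optim(as.vector(X0), .dg_stress, .dg_gradient,
                         tg = tg1, n = na, method = "BFGS",
                         control = list(maxit = 250L, reltol = 1e-10))
    # stage 2: full target set including steric lower bounds
    fit2 <- stats::optim(fit1$par, .dg_stress, .dg_gradient,
                         tg = tg, n = na, method = "BFGS",
                         control = list(maxit = 300L, reltol = 1e-12))
    X <- matrix(fit2$par, na, 3L)
    if (.bonds_sane(mol, X)) return(X)
  }
  stop("conformer embedding failed for '", mol$name,
       "' after bounded retries")
}

# all bond lengths within the chemically plausible 0.6-2.0 Angstrom window
.bonds_sane <- function(mol, X) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(TRUE)
  d <- sqrt(rowSums((X[b$a, , drop = FALSE] - X[b$b, , drop = FALSE])^2))
  all(d > 0.6 & d < 2.0)
}

#' Add Gaussian noise to conformer coordinates
#'
#' Deterministic per seed. Used for matcher tolerance testing.
#'
#' @param mol A [Molecule] with at least one conformer.
#' @param sigma Noise standard deviation in Angstrom (>= 0).
#' @param seed Integer random seed.
#' @return The molecule with every conformer independently perturbed.
#' @export
perturb_conformer <- function(mol, sigma, seed = 1L) {
  if (length(mol$conformers) == 0L) stop("molecule has no conformer")
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(mol)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% 2147483647L)
  mol$conformers <- lapply(mol$conformers, function(cf)
    cf + matrix(stats::rnorm(length(cf), sd = sigma), nrow(cf), 3L))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  mol
}
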