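# Independent oracles and generators shared across the suite.
# These deliberately avoid the package's own code paths: the superposition
# uses Horn's quaternion method (the package uses SVD Kabsch) and the
# assignment search is plain exhaustive enumeration without pruning.

# Horn closed-form absolute orientation: superpose P onto Q (rows = points)
horn_superpose <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- t(Pc) %*% Qc
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  aligned <- Pc %*% t(R)
  list(aligned = sweep(aligned, 2, cq, `+`),
       rmsd = sqrt(mean(rowSums((aligned - Qc)^2))),
       R = t(R), t = cq - as.numeric(cp %*% t(R)))
}

# exhaustive injective assignment search; same acceptance contract as the
# matcher (deviation <= max(radius, tol) + 1e-9, zero exclusion clashes)
brute_force_match <- function(ligand_features, model, tolerance = 1.5,
                              ligand_coords = NULL) {
  mf <- model$features[model$features$kind != "exclusion", , drop = FALSE]
  ex <- model$features[model$features$kind == "exclusion", , drop = FALSE]
  lf <- ligand_features
  nm <- nrow(mf)
  if (is.null(lf) || nrow(lf) == 0L)
    return(list(matched = FALSE, rmsd = NA_real_))
  Mx <- as.matrix(mf[, c("x", "y", "z")])
  Lx <- as.matrix(lf[, c("x", "y", "z")])
  best <- Inf
  found <- FALSE
  assign_rec <- function(pos, used) {
    if (pos > nm) {
      idx <- used
      fit <- horn_superpose(Lx[idx, , drop = FALSE], Mx)
      devs <- sqrt(rowSums((fit$aligned - Mx)^2))
      if (any(devs > pmax(mf$radius, tolerance) + 1e-9)) return(invisible())
      if (nrow(ex) > 0L && !is.null(ligand_coords)) {
        AX <- sweep(ligand_coords %*% fit$R, 2, fit$t, `+`)
        for (e in seq_len(nrow(ex))) {
          de <- sqrt(rowSums((AX - matrix(
            as.numeric(ex[e, c("x", "y", "z")]), nrow(AX), 3,
            byrow = TRUE))^2))
          if (any(de < ex$radius[e])) return(invisible())
        }
      }
      found <<- TRUE
      if (fit$rmsd < best) best <<- fit$rmsd
      return(invisible())
    }
    for (ci in seq_len(nrow(lf))) {
      if (ci %in% used) next
      if (lf$kind[ci] != mf$kind[pos]) next
      assign_rec(pos + 1L, c(used, ci))
    }
    invisible()
  }
  assign_rec(1L, integer(0))
  list(matched = found, rmsd = if (found) best else NA_real_)
}

# random synthetic feature-matching instance; roughly half are solvable
# perturbed copies of the model, half unrelated clouds
random_match_instance <- function(seed) {
  set.seed(seed)
  n_model <- sample(3:5, 1)
  kinds <- sample(c("donor", "acceptor", "hydrophobic"), n_model,
                  replace = TRUE)
  centers <- matrix(runif(n_model * 3, -4, 4), n_model, 3)
  feats <- do.call(rbind, lapply(seq_len(n_model), function(i)
    data.frame(label = paste0("f", i), kind = kinds[i],
               x = centers[i, 1], y = centers[i, 2], z = centers[i, 3],
               radius = 1.5, dx = NA_real_, dy = NA_real_, dz = NA_real_,
               source_atoms = "", stringsAsFactors = FALSE)))
  model <- new_pharmacophore_model(paste0("rand", seed), feats)
  n_lig <- sample(n_model:8, 1)
  if (runif(1) < 0.5) {
    # solvable: perturbed, rigidly moved copy of the model plus distractors
    base <- centers + matrix(rnorm(n_model * 3, sd = 0.3), n_model, 3)
    extra <- n_lig - n_model
    lig_kinds <- c(kinds, sample(c("donor", "acceptor", "hydrophobic"),
                                 extra, replace = TRUE))
    L <- rbind(base, matrix(runif(extra * 3, -6, 6), extra, 3))
    th <- runif(3, 0, 2 * pi)
    R <- rot3(th)
    L <- sweep(L %*% R, 2, runif(3, -5, 5), `+`)
  } else {
    lig_kinds <- sample(c("donor", "acceptor", "hydrophobic"), n_lig,
                        replace = TRUE)
    L <- matrix(runif(n_lig * 3, -6, 6), n_lig, 3)
  }
  lf <- do.call(rbind, lapply(seq_len(n_lig), function(i)
    data.frame(label = paste0("l", i), kind = lig_kinds[i],
               x = L[i, 1], y = L[i, 2], z = L[i, 3], radius = 1.5,
               dx = NA_real_, dy = NA_real_, dz = NA_real_,
               source_atoms = "", stringsAsFactors = FALSE)))
  list(model = model, ligand_features = lf)
}

# rotation matrix from three Euler angles
rot3 <- function(th) {
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3, 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                 sin(th[2]), 0, cos(th[2])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

# apply a random rigid motion to all conformers of a molecule
rigidly_move <- function(mol, seed) {
  set.seed(seed)
  R <- rot3(runif(3, 0, 2 * pi))
  tr <- runif(3, -8, 8)
  mol$conformers <- lapply(mol$conformers, function(X)
    sweep(X %*% R, 2, tr, `+`))
  mol
}

# the printed reference descriptor table used across tests
# (id, TPSA, MW, nON, nOHNH, nviolations, nrotb)
reference_table2 <- function() {
  data.frame(
    id = c("Zinc67664832", "Zinc20267861", "Zinc18204217", "Zinc38735350",
           "Zinc33254827", "Amlodipine"),
    tpsa = c(128.10, 102.97, 123.39, 138.39, 82.46, 101.51),
    mw = c(437.90, 485.36, NA, 469.97, 395.46, 409.89),
    n_on = c(9L, 8L, 8L, 9L, 7L, 7L),
    n_ohnh = c(4L, 2L, 2L, 7L, 1L, 4L),
    n_violations = c(0L, 0L, 1L, 1L, 0L, 0L),
    n_rotb = c(12L, 12L, 5L, 14L, 6L, 10L),
    stringsAsFactors = FALSE)
}

# simple independent atom-contribution logP for a restricted molecule
# class (acyclic saturated C/N/O skeletons and plain benzene rings):
# classifies atoms with its own flat rules and sums table values
simple_logp_oracle <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  deg <- integer(nrow(a))
  for (k in seq_len(nrow(b))) {
    deg[b$a[k]] <- deg[b$a[k]] + 1L
    deg[b$b[k]] <- deg[b$b[k]] + 1L
  }
  nb_of <- function(i) c(b$b[b$a == i], b$a[b$b == i])
  total <- 0
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]; h <- a$implicit_h[i]
    nb <- nb_of(i)
    if (el == "C" && a$aromatic[i]) {
      nonar <- nb[!a$aromatic[nb]]
      v <- if (length(nonar) == 0L) 0.1581
           else if (a$element[nonar[1]] == "C") 0.136
           else if (a$element[nonar[1]] == "N") 0.4619
           else 0.5437
      total <- total + v + h * 0.1230
    } else if (el == "C") {
      het <- any(a$element[nb] %in% c("N", "O"))
      arom <- any(a$aromatic[nb])
      v <- if (het) { if (h >= 2) -0.2035 else -0.2051 }
           else if (arom) { c(-0.0967, 0.1193, -0.0516, 0.08452)[h + 1] }
           else if (h >= 1 && deg[i] <= 2) 0.1441 else 0
      total <- total + v + h * 0.1230
    } else if (el == "N") {
      arom <- any(a$aromatic[nb])
      v <- if (h >= 2) { if (arom) -1.027 else -1.019 }
           else if (h == 1) { if (arom) -0.5188 else -0.7096 }
           else { if (arom) -0.4458 else -0.3187 }
      total <- total + v + h * 0.2142
    } else if (el == "O") {
      arom <- any(a$aromatic[nb])
      v <- if (h == 1) -0.2893 else if (arom) -0.4195 else -0.0684
      total <- total + v + h * (-0.2677)
    } else stop("oracle limited to C/N/O")
  }
  total
}

# random molecule from the restricted class the logP oracle understands
random_simple_smiles <- function(seed) {
  set.seed(seed)
  n <- sample(3:7, 1)
  atoms <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
  # avoid adjacent heteroatoms (keeps typing unambiguous)
  for (i in seq_len(n - 1)) {
    if (atoms[i] != "C" && atoms[i + 1] != "C") atoms[i + 1] <- "C"
  }
  smi <- paste(atoms, collapse = "")
  if (runif(1) < 0.4) smi <- paste0(smi, "c1ccccc1")
  smi
}
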