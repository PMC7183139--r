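# 3D pharmacophores: ligand feature perception, model construction and
# serialization, and rigid "fit all features" matching with exclusion
# volumes.
#
# Feature tables are data frames with columns label, kind (donor, acceptor,
# hydrophobic, exclusion), x/y/z center (Angstrom), radius (tolerance
# sphere), dx/dy/dz (optional unit direction, NA when absent) and
# source_atoms (comma-joined atom indices, "" for protein-derived spheres).

.FEATURE_KINDS <- c("donor", "acceptor", "hydrophobic", "exclusion")

.feature_row <- function(label, kind, center, radius, direction = NULL,
                         source_atoms = integer(0)) {
  if (is.null(direction)) direction <- c(NA_real_, NA_real_, NA_real_)
  data.frame(label = label, kind = kind,
             x = center[1L], y = center[2L], z = center[3L],
             radius = radius,
             dx = direction[1L], dy = direction[2L], dz = direction[3L],
             source_atoms = paste(source_atoms, collapse = ","),
             stringsAsFactors = FALSE)
}

# Conformer-independent feature definitions: kind + source atom set.
# Donors: N/O bearing >= 1 H. Acceptors: N/O with an available lone pair
# (no positive charge; aromatic nitrogen only when two-connected, since a
# three-connected or protonated ring nitrogen donates its pair to the pi
# system; amide nitrogens excluded). Hydrophobics: aromatic ring centroids,
# halogens on aromatic carbon, and connected clusters of uncharged
# non-aromatic carbons with no N/O neighbor (singleton clusters only for
# terminal methyl groups).
.feature_defs <- function(mol) {
  a <- mol$atoms
  el <- a$element
  defs <- list()
  add <- function(kind, atoms_) {
    defs[[length(defs) + 1L]] <<- list(kind = kind, atoms = sort(atoms_))
  }
  nbrs <- lapply(seq_len(nrow(a)), function(i) .neighbors(mol, i))
  carbonyl_c <- vapply(seq_len(nrow(a)), function(i)
    el[i] == "C" && any(el[.double_bond_partners(mol, i)] == "O"), FALSE)
  for (i in seq_len(nrow(a))) {
    if (!el[i] %in% c("N", "O")) next
    if (a$implicit_h[i] >= 1L) add("donor", i)
    lone_pair <- a$charge[i] <= 0L
    if (el[i] == "N") {
      if (a$aromatic[i] && (length(nbrs[[i]]) >= 3L || a$implicit_h[i] >= 1L))
        lone_pair <- FALSE
      if (!a$aromatic[i] && any(carbonyl_c[nbrs[[i]]])) lone_pair <- FALSE
    }
    if (lone_pair) add("acceptor", i)
  }
  rings <- .aromatic_rings(mol)
  for (r in rings) add("hydrophobic", r)
  for (i in which(el %in% c("F", "Cl", "Br", "I"))) {
    nb <- nbrs[[i]]
    if (length(nb) == 1L && el[nb] == "C" && a$aromatic[nb]) {
      add("hydrophobic", i)
    }
  }
  qual <- el == "C" & !a$aromatic & a$charge == 0L &
    !vapply(seq_len(nrow(a)), function(i) any(el[nbrs[[i]]] %in% c("N", "O")),
            FALSE)
  comp <- .components(which(qual), mol)
  for (cl in comp) {
    if (length(cl) >= 2L) add("hydrophobic", cl)
    else if (a$implicit_h[cl] >= 3L) add("hydrophobic", cl)  # terminal methyl
  }
  # deterministic order: kind, then source atoms
  ord <- order(match(vapply(defs, `[[`, "", "kind"), .FEATURE_KINDS),
               vapply(defs, function(d) min(d$atoms), 0L),
               vapply(defs, function(d) length(d$atoms), 0L))
  defs[ord]
}

# connected components of the atom subset `keep` under the bond graph
.components <- function(keep, mol) {
  if (length(keep) == 0L) return(list())
  b <- mol$bonds
  comp <- list()
  left <- keep
  while (length(left) > 0L) {
    grp <- left[1L]
    repeat {
      ext <- unique(c(b$b[b$a %in% grp], b$a[b$b %in% grp]))
      ext <- intersect(ext, left)
      new <- setdiff(ext, grp)
      if (length(new) == 0L) break
      grp <- c(grp, new)
    }
    comp[[length(comp) + 1L]] <- sort(grp)
    left <- setdiff(left, grp)
  }
  comp
}

#' Perceive pharmacophoric features of a conformer
#'
#' Detects hydrogen-bond donors and acceptors and hydrophobic centers on
#' one conformer of a molecule. Donor and acceptor features sit on the
#' heavy atom; hydrophobic features sit on the ring or cluster centroid.
#' Donor features carry a direction pointing away from the heavy-atom
#' neighbors (the average hydrogen direction).
#'
#' @param mol A [Molecule] with conformers.
#' @param conformer_index Which conformer to use (default 1).
#' @return Feature data frame (see package docs); deterministic order.
#' @export
perceive_features <- function(mol, conformer_index = 1L) {
  if (conformer_index < 1L || conformer_index > length(mol$conformers))
    stop("missing conformer ", conformer_index, " (molecule has ",
         length(mol$conformers), ")")
  X <- mol$conformers[[conformer_index]]
  defs <- .feature_defs(mol)
  counts <- stats::setNames(integer(length(.FEATURE_KINDS)), .FEATURE_KINDS)
  rows <- lapply(defs, function(d) {
    counts[d$kind] <<- counts[d$kind] + 1L
    center <- colMeans(X[d$atoms, , drop = FALSE])
    dir <- NULL
    if (d$kind == "donor") {
      i <- d$atoms
      nb <- .neighbors(mol, i)
      if (length(nb) > 0L) {
        v <- -colSums(t(t(X[nb, , drop = FALSE]) - X[i, ]) /
                        sqrt(rowSums((X[nb, , drop = FALSE] -
                                        matrix(X[i, ], length(nb), 3L,
                                               byrow = TRUE))^2)))
        nv <- sqrt(sum(v^2))
        if (nv > 1e-8) dir <- v / nv
      }
    }
    .feature_row(paste0(d$kind, counts[d$kind]), d$kind, center,
                 radius = 1.5, direction = dir, source_atoms = d$atoms)
  })
  do.call(rbind, rows)
}

#' @rdname perceive_features
#' @param kind Optional kind filter for counting.
#' @return `count_features` returns the conformer-independent number of
#'   perceivable features, per kind.
#' @export
count_features <- function(mol, kind = NULL) {
  defs <- .feature_defs(mol)
  kinds <- vapply(defs, `[[`, "", "kind")
  if (is.null(kind)) table(factor(kinds, levels = .FEATURE_KINDS))
  else sum(kinds == kind)
}

# ---------------------------------------------------------------------------
# model construction and (de)serialization

.MODEL_SCHEMA <- "phorescreen-model/1"

#' Build the reference L-VGCC pharmacophore model
#'
#' Deterministically embeds the amlodipine query (the dihydropyridine
#' channel blocker the model was designed around), perceives its features
#' and assembles the six-feature model: two hydrogen-bond donors (the
#' dihydropyridine ring N-H and the terminal ammonium) and four hydrophobic
#' groups (phenyl ring centroid, ring chlorine, carboxyethyl methyl and the
#' ring methyl). One exclusion sphere is placed along each donor direction,
#' marking the protein-occupied region the donated hydrogen points into.
#'
#' @param seed Embedding seed (default 42).
#' @param tolerance_radius Feature tolerance radius in Angstrom.
#' @param exclusion_radius Radius of the exclusion spheres.
#' @param exclusion_offset Distance from donor center to exclusion sphere
#'   center.
#' @return A `PharmacophoreModel`.
#' @export
build_reference_model <- function(seed = 42L, tolerance_radius = 1.5,
                                  exclusion_radius = 1.2,
                                  exclusion_offset = 3.0) {
  amlo <- fixture_library()[["Amlodipine"]]
  amlo <- embed_conformers(amlo, 1L, seed)
  feats <- perceive_features(amlo, 1L)
  donors <- feats[feats$kind == "donor", , drop = FALSE]
  hydro <- feats[feats$kind == "hydrophobic", , drop = FALSE]
  if (nrow(donors) < 2L)
    stop("model build: perception yielded ", nrow(donors), " donors (< 2)")
  if (nrow(hydro) < 4L)
    stop("model build: perception yielded ", nrow(hydro),
         " hydrophobics (< 4)")
  donors <- donors[seq_len(2L), , drop = FALSE]
  # ring centroids and aromatic halogens first, then small clusters
  n_src <- vapply(strsplit(hydro$source_atoms, ","), length, 0L)
  # order: ring centroid (>=5 atoms), halogen/methyl singletons, clusters
  ord <- order(ifelse(n_src >= 5L, 0L, n_src), hydro$label)
  hydro <- hydro[ord, , drop = FALSE][seq_len(4L), , drop = FALSE]
  sel <- rbind(donors, hydro)
  sel$radius <- tolerance_radius
  sel$label <- c("HBD1", "HBD2", paste0("Hydrophobic", 1:4))
  X <- amlo$conformers[[1L]]
  excl <- list()
  for (i in seq_len(2L)) {
    dvec <- as.numeric(donors[i, c("dx", "dy", "dz")])
    ctr <- as.numeric(donors[i, c("x", "y", "z")])
    off <- exclusion_offset
    repeat {
      ec <- ctr + off * dvec
      dmin <- min(sqrt(colSums((t(X) - ec)^2)))
      if (dmin > exclusion_radius + 0.2 || off > exclusion_offset + 3)
        break
      off <- off + 0.5
    }
    excl[[i]] <- .feature_row(paste0("Exclusion", i), "exclusion", ec,
                              exclusion_radius)
  }
  feats_out <- rbind(sel, do.call(rbind, excl))
  rownames(feats_out) <- NULL
  new_pharmacophore_model("L-VGCC-sixfeature", feats_out, require_all = TRUE)
}

#' Construct a PharmacophoreModel
#'
#' @param name Model name.
#' @param features Feature data frame.
#' @param require_all Must every non-exclusion feature be matched (the
#'   screening rule used throughout)?
#' @return A validated `PharmacophoreModel`.
#' @export
new_pharmacophore_model <- function(name, features, require_all = TRUE) {
  m <- structure(list(name = name, require_all = require_all,
                      features = features, schema = .MODEL_SCHEMA),
                 class = "PharmacophoreModel")
  validate_pharmacophore_model(m)
  m
}

#' Validate a PharmacophoreModel
#' @param m A `PharmacophoreModel`.
#' @return `m` invisibly; errors on invariant violation.
#' @export
validate_pharmacophore_model <- function(m) {
  f <- m$features
  if (is.null(f) || nrow(f) == 0L) stop("model has no features")
  if (!all(f$kind %in% .FEATURE_KINDS))
    stop("unknown feature kind: ", paste(setdiff(f$kind, .FEATURE_KINDS),
                                         collapse = ", "))
  if (sum(f$kind != "exclusion") < 1L)
    stop("model needs at least one non-exclusion feature")
  if (any(f$radius <= 0)) stop("feature radius must be > 0")
  if (anyDuplicated(f$label)) stop("feature labels must be unique")
  if (any(!is.finite(as.matrix(f[, c("x", "y", "z")]))))
    stop("non-finite feature center")
  has_dir <- !is.na(f$dx)
  if (any(has_dir)) {
    nrm <- sqrt(f$dx[has_dir]^2 + f$dy[has_dir]^2 + f$dz[has_dir]^2)
    if (any(abs(nrm - 1) > 1e-6))
      stop("feature direction must have unit norm")
  }
  invisible(m)
}

#' @export
print.PharmacophoreModel <- function(x, ...) {
  tab <- table(x$features$kind)
  cat(sprintf("<PharmacophoreModel %s: %s>\n", x$name,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Save / load a pharmacophore model as JSON
#'
#' Lossless round trip; centers are stored to 4 decimals.
#'
#' @param m A `PharmacophoreModel`.
#' @param path File path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(m, path) {
  validate_pharmacophore_model(m)
  f <- m$features
  feats <- lapply(seq_len(nrow(f)), function(i) {
    dir_ <- if (is.na(f$dx[i])) NULL else c(f$dx[i], f$dy[i], f$dz[i])
    list(label = f$label[i], kind = f$kind[i],
         center = c(f$x[i], f$y[i], f$z[i]),
         radius = f$radius[i], direction = dir_,
         source_atoms = if (nzchar(f$source_atoms[i]))
           as.integer(strsplit(f$source_atoms[i], ",")[[1L]]) else integer(0))
  })
  obj <- list(schema = m$schema, name = m$name, require_all = m$require_all,
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("name", "features")) {
    if (is.null(obj[[key]]))
      stop("model schema error at /", key, ": missing")
  }
  rows <- lapply(seq_along(obj$features), function(i) {
    ft <- obj$features[[i]]
    for (key in c("label", "kind", "center", "radius")) {
      if (is.null(ft[[key]]))
        stop("model schema error at /features/", i, "/", key, ": missing")
    }
    ctr <- as.numeric(unlist(ft$center))
    if (length(ctr) != 3L)
      stop("model schema error at /features/", i, "/center: need 3 values")
    dir_ <- if (is.null(ft$direction)) NULL else as.numeric(unlist(ft$direction))
    .feature_row(ft$label, ft$kind, ctr, as.numeric(ft$radius), dir_,
                 if (is.null(ft$source_atoms)) integer(0)
                 else as.integer(unlist(ft$source_atoms)))
  })
  new_pharmacophore_model(obj$name, do.call(rbind, rows),
                          require_all = isTRUE(obj$require_all))
}

#' The packaged reference model
#'
#' Loads the normative six-feature L-VGCC model JSON shipped with the
#' package (generated once by [build_reference_model()]).
#'
#' @return A `PharmacophoreModel`.
#' @export
reference_model <- function() {
  load_model(system.file("extdata", "lvgcc_model.json",
                         package = "phorescreen", mustWork = TRUE))
}

# ---------------------------------------------------------------------------
# matching

# least-squares rigid superposition of rows of P onto rows of Q;
# returns rotation R (applied as X %*% R), translation t and rmsd
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_ <- cq - as.numeric(cp %*% R)
  aligned <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((aligned - Qc)^2)))
  list(R = R, t = t_, rmsd = rmsd)
}

.apply_transform <- function(X, tr) {
  sweep(X %*% tr$R, 2L, tr$t, `+`)
}

#' Match ligand features against a pharmacophore model
#'
#' Searches injective, type-compatible assignments of ligand features to
#' every non-exclusion model feature. Candidate pairs are pruned by
#' pairwise-distance compatibility (`|d_model - d_ligand| <= 2 * tolerance`);
#' each surviving complete assignment is scored by least-squares rigid
#' superposition of the ligand feature centers onto the model centers. An
#' assignment is accepted when every aligned ligand feature lies within
#' `max(feature radius, tolerance)` of its model feature and no ligand heavy
#' atom falls inside an exclusion sphere. The lowest-RMSD accepted
#' assignment wins; ties break lexicographically for determinism.
#'
#' @param ligand_features Feature data frame from [perceive_features()]
#'   (one conformer).
#' @param model A `PharmacophoreModel`.
#' @param tolerance Match tolerance in Angstrom (default 1.5).
#' @param ligand_coords Optional heavy-atom coordinate matrix of the same
#'   conformer, used for exclusion-volume checking.
#' @return A `MatchResult`: `matched`, `mapping` (model label -> ligand
#'   feature index), `rmsd`, `n_exclusion_clashes`, `conformer_index`,
#'   `diagnostics`.
#' @export
match_features <- function(ligand_features, model, tolerance = 1.5,
                           ligand_coords = NULL) {
  validate_pharmacophore_model(model)
  mf <- model$features[model$features$kind != "exclusion", , drop = FALSE]
  ex <- model$features[model$features$kind == "exclusion", , drop = FALSE]
  lf <- ligand_features
  no_match <- function(diag_) {
    structure(list(matched = FALSE, mapping = NULL, rmsd = NA_real_,
                   n_exclusion_clashes = NA_integer_,
                   conformer_index = NA_integer_, diagnostics = diag_),
              class = "MatchResult")
  }
  if (is.null(lf) || nrow(lf) == 0L) return(no_match("no ligand features"))
  nm <- nrow(mf)
  cand <- lapply(seq_len(nm), function(i) which(lf$kind == mf$kind[i]))
  if (any(vapply(cand, length, 0L) == 0L))
    return(no_match(paste0("no ligand feature of kind '",
                           mf$kind[which.min(vapply(cand, length, 0L))], "'")))
  Mx <- as.matrix(mf[, c("x", "y", "z")])
  Lx <- as.matrix(lf[, c("x", "y", "z")])
  Dm <- as.matrix(stats::dist(Mx))
  Dl <- as.matrix(stats::dist(Lx))
  # lossless pairwise pruning bound: an accepted assignment can displace
  # features i and j by at most max(r_i, tol) + max(r_j, tol); this equals
  # 2 * tolerance when all radii equal the tolerance
  slack <- pmax(mf$radius, tolerance)
  prune_bound <- outer(slack, slack, `+`)
  # most-constrained-first ordering
  ordm <- order(vapply(cand, length, 0L))
  best <- NULL
  best_rejected <- NULL
  assign_ <- integer(nm)  # in ordm positions
  search <- function(pos) {
    if (pos > nm) {
      lig_idx <- assign_[order(ordm)]  # back to model feature order
      tr <- .kabsch(Lx[lig_idx, , drop = FALSE], Mx)
      aligned <- .apply_transform(Lx[lig_idx, , drop = FALSE], tr)
      devs <- sqrt(rowSums((aligned - Mx)^2))
      within <- devs <= pmax(mf$radius, tolerance) + 1e-9
      clashes <- 0L
      if (nrow(ex) > 0L && !is.null(ligand_coords)) {
        AX <- .apply_transform(ligand_coords, tr)
        for (e in seq_len(nrow(ex))) {
          de <- sqrt(rowSums((AX - matrix(as.numeric(ex[e, c("x", "y", "z")]),
                                          nrow(AX), 3L, byrow = TRUE))^2))
          clashes <- clashes + sum(de < ex$radius[e])
        }
      }
      ok <- all(within) && clashes == 0L
      cand_res <- list(mapping = stats::setNames(lig_idx, mf$label),
                       rmsd = tr$rmsd, clashes = clashes, ok = ok)
      if (ok) {
        if (is.null(best) || cand_res$rmsd < best$rmsd - 1e-12 ||
            (abs(cand_res$rmsd - best$rmsd) <= 1e-12 &&
             paste(cand_res$mapping, collapse = ",") <
               paste(best$mapping, collapse = ","))) best <<- cand_res
      } else {
        if (is.null(best_rejected) || cand_res$rmsd < best_rejected$rmsd)
          best_rejected <<- cand_res
      }
      return(invisible(NULL))
    }
    i <- ordm[pos]
    for (ci in cand[[i]]) {
      if (pos > 1L && ci %in% assign_[seq_len(pos - 1L)]) next
      ok <- TRUE
      for (prev in seq_len(pos - 1L)) {
        j <- ordm[prev]
        if (abs(Dm[i, j] - Dl[ci, assign_[prev]]) > prune_bound[i, j]) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_[pos] <<- ci
      search(pos + 1L)
    }
    invisible(NULL)
  }
  search(1L)
  if (!is.null(best)) {
    structure(list(matched = TRUE, mapping = best$mapping, rmsd = best$rmsd,
                   n_exclusion_clashes = 0L, conformer_index = NA_integer_,
                   diagnostics = "ok"),
              class = "MatchResult")
  } else if (!is.null(best_rejected)) {
    structure(list(matched = FALSE, mapping = best_rejected$mapping,
                   rmsd = best_rejected$rmsd,
                   n_exclusion_clashes = best_rejected$clashes,
                   conformer_index = NA_integer_,
                   diagnostics = "all assignments rejected"),
              class = "MatchResult")
  } else {
    no_match("no distance-compatible assignment")
  }
}

#' @export
print.MatchResult <- function(x, ...) {
  if (x$matched) {
    cat(sprintf("<MatchResult: matched, rmsd %.4f A, conformer %s>\n",
                x$rmsd, ifelse(is.na(x$conformer_index), "?",
                               x$conformer_index)))
  } else {
    cat(sprintf("<MatchResult: no match (%s)>\n", x$diagnostics))
  }
  invisible(x)
}

#' Screen one molecule against a model over a conformer ensemble
#'
#' Embeds `n_conformers` seeded conformers, perceives features on each and
#' returns the best [match_features()] result (a match beats a non-match;
#' among matches the lowest RMSD wins). A feature-count prefilter skips
#' embedding entirely when the molecular graph cannot supply enough
#' features of some required kind for any conformer.
#'
#' @param mol A [Molecule].
#' @param model A `PharmacophoreModel`.
#' @param n_conformers Ensemble size (default 25).
#' @param seed Embedding seed (default 42).
#' @param tolerance Match tolerance in Angstrom.
#' @return A `MatchResult` with `conformer_index` set for matches.
#' @export
screen_molecule <- function(mol, model, n_conformers = 25L, seed = 42L,
                            tolerance = 1.5) {
  if (n_conformers == 0L)
    return(structure(list(matched = FALSE, mapping = NULL, rmsd = NA_real_,
                          n_exclusion_clashes = NA_integer_,
                          conformer_index = NA_integer_,
                          diagnostics = "no conformers"),
                     class = "MatchResult"))
  mf <- model$features[model$features$kind != "exclusion", , drop = FALSE]
  need <- table(mf$kind)
  defs <- .feature_defs(mol)
  have <- table(factor(vapply(defs, `[[`, "", "kind"),
                       levels = .FEATURE_KINDS))
  lacking <- names(need)[need > have[names(need)]]
  if (length(lacking) > 0L)
    return(structure(list(matched = FALSE, mapping = NULL, rmsd = NA_real_,
                          n_exclusion_clashes = NA_integer_,
                          conformer_index = NA_integer_,
                          diagnostics = paste0("too few ", lacking[1L],
                                               " features")),
                     class = "MatchResult"))
  # lazy embedding: conformer k depends only on (mol, seed, k), so the
  # early break on a near-perfect match skips the remaining embeddings
  na <- nrow(mol$atoms)
  tg <- .dg_targets(mol)
  mol$conformers <- vector("list", n_conformers)
  best <- NULL
  for (k in seq_len(n_conformers)) {
    mol$conformers[[k]] <- .embed_one(mol, tg, na, seed, k)
    lf <- perceive_features(mol, k)
    res <- match_features(lf, model, tolerance,
                          ligand_coords = mol$conformers[[k]])
    res$conformer_index <- k
    better <- is.null(best) ||
      (res$matched && !best$matched) ||
      (res$matched == best$matched && !is.na(res$rmsd) &&
         (is.na(best$rmsd) || res$rmsd < best$rmsd))
    if (better) best <- res
    if (best$matched && best$rmsd < 1e-9) break
  }
  best
}
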