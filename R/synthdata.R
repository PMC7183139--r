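# Fixtures and synthetic-input generators: the six-compound reference
# library, feature-knockout decoys, and toy binding pockets with planted
# hydrogen-bond geometry.

# the six screening compounds (ZINC protomers as catalogued + the
# amlodipine query in its ammonium form)
.FIXTURE_SMILES <- c(
  Zinc67664832 = "CCOC(=O)C1=C(NC(=C([C@H]1c2ccccc2Cl)C(=O)OC)C)COCC[N-][NH2+][NH-]",
  Zinc20267861 = "CCOC(=O)C1=C(NC(=C([C@H]1c2ccccc2Cl)C(=O)OC)C)COCCNC(=O)CCl",
  Zinc18204217 = "c1cc(c(cc1Cl)Cl)[C@H](/C(=N\\NC(=O)c2ccncc2)/c3c(nc4cc(ccc4n3)Cl)[O-])O",
  Zinc38735350 = "CCOC(=O)C1=C(NC(=C([C@@H]1c2ccccc2Cl)C(=O)OC)COCC[NH3+])COCC[NH3+]",
  Zinc33254827 = "Cc1cc2c(cc1C)n(c(=O)c(n2)C)CC(=O)NCc3ccc(cc3OC)OC",
  Amlodipine = "CCOC(=O)C1=C(NC(=C([C@@H]1c2ccccc2Cl)C(=O)OC)C)COCC[NH3+]"
)

#' The six-compound fixture library
#'
#' The five ZINC hits plus the amlodipine query, parsed from their
#' catalogued SMILES (charged protomers kept as drawn; the amlodipine entry
#' carries its terminal ammonium).
#'
#' @return Named list of six [Molecule] objects.
#' @export
fixture_library <- function() {
  out <- lapply(names(.FIXTURE_SMILES), function(nm)
    parse_smiles(.FIXTURE_SMILES[[nm]], nm))
  stats::setNames(out, names(.FIXTURE_SMILES))
}

#' Generate feature-knockout decoys
#'
#' Derives `n` decoy molecules from a base compound by a structural edit
#' that removes a pharmacophoric feature class:
#' \describe{
#'   \item{remove_donor}{every N-H/O-H group is capped: terminal ammonium
#'     groups become methyls, other donors are methylated, so the donor
#'     count drops to zero.}
#'   \item{remove_hydrophobic}{the halogenated aromatic ring is excised and
#'     the attachment atom re-hydrogenated.}
#'   \item{scramble_geometry}{the graph is kept but one embedded conformer
#'     is replaced with random coordinates.}
#'   \item{none}{unedited copies (conformers, when embedded downstream, are
#'     re-generated per decoy seed).}
#' }
#'
#' @param base A [Molecule] to edit.
#' @param knockout One of `"remove_donor"`, `"remove_hydrophobic"`,
#'   `"scramble_geometry"`, `"none"`.
#' @param n Number of decoys (>= 1).
#' @param seed Integer seed (controls geometry only; the graph edit is
#'   deterministic).
#' @return List of `n` [Molecule] objects named `<base>_<knockout>_<i>`.
#' @export
generate_decoys <- function(base, knockout = c("remove_donor",
                                               "remove_hydrophobic",
                                               "scramble_geometry", "none"),
                            n = 1L, seed = 1L) {
  knockout <- match.arg(knockout)
  if (n < 1L) stop("n must be >= 1")
  edited <- switch(knockout,
    remove_donor = .edit_remove_donors(base),
    remove_hydrophobic = .edit_remove_halo_ring(base),
    scramble_geometry = base,
    none = base)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- edited
    m$name <- sprintf("%s_%s_%d", base$name, knockout, i)
    if (knockout == "scramble_geometry") {
      m <- embed_conformers(m, 1L, seed + i)
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed((seed * 131071L + i) %% 2147483647L)
      m$conformers[[1L]] <- matrix(stats::rnorm(nrow(m$atoms) * 3L, sd = 4),
                                   nrow(m$atoms), 3L)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    out[[i]] <- m
  }
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

# cap every N-H / O-H: [NH3+]->CH3 (terminal), otherwise methylate
.edit_remove_donors <- function(mol) {
  a <- mol$atoms
  donors <- which(a$element %in% c("N", "O") & a$implicit_h > 0L)
  if (length(donors) == 0L)
    stop("base '", mol$name, "' has no donors to remove")
  for (i in donors) {
    if (a$charge[i] > 0L && .heavy_degree(mol)[i] == 1L) {
      # terminal protonated amine -> methyl carbon
      a$element[i] <- "C"
      a$charge[i] <- 0L
      a$implicit_h[i] <- 3L
    } else if (a$charge[i] != 0L) {
      stop("cannot cap charged donor at atom ", i)
    } else {
      # N-/O-methylation: drop one H, attach CH3
      a$implicit_h[i] <- a$implicit_h[i] - 1L
      a <- rbind(a, data.frame(element = "C", charge = 0L, implicit_h = 3L,
                               aromatic = FALSE, stereo = "", bracket = FALSE,
                               stringsAsFactors = FALSE))
      mol$bonds <- rbind(mol$bonds,
                         data.frame(a = i, b = nrow(a), order = "single",
                                    in_ring = FALSE, stringsAsFactors = FALSE))
    }
  }
  mol$atoms <- a
  mol$conformers <- list()
  mol$smiles <- NULL
  validate_molecule(mol)
  mol
}

# excise the aromatic ring bearing a halogen (plus the halogen itself)
.edit_remove_halo_ring <- function(mol) {
  a <- mol$atoms
  halo <- which(a$element %in% c("F", "Cl", "Br", "I"))
  rings <- .aromatic_rings(mol)
  target <- NULL; hx <- NULL
  for (h in halo) {
    nb <- .neighbors(mol, h)
    for (r in rings) {
      if (length(nb) == 1L && nb %in% r) { target <- r; hx <- h; break }
    }
    if (!is.null(target)) break
  }
  if (is.null(target))
    stop("base '", mol$name, "' has no halogenated aromatic ring to remove")
  drop <- c(target, hx)
  keep <- setdiff(seq_len(nrow(a)), drop)
  idx_map <- match(seq_len(nrow(a)), keep)
  b <- mol$bonds
  cut <- b$a %in% drop | b$b %in% drop
  # re-hydrogenate attachment atoms losing a bond to the excised ring
  sever <- b[cut & !(b$a %in% drop & b$b %in% drop), , drop = FALSE]
  for (k in seq_len(nrow(sever))) {
    att <- if (sever$a[k] %in% drop) sever$b[k] else sever$a[k]
    a$implicit_h[att] <- a$implicit_h[att] + 1L
  }
  b <- b[!cut, , drop = FALSE]
  b$a <- idx_map[b$a]; b$b <- idx_map[b$b]
  mol$atoms <- a[keep, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  mol$bonds <- b
  mol$conformers <- list()
  mol$smiles <- NULL
  validate_molecule(mol)
  mol
}

#' Generate a toy binding pocket with planted geometry
#'
#' Builds a rigid poly-ether probe ligand and places pseudo-residues around
#' it so that exactly `n_residues` residues fall within the default 4.5
#' Angstrom contact cutoff, exactly `n_planted_hbonds` of them donate an
#' ideal hydrogen bond (N-H...O, heavy-atom distance 2.9 Angstrom, angle
#' 180 degrees) to a ligand ether oxygen, and exactly `n_site_members`
#' residues appear in the active-site spec. Two far decoy residues sit
#' outside the cutoff. The generator self-checks that no unplanted
#' donor-acceptor pair comes within hydrogen-bonding range.
#'
#' @param n_residues Residues within the contact cutoff.
#' @param n_planted_hbonds Planted ideal hydrogen bonds
#'   (`<= n_residues`).
#' @param n_site_members Residues listed in the active-site spec
#'   (`<= n_residues`).
#' @param seed Integer seed for angular placement jitter.
#' @return List with `pdb` (PDB text lines), `pose` ([Molecule] with one
#'   conformer), `site` (active-site spec data frame), and `manifest`
#'   (planted ground truth).
#' @export
generate_toy_pocket <- function(n_residues, n_planted_hbonds,
                                n_site_members, seed = 7L) {
  if (n_planted_hbonds > n_residues)
    stop("infeasible: n_planted_hbonds > n_residues")
  if (n_site_members > n_residues)
    stop("infeasible: n_site_members > n_residues")
  if (n_residues < 0L || n_residues > 24L)
    stop("n_residues must be in 0..24")
  # rigid probe ligand: alternating C/O chain along x, 1.43 A spacing
  n_ox <- max(3L, n_planted_hbonds)
  n_lig <- 2L * n_ox + 1L
  el <- rep(c("C", "O"), length.out = n_lig)
  X <- cbind((seq_len(n_lig) - 1L) * 1.43, 0, 0)
  atoms <- data.frame(element = el, charge = 0L,
                      implicit_h = ifelse(el == "C", 2L, 0L),
                      aromatic = FALSE, stereo = "", bracket = FALSE,
                      stringsAsFactors = FALSE)
  atoms$implicit_h[1L] <- 3L
  if (el[n_lig] == "C") atoms$implicit_h[n_lig] <- 3L
  bonds <- data.frame(a = seq_len(n_lig - 1L), b = seq_len(n_lig - 1L) + 1L,
                      order = "single", in_ring = FALSE,
                      stringsAsFactors = FALSE)
  pose <- new_molecule("toy_pose", atoms, bonds, conformers = list(X))
  ox_idx <- which(el == "O")
  c_idx <- which(el == "C")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% 2147483647L)
  jitter <- stats::runif(1L, 0, 2 * pi)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  pdb <- character(0)
  serial <- 0L
  res_rows <- list()
  emit <- function(resno, resname, atname, elem, p) {
    serial <<- serial + 1L
    pdb <<- c(pdb, sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, substr(atname, 1L, 4L), resname, resno, p[1L], p[2L], p[3L],
      elem))
  }
  # directions in the y-z plane (perpendicular to the ligand axis) keep
  # every residue's atoms away from non-target ligand oxygens
  for (r in seq_len(n_residues)) {
    theta <- jitter + 2 * pi * (r - 1L) / max(1L, n_residues)
    dirv <- c(0, cos(theta), sin(theta))
    if (r <= n_planted_hbonds) {
      anchor <- X[ox_idx[r], ]
      npos <- anchor + 2.9 * dirv
      hpos <- anchor + 1.9 * dirv  # N-H along N->O: angle exactly 180
      cpos <- anchor + 4.35 * dirv
      emit(r, "GLY", "N", "N", npos)
      emit(r, "GLY", "H", "H", hpos)
      emit(r, "GLY", "CA", "C", cpos)
    } else {
      anchor <- X[c_idx[(r - n_planted_hbonds - 1L) %% length(c_idx) + 1L], ]
      emit(r, "ALA", "CA", "C", anchor + 4.0 * dirv)
      emit(r, "ALA", "CB", "C", anchor + 5.4 * dirv)
    }
    res_rows[[r]] <- data.frame(chain = "A",
                                resname = if (r <= n_planted_hbonds) "GLY"
                                          else "ALA",
                                resno = r, stringsAsFactors = FALSE)
  }
  # far decoy residues outside the cutoff
  for (rr in 1:2) {
    anchor <- X[ceiling(n_lig / 2), ]
    theta <- jitter + pi / 3 * rr + 0.1
    dirv <- c(0, cos(theta), sin(theta))
    emit(n_residues + rr, "LEU", "CA", "C", anchor + 12.0 * dirv)
  }
  pdb <- c(pdb, "END")
  site <- if (n_site_members > 0L)
    do.call(rbind, res_rows[seq_len(n_site_members)])
  else data.frame(chain = character(0), resname = character(0),
                  resno = integer(0), stringsAsFactors = FALSE)

  # self-check: planted pairs are ideal; no accidental donor/acceptor pair
  prot <- .parse_pdb_lines(pdb)
  pn <- prot[prot$elesy == "N", , drop = FALSE]
  for (r in seq_len(NROW(pn))) {
    dmin <- sqrt(colSums((t(X[ox_idx, , drop = FALSE]) -
                            as.numeric(pn[r, c("x", "y", "z")]))^2))
    # PDB coordinates carry three decimals, hence the 5e-3 slack
    stopifnot(abs(min(dmin) - 2.9) < 5e-3,
              sum(dmin < 3.55) == 1L)
  }
  manifest <- list(n_residues = n_residues,
                   n_planted_hbonds = n_planted_hbonds,
                   n_site_members = n_site_members, seed = seed,
                   contact_cutoff = 4.5, hbond_dist = 2.9,
                   hbond_angle = 180)
  list(pdb = pdb, pose = pose, site = site, manifest = manifest)
}
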