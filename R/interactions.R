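# Protein-ligand pose annotation: surrounding residues within a contact
# cutoff, geometric hydrogen bonds, and active-site interaction counts.
# Docked poses are inputs; no docking or scoring happens here.

# light column parser used where PDB text is held in memory (the toy-pocket
# self-check); file input goes through bio3d in read_protein()
.parse_pdb_lines <- function(lines) {
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(rec) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), elety = character(0),
                      elesy = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), insert = character(0),
                      stringsAsFactors = FALSE))
  data.frame(
    chain = trimws(substr(rec, 22L, 22L)),
    resno = as.integer(substr(rec, 23L, 26L)),
    resid = trimws(substr(rec, 18L, 20L)),
    elety = trimws(substr(rec, 13L, 16L)),
    elesy = trimws(substr(rec, 77L, 78L)),
    x = as.numeric(substr(rec, 31L, 38L)),
    y = as.numeric(substr(rec, 39L, 46L)),
    z = as.numeric(substr(rec, 47L, 54L)),
    insert = trimws(substr(rec, 27L, 27L)),
    stringsAsFactors = FALSE
  )
}

#' Read a protein structure from PDB
#'
#' Parses ATOM/HETATM records via \pkg{bio3d} into a flat atom table with
#' chain, residue number (insertion codes preserved), residue and atom
#' names, element symbol and coordinates.
#'
#' @param pdb_path Path to a PDB file.
#' @return A `ProteinStructure`: data frame of atoms with attributes.
#' @export
read_protein <- function(pdb_path) {
  if (!file.exists(pdb_path)) stop("no such file: ", pdb_path)
  pdb <- tryCatch(bio3d::read.pdb(pdb_path, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse PDB '", pdb_path, "': ",
                         conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no ATOM records in ", pdb_path)
  el <- trimws(at$elesy)
  guess <- toupper(substr(trimws(at$elety), 1L, 1L))
  el[!nzchar(el)] <- guess[!nzchar(el)]
  out <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                    elety = trimws(at$elety), elesy = el,
                    x = at$x, y = at$y, z = at$z,
                    insert = ifelse(is.na(at$insert), "", at$insert),
                    stringsAsFactors = FALSE)
  structure(out, class = c("ProteinStructure", "data.frame"))
}

#' @export
print.ProteinStructure <- function(x, ...) {
  nres <- nrow(unique(x[, c("chain", "resno", "insert")]))
  cat(sprintf("<ProteinStructure: %d atoms, %d residues, chains %s>\n",
              nrow(x), nres, paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

# residue identifier strings "CHAIN:RES#"
.residue_ids <- function(prot) {
  paste0(prot$chain, ":", prot$resid, prot$resno,
         ifelse(nzchar(prot$insert), prot$insert, ""))
}

#' Find protein-ligand heavy-atom contacts
#'
#' All heavy-atom pairs (one ligand, one protein atom) within the cutoff,
#' sorted by distance.
#'
#' @param pose A [Molecule] with at least one conformer (the docked pose).
#' @param protein A `ProteinStructure`.
#' @param cutoff Contact cutoff in Angstrom (default 4.5).
#' @param conformer_index Pose conformer to use.
#' @return Data frame of contacts: `residue`, `ligand_atom`,
#'   `protein_atom` (row index), `protein_elety`, `distance`.
#' @export
find_contacts <- function(pose, protein, cutoff = 4.5,
                          conformer_index = 1L) {
  if (length(pose$conformers) < conformer_index)
    stop("pose has no conformer ", conformer_index)
  if (cutoff <= 0) stop("cutoff must be > 0")
  X <- pose$conformers[[conformer_index]]
  heavy_p <- which(protein$elesy != "H")
  P <- as.matrix(protein[heavy_p, c("x", "y", "z")])
  rid <- .residue_ids(protein)[heavy_p]
  res <- list()
  for (i in seq_len(nrow(X))) {
    d <- sqrt(colSums((t(P) - X[i, ])^2))
    hit <- which(d <= cutoff)
    if (length(hit) > 0L)
      res[[length(res) + 1L]] <- data.frame(
        residue = rid[hit], ligand_atom = i, protein_atom = heavy_p[hit],
        protein_elety = protein$elety[heavy_p[hit]], distance = d[hit],
        stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(residue = character(0), ligand_atom = integer(0),
                      protein_atom = integer(0),
                      protein_elety = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$distance), , drop = FALSE]
}

# ligand-side donor/acceptor atom indices (graph chemistry)
.ligand_polar_atoms <- function(pose) {
  a <- pose$atoms
  donors <- which(a$element %in% c("N", "O") & a$implicit_h > 0L)
  defs <- .feature_defs(pose)
  acceptors <- sort(unlist(lapply(defs[vapply(defs, `[[`, "", "kind") ==
                                         "acceptor"], `[[`, "atoms")))
  list(donors = donors, acceptors = acceptors)
}

#' Find geometric hydrogen bonds between pose and protein
#'
#' Donor-acceptor pairs in either direction with heavy-atom distance
#' `<= d_max` and D-H...A angle `>= angle_min`. Protein donors with
#' explicit hydrogens use the recorded H positions; donors without explicit
#' hydrogens (the common case for crystallographic PDB files, and always
#' for the implicit-hydrogen ligand model) have the hydrogen inferred along
#' the donor-acceptor axis, which satisfies any angle criterion.
#'
#' @param pose A [Molecule] with a conformer.
#' @param protein A `ProteinStructure`.
#' @param d_max Maximum heavy-atom donor-acceptor distance (default 3.5).
#' @param angle_min Minimum D-H...A angle in degrees (default 120).
#' @param conformer_index Pose conformer to use.
#' @return Data frame: `residue`, `direction`
#'   (`"protein->ligand"`/`"ligand->protein"`), `donor`, `acceptor`,
#'   `distance`, `angle`.
#' @export
find_hbonds <- function(pose, protein, d_max = 3.5, angle_min = 120,
                        conformer_index = 1L) {
  X <- pose$conformers[[conformer_index]]
  lig <- .ligand_polar_atoms(pose)
  pol_p <- which(protein$elesy %in% c("N", "O"))
  hyd_p <- which(protein$elesy == "H")
  P <- as.matrix(protein[, c("x", "y", "z")])
  rid <- .residue_ids(protein)
  out <- list()
  angle_deg <- function(a, b, c) {
    v1 <- a - b; v2 <- c - b
    cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  }
  # protein donor (N/O) -> ligand acceptor
  for (p in pol_p) {
    # explicit H attached to this protein atom (same residue, within 1.3 A)
    hs <- hyd_p[protein$chain[hyd_p] == protein$chain[p] &
                  protein$resno[hyd_p] == protein$resno[p]]
    if (length(hs) > 0L) {
      hd <- sqrt(rowSums((P[hs, , drop = FALSE] -
                            matrix(P[p, ], length(hs), 3L, byrow = TRUE))^2))
      hs <- hs[hd < 1.3]
    }
    for (j in lig$acceptors) {
      d <- sqrt(sum((P[p, ] - X[j, ])^2))
      if (d > d_max) next
      ang <- if (length(hs) > 0L) {
        max(vapply(hs, function(h) angle_deg(P[p, ], P[h, ], X[j, ]), 0))
      } else 180
      if (ang >= angle_min)
        out[[length(out) + 1L]] <- data.frame(
          residue = rid[p], direction = "protein->ligand", donor = p,
          acceptor = j, distance = d, angle = ang, stringsAsFactors = FALSE)
    }
  }
  # ligand donor -> protein acceptor (N/O); ligand H are implicit, so the
  # inferred-H angle is ideal by construction
  for (i in lig$donors) {
    for (p in pol_p) {
      d <- sqrt(sum((X[i, ] - P[p, ])^2))
      if (d > d_max) next
      key_dup <- FALSE
      for (o in out) if (o$donor == p && o$acceptor == i) key_dup <- TRUE
      if (key_dup) next
      out[[length(out) + 1L]] <- data.frame(
        residue = rid[p], direction = "ligand->protein", donor = i,
        acceptor = p, distance = d, angle = 180, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(residue = character(0), direction = character(0),
                      donor = integer(0), acceptor = integer(0),
                      distance = numeric(0), angle = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summarize protein-ligand interactions (report-table semantics)
#'
#' Combines [find_contacts()] and [find_hbonds()] into the per-pose report
#' row: surrounding residues within the cutoff, hydrogen-bond count, and
#' the number of surrounding residues that belong to the active-site spec.
#' An externally supplied docking score is copied through verbatim, never
#' computed.
#'
#' @param pose A [Molecule] with a conformer.
#' @param protein A `ProteinStructure`.
#' @param site Active-site spec: data frame with `chain`, `resname`,
#'   `resno` (e.g. from [load_active_site()]), or `NULL`.
#' @param external_score Optional externally computed binding energy
#'   (kcal/mol), passed through.
#' @param cutoff Contact cutoff in Angstrom.
#' @param d_max,angle_min Hydrogen-bond criteria.
#' @return An `InteractionTable`: `surrounding_residues`, `n_hbonds`,
#'   `n_active_site_interactions`, `external_score`.
#' @export
summarize_interactions <- function(pose, protein, site = NULL,
                                   external_score = NULL, cutoff = 4.5,
                                   d_max = 3.5, angle_min = 120) {
  contacts <- find_contacts(pose, protein, cutoff)
  surrounding <- unique(contacts$residue)
  hb <- find_hbonds(pose, protein, d_max, angle_min)
  n_hb <- nrow(unique(hb[, c("donor", "acceptor")]))
  n_site <- 0L
  if (!is.null(site) && nrow(site) > 0L && length(surrounding) > 0L) {
    site_ids <- paste0(site$chain, ":", site$resname, site$resno)
    n_site <- sum(surrounding %in% site_ids)
  }
  structure(list(surrounding_residues = surrounding,
                 n_hbonds = n_hb,
                 n_active_site_interactions = n_site,
                 external_score = if (is.null(external_score)) NA_real_
                                  else external_score),
            class = "InteractionTable")
}

#' @export
print.InteractionTable <- function(x, ...) {
  cat(sprintf(
    "<InteractionTable: %d surrounding residue(s), %d H-bond(s), %d active-site interaction(s)%s>\n",
    length(x$surrounding_residues), x$n_hbonds,
    x$n_active_site_interactions,
    if (!is.na(x$external_score))
      sprintf(", external score %.1f kcal/mol", x$external_score) else ""))
  invisible(x)
}

#' Load an active-site specification from JSON
#'
#' The JSON is a list of objects with `chain`, `resname`, `resno`.
#'
#' @param path JSON file path.
#' @return Data frame with columns `chain`, `resname`, `resno`.
#' @export
load_active_site <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$residues)) stop("site schema error at /residues: missing")
  res <- as.data.frame(obj$residues, stringsAsFactors = FALSE)
  if (nrow(res) == 0L) stop("active-site spec is empty")
  if (anyDuplicated(res)) stop("duplicate active-site entries")
  res
}

#' The packaged L-VGCC active-site residue list
#'
#' The channel-pore binding-site residues (chains A-D) shipped with the
#' package, as predicted for the modeled pore domain.
#'
#' @return Data frame with columns `chain`, `resname`, `resno`.
#' @export
lvgcc_active_site <- function() {
  load_active_site(system.file("extdata", "lvgcc_active_site.json",
                               package = "phorescreen", mustWork = TRUE))
}

#' Write an active-site specification to JSON
#' @param site Data frame with `chain`, `resname`, `resno`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_active_site <- function(site, path) {
  jsonlite::write_json(list(residues = site), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
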