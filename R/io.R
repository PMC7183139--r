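# File input/output: SMILES files (.smi), SDF V2000 molblocks (with
# M CHG charge records, which matter for the charged ZINC protomers), and
# the toy-pocket bundle.

#' Read a SMILES file
#'
#' One record per line: `SMILES<whitespace>ID`; the ID is optional. Blank
#' lines and `#` comments are skipped. Unparsable records become warnings
#' (collected in the `errors` attribute) unless `strict = TRUE`.
#'
#' @param path File path.
#' @param strict Error on the first unparsable record?
#' @return Named list of [Molecule] objects.
#' @export
read_smi <- function(path, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mols <- list()
  errs <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "[[:space:]]+")[[1L]]
    nm <- if (length(parts) >= 2L) parts[2L] else paste0("mol", i)
    m <- tryCatch(parse_smiles(parts[1L], nm), error = function(e) e)
    if (inherits(m, "error")) {
      msg <- paste0("line ", i, " (", nm, "): ", conditionMessage(m))
      if (strict) stop(msg)
      errs <- c(errs, msg)
      warning(msg)
    } else {
      mols[[nm]] <- m
    }
  }
  attr(mols, "errors") <- errs
  mols
}

#' Write molecules to a SMILES file
#'
#' @param mols List of [Molecule] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smi <- function(mols, path) {
  lines <- vapply(mols, function(m) {
    smi <- if (!is.null(m$smiles)) m$smiles else write_smiles(m)
    paste0(smi, "\t", m$name)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SDF V2000

.SDF_CHARGE_CODES <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L,
                       `7` = -3L)

#' Read an SDF (V2000) file
#'
#' Parses atom coordinates, elements, bond orders and formal charges
#' (`M  CHG` records override the atom-block charge column). Implicit
#' hydrogens are assigned from standard valences; bond order 4 is read as
#' aromatic.
#'
#' @param path File path.
#' @return Named list of [Molecule] objects, each with one conformer.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split into molblocks on $$$$
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mols <- list()
  for (bi in seq_along(starts)) {
    blk <- lines[starts[bi]:ends[bi]]
    blk <- blk[blk != "$$$$"]
    if (all(!nzchar(trimws(blk)))) next
    m <- .parse_molblock(blk)
    nm <- if (nzchar(m$name)) m$name else paste0("mol", bi)
    mols[[nm]] <- m
  }
  mols
}

.parse_molblock <- function(blk) {
  if (length(blk) < 4L) stop("truncated molblock")
  name <- trimws(blk[1L])
  counts <- blk[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  if (is.na(na) || na < 1L) stop("molblock counts line unreadable: '",
                                 counts, "'")
  at_lines <- blk[5:(4L + na)]
  el <- trimws(substr(at_lines, 32L, 34L))
  xyz <- cbind(as.numeric(substr(at_lines, 1L, 10L)),
               as.numeric(substr(at_lines, 11L, 20L)),
               as.numeric(substr(at_lines, 21L, 30L)))
  if (any(!is.finite(xyz))) stop("malformed coordinate field in molblock '",
                                 name, "'")
  chg_code <- suppressWarnings(as.integer(substr(at_lines, 37L, 39L)))
  charge <- integer(na)
  known <- !is.na(chg_code) & as.character(chg_code) %in%
    names(.SDF_CHARGE_CODES)
  charge[known] <- .SDF_CHARGE_CODES[as.character(chg_code[known])]
  order_map <- c("1" = "single", "2" = "double", "3" = "triple",
                 "4" = "aromatic")
  if (nb > 0L) {
    bd_lines <- blk[(5L + na):(4L + na + nb)]
    ba <- as.integer(substr(bd_lines, 1L, 3L))
    bb <- as.integer(substr(bd_lines, 4L, 6L))
    bo <- order_map[trimws(substr(bd_lines, 7L, 9L))]
    if (anyNA(bo)) stop("unsupported bond order in molblock '", name, "'")
    bonds <- data.frame(a = ba, b = bb, order = unname(bo),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0),
                        order = character(0), stringsAsFactors = FALSE)
  }
  # property block: M  CHG overrides
  prop <- blk[grepl("^M  CHG", blk)]
  if (length(prop) > 0L) {
    charge[] <- 0L
    for (ln in prop) {
      nn <- as.integer(substr(ln, 7L, 9L))
      for (e in seq_len(nn)) {
        off <- 10L + (e - 1L) * 8L
        ai <- as.integer(substr(ln, off, off + 3L))
        qv <- as.integer(substr(ln, off + 4L, off + 7L))
        charge[ai] <- qv
      }
    }
  }
  aromatic <- rep(FALSE, na)
  if (nrow(bonds) > 0L) {
    ar <- bonds$order == "aromatic"
    aromatic[unique(c(bonds$a[ar], bonds$b[ar]))] <- TRUE
  }
  atoms <- data.frame(element = el, charge = charge, implicit_h = 0L,
                      aromatic = aromatic, stereo = "", bracket = FALSE,
                      stringsAsFactors = FALSE)
  bonds$in_ring <- .ring_bond_flags(na, bonds)
  # implicit H from charge-adjusted standard valences
  w <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
  bsum <- numeric(na)
  for (k in seq_len(nrow(bonds))) {
    bsum[bonds$a[k]] <- bsum[bonds$a[k]] + w[[bonds$order[k]]]
    bsum[bonds$b[k]] <- bsum[bonds$b[k]] + w[[bonds$order[k]]]
  }
  h <- integer(na)
  for (i in seq_len(na)) {
    vals <- .DEFAULT_VALENCES[[el[i]]]
    if (is.null(vals) || el[i] == "H") next
    if (aromatic[i]) vals <- vals[1L]
    need <- as.integer(ceiling(bsum[i] - 1e-9))
    if (charge[i] != 0L && el[i] %in% c("N", "O")) {
      h[i] <- max(0L, vals[1L] + charge[i] - need)
    } else {
      fit <- vals[vals >= need]
      h[i] <- if (length(fit) > 0L) as.integer(fit[1L] - need) else 0L
    }
  }
  # explicit hydrogens present in the file shadow implicit ones
  for (k in seq_len(nrow(bonds))) {
    if (el[bonds$a[k]] == "H" && el[bonds$b[k]] != "H")
      h[bonds$b[k]] <- max(0L, h[bonds$b[k]] - 1L)
    if (el[bonds$b[k]] == "H" && el[bonds$a[k]] != "H")
      h[bonds$a[k]] <- max(0L, h[bonds$a[k]] - 1L)
  }
  atoms$implicit_h <- h
  bonds$explicit_order <- NULL
  new_molecule(name, atoms, bonds, conformers = list(unname(xyz)))
}

#' Write molecules to an SDF (V2000) file
#'
#' Writes each molecule's first conformer (zero coordinates when absent)
#' with formal charges as `M  CHG` records.
#'
#' @param mols A [Molecule] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    X <- if (length(m$conformers) > 0L) m$conformers[[1L]]
         else matrix(0, nrow(m$atoms), 3L)
    order_code <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
    lines <- c(m$name, "  phorescreen", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(m$atoms), nrow(m$bonds)))
    for (i in seq_len(nrow(m$atoms))) {
      lines <- c(lines, sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        X[i, 1L], X[i, 2L], X[i, 3L], m$atoms$element[i]))
    }
    for (k in seq_len(nrow(m$bonds))) {
      lines <- c(lines, sprintf("%3d%3d%3d  0", m$bonds$a[k], m$bonds$b[k],
                                order_code[[m$bonds$order[k]]]))
    }
    chg <- which(m$atoms$charge != 0L)
    if (length(chg) > 0L) {
      for (grp in split(chg, ceiling(seq_along(chg) / 8L))) {
        lines <- c(lines, paste0(
          sprintf("M  CHG%3d", length(grp)),
          paste(sprintf("%4d%4d", grp, m$atoms$charge[grp]), collapse = "")))
      }
    }
    lines <- c(lines, "M  END", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a toy-pocket bundle to a directory
#'
#' Writes `pocket.pdb`, `pose.sdf`, `site.json` and `manifest.json` as
#' produced by [generate_toy_pocket()].
#'
#' @param pocket Result of [generate_toy_pocket()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_toy_pocket <- function(pocket, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(pocket$pdb, file.path(dir, "pocket.pdb"))
  write_sdf(pocket$pose, file.path(dir, "pose.sdf"))
  save_active_site(pocket$site, file.path(dir, "site.json"))
  jsonlite::write_json(pocket$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
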