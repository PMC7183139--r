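# Pipeline orchestration: descriptors -> drug-likeness -> pharmacophore
# screening -> ranked hit report.

#' Default screening configuration
#'
#' @param max_violations Lipinski violations allowed to pass (default 1).
#' @param n_conformers Conformers per molecule for pharmacophore screening.
#' @param seed Embedding seed.
#' @param tolerance Pharmacophore match tolerance in Angstrom.
#' @param do_phore Run the pharmacophore stage? (Descriptors and
#'   drug-likeness are always computed, so the property table can be
#'   reported for non-hits too.)
#' @return Named list of settings.
#' @export
screen_config <- function(max_violations = 1L, n_conformers = 25L,
                          seed = 42L, tolerance = 1.5, do_phore = TRUE) {
  list(max_violations = as.integer(max_violations),
       n_conformers = as.integer(n_conformers), seed = as.integer(seed),
       tolerance = tolerance, do_phore = isTRUE(do_phore))
}

#' Run the full screening pipeline over a compound library
#'
#' Every compound receives descriptors and a Lipinski report; when the
#' pharmacophore stage is enabled, each compound is screened against the
#' model over a seeded conformer ensemble. Matched compounds are ranked by
#' ascending match RMSD, ties broken by descending estimated absorption,
#' then input order. Per-compound failures are recorded and skipped
#' without aborting the run.
#'
#' @param library List of [Molecule] objects (or SMILES strings).
#' @param model A `PharmacophoreModel`, or `NULL` to skip matching.
#' @param config See [screen_config()].
#' @return A `HitTable` data frame: one row per compound with descriptor,
#'   rule, match and rank columns.
#' @export
run_screen <- function(library, model = NULL,
                       config = screen_config()) {
  if (length(library) == 0L) stop("library is empty")
  rows <- vector("list", length(library))
  n_ok <- 0L
  for (i in seq_along(library)) {
    m <- library[[i]]
    row <- tryCatch({
      if (is.character(m)) {
        nm <- if (!is.null(names(library)) && nzchar(names(library)[i]))
          names(library)[i] else paste0("mol", i)
        m <- parse_smiles(m, nm)
      }
      d <- descriptor_set(m)
      r <- lipinski_report(d)
      matched <- NA
      rmsd <- NA_real_
      conf <- NA_integer_
      if (config$do_phore && !is.null(model)) {
        res <- screen_molecule(m, model, config$n_conformers, config$seed,
                               config$tolerance)
        matched <- res$matched
        rmsd <- res$rmsd
        conf <- res$conformer_index
      }
      n_ok <- n_ok + 1L
      data.frame(id = m$name,
                 smiles = if (!is.null(m$smiles)) m$smiles
                          else write_smiles(m),
                 mw = d$mw, logp = d$logp, tpsa = d$tpsa, n_on = d$n_on,
                 n_ohnh = d$n_ohnh, n_rotb = d$n_rotb, pct_ab = d$pct_ab,
                 n_violations = r$n_violations,
                 druglike = r$n_violations <= config$max_violations,
                 matched = matched, phore_rmsd = rmsd,
                 conformer_index = conf, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      nm <- if (inherits(m, "Molecule")) m$name
            else if (!is.null(names(library)) && nzchar(names(library)[i]))
              names(library)[i] else paste0("mol", i)
      data.frame(id = nm, smiles = if (is.character(m)) m else NA_character_,
                 mw = NA_real_, logp = NA_real_, tpsa = NA_real_,
                 n_on = NA_integer_, n_ohnh = NA_integer_,
                 n_rotb = NA_integer_, pct_ab = NA_real_,
                 n_violations = NA_integer_, druglike = NA,
                 matched = NA, phore_rmsd = NA_real_,
                 conformer_index = NA_integer_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- row
  }
  if (n_ok == 0L) stop("all compounds failed: ",
                       rows[[1L]]$error)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  # rank matched compounds: ascending rmsd, descending pct_ab, input order
  out$rank <- NA_integer_
  hit <- which(!is.na(out$matched) & out$matched)
  if (length(hit) > 0L) {
    ord <- hit[order(out$phore_rmsd[hit], -out$pct_ab[hit], hit)]
    out$rank[ord] <- seq_along(ord)
  }
  class(out) <- c("HitTable", "data.frame")
  out
}

#' @export
print.HitTable <- function(x, ...) {
  nhit <- sum(!is.na(x$rank))
  cat(sprintf("<HitTable: %d compound(s), %d ranked hit(s)>\n",
              nrow(x), nhit))
  print.data.frame(utils::head(as.data.frame(x)[
    order(is.na(x$rank), x$rank), c("id", "mw", "tpsa", "n_violations",
                                    "matched", "phore_rmsd", "rank")], 10L),
    digits = 4L)
  invisible(x)
}

#' Write a hit table as TSV
#'
#' Fixed column order, floats at 2 decimals (molecular weight at 3);
#' byte-identical output for identical inputs.
#'
#' @param hits A `HitTable` from [run_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  cols <- c("id", "smiles", "mw", "logp", "tpsa", "n_on", "n_ohnh",
            "n_rotb", "pct_ab", "n_violations", "matched", "phore_rmsd",
            "rank")
  fmt2 <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", v))
  lines <- paste(cols, collapse = "\t")
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    lines <- c(lines, paste(c(
      h$id, ifelse(is.na(h$smiles), "NA", h$smiles),
      ifelse(is.na(h$mw), "NA", sprintf("%.3f", h$mw)),
      fmt2(h$logp), fmt2(h$tpsa),
      ifelse(is.na(h$n_on), "NA", h$n_on),
      ifelse(is.na(h$n_ohnh), "NA", h$n_ohnh),
      ifelse(is.na(h$n_rotb), "NA", h$n_rotb),
      fmt2(h$pct_ab),
      ifelse(is.na(h$n_violations), "NA", h$n_violations),
      ifelse(is.na(h$matched), "NA", ifelse(h$matched, "true", "false")),
      fmt2(h$phore_rmsd),
      ifelse(is.na(h$rank), "NA", h$rank)), collapse = "\t"))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
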