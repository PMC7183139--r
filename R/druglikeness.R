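# Lipinski rule-of-five evaluation: MW <= 500, logP <= 5, donors <= 5,
# acceptors <= 10, each boundary inclusive.

#' Lipinski rule-of-five report
#'
#' Evaluates the four rules against a [descriptor_set()] result. Boundaries
#' are inclusive: a molecular weight of exactly 500 passes.
#'
#' @param d A `DescriptorSet`.
#' @return A `RuleReport` (named list): logical `mw_ok`, `logp_ok`,
#'   `hbd_ok`, `hba_ok` and integer `n_violations` (0-4).
#' @export
lipinski_report <- function(d) {
  flags <- c(mw_ok = d$mw <= 500,
             logp_ok = d$logp <= 5,
             hbd_ok = d$n_ohnh <= 5,
             hba_ok = d$n_on <= 10)
  structure(c(as.list(flags),
              list(n_violations = as.integer(sum(!flags)), name = d$name)),
            class = "RuleReport")
}

#' @export
print.RuleReport <- function(x, ...) {
  lab <- c("MW<=500", "logP<=5", "nOHNH<=5", "nON<=10")
  ok <- unlist(x[c("mw_ok", "logp_ok", "hbd_ok", "hba_ok")])
  cat(sprintf("<RuleReport %s: %d violation(s)%s>\n", x$name, x$n_violations,
              if (any(!ok)) paste0(" [", paste(lab[!ok], collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Drug-likeness filter over rule reports
#'
#' @param reports List of `RuleReport` objects.
#' @param max_violations Maximum violations allowed to pass (default 1,
#'   i.e. compounds violating more than one rule are flagged).
#' @return Logical pass/fail mask, in input order.
#' @export
apply_druglike_filter <- function(reports, max_violations = 1L) {
  if (max_violations < 0L) stop("max_violations must be >= 0")
  vapply(reports, function(r) r$n_violations <= max_violations, FALSE)
}
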