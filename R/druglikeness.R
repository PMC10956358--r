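#' Default drug-likeness rule set
#'
#' Literature-standard cutoffs for the five classic filters.  All boundary
#' comparisons are inclusive (a property exactly at a limit passes).
#' Lipinski's rule of five conventionally accepts up to one violation; the
#' maximum is configurable in [evaluate_rules()].
#'
#' @return A named list of rule definitions, each a list of sub-rules
#'   `(field, op, limit)`.
#' @export
druglikeness_rules <- function() {
  list(
    lipinski = list(
      list(field = "mw", op = "<=", limit = 500),
      list(field = "logp", op = "<=", limit = 5),
      list(field = "hbd", op = "<=", limit = 5),
      list(field = "hba", op = "<=", limit = 10)),
    ghose = list(
      list(field = "mw", op = ">=", limit = 160),
      list(field = "mw", op = "<=", limit = 480),
      list(field = "logp", op = ">=", limit = -0.4),
      list(field = "logp", op = "<=", limit = 5.6),
      list(field = "molar_refractivity", op = ">=", limit = 40),
      list(field = "molar_refractivity", op = "<=", limit = 130),
      list(field = "heavy_atoms", op = ">=", limit = 20),
      list(field = "heavy_atoms", op = "<=", limit = 70)),
    veber = list(
      list(field = "rot_bonds", op = "<=", limit = 10),
      list(field = "tpsa", op = "<=", limit = 140)),
    egan = list(
      list(field = "logp", op = "<=", limit = 5.88),
      list(field = "tpsa", op = "<=", limit = 131.6)),
    muegge = list(
      list(field = "mw", op = ">=", limit = 200),
      list(field = "mw", op = "<=", limit = 600),
      list(field = "logp", op = ">=", limit = -2),
      list(field = "logp", op = "<=", limit = 5),
      list(field = "tpsa", op = "<=", limit = 150),
      list(field = "rings", op = "<=", limit = 7),
      list(field = "rot_bonds", op = "<=", limit = 15),
      list(field = "hba", op = "<=", limit = 10),
      list(field = "hbd", op = "<=", limit = 5)))
}

#' Evaluate drug-likeness rules on a physicochemical profile
#'
#' Properties are consumed, never computed: the profile must already carry
#' molecular weight (`mw`, g/mol), `logp`, hydrogen-bond donor/acceptor
#' counts (`hbd`, `hba`), topological polar surface area (`tpsa`, A^2),
#' rotatable bonds (`rot_bonds`), and - for Ghose/Muegge -
#' `molar_refractivity`, `heavy_atoms`, `rings`.
#'
#' @param profile A named list or single-row data frame of properties.
#' @param rules Rule set (default [druglikeness_rules()]); subset to
#'   evaluate fewer rules.
#' @param lipinski_max_violations Violations tolerated before Lipinski
#'   rejects (default 1, the rule-of-five convention).  All other rules
#'   reject on any violation.
#' @return A named list per rule: `accept` (logical) and `violations`
#'   (character vector, e.g. `"tpsa > 131.6"`).
#' @export
evaluate_rules <- function(profile, rules = druglikeness_rules(),
                           lipinski_max_violations = 1L) {
  if (is.data.frame(profile)) {
    if (nrow(profile) != 1L) stop("one profile at a time", call. = FALSE)
    profile <- as.list(profile)
  }
  lapply_named <- function(nms, f) stats::setNames(lapply(nms, f), nms)
  lapply_named(names(rules), function(rule_name) {
    sub <- rules[[rule_name]]
    fields <- unique(vapply(sub, `[[`, character(1), "field"))
    missing_fields <- fields[!vapply(fields, function(f)
      !is.null(profile[[f]]) && is.finite(profile[[f]]), logical(1))]
    if (length(missing_fields)) {
      stop("rule '", rule_name, "' requires missing field(s): ",
           paste(missing_fields, collapse = ", "), call. = FALSE)
    }
    viol <- character(0)
    for (s in sub) {
      v <- profile[[s$field]]
      ok <- if (s$op == "<=") v <= s$limit else v >= s$limit
      if (!ok) {
        viol <- c(viol, paste(s$field, if (s$op == "<=") ">" else "<",
                              s$limit))
      }
    }
    max_viol <- if (rule_name == "lipinski") lipinski_max_violations else 0L
    list(accept = length(viol) <= max_viol, violations = viol)
  })
}

#' Evaluate drug-likeness rules for a table of compounds
#'
#' @param profiles Data frame with an `id` column plus the property columns
#'   used by `rules`.
#' @param rules Rule set (default [druglikeness_rules()]).
#' @param lipinski_max_violations Passed to [evaluate_rules()].
#' @return Data frame: `id`, one `<rule>` verdict column
#'   (`"Accept"`/`"Reject"`), and one `<rule>_violations` column
#'   (semicolon-separated).
#' @export
evaluate_rules_table <- function(profiles, rules = druglikeness_rules(),
                                 lipinski_max_violations = 1L) {
  stopifnot(is.data.frame(profiles), "id" %in% names(profiles))
  out <- data.frame(id = profiles$id, stringsAsFactors = FALSE)
  verdicts <- lapply(seq_len(nrow(profiles)), function(i) {
    evaluate_rules(profiles[i, , drop = FALSE], rules,
                   lipinski_max_violations)
  })
  for (rule_name in names(rules)) {
    out[[rule_name]] <- vapply(verdicts, function(v)
      if (v[[rule_name]]$accept) "Accept" else "Reject", character(1))
    out[[paste0(rule_name, "_violations")]] <- vapply(verdicts, function(v)
      paste(v[[rule_name]]$violations, collapse = "; "), character(1))
  }
  out
}
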