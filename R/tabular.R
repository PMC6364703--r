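# Tabular model dialect: a reactions TSV (id, equation, lower_bound,
# upper_bound, gpr, subsystem) plus a metabolites TSV (id, name, compartment).
# Equations are written as "2 a + 3 b --> c" over metabolite ids; the arrow
# ("-->" or "<=>") is purely cosmetic, directionality lives in the bounds.

#' Format a stoichiometry vector as an equation string
#' @param stoich Named numeric vector (negative = consumed).
#' @param reversible Use `<=>` instead of `-->`.
#' @return Equation string.
#' @export
format_equation <- function(stoich, reversible = FALSE) {
  side <- function(coefs) {
    if (length(coefs) == 0) return("")
    paste(vapply(seq_along(coefs), function(i) {
      coef <- abs(coefs[[i]])
      if (coef == 1) names(coefs)[i] else paste(format(coef, scientific = FALSE),
                                                names(coefs)[i])
    }, character(1)), collapse = " + ")
  }
  arrow <- if (reversible) "<=>" else "-->"
  paste(side(stoich[stoich < 0]), arrow, side(stoich[stoich > 0]))
}

#' Parse an equation string into a stoichiometry vector
#' @param equation Equation string, e.g. `"2 a + b --> c"`.
#' @return Named numeric vector keyed by metabolite id.
#' @export
parse_equation <- function(equation) {
  arrow <- regmatches(equation, regexpr("-->|<=>|<->|=>", equation))
  if (length(arrow) == 0) stop("equation lacks an arrow: ", equation, call. = FALSE)
  sides <- strsplit(equation, arrow[1], fixed = TRUE)[[1]]
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms[nzchar(terms)]) {
      parts <- strsplit(term, "\\s+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1
        met <- parts
      } else {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop("bad coefficient in term '", term, "'", call. = FALSE)
        met <- paste(parts[-1], collapse = " ")
      }
      out[met] <- (out[met] %||% 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  combined <- lhs
  for (met in names(rhs)) combined[met] <- (combined[met] %||% 0) + rhs[met]
  combined[combined != 0]
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 ||
      (length(a) == 1 && is.atomic(a) && is.na(a))) b else a
}

#' Read a model from the tabular dialect
#'
#' @param reactions_path TSV with columns `id`, `equation`, `lower_bound`,
#'   `upper_bound`, `gpr`, `subsystem`.
#' @param metabolites_path TSV with columns `id`, `name`, `compartment`.
#' @param biomass_reaction_id Id of the biomass reaction.
#' @return A [gsm()].
#' @export
read_gsm_tsv <- function(reactions_path, metabolites_path, biomass_reaction_id) {
  rx <- utils::read.delim(reactions_path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  mets <- utils::read.delim(metabolites_path, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            na.strings = c("NA"))
  rx$stoichiometry <- lapply(rx$equation, parse_equation)
  rx$equation <- NULL
  gsm(rx, mets, biomass_reaction_id)
}

#' Write a model in the tabular dialect
#'
#' @param model A [gsm()].
#' @param reactions_path,metabolites_path Output TSV paths.
#' @return Invisibly, the model.
#' @export
write_gsm_tsv <- function(model, reactions_path, metabolites_path) {
  rx <- model$reactions
  out <- data.frame(
    id = rx$id,
    equation = vapply(seq_len(nrow(rx)), function(i) {
      format_equation(rx$stoichiometry[[i]], reversible = rx$lower_bound[i] < 0)
    }, character(1)),
    lower_bound = rx$lower_bound,
    upper_bound = rx$upper_bound,
    gpr = rx$gpr,
    subsystem = rx$subsystem,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, reactions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(model$metabolites[, c("id", "name", "compartment")],
                     metabolites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(model)
}
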