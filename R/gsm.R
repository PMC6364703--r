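# Core genome-scale model container.
#
# A `gsm` is a list of two tibbles plus bookkeeping:
#   metabolites: id, name, compartment
#   reactions:   id, stoichiometry (list of named numerics, negative =
#                consumed), lower_bound, upper_bound, gpr, subsystem
# Bounds are in mmol gDW^-1 hr^-1; reactions without stated bounds default to
# +/- 10,000, a single global "effectively unbounded" magnitude shared with
# the transfer-reaction cap.

#' Default flux bound magnitude (mmol gDW^-1 hr^-1)
#' @keywords internal
DEFAULT_BOUND <- 10000

#' Construct a genome-scale model
#'
#' @param reactions Tibble/data frame with columns `id`, `stoichiometry`
#'   (list column of named numeric vectors keyed by metabolite id; negative
#'   coefficients consume, positive produce), `lower_bound`, `upper_bound`,
#'   and optionally `gpr` (boolean gene rule string) and `subsystem`.
#' @param metabolites Tibble/data frame with columns `id`, `compartment`, and
#'   optionally `name`.
#' @param biomass_reaction_id Id of the biomass (growth) reaction.
#' @param exchange_ids Optional character vector of exchange reaction ids;
#'   when `NULL`, reactions touching exactly one metabolite are taken as
#'   exchanges.
#'
#' @return An object of class `gsm`.
#' @export
gsm <- function(reactions, metabolites, biomass_reaction_id,
                exchange_ids = NULL) {
  reactions <- tibble::as_tibble(reactions)
  metabolites <- tibble::as_tibble(metabolites)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  reactions$lower_bound[is.na(reactions$lower_bound)] <- -DEFAULT_BOUND
  reactions$upper_bound[is.na(reactions$upper_bound)] <- DEFAULT_BOUND

  if (is.null(exchange_ids)) {
    n_met <- vapply(reactions$stoichiometry, length, integer(1))
    exchange_ids <- reactions$id[n_met == 1L]
  }
  model <- structure(
    list(
      reactions = reactions,
      metabolites = metabolites,
      biomass_reaction_id = biomass_reaction_id,
      exchange_ids = exchange_ids
    ),
    class = "gsm"
  )
  validate_gsm(model)
}

#' Validate a genome-scale model's structural invariants
#'
#' Checks id uniqueness, referential integrity of every stoichiometry entry,
#' bound ordering (lower <= upper), presence of the biomass reaction, that
#' declared exchanges touch exactly one metabolite, and that every GPR string
#' parses to a valid and/or tree.
#'
#' @param model A `gsm`.
#' @return The model, invisibly unchanged, or an error.
#' @export
validate_gsm <- function(model) {
  rx <- model$reactions
  mets <- model$metabolites
  if (anyDuplicated(rx$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rx$id[duplicated(rx$id)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(rx))) {
    s <- rx$stoichiometry[[i]]
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown) > 0) {
      stop("reaction '", rx$id[i], "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  bad <- rx$lower_bound > rx$upper_bound
  if (any(bad)) {
    stop("lower_bound > upper_bound for: ",
         paste(rx$id[bad], collapse = ", "), call. = FALSE)
  }
  if (!model$biomass_reaction_id %in% rx$id) {
    stop("biomass reaction '", model$biomass_reaction_id,
         "' not present in the model", call. = FALSE)
  }
  for (ex in model$exchange_ids) {
    s <- rx$stoichiometry[[match(ex, rx$id)]]
    if (length(s) != 1L) {
      stop("exchange reaction '", ex, "' must touch exactly one metabolite",
           call. = FALSE)
    }
  }
  for (i in seq_len(nrow(rx))) {
    if (nzchar(rx$gpr[i])) parse_gpr(rx$gpr[i]) # errors on malformed rules
  }
  invisible(model)
}

#' @export
print.gsm <- function(x, ...) {
  s <- model_stats(x)
  cat("<gsm> ", s$n_reactions, " reactions, ", s$n_metabolites,
      " metabolites, ", s$n_genes, " genes, ", s$n_exchanges,
      " exchanges\n", sep = "")
  cat("biomass: ", x$biomass_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Gene ids referenced by a model's GPR rules
#' @param model A `gsm`.
#' @return Character vector of unique gene ids.
#' @export
gene_ids <- function(model) {
  gprs <- model$reactions$gpr
  sort(unique(unlist(lapply(gprs[nzchar(gprs)], gpr_genes))))
}

#' Summarise model size
#'
#' @param model A `gsm`.
#' @return A one-row tibble with `n_reactions`, `n_metabolites`, `n_genes`,
#'   and `n_exchanges`.
#' @export
model_stats <- function(model) {
  tibble::tibble(
    n_reactions = nrow(model$reactions),
    n_metabolites = nrow(model$metabolites),
    n_genes = length(gene_ids(model)),
    n_exchanges = length(model$exchange_ids)
  )
}
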