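# Diazotrophy extension: nitrogen-fixation reactions replicated into every
# TPM plus the nitrogenase/oxygen mutual-exclusion MILP. Nitrogenase is
# irreversibly inhibited by oxygen, so per TPM at most one of {N2 fixation,
# O2 carry-over to the next TPM} may be active:
#   LB_fix * y_n2 <= v_fix      <= UB_fix * y_n2
#   LB_o2  * y_o2 <= v_o2transfer <= UB_o2 * y_o2
#   y_n2 + y_o2 <= 1
# Big-M values are each governed reaction's own bounds, keeping the
# relaxation tight. Only the inter-TPM O2 transfer (carry-over) is gated,
# not the extracellular O2 exchange.

#' Add nitrogen-fixation reactions to a diel model
#'
#' The supplied reactions (the ATP-hydrolyzing dinitrogen reduction itself,
#' the N2 exchange, and the two diffusion transport steps linking the
#' extracellular space, periplasm, and cytosol) are replicated into every
#' TPM exactly like core reactions. New metabolites they introduce are added
#' to each TPM; they do not receive transfer reactions.
#'
#' @param model An assembled `diel_model`.
#' @param nif_reactions Tibble in the [gsm()] reaction layout (`id`,
#'   `stoichiometry`, `lower_bound`, `upper_bound`, optional `gpr`,
#'   `subsystem`).
#' @param nif_metabolites Optional tibble (`id`, `name`, `compartment`) for
#'   metabolites not already in the base model.
#' @return The extended model; `model$nif_ids` records the added base ids.
#' @export
add_nitrogen_fixation <- function(model, nif_reactions,
                                  nif_metabolites = NULL) {
  nif <- tibble::as_tibble(nif_reactions)
  if (!"gpr" %in% names(nif)) nif$gpr <- ""
  if (!"subsystem" %in% names(nif)) nif$subsystem <- ""

  known <- model$base$metabolites$id
  new_mets <- if (is.null(nif_metabolites)) {
    tibble::tibble(id = character(0), name = character(0),
                   compartment = character(0))
  } else {
    tibble::as_tibble(nif_metabolites) |>
      dplyr::filter(!.data$id %in% known)
  }
  all_mets <- c(known, new_mets$id)
  referenced <- unique(unlist(lapply(nif$stoichiometry, names)))
  unknown <- setdiff(referenced, all_mets)
  if (length(unknown) > 0) {
    stop("nif reactions reference undeclared metabolite(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  # The fixation substrate must be reachable: demand an exchange (a
  # single-metabolite reaction) and a connected transport chain so that N2
  # can diffuse from the environment into the cytosol.
  n_touched <- vapply(nif$stoichiometry, length, integer(1))
  if (!any(n_touched == 1L)) {
    stop("nif reaction set lacks an exchange reaction; ",
         "N2 cannot enter the system", call. = FALSE)
  }
  if (!any(n_touched == 2L)) {
    stop("nif reaction set lacks transport reactions; ",
         "N2 cannot reach the cytosol", call. = FALSE)
  }

  K <- model$config$n_tpm
  if (nrow(new_mets) > 0) {
    extra <- tidyr::crossing(tpm = seq_len(K), base_id = new_mets$id) |>
      dplyr::left_join(new_mets, by = c(base_id = "id")) |>
      dplyr::mutate(instance_id = instance_met_id(.data$base_id, .data$tpm)) |>
      dplyr::select("instance_id", "base_id", "tpm", "compartment")
    model$metabolites <- dplyr::bind_rows(model$metabolites, extra)
    model$base$metabolites <- dplyr::bind_rows(model$base$metabolites,
                                               new_mets)
  }

  rows <- vector("list", K)
  for (k in seq_len(K)) {
    rows[[k]] <- tibble::tibble(
      instance_id = instance_rxn_id(nif$id, k),
      base_id = nif$id,
      tpm = k,
      type = "core",
      metabolite = NA_character_,
      lb = nif$lower_bound,
      ub = nif$upper_bound,
      ub_unscaled = nif$upper_bound,
      ratio = NA_real_,
      stoich = lapply(nif$stoichiometry, function(s) {
        stats::setNames(as.numeric(s), instance_met_id(names(s), k))
      })
    )
  }
  model$reactions <- dplyr::bind_rows(model$reactions, dplyr::bind_rows(rows))
  model$base$reactions <- dplyr::bind_rows(
    model$base$reactions,
    nif[, c("id", "stoichiometry", "lower_bound", "upper_bound", "gpr",
            "subsystem")]
  )
  ex <- nif$id[n_touched == 1L]
  model$base$exchange_ids <- c(model$base$exchange_ids, ex)
  model$nif_ids <- nif$id
  model
}

#' Impose the nitrogenase / oxygen mutual-exclusion constraints
#'
#' Adds, per TPM, two binary indicators (fixation active; O2 transferred to
#' the next TPM) with big-M rows taken from the governed reactions' own
#' bounds, and the exclusion row `y_n2 + y_o2 <= 1`.
#'
#' @param model A `diel_model` after [add_nitrogen_fixation()] and with
#'   transfers present.
#' @param fixation_id Base id of the nitrogen-fixation reaction.
#' @param o2_metabolite_id Metabolite id of cytosolic oxygen (its transfer
#'   reactions are the gated carry-over).
#' @return The model with `binaries` and `exclusion_rows` populated.
#' @export
add_oxygen_exclusion <- function(model, fixation_id, o2_metabolite_id) {
  rx <- model$reactions
  K <- model$config$n_tpm
  binaries <- list()
  rows <- list()
  for (k in seq_len(K)) {
    fix_inst <- instance_rxn_id(fixation_id, k)
    o2_inst <- transfer_rxn_id(o2_metabolite_id, k, next_tpm(k, K))
    fi <- match(fix_inst, rx$instance_id)
    oi <- match(o2_inst, rx$instance_id)
    if (is.na(fi)) {
      stop("fixation instance '", fix_inst, "' not found; run ",
           "add_nitrogen_fixation() first", call. = FALSE)
    }
    if (is.na(oi)) {
      stop("O2 transfer reaction '", o2_inst, "' not found; is '",
           o2_metabolite_id, "' a transferable metabolite?", call. = FALSE)
    }
    y_n2 <- paste0("y_n2fix_tpm", k)
    y_o2 <- paste0("y_o2transfer_tpm", k)
    binaries[[length(binaries) + 1L]] <- tibble::tibble(
      var_id = c(y_n2, y_o2), tpm = k, kind = c("n2", "o2"),
      governed = c(fix_inst, o2_inst), lb = 0, ub = 1)
    # v - UB*y <= 0 and v - LB*y >= 0 for each governed pair
    rows[[length(rows) + 1L]] <- tibble::tibble(
      label = c(paste0("bigM_ub_n2_tpm", k), paste0("bigM_lb_n2_tpm", k),
                paste0("bigM_ub_o2_tpm", k), paste0("bigM_lb_o2_tpm", k),
                paste0("exclusion_tpm", k)),
      coefs = list(
        stats::setNames(c(1, -rx$ub[fi]), c(fix_inst, y_n2)),
        stats::setNames(c(1, -rx$lb[fi]), c(fix_inst, y_n2)),
        stats::setNames(c(1, -rx$ub[oi]), c(o2_inst, y_o2)),
        stats::setNames(c(1, -rx$lb[oi]), c(o2_inst, y_o2)),
        stats::setNames(c(1, 1), c(y_n2, y_o2))
      ),
      lb = c(-Inf, 0, -Inf, 0, -Inf),
      ub = c(0, Inf, 0, Inf, 1)
    )
  }
  model$binaries <- dplyr::bind_rows(binaries)
  model$exclusion_rows <- dplyr::bind_rows(rows)
  model
}

#' Fix the exclusion binaries at given values
#'
#' Used to freeze the MILP incumbent's fixation schedule before re-running
#' the (purely linear) pFBA and FVA stages.
#'
#' @param model A `diel_model` with binaries.
#' @param values Named numeric vector (`var_id` -> 0/1), e.g. from
#'   `solution$binaries`.
#' @return The model with binary bounds pinned.
#' @export
freeze_binaries <- function(model, values) {
  stopifnot(!is.null(model$binaries))
  idx <- match(model$binaries$var_id, names(values))
  if (anyNA(idx)) stop("values must cover every binary", call. = FALSE)
  v <- round(as.numeric(values[idx]))
  model$binaries$lb <- v
  model$binaries$ub <- v
  model
}

#' Solve the diazotrophic model
#'
#' Maximizes biomass as a mixed-integer problem over the exclusion binaries.
#' The returned solution carries the incumbent binary schedule
#' (`solution$binaries`), which [diazotroph_cascade()] freezes for the
#' transfer-minimizing pFBA and FVA stages.
#'
#' @param model A `diel_model` with exclusion rows present.
#' @return A `flux_solution`.
#' @export
solve_diazotroph <- function(model) {
  stopifnot(!is.null(model$binaries))
  maximize_biomass(model)
}

#' Full cascade for a diazotrophic model
#'
#' MILP biomass maximization, then pFBA and FVA with the binaries frozen at
#' the incumbent schedule (`free_binaries = TRUE` leaves them free, which is
#' considerably slower).
#'
#' @param model A `diel_model` with exclusion rows.
#' @param fva_targets Passed to [fva()].
#' @param free_binaries Keep binaries free during pFBA/FVA.
#' @return A `diel_cascade` (see [solve_cascade()]).
#' @export
diazotroph_cascade <- function(model, fva_targets = NULL,
                               free_binaries = FALSE) {
  bm <- solve_diazotroph(model)
  if (bm$status != "optimal") {
    return(structure(list(biomass = bm, f = NA_real_, pfba = NULL,
                          fva = NULL), class = "diel_cascade"))
  }
  work <- if (free_binaries) {
    model
  } else {
    freeze_binaries(model, stats::setNames(bm$binaries$value,
                                           bm$binaries$var_id))
  }
  pf <- minimize_transfers(work, bm$objective_value)
  ranges <- fva(work, bm$objective_value, pf$f, targets = fva_targets)
  structure(list(biomass = bm, f = pf$f, pfba = pf$solution, fva = ranges),
            class = "diel_cascade")
}

#' Classify per-reaction differences between two strains' FVA envelopes
#'
#' Ranges are compared instance by instance at tolerance `tau`:
#' `upregulated` when the mutant range lies wholly above the wild-type range
#' (`mut_min > wt_max + tau`), `downregulated` when wholly below, otherwise
#' `unchanged` (overlap). `switched` marks reactions whose two ranges both
#' exclude zero with opposite signs. A strain finds a reaction `essential`
#' when its range is strictly positive (`min > tau`) or strictly negative
#' (`max < -tau`).
#'
#' @param wt,mut `fva_result` tibbles over the same reaction-instance
#'   universe.
#' @param tau Zero/overlap tolerance.
#' @return A tibble with the two ranges, `direction`, `switched`,
#'   `essential_wt`, `essential_mut`, and a combined `class` token.
#' @export
compare_ranges <- function(wt, mut, tau = FLUX_TOL) {
  unmatched <- c(setdiff(wt$instance_id, mut$instance_id),
                 setdiff(mut$instance_id, wt$instance_id))
  if (length(unmatched) > 0) {
    stop("reaction-instance universes differ: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  merged <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(wt), "instance_id", "base_id", "tpm",
                  wt_min = "min", wt_max = "max"),
    dplyr::select(tibble::as_tibble(mut), "instance_id",
                  mut_min = "min", mut_max = "max"),
    by = "instance_id"
  )
  merged |>
    dplyr::mutate(
      direction = dplyr::case_when(
        .data$mut_min > .data$wt_max + tau ~ "upregulated",
        .data$mut_max < .data$wt_min - tau ~ "downregulated",
        TRUE ~ "unchanged"
      ),
      essential_wt = .data$wt_min > tau | .data$wt_max < -tau,
      essential_mut = .data$mut_min > tau | .data$mut_max < -tau,
      switched = .data$essential_wt & .data$essential_mut &
        sign(.data$wt_min + .data$wt_max) != sign(.data$mut_min + .data$mut_max),
      class = dplyr::case_when(
        .data$switched ~ "switched",
        .data$direction != "unchanged" ~ .data$direction,
        .data$essential_mut & !.data$essential_wt ~ "essential_mut_only",
        .data$essential_mut & .data$essential_wt ~ "essential_both",
        TRUE ~ "unchanged"
      )
    )
}

#' Summarise a strain comparison with instance and unique-reaction counts
#'
#' Deduplication is by base reaction id across TPMs, so a reaction flagged in
#' several TPMs counts once in the `unique` columns.
#'
#' @param comparison Output of [compare_ranges()].
#' @return One-row tibble of instance-level and deduplicated counts.
#' @export
summarize_comparison <- function(comparison) {
  uniq <- function(flag) length(unique(comparison$base_id[flag]))
  up <- comparison$direction == "upregulated"
  down <- comparison$direction == "downregulated"
  ess <- comparison$essential_mut
  tibble::tibble(
    n_changed = sum(up | down),
    n_changed_unique = uniq(up | down),
    n_up = sum(up), n_up_unique = uniq(up),
    n_down = sum(down), n_down_unique = uniq(down),
    n_essential_mut = sum(ess), n_essential_mut_unique = uniq(ess),
    n_essential_mut_only = sum(ess & !comparison$essential_wt),
    n_switched = sum(comparison$switched)
  )
}
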