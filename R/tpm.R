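# Multi-phase (diel) model assembly: replicate a base model into K linked
# time point models (TPMs), join them with irreversible metabolite-transfer
# reactions, impose light/dark uptake bounds, place the biomass drain in a
# single TPM, and couple photosynthesis to pigment availability.

#' Configuration for diel model assembly
#'
#' Defaults are the standard 12-TPM instance: a 12 h light / 12 h dark cycle
#' split into twelve 2-hour TPMs, CO2 uptake capped at 1.1 and photon uptake
#' at 60 mmol gDW^-1 hr^-1 during the six light TPMs, a basal ATP maintenance
#' demand of 10 mmol gDW^-1 hr^-1 in every TPM, a transfer-flux cap of 10,000,
#' and a pigment-coupling constant `m_c` of 1000.
#'
#' @param n_tpm Number of time point models (K).
#' @param n_light Number of light TPMs (the first `n_light` of the cycle).
#' @param hours_per_tpm Duration represented by each TPM, hours.
#' @param co2_uptake_ub Light-phase CO2 uptake upper bound.
#' @param photon_uptake_ub Light-phase photon uptake upper bound.
#' @param atp_maintenance_lb ATP maintenance lower bound, every TPM.
#' @param m_c Pigment-coupling big constant; photosynthesis flux in TPM k is
#'   capped at `0.5 * m_c * (pigment transfer out - pigment transfer in)`.
#' @param transfer_ub Upper bound on every transfer reaction.
#' @param transfer_compartments Compartment tokens whose metabolites are
#'   transferred between consecutive TPMs.
#' @param non_transfer_metabolites Metabolite ids never transferred even when
#'   in a transfer compartment (photons, protons, and the like).
#' @param pigment_metabolite_ids Pigment (chlorophyll) metabolite ids.
#' @param photosynthesis_reaction_ids Reactions subject to pigment coupling.
#' @param co2_uptake_id,photon_uptake_id,atp_maintenance_id Reaction ids the
#'   phase bounds act on.
#' @param biomass_tpm TPM holding the single biomass drain.
#' @param wrap_around Create the closing transfer from TPM K back to TPM 1,
#'   making the transfer graph a directed cycle (periodic steady state).
#' @return A `tpm_config` list.
#' @export
tpm_config <- function(n_tpm = 12L,
                       n_light = 6L,
                       hours_per_tpm = 2,
                       co2_uptake_ub = 1.1,
                       photon_uptake_ub = 60,
                       atp_maintenance_lb = 10,
                       m_c = 1000,
                       transfer_ub = 10000,
                       transfer_compartments = c("c", "cx"),
                       non_transfer_metabolites = character(0),
                       pigment_metabolite_ids = character(0),
                       photosynthesis_reaction_ids = character(0),
                       co2_uptake_id = NULL,
                       photon_uptake_id = NULL,
                       atp_maintenance_id = NULL,
                       biomass_tpm = n_tpm,
                       wrap_around = TRUE) {
  n_tpm <- as.integer(n_tpm)
  n_light <- as.integer(n_light)
  stopifnot(n_tpm >= 1L, n_light >= 1L, n_light <= n_tpm, m_c > 0,
            hours_per_tpm > 0, transfer_ub >= 0)
  if (biomass_tpm < 1L || biomass_tpm > n_tpm) {
    stop("biomass_tpm must lie in 1..n_tpm", call. = FALSE)
  }
  structure(
    list(n_tpm = n_tpm, n_light = n_light, hours_per_tpm = hours_per_tpm,
         co2_uptake_ub = co2_uptake_ub, photon_uptake_ub = photon_uptake_ub,
         atp_maintenance_lb = atp_maintenance_lb, m_c = m_c,
         transfer_ub = transfer_ub,
         transfer_compartments = transfer_compartments,
         non_transfer_metabolites = non_transfer_metabolites,
         pigment_metabolite_ids = pigment_metabolite_ids,
         photosynthesis_reaction_ids = photosynthesis_reaction_ids,
         co2_uptake_id = co2_uptake_id, photon_uptake_id = photon_uptake_id,
         atp_maintenance_id = atp_maintenance_id,
         biomass_tpm = as.integer(biomass_tpm), wrap_around = wrap_around),
    class = "tpm_config"
  )
}

check_config_ids <- function(base, config) {
  rx_ids <- base$reactions$id
  met_ids <- base$metabolites$id
  offenders <- c(
    setdiff(config$pigment_metabolite_ids, met_ids),
    setdiff(config$non_transfer_metabolites, met_ids),
    setdiff(config$photosynthesis_reaction_ids, rx_ids),
    setdiff(stats::na.omit(c(config$co2_uptake_id, config$photon_uptake_id,
                             config$atp_maintenance_id)), rx_ids)
  )
  if (length(offenders) > 0) {
    stop("configured ids not present in the base model: ",
         paste(unique(offenders), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

instance_rxn_id <- function(id, k) paste0(id, "_tpm", k)
instance_met_id <- function(id, k) paste0(id, "[tpm", k, "]")
transfer_rxn_id <- function(met, from, to) {
  paste0("TR_", met, "_tpm", from, "_to_tpm", to)
}
next_tpm <- function(k, n_tpm) if (k == n_tpm) 1L else k + 1L
prev_tpm <- function(k, n_tpm) if (k == 1L) n_tpm else k - 1L

#' Replicate a base model into K time point models
#'
#' Every base reaction becomes K instances suffixed `_tpmX` and every
#' metabolite K instances suffixed `[tpmX]`, X in 1..K. Bounds, GPRs, and
#' stoichiometry are copied verbatim; base upper bounds are remembered per
#' instance (`ub_unscaled`) for later transcriptome scaling.
#'
#' @param base A [gsm()].
#' @param config A [tpm_config()].
#' @return A `diel_model`.
#' @export
replicate_tpm <- function(base, config) {
  validate_gsm(base)
  check_config_ids(base, config)
  K <- config$n_tpm
  rx <- base$reactions
  mets <- base$metabolites

  met_tab <- tidyr::crossing(tpm = seq_len(K),
                             base_id = mets$id) |>
    dplyr::left_join(mets, by = c(base_id = "id")) |>
    dplyr::mutate(instance_id = instance_met_id(.data$base_id, .data$tpm)) |>
    dplyr::select("instance_id", "base_id", "tpm", "compartment")

  rows <- vector("list", K)
  for (k in seq_len(K)) {
    stoich_k <- lapply(rx$stoichiometry, function(s) {
      stats::setNames(as.numeric(s), instance_met_id(names(s), k))
    })
    rows[[k]] <- tibble::tibble(
      instance_id = instance_rxn_id(rx$id, k),
      base_id = rx$id,
      tpm = k,
      type = "core",
      metabolite = NA_character_,
      lb = rx$lower_bound,
      ub = rx$upper_bound,
      ub_unscaled = rx$upper_bound,
      ratio = NA_real_,
      stoich = stoich_k
    )
  }

  structure(
    list(
      base = base,
      config = config,
      reactions = dplyr::bind_rows(rows),
      metabolites = met_tab,
      coupling_rows = tibble::tibble(label = character(0), tpm = integer(0),
                                     coefs = list(), rhs = numeric(0)),
      binaries = NULL,
      exclusion_rows = NULL,
      biomass_instance_id = NULL,
      transfers_added = FALSE,
      phase_bounds_applied = FALSE
    ),
    class = "diel_model"
  )
}

#' @export
print.diel_model <- function(x, ...) {
  n_core <- sum(x$reactions$type == "core")
  n_tr <- sum(x$reactions$type == "transfer")
  cat("<diel_model> K=", x$config$n_tpm, " (", x$config$n_light, " light): ",
      n_core, " core instances, ", n_tr, " transfer reactions, ",
      nrow(x$coupling_rows), " coupling rows",
      if (!is.null(x$binaries)) paste0(", ", nrow(x$binaries), " binaries"),
      "\n", sep = "")
  invisible(x)
}

transferable_metabolites <- function(base, config) {
  mets <- base$metabolites
  keep <- mets$compartment %in% config$transfer_compartments &
    !(mets$id %in% config$non_transfer_metabolites)
  mets$id[keep]
}

#' Add inter-TPM transfer reactions
#'
#' One irreversible transfer reaction is created per eligible metabolite per
#' TPM boundary k -> k+1 (plus K -> 1 when `wrap_around`), moving a
#' metabolite's surplus forward in time. Eligible metabolites are those in a
#' transfer compartment and not excluded (photons/protons are structurally
#' never transferred). Bounds are \[0, `transfer_ub`\].
#'
#' @param model A `diel_model` from [replicate_tpm()].
#' @param config The same [tpm_config()].
#' @return The model with transfer reactions appended.
#' @export
add_transfers <- function(model, config = model$config) {
  if (model$transfers_added) {
    stop("transfer reactions already added", call. = FALSE)
  }
  K <- config$n_tpm
  eligible <- transferable_metabolites(model$base, config)
  boundaries <- if (config$wrap_around) seq_len(K) else seq_len(K - 1L)

  rows <- list()
  for (k in boundaries) {
    k_next <- next_tpm(k, K)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      instance_id = transfer_rxn_id(eligible, k, k_next),
      base_id = paste0("TR_", eligible),
      tpm = as.integer(k),
      type = "transfer",
      metabolite = eligible,
      lb = 0,
      ub = config$transfer_ub,
      ub_unscaled = config$transfer_ub,
      ratio = NA_real_,
      stoich = lapply(eligible, function(m) {
        stats::setNames(c(-1, 1), c(instance_met_id(m, k),
                                    instance_met_id(m, k_next)))
      })
    )
  }
  model$reactions <- dplyr::bind_rows(model$reactions, dplyr::bind_rows(rows))
  model$transfers_added <- TRUE
  model
}

#' Apply light/dark phase bounds
#'
#' CO2 and photon uptake instances receive their configured upper bounds in
#' the light TPMs (k <= `n_light`) and an upper bound of 0 in the dark; the
#' ATP maintenance instance receives its lower bound in every TPM.
#'
#' @param model A `diel_model`.
#' @param config The same [tpm_config()].
#' @return The model with phase bounds set.
#' @export
apply_phase_bounds <- function(model, config = model$config) {
  for (field in c("co2_uptake_id", "photon_uptake_id", "atp_maintenance_id")) {
    if (is.null(config[[field]])) {
      stop("tpm_config$", field, " must be set before applying phase bounds",
           call. = FALSE)
    }
  }
  rx <- model$reactions
  light <- rx$tpm <= config$n_light
  co2 <- rx$type == "core" & rx$base_id == config$co2_uptake_id
  photon <- rx$type == "core" & rx$base_id == config$photon_uptake_id
  atpm <- rx$type == "core" & rx$base_id == config$atp_maintenance_id
  if (!any(co2) || !any(photon) || !any(atpm)) {
    stop("configured uptake/maintenance reactions missing from the model",
         call. = FALSE)
  }
  rx$ub[co2] <- ifelse(light[co2], config$co2_uptake_ub, 0)
  rx$ub[photon] <- ifelse(light[photon], config$photon_uptake_ub, 0)
  rx$lb[co2] <- pmin(rx$lb[co2], rx$ub[co2])
  rx$lb[photon] <- pmin(rx$lb[photon], rx$ub[photon])
  rx$lb[atpm] <- config$atp_maintenance_lb
  model$reactions <- rx
  model$phase_bounds_applied <- TRUE
  model
}

#' Restrict the biomass drain to a single TPM
#'
#' The biomass instance in TPM `biomass_tpm` keeps its bounds; all other
#' biomass instances are bounded to zero (kept in place rather than deleted,
#' so strain comparisons retain aligned reaction indices).
#'
#' @param model A `diel_model`.
#' @param config The same [tpm_config()].
#' @return The model with a single active biomass instance.
#' @export
place_biomass <- function(model, config = model$config) {
  if (config$biomass_tpm < 1L || config$biomass_tpm > config$n_tpm) {
    stop("biomass_tpm out of range 1..", config$n_tpm, call. = FALSE)
  }
  rx <- model$reactions
  bio <- rx$type == "core" & rx$base_id == model$base$biomass_reaction_id
  off <- bio & rx$tpm != config$biomass_tpm
  rx$lb[off] <- 0
  rx$ub[off] <- 0
  model$reactions <- rx
  model$biomass_instance_id <-
    instance_rxn_id(model$base$biomass_reaction_id, config$biomass_tpm)
  model
}

#' Couple photosynthesis to pigment availability
#'
#' For every configured photosynthesis reaction instance in TPM k, adds the
#' inequality `v_photo,k <= 0.5 * m_c * (pigment transfer out(k) - pigment
#' transfer in(k))`: photosynthetic flux is only available where the pigment
#' stock is being built up. With several pigment species the summed transfer
#' difference over the configured pool is used.
#'
#' TPM 1 is the cycle start and has no incoming-pigment term (the wrap-around
#' transfer, when present, still carries the pigment stock back for mass
#' balance). This is forced, not a convention: because photosynthesis fluxes
#' are non-negative, each coupling row requires its transfer difference to be
#' non-negative, and the differences telescope to exactly zero around a
#' closed ring — a fully cyclic k-1 term would pin every photosynthesis flux
#' to zero.
#'
#' @param model A `diel_model` with transfers added.
#' @param config The same [tpm_config()].
#' @return The model with coupling rows recorded.
#' @export
add_pigment_coupling <- function(model, config = model$config) {
  if (length(config$pigment_metabolite_ids) == 0 ||
      length(config$photosynthesis_reaction_ids) == 0) {
    return(model)
  }
  if (!model$transfers_added) {
    stop("add_transfers() must run before add_pigment_coupling()",
         call. = FALSE)
  }
  K <- config$n_tpm
  if (K == 1L && !config$wrap_around) {
    # a single unlinked TPM has no transfer boundaries, hence no pigment
    # inventory dynamics to couple against
    return(model)
  }
  existing <- model$reactions$instance_id
  rows <- list()
  for (k in seq_len(K)) {
    k_next <- next_tpm(k, K)
    out_ids <- transfer_rxn_id(config$pigment_metabolite_ids, k, k_next)
    in_ids <- if (k == 1L) {
      character(0) # cycle start: no incoming-pigment term
    } else {
      transfer_rxn_id(config$pigment_metabolite_ids, k - 1L, k)
    }
    out_ids <- out_ids[out_ids %in% existing]
    in_ids <- in_ids[in_ids %in% existing]
    if (length(out_ids) == 0) {
      if (!config$wrap_around && k == K) {
        # acyclic debug mode: the last TPM has no outgoing boundary, so the
        # transfer-based pigment inventory estimate does not exist there
        next
      }
      stop("no pigment transfer reactions found for TPM ", k,
           "; are the pigment metabolites transferable?", call. = FALSE)
    }
    half_mc <- config$m_c / 2
    for (rid in config$photosynthesis_reaction_ids) {
      coefs <- c(
        stats::setNames(1, instance_rxn_id(rid, k)),
        stats::setNames(rep(-half_mc, length(out_ids)), out_ids),
        stats::setNames(rep(+half_mc, length(in_ids)), in_ids)
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        label = paste0("pigment_coupling_", rid, "_tpm", k),
        tpm = as.integer(k),
        coefs = list(coefs),
        rhs = 0
      )
    }
  }
  model$coupling_rows <- dplyr::bind_rows(model$coupling_rows,
                                          dplyr::bind_rows(rows))
  model
}

#' Assemble a complete diel model in one call
#'
#' Convenience pipeline: [replicate_tpm()], [add_transfers()],
#' [apply_phase_bounds()], [place_biomass()], [add_pigment_coupling()].
#'
#' @param base A [gsm()].
#' @param config A [tpm_config()].
#' @return A ready-to-solve `diel_model`.
#' @export
build_diel_model <- function(base, config) {
  replicate_tpm(base, config) |>
    add_transfers(config) |>
    apply_phase_bounds(config) |>
    place_biomass(config) |>
    add_pigment_coupling(config)
}
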