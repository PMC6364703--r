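# The three-stage optimization cascade over an assembled diel model:
#   1. maximize_biomass  — LP (or MILP with diazotrophy rows) maximizing the
#      biomass instance flux subject to per-TPM steady state, phase bounds,
#      transfer bounds, and pigment coupling.
#   2. minimize_transfers — with biomass fixed at its maximum, minimize the
#      sum of all transfer fluxes (modified parsimonious FBA; this is what
#      prevents unbounded cycling around the TPM ring).
#   3. fva — per-reaction min/max flux with biomass fixed and the total
#      transfer flow capped at the pFBA budget f.

#' Flux tolerance used for "zero" classification throughout
#' @export
FLUX_TOL <- 1e-6

model_variables <- function(model) {
  vars <- model$reactions$instance_id
  if (!is.null(model$binaries)) vars <- c(vars, model$binaries$var_id)
  vars
}

# Build the backend problem skeleton (variables, bounds, constraint rows)
# shared by all three stages.
assemble_problem <- function(model, fix_biomass = NULL, transfer_cap = NULL,
                             lb_override = NULL, ub_override = NULL) {
  rx <- model$reactions
  vars <- model_variables(model)
  var_idx <- stats::setNames(seq_along(vars), vars)
  n <- length(vars)

  lb <- c(rx$lb, if (!is.null(model$binaries)) model$binaries$lb)
  ub <- c(rx$ub, if (!is.null(model$binaries)) model$binaries$ub)
  integrality <- c(rep(0L, nrow(rx)),
                   if (!is.null(model$binaries)) rep(1L, nrow(model$binaries)))

  if (!is.null(lb_override)) {
    lb[var_idx[names(lb_override)]] <- unname(lb_override)
  }
  if (!is.null(ub_override)) {
    ub[var_idx[names(ub_override)]] <- unname(ub_override)
  }
  if (!is.null(fix_biomass)) {
    bio <- var_idx[[model$biomass_instance_id]]
    lb[bio] <- fix_biomass
    ub[bio] <- fix_biomass
  }

  met_idx <- stats::setNames(seq_len(nrow(model$metabolites)),
                             model$metabolites$instance_id)
  n_met <- nrow(model$metabolites)

  ti <- vector("list", nrow(rx))
  for (r in seq_len(nrow(rx))) {
    s <- rx$stoich[[r]]
    if (length(s) == 0) next
    agg <- tapply(as.numeric(s), names(s), sum) # duplicate names (self-wrap) sum out
    agg <- agg[agg != 0]
    if (length(agg) == 0) next
    ti[[r]] <- cbind(met_idx[names(agg)], r, as.numeric(agg))
  }
  trip <- do.call(rbind, ti)
  i <- trip[, 1]
  j <- trip[, 2]
  x <- trip[, 3]
  row_lb <- rep(0, n_met)
  row_ub <- rep(0, n_met)

  add_row <- function(coefs, r_lb, r_ub) {
    agg <- tapply(as.numeric(coefs), names(coefs), sum)
    ridx <- length(row_lb) + 1L
    i <<- c(i, rep(ridx, length(agg)))
    j <<- c(j, unname(var_idx[names(agg)]))
    x <<- c(x, as.numeric(agg))
    row_lb <<- c(row_lb, r_lb)
    row_ub <<- c(row_ub, r_ub)
  }

  if (nrow(model$coupling_rows) > 0) {
    for (r in seq_len(nrow(model$coupling_rows))) {
      add_row(model$coupling_rows$coefs[[r]], -Inf,
              model$coupling_rows$rhs[r])
    }
  }
  if (!is.null(model$exclusion_rows) && nrow(model$exclusion_rows) > 0) {
    for (r in seq_len(nrow(model$exclusion_rows))) {
      add_row(model$exclusion_rows$coefs[[r]],
              model$exclusion_rows$lb[r], model$exclusion_rows$ub[r])
    }
  }
  if (!is.null(transfer_cap)) {
    tr <- rx$instance_id[rx$type == "transfer"]
    if (length(tr) > 0) {
      add_row(stats::setNames(rep(1, length(tr)), tr), -Inf, transfer_cap)
    }
  }

  list(
    n = n,
    lb = lb,
    ub = ub,
    A = list(i = as.list(unname(i) - 1L), j = as.list(unname(j) - 1L),
             x = as.list(unname(x))),
    row_lb = unname(row_lb),
    row_ub = unname(row_ub),
    integrality = integrality,
    objectives = list(),
    .var_idx = var_idx
  )
}

strip_internal <- function(problem) {
  problem$.var_idx <- NULL
  problem
}

objective_for <- function(problem, ids, weights = 1, sense, want_x = FALSE) {
  coef <- numeric(problem$n)
  coef[problem$.var_idx[ids]] <- weights
  new_objective(coef, sense, want_x)
}

flux_solution_from <- function(model, result) {
  rx <- model$reactions
  fluxes <- if (!is.null(result$x)) {
    tibble::tibble(
      instance_id = rx$instance_id,
      base_id = rx$base_id,
      tpm = rx$tpm,
      type = rx$type,
      metabolite = rx$metabolite,
      flux = result$x[seq_len(nrow(rx))]
    )
  } else {
    NULL
  }
  structure(
    list(status = result$status,
         objective_value = result$objective,
         fluxes = fluxes,
         binaries = if (!is.null(model$binaries) && !is.null(result$x)) {
           tibble::tibble(var_id = model$binaries$var_id,
                          tpm = model$binaries$tpm,
                          kind = model$binaries$kind,
                          value = round(result$x[
                            nrow(rx) + seq_len(nrow(model$binaries))]))
         }),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status,
      ", objective: ", format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Maximize biomass production
#'
#' Stage one of the cascade: maximize the flux through the single active
#' biomass instance. Solver failures are reported through `status`, never as
#' silent zeros.
#'
#' @param model An assembled `diel_model` (see [build_diel_model()]).
#' @return A `flux_solution` with `status`, `objective_value`, and a `fluxes`
#'   tibble (one row per reaction instance).
#' @export
maximize_biomass <- function(model) {
  stopifnot(!is.null(model$biomass_instance_id))
  problem <- assemble_problem(model)
  problem$objectives <- list(objective_for(problem, model$biomass_instance_id,
                                           1, "max", want_x = TRUE))
  res <- backend_solve(list(strip_internal(problem)))[[1]][[1]]
  flux_solution_from(model, res)
}

#' Minimize total transfer flux at fixed biomass
#'
#' Stage two (modified parsimonious FBA): biomass is fixed at `biomass_max`
#' by an equality and the summed flux through every transfer reaction is
#' minimized, yielding the transfer budget `f`. If the equality-fixed problem
#' is numerically infeasible the fix is retried with a relative slack of
#' 1e-6 and a warning.
#'
#' @param model An assembled `diel_model`.
#' @param biomass_max Objective value from [maximize_biomass()].
#' @return A list with `f` (the budget) and `solution` (a `flux_solution`
#'   whose objective is `f`).
#' @export
minimize_transfers <- function(model, biomass_max) {
  tr_ids <- model$reactions$instance_id[model$reactions$type == "transfer"]
  solve_once <- function(bm_lb, bm_ub) {
    problem <- assemble_problem(model)
    bio <- problem$.var_idx[[model$biomass_instance_id]]
    problem$lb[bio] <- bm_lb
    problem$ub[bio] <- bm_ub
    if (length(tr_ids) == 0) {
      problem$objectives <- list(objective_for(
        problem, model$biomass_instance_id, 0, "min", want_x = TRUE))
    } else {
      problem$objectives <- list(objective_for(problem, tr_ids, 1, "min",
                                               want_x = TRUE))
    }
    backend_solve(list(strip_internal(problem)))[[1]][[1]]
  }
  res <- solve_once(biomass_max, biomass_max)
  if (res$status == "infeasible") {
    warning("equality-fixed biomass numerically infeasible; ",
            "retrying with 1e-6 relative slack")
    slack <- 1e-6 * max(1, abs(biomass_max))
    res <- solve_once(biomass_max - slack, biomass_max + slack)
  }
  sol <- flux_solution_from(model, res)
  f <- if (length(tr_ids) == 0 && res$status == "optimal") 0 else res$objective
  sol$objective_value <- f
  list(f = f, solution = sol)
}

#' Flux variability analysis under fixed biomass and capped transfers
#'
#' Stage three: for every target reaction instance, minimize and maximize its
#' flux subject to the assembled constraints plus the biomass equality and
#' the transfer-flow cap `sum(transfers) <= f`. All sub-problems share one
#' feasible region and are solved in a single batched backend call; results
#' are independent of target ordering. Per-target solver failures are
#' recorded (`NA` range) without aborting the remaining targets.
#'
#' @param model An assembled `diel_model`.
#' @param biomass_max Fixed biomass value.
#' @param f Transfer budget from [minimize_transfers()].
#' @param targets Character vector of reaction instance ids; defaults to all
#'   transfer reactions.
#' @return A tibble (`fva_result`) with columns `instance_id`, `base_id`,
#'   `tpm`, `type`, `metabolite`, `min`, `max`, `status`.
#' @export
fva <- function(model, biomass_max, f, targets = NULL) {
  rx <- model$reactions
  if (is.null(targets)) {
    targets <- rx$instance_id[rx$type == "transfer"]
  }
  missing <- setdiff(targets, rx$instance_id)
  if (length(missing) > 0) {
    stop("unknown reaction instances: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  problem <- assemble_problem(model, fix_biomass = biomass_max,
                              transfer_cap = f)
  objs <- list()
  for (t in targets) {
    objs[[length(objs) + 1L]] <- objective_for(problem, t, 1, "min")
    objs[[length(objs) + 1L]] <- objective_for(problem, t, 1, "max")
  }
  problem$objectives <- objs
  res <- backend_solve(list(strip_internal(problem)))[[1]]

  pick <- match(targets, rx$instance_id)
  out <- tibble::tibble(
    instance_id = targets,
    base_id = rx$base_id[pick],
    tpm = rx$tpm[pick],
    type = rx$type[pick],
    metabolite = rx$metabolite[pick],
    min = vapply(seq_along(targets), function(i) res[[2 * i - 1]]$objective,
                 numeric(1)),
    max = vapply(seq_along(targets), function(i) res[[2 * i]]$objective,
                 numeric(1)),
    status = vapply(seq_along(targets), function(i) {
      s1 <- res[[2 * i - 1]]$status
      s2 <- res[[2 * i]]$status
      if (s1 == "optimal" && s2 == "optimal") "optimal" else s1
    }, character(1))
  )
  class(out) <- c("fva_result", class(out))
  attr(out, "biomass_max") <- biomass_max
  attr(out, "f") <- f
  out
}

#' Run the full biomass / pFBA / FVA cascade
#'
#' @param model An assembled `diel_model`.
#' @param fva_targets Targets passed to [fva()] (default: all transfers).
#' @return A list of class `diel_cascade` with elements `biomass`
#'   (`flux_solution`), `f`, `pfba` (`flux_solution`), and `fva`
#'   (`fva_result`); `fva` is `NULL` when biomass maximization fails.
#' @export
solve_cascade <- function(model, fva_targets = NULL) {
  bm <- maximize_biomass(model)
  if (bm$status != "optimal") {
    return(structure(list(biomass = bm, f = NA_real_, pfba = NULL,
                          fva = NULL), class = "diel_cascade"))
  }
  pf <- minimize_transfers(model, bm$objective_value)
  ranges <- fva(model, bm$objective_value, pf$f, targets = fva_targets)
  structure(list(biomass = bm, f = pf$f, pfba = pf$solution, fva = ranges),
            class = "diel_cascade")
}

#' @export
print.diel_cascade <- function(x, ...) {
  cat("<diel_cascade>\n  biomass: ", x$biomass$status, " ",
      format(x$biomass$objective_value), "\n  transfer budget f: ",
      format(x$f), "\n  fva targets: ",
      if (is.null(x$fva)) 0 else nrow(x$fva), "\n", sep = "")
  invisible(x)
}

#' Derive capacity bounds from the unsegmented base model
#'
#' Mirrors the bound-derivation step used before expression scaling: flux
#' variability analysis of the base (single, lights-on) model under the
#' configured uptake limits and maintenance demand determines each
#' reaction's largest feasible flux range, and that attainable maximum
#' becomes its unscaled upper bound. Lower bounds are relaxed to
#' `min(fva_min, 0)` so no reaction is ever forced on; exchange reactions
#' and the biomass drain keep their original bounds (the diel optimum pools
#' flux across phases and must not be capped by a single-phase biomass
#' maximum).
#'
#' @param base A [gsm()].
#' @param config A [tpm_config()] supplying the uptake/maintenance bounds.
#' @return The base model with tightened reaction bounds.
#' @export
capacity_bounds <- function(base, config) {
  validate_gsm(base)
  rx <- base$reactions
  lb <- rx$lower_bound
  ub <- rx$upper_bound
  idx <- function(id) match(id, rx$id)
  ub[idx(config$co2_uptake_id)] <- min(ub[idx(config$co2_uptake_id)],
                                       config$co2_uptake_ub)
  ub[idx(config$photon_uptake_id)] <- min(ub[idx(config$photon_uptake_id)],
                                          config$photon_uptake_ub)
  lb[idx(config$atp_maintenance_id)] <- config$atp_maintenance_lb

  met_idx <- stats::setNames(seq_len(nrow(base$metabolites)),
                             base$metabolites$id)
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  for (r in seq_len(nrow(rx))) {
    s <- rx$stoichiometry[[r]]
    trip$i <- c(trip$i, unname(met_idx[names(s)]))
    trip$j <- c(trip$j, rep(r, length(s)))
    trip$x <- c(trip$x, as.numeric(s))
  }
  exempt <- rx$id %in% c(base$exchange_ids, base$biomass_reaction_id)
  targets <- which(!exempt)
  problem <- list(
    n = nrow(rx), lb = lb, ub = ub,
    A = list(i = as.list(unname(trip$i) - 1L),
             j = as.list(unname(trip$j) - 1L),
             x = as.list(unname(trip$x))),
    row_lb = rep(0, nrow(base$metabolites)),
    row_ub = rep(0, nrow(base$metabolites)),
    objectives = unlist(lapply(targets, function(r) {
      coef <- numeric(nrow(rx))
      coef[r] <- 1
      list(new_objective(coef, "min"), new_objective(coef, "max"))
    }), recursive = FALSE)
  )
  res <- backend_solve(list(problem))[[1]]
  out <- base
  for (i in seq_along(targets)) {
    r <- targets[i]
    lo <- res[[2 * i - 1]]
    hi <- res[[2 * i]]
    if (lo$status != "optimal" || hi$status != "optimal") next
    out$reactions$upper_bound[r] <- hi$objective
    out$reactions$lower_bound[r] <- min(lo$objective, 0)
  }
  validate_gsm(out)
  out
}

#' Detect reactions able to carry flux with all exchanges closed
#'
#' Flux variability analysis on the *base* model with every exchange bounded
#' to zero; any reaction whose attainable flux magnitude exceeds `tol` sits
#' on a thermodynamically infeasible (unbounded) internal loop.
#'
#' @param base A [gsm()].
#' @param tol Zero-flux tolerance.
#' @return Character vector of flagged reaction ids (sorted, deterministic).
#' @export
check_unbounded_loops <- function(base, tol = FLUX_TOL) {
  validate_gsm(base)
  rx <- base$reactions
  met_idx <- stats::setNames(seq_len(nrow(base$metabolites)),
                             base$metabolites$id)
  lb <- rx$lower_bound
  ub <- rx$upper_bound
  closed <- rx$id %in% base$exchange_ids
  lb[closed] <- 0
  ub[closed] <- 0

  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  for (r in seq_len(nrow(rx))) {
    s <- rx$stoichiometry[[r]]
    trip$i <- c(trip$i, unname(met_idx[names(s)]))
    trip$j <- c(trip$j, rep(r, length(s)))
    trip$x <- c(trip$x, as.numeric(s))
  }
  internal <- which(!closed)
  problem <- list(
    n = nrow(rx), lb = lb, ub = ub,
    A = list(i = as.list(unname(trip$i) - 1L), j = as.list(unname(trip$j) - 1L),
             x = as.list(unname(trip$x))),
    row_lb = rep(0, nrow(base$metabolites)),
    row_ub = rep(0, nrow(base$metabolites)),
    objectives = unlist(lapply(internal, function(r) {
      coef <- numeric(nrow(rx))
      coef[r] <- 1
      list(new_objective(coef, "min"), new_objective(coef, "max"))
    }), recursive = FALSE)
  )
  res <- backend_solve(list(problem))[[1]]
  flagged <- vapply(seq_along(internal), function(i) {
    lo <- res[[2 * i - 1]]$objective
    hi <- res[[2 * i]]$objective
    isTRUE(abs(lo) > tol) || isTRUE(abs(hi) > tol)
  }, logical(1))
  sort(rx$id[internal[flagged]])
}
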