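# broom-style accessors for fitted/solved objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flux solution into one row per reaction instance
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return Tibble `instance_id`, `base_id`, `tpm`, `type`, `metabolite`,
#'   `flux` (empty when the solve failed).
#' @export
tidy.flux_solution <- function(x, ...) {
  if (is.null(x$fluxes)) {
    return(tibble::tibble(instance_id = character(0),
                          base_id = character(0), tpm = integer(0),
                          type = character(0), metabolite = character(0),
                          flux = numeric(0)))
  }
  x$fluxes
}

#' One-row summary of a flux solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return Tibble `status`, `objective_value`.
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective_value = x$objective_value)
}

#' Tidy a cascade into the per-reaction FVA envelope
#'
#' @param x A `diel_cascade`.
#' @param ... Unused.
#' @return The `fva_result` tibble (empty if FVA did not run).
#' @export
tidy.diel_cascade <- function(x, ...) {
  if (is.null(x$fva)) return(tibble::tibble())
  tibble::as_tibble(x$fva)
}

#' One-row summary of a cascade
#'
#' @param x A `diel_cascade`.
#' @param ... Unused.
#' @return Tibble `status`, `biomass`, `transfer_budget`, `n_fva_targets`.
#' @export
glance.diel_cascade <- function(x, ...) {
  tibble::tibble(
    status = x$biomass$status,
    biomass = x$biomass$objective_value,
    transfer_budget = x$f,
    n_fva_targets = if (is.null(x$fva)) 0L else nrow(x$fva)
  )
}

#' One-row summary of a noise-robustness experiment
#'
#' @param x A `noise_robustness` result.
#' @param ... Unused.
#' @return Tibble `mean_deviation_pct`, `n_replicates`, `n_infeasible`,
#'   `n_excluded`.
#' @export
glance.noise_robustness <- function(x, ...) {
  tibble::tibble(
    mean_deviation_pct = x$mean_deviation_pct,
    n_replicates = nrow(x$per_replicate),
    n_infeasible = x$n_infeasible,
    n_excluded = x$n_excluded
  )
}
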