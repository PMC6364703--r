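# Transcriptome-derived bound scaling (the E-flux "valve" scheme).
#
# Per gene, expression at each TPM is divided by that gene's maximum across
# TPMs — a linear max-normalisation, deliberately without any sigmoid or
# other nonlinear transform. GPR rules fold gene ratios into one reaction
# ratio (isozymes take the max, complex subunits the min), and each core
# reaction instance's upper bound is throttled to `base_ub * a_jk`.

#' Per-gene, per-TPM expression ratios
#'
#' @param expr Long tibble with columns `gene`, `tpm`, `value`
#'   (non-negative normalized intensities). Every included gene must carry a
#'   value for every TPM.
#' @return Tibble `gene`, `tpm`, `ratio` with `ratio = value / max(value)`
#'   per gene. Genes whose series is all zero are uninformative and get
#'   ratio 1 everywhere, with a warning.
#' @export
compute_gene_ratios <- function(expr) {
  expr <- tibble::as_tibble(expr)
  stopifnot(all(c("gene", "tpm", "value") %in% names(expr)))
  if (any(expr$value < 0)) stop("expression values must be >= 0", call. = FALSE)
  counts <- dplyr::count(expr, .data$gene)
  if (length(unique(counts$n)) > 1L) {
    full_n <- max(counts$n)
    partial <- counts$gene[counts$n < full_n]
    stop("genes with incomplete TPM coverage: ",
         paste(partial, collapse = ", "), call. = FALSE)
  }
  allzero <- expr |>
    dplyr::summarise(z = all(.data$value == 0), .by = "gene") |>
    dplyr::filter(.data$z)
  if (nrow(allzero) > 0) {
    warning("gene(s) with all-zero expression treated as uninformative ",
            "(ratio 1): ", paste(allzero$gene, collapse = ", "))
  }
  expr |>
    dplyr::mutate(ratio = .data$value / max(.data$value), .by = "gene") |>
    dplyr::mutate(ratio = ifelse(is.nan(.data$ratio), 1, .data$ratio)) |>
    dplyr::select("gene", "tpm", "ratio")
}

#' Fold gene ratios into per-reaction, per-TPM ratios via GPR rules
#'
#' @param base A [gsm()]; reactions with an empty GPR (or whose genes are all
#'   absent from `gene_ratios`) get ratio 1.
#' @param gene_ratios Tibble `gene`, `tpm`, `ratio` from
#'   [compute_gene_ratios()].
#' @return Tibble `reaction`, `tpm`, `ratio` covering every reaction and TPM
#'   present in `gene_ratios`.
#' @export
reaction_ratios <- function(base, gene_ratios) {
  tpms <- sort(unique(gene_ratios$tpm))
  rx <- base$reactions
  trees <- lapply(rx$gpr, parse_gpr)
  by_tpm <- split(gene_ratios, gene_ratios$tpm)
  out <- lapply(tpms, function(k) {
    gk <- by_tpm[[as.character(k)]]
    ratios <- stats::setNames(gk$ratio, gk$gene)
    tibble::tibble(
      reaction = rx$id,
      tpm = as.integer(k),
      ratio = vapply(trees, evaluate_gpr, numeric(1), gene_ratios = ratios)
    )
  })
  dplyr::bind_rows(out)
}

#' Throttle reaction upper bounds by expression ratios
#'
#' Each core reaction instance's upper bound becomes
#' `min(current_ub, base_ub * a_jk)` — the base-model bound scaled by the
#' ratio, without overriding structural constraints (dark-phase shutoffs,
#' biomass placement) already in force. Lower bounds are left unscaled, as
#' the constraint acts on the maximum attainable flux; `scale_reversible`
#' additionally scales the magnitude of negative lower bounds (classic
#' E-flux) for sensitivity analysis. Transfer reactions, exchanges, and the
#' biomass instance are never scaled.
#'
#' @param model An assembled `diel_model`.
#' @param ratios Tibble `reaction`, `tpm`, `ratio` with ratios in \[0, 1\];
#'   (reaction, tpm) pairs absent from the table default to 1.
#' @param scale_reversible Also scale `|lower_bound|` for reversible
#'   reactions (default `FALSE`).
#' @return The model with scaled bounds and the applied ratio recorded per
#'   instance.
#' @export
apply_eflux <- function(model, ratios, scale_reversible = FALSE) {
  ratios <- tibble::as_tibble(ratios)
  stopifnot(all(c("reaction", "tpm", "ratio") %in% names(ratios)))
  if (any(ratios$ratio < 0 | ratios$ratio > 1)) {
    stop("expression ratios must lie in [0, 1]", call. = FALSE)
  }
  rx <- model$reactions
  exempt <- rx$type != "core" |
    rx$base_id %in% model$base$exchange_ids |
    rx$base_id == model$base$biomass_reaction_id
  key <- paste(rx$base_id, rx$tpm)
  lookup <- stats::setNames(ratios$ratio, paste(ratios$reaction, ratios$tpm))
  a <- unname(lookup[key])
  a[is.na(a)] <- 1
  a[exempt] <- 1

  rx$ratio <- a
  rx$ub <- pmin(rx$ub, rx$ub_unscaled * a)
  if (scale_reversible) {
    neg <- rx$lb < 0 & !exempt
    rx$lb[neg] <- pmax(rx$lb[neg], -abs(rx$lb[neg]) * a[neg])
  }
  rx$lb <- pmin(rx$lb, rx$ub)
  model$reactions <- rx
  model
}

#' Noise robustness of predicted transfer fluxes
#'
#' Re-runs the cascade under perturbed expression: per replicate, Gaussian
#' noise with per-gene standard deviation equal to the standard deviation of
#' that gene's max-normalized series is added to the normalized ratios, the
#' result clamped to \[0, 1\], reaction ratios rebuilt through the GPRs, and
#' the biomass/pFBA cascade re-solved. The reported deviation is the mean
#' over metabolite-boundary pairs (and replicates) of
#' `|perturbed - baseline| / |baseline| * 100`, excluding pairs whose
#' baseline transfer flux is below `tol`.
#'
#' @param model An *unscaled* assembled `diel_model`.
#' @param expr Expression tibble (`gene`, `tpm`, `value`).
#' @param n_reps Number of noise replicates.
#' @param seed RNG seed; the experiment is reproducible under it.
#' @param tol Zero-flux tolerance for the exclusion rule.
#' @param sigma_scale Multiplier on the per-gene noise SD (0 forces
#'   noise-free replicates).
#' @return A list of class `noise_robustness`: `mean_deviation_pct`,
#'   `per_replicate` (tibble `rep`, `deviation_pct`, `status`),
#'   `n_excluded` (baseline pairs below `tol`), `n_infeasible`.
#' @export
noise_robustness <- function(model, expr, n_reps = 20, seed = 1,
                             tol = FLUX_TOL, sigma_scale = 1) {
  gene_ratios <- compute_gene_ratios(expr)
  sds <- gene_ratios |>
    dplyr::summarise(sd = stats::sd(.data$ratio), .by = "gene")
  sd_lookup <- stats::setNames(sds$sd, sds$gene)

  baseline_model <- apply_eflux(model, reaction_ratios(model$base, gene_ratios))
  base_cascade <- solve_cascade(baseline_model)
  if (base_cascade$biomass$status != "optimal") {
    stop("baseline model is not solvable; cannot assess noise robustness",
         call. = FALSE)
  }
  baseline <- transfer_fluxes(base_cascade$pfba)
  keep <- abs(baseline$flux) >= tol
  n_excluded <- sum(!keep)
  baseline <- baseline[keep, ]

  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    noisy <- gene_ratios
    noise <- stats::rnorm(nrow(noisy), 0,
                          sigma_scale * sd_lookup[noisy$gene])
    noise[is.na(noise)] <- 0 # constant series have sd 0
    noisy$ratio <- pmin(pmax(noisy$ratio + noise, 0), 1)
    perturbed_model <- apply_eflux(model, reaction_ratios(model$base, noisy))
    bm <- maximize_biomass(perturbed_model)
    if (bm$status != "optimal") {
      reps[[r]] <- tibble::tibble(rep = r, deviation_pct = NA_real_,
                                  status = bm$status)
      next
    }
    pf <- minimize_transfers(perturbed_model, bm$objective_value)
    pert <- transfer_fluxes(pf$solution)
    merged <- dplyr::left_join(baseline, pert,
                               by = c("metabolite", "tpm"),
                               suffix = c("_base", "_pert"))
    dev <- mean(abs(merged$flux_pert - merged$flux_base) /
                  abs(merged$flux_base)) * 100
    reps[[r]] <- tibble::tibble(rep = r, deviation_pct = dev,
                                status = "optimal")
  }
  per_rep <- dplyr::bind_rows(reps)
  structure(
    list(mean_deviation_pct = mean(per_rep$deviation_pct, na.rm = TRUE),
         per_replicate = per_rep,
         n_excluded = n_excluded,
         n_infeasible = sum(per_rep$status != "optimal")),
    class = "noise_robustness"
  )
}

#' @export
print.noise_robustness <- function(x, ...) {
  cat("<noise_robustness> mean deviation: ",
      format(x$mean_deviation_pct), "% over ",
      nrow(x$per_replicate), " replicates (", x$n_infeasible,
      " infeasible, ", x$n_excluded, " near-zero baseline pairs excluded)\n",
      sep = "")
  invisible(x)
}

#' Per-metabolite, per-boundary transfer fluxes of a solution
#'
#' @param solution A `flux_solution` with fluxes.
#' @return Tibble `metabolite`, `tpm` (source TPM of the boundary), `flux`.
#' @export
transfer_fluxes <- function(solution) {
  stopifnot(!is.null(solution$fluxes))
  solution$fluxes |>
    dplyr::filter(.data$type == "transfer") |>
    dplyr::select("metabolite", "tpm", "flux")
}
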