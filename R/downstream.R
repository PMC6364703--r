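# Post-solution analyses: active transcriptomic bounds, flux control
# coefficients, metabolite-metabolite rank correlation of transfer-flux
# profiles, category aggregation, and normalized accumulation profiles.

#' Reactions whose transcriptomic bound limits the optimum
#'
#' A reaction instance has an *active bound* when its FVA maximum sits at
#' its expression-scaled upper bound (within `tau * max(1, |bound|)`) and
#' that bound is genuinely constricted below the unscaled base bound — these
#' are the constraints that limit metabolism when biomass is maximized.
#'
#' @param model An E-flux-scaled `diel_model`.
#' @param ranges An `fva_result` covering the scaled core instances.
#' @param solution Optional `flux_solution` (its flux at each flagged
#'   instance is reported when given).
#' @param tau Tolerance.
#' @return Tibble of flagged instances (`instance_id`, `base_id`, `tpm`,
#'   `ub_scaled`, `ub_unscaled`, `fva_max`, optionally `flux`), with the
#'   deduplicated unique-reaction count in attribute `n_unique`.
#' @export
find_active_bounds <- function(model, ranges, solution = NULL,
                               tau = FLUX_TOL) {
  rx <- model$reactions
  pick <- match(ranges$instance_id, rx$instance_id)
  scaled <- rx$ub[pick]
  unscaled <- rx$ub_unscaled[pick]
  at_bound <- abs(ranges$max - scaled) <= tau * pmax(1, abs(scaled))
  # only expression-constricted bounds count, not structural shutoffs
  # (dark-phase zeros, displaced biomass instances)
  constricted <- !is.na(rx$ratio[pick]) & rx$ratio[pick] < 1 &
    scaled < unscaled - tau
  flagged <- which(at_bound & constricted & rx$type[pick] == "core")

  out <- tibble::tibble(
    instance_id = ranges$instance_id[flagged],
    base_id = rx$base_id[pick[flagged]],
    tpm = rx$tpm[pick[flagged]],
    ub_scaled = scaled[flagged],
    ub_unscaled = unscaled[flagged],
    fva_max = ranges$max[flagged]
  )
  if (!is.null(solution) && !is.null(solution$fluxes)) {
    out <- dplyr::left_join(
      out, dplyr::select(solution$fluxes, "instance_id", "flux"),
      by = "instance_id")
  }
  attr(out, "n_unique") <- length(unique(out$base_id))
  out
}

#' Flux control coefficients of transcriptomic bounds
#'
#' For each expression-constrained reaction instance (applied ratio < 1),
#' the scaled upper bound x is tightened multiplicatively by `delta`
#' (default 1%), biomass is re-maximized, and the control coefficient
#' `C = (dv_biomass / dx) * (x / v_biomass)` is computed from the finite
#' difference. Instances whose bound is slack at the optimum have C = 0;
#' coefficients with `|C| <= tau` are reported as zero. A perturbed problem
#' that turns infeasible yields `NA` (undefined), never zero. All perturbed
#' problems are solved in one batched backend call.
#'
#' @param model An E-flux-scaled `diel_model`.
#' @param delta Relative perturbation of the bound (0.01 = 1%). The bound is
#'   tightened (multiplied by `1 - delta`), which is guaranteed to probe a
#'   binding constraint.
#' @param tau Zero tolerance.
#' @return Tibble `instance_id`, `base_id`, `tpm`, `bound`, `coefficient`.
#' @export
flux_control_coefficients <- function(model, delta = 0.01, tau = FLUX_TOL) {
  rx <- model$reactions
  constrained <- which(rx$type == "core" & !is.na(rx$ratio) & rx$ratio < 1)
  base_solution <- maximize_biomass(model)
  if (base_solution$status != "optimal") {
    stop("baseline biomass maximization failed: ", base_solution$status,
         call. = FALSE)
  }
  v0 <- base_solution$objective_value

  problems <- lapply(constrained, function(idx) {
    p <- assemble_problem(
      model,
      ub_override = stats::setNames(rx$ub[idx] * (1 - delta),
                                    rx$instance_id[idx]))
    p$objectives <- list(objective_for(p, model$biomass_instance_id, 1, "max"))
    strip_internal(p)
  })
  coef <- rep(0, length(constrained))
  if (length(problems) > 0) {
    res <- backend_solve(problems)
    for (i in seq_along(constrained)) {
      r <- res[[i]][[1]]
      if (r$status != "optimal") {
        coef[i] <- NA_real_
        next
      }
      # relative change ratio: ((v' - v)/v) / ((x' - x)/x), with x'/x = 1-delta
      c_i <- if (v0 == 0) 0 else ((r$objective - v0) / v0) / (-delta)
      coef[i] <- if (abs(c_i) <= tau) 0 else c_i
    }
  }
  tibble::tibble(
    instance_id = rx$instance_id[constrained],
    base_id = rx$base_id[constrained],
    tpm = rx$tpm[constrained],
    bound = rx$ub[constrained],
    coefficient = coef
  )
}

#' Spearman rank correlation by the explicit rank-product formula
#'
#' Mid-ranks are assigned to ties; the coefficient is
#' `r_s = (n * sum(uv) - sum(u) * sum(v)) / sqrt((n * sum(u^2) - sum(u)^2) *
#' (n * sum(v^2) - sum(v)^2))` over the two rank vectors.
#'
#' @param a,b Numeric vectors of equal length.
#' @return The rank correlation coefficient.
#' @export
spearman_rho <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  u <- rank(a)
  v <- rank(b)
  num <- n * sum(u * v) - sum(u) * sum(v)
  den <- sqrt((n * sum(u^2) - sum(u)^2) * (n * sum(v^2) - sum(v)^2))
  if (den == 0) return(NA_real_)
  num / den
}

spearman_pvalue <- function(rho, n) {
  if (is.na(rho) || n < 3) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Metabolite-metabolite correlation analysis
#'
#' Pairwise Spearman rank correlation of per-TPM transfer-flux profiles,
#' used as proxies for metabolite levels. Each profile is first normalized
#' by its maximum across TPMs; all-zero profiles are excluded. Two-sided
#' p-values come from the t approximation; pairs with `p >= alpha` are
#' retained but flagged insignificant. No multiple-testing correction is
#' applied by default; `adjust = "BH"` switches on Benjamini-Hochberg.
#'
#' @param profiles Long tibble `metabolite`, `tpm`, `flux` (typically the
#'   FVA maximum transfer flux, see [transfer_profiles()]).
#' @param alpha Significance cutoff.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble `a`, `b`, `r_s`, `p_value`, `significant`.
#' @export
mmca <- function(profiles, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  profiles <- tibble::as_tibble(profiles)
  stopifnot(all(c("metabolite", "tpm", "flux") %in% names(profiles)))
  n_tpm <- length(unique(profiles$tpm))
  if (n_tpm < 3) {
    stop("rank correlation needs at least 3 TPMs", call. = FALSE)
  }
  wide <- profiles |>
    dplyr::arrange(.data$tpm) |>
    tidyr::pivot_wider(names_from = "tpm", values_from = "flux")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$metabolite
  keep <- apply(mat, 1, function(r) any(r != 0))
  mat <- mat[keep, , drop = FALSE]
  mat <- mat / apply(mat, 1, max) # normalize to the profile maximum

  mets <- rownames(mat)
  if (length(mets) < 2) {
    return(tibble::tibble(a = character(0), b = character(0),
                          r_s = numeric(0), p_value = numeric(0),
                          significant = logical(0)))
  }
  pairs <- utils::combn(mets, 2)
  r_s <- vapply(seq_len(ncol(pairs)), function(i) {
    spearman_rho(mat[pairs[1, i], ], mat[pairs[2, i], ])
  }, numeric(1))
  p <- vapply(r_s, spearman_pvalue, numeric(1), n = n_tpm)
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  tibble::tibble(
    a = pairs[1, ], b = pairs[2, ], r_s = r_s, p_value = p,
    significant = !is.na(p) & p < alpha
  )
}

#' Per-metabolite transfer-flux profiles from an FVA result
#'
#' @param ranges An `fva_result` over transfer reactions.
#' @param which Use the `"max"` (default) or `"min"` envelope as the level
#'   proxy.
#' @return Tibble `metabolite`, `tpm`, `flux`.
#' @export
transfer_profiles <- function(ranges, which = c("max", "min")) {
  which <- match.arg(which)
  ranges |>
    tibble::as_tibble() |>
    dplyr::filter(.data$type == "transfer") |>
    dplyr::transmute(metabolite = .data$metabolite, tpm = .data$tpm,
                     flux = .data[[which]])
}

#' Sum transfer-flux envelopes by metabolite category
#'
#' @param ranges An `fva_result` over transfer reactions.
#' @param annotation Tibble `metabolite`, `category`. Metabolites without an
#'   annotation are grouped under `"unclassified"` with a warning.
#' @return Tibble `category`, `tpm`, `min_total`, `max_total` (sums over
#'   member metabolites).
#' @export
aggregate_by_category <- function(ranges, annotation) {
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(c("metabolite", "category") %in% names(annotation)))
  tr <- ranges |>
    tibble::as_tibble() |>
    dplyr::filter(.data$type == "transfer")
  missing <- setdiff(unique(tr$metabolite), annotation$metabolite)
  if (length(missing) > 0) {
    warning("unannotated metabolite(s) grouped as 'unclassified': ",
            paste(missing, collapse = ", "))
  }
  out <- tr |>
    dplyr::left_join(annotation, by = "metabolite") |>
    dplyr::mutate(category = dplyr::coalesce(.data$category,
                                             "unclassified")) |>
    dplyr::summarise(min_total = sum(.data$min), max_total = sum(.data$max),
                     .by = c("category", "tpm"))
  # categories declared in the annotation but without transferring members
  # still appear, as all-zero profiles
  out |>
    tidyr::complete(
      category = union(unique(annotation$category), unique(out$category)),
      tpm = unique(tr$tpm),
      fill = list(min_total = 0, max_total = 0)) |>
    dplyr::arrange(.data$category, .data$tpm)
}

#' Normalize a per-TPM series to its maximum
#'
#' @param series Numeric vector with at least one positive value.
#' @return The series divided by its maximum (so the output peaks at 1).
#' @export
normalize_profile <- function(series) {
  m <- max(series)
  if (m <= 0) stop("cannot normalize an all-zero (or non-positive) series",
                   call. = FALSE)
  series / m
}
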