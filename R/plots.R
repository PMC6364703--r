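# ggplot2 views of solved objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot transfer-flux envelopes over the diel cycle
#'
#' Ribbons span the FVA minimum/maximum transfer flux per metabolite and
#' TPM boundary; the line tracks the envelope maximum (the usual level
#' proxy).
#'
#' @param object An `fva_result` over transfer reactions.
#' @param metabolites Optional subset of metabolite ids to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fva_result <- function(object, metabolites = NULL, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::filter(.data$type == "transfer")
  if (!is.null(metabolites)) {
    dat <- dplyr::filter(dat, .data$metabolite %in% metabolites)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$tpm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$max), colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$min), colour = "seagreen") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metabolite), scales = "free_y") +
    ggplot2::labs(x = "time point model",
                  y = "transfer flux (mmol gDW⁻¹ hr⁻¹)")
}

#' Plot category-wise transfer-flux profiles
#'
#' @param profiles Output of [aggregate_by_category()].
#' @return A ggplot with one facet per category showing the summed
#'   minimum/maximum envelopes.
#' @export
plot_category_profiles <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$tpm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_total,
                                      ymax = .data$max_total),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$max_total),
                       colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$min_total),
                       colour = "seagreen") +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_y") +
    ggplot2::labs(x = "time point model",
                  y = "summed transfer flux (mmol gDW⁻¹ hr⁻¹)")
}

#' Plot a metabolite-metabolite correlation matrix
#'
#' Insignificant pairs (p >= alpha at testing time) are blanked.
#'
#' @param correlations Output of [mmca()].
#' @return A ggplot tile map of significant rank correlations.
#' @export
plot_mmca <- function(correlations) {
  sym <- dplyr::bind_rows(
    correlations,
    dplyr::rename(correlations, a = "b", b = "a")
  ) |>
    dplyr::mutate(r_shown = ifelse(.data$significant, .data$r_s, NA_real_))
  ggplot2::ggplot(sym, ggplot2::aes(x = .data$a, y = .data$b,
                                    fill = .data$r_shown)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1),
                                  na.value = "white",
                                  name = "Spearman r") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}
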