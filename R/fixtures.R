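# Self-contained toy fixtures: a minimal carbon- and energy-consistent
# phototroph model plus synthetic diel expression series, so every stage of
# the framework can be exercised without any external model or data.
#
# The toy couples photon capture to a pigment pool (chlorophyll analogue),
# fixes CO2 into a hexose, banks surplus carbon in a glycogen-analogue
# storage polymer (1 polymer unit = 6 hexose units, so moving stored carbon
# costs six-fold less transfer flux than moving free hexose — the same
# parsimony argument that makes glycogen the preferred reserve), respires it
# in the dark against an ATP maintenance demand, and drains biomass.
# Stoichiometric coefficients are integers so oracle LPs are numerically
# exact to solver tolerance.

#' Specification for the toy phototroph model
#'
#' @param n_tpm,n_light Cycle discretisation (defaults: 12 TPMs, 6 light).
#' @param include_storage Include the glycogen-analogue storage couple.
#' @param include_pigment Include the chlorophyll pool, its synthesis and
#'   degradation, and make biomass require pigment.
#' @param include_nif Also splice the nitrogen-fixation set
#'   ([make_nif_set()]) into the base model.
#' @param seed RNG seed carried by the spec (used by expression fixtures).
#' @param bound_scale Multiplier on the default internal bound magnitude.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(n_tpm = 12L, n_light = 6L, include_storage = TRUE,
                     include_pigment = TRUE, include_nif = FALSE,
                     seed = 1L, bound_scale = 1) {
  stopifnot(n_tpm >= 1, n_light >= 1, n_light <= n_tpm, bound_scale > 0)
  structure(list(n_tpm = as.integer(n_tpm), n_light = as.integer(n_light),
                 include_storage = include_storage,
                 include_pigment = include_pigment,
                 include_nif = include_nif, seed = as.integer(seed),
                 bound_scale = bound_scale),
            class = "toy_spec")
}

toy_carbon_counts <- function() {
  c(co2_e = 1, co2_c = 1, hexose_c = 6, glycogen_c = 36, chl_c = 6,
    photon_e = 0, photon_c = 0, o2_e = 0, o2_c = 0, nh3_e = 0, nh3_c = 0,
    atp_c = 0, adp_c = 0, nadph_c = 0, nadp_c = 0,
    n2_e = 0, n2_p = 0, n2_c = 0)
}

#' Build the toy phototroph base model
#'
#' Photon and CO2 exchanges; pigment-gated light reactions (a linear chain
#' producing NADPH and evolving O2, and a cyclic branch producing ATP);
#' carbon fixation to a hexose; storage polymer synthesis/degradation; a
#' high-yield respiration; ATP maintenance; and a biomass drain consuming
#' hexose, pigment, ammonia, and ATP. Every internal metabolite is both
#' producible and consumable.
#'
#' @param spec A [toy_spec()].
#' @return A [gsm()] with a `carbon` attribute (per-metabolite carbon counts
#'   used by the elemental audit).
#' @export
make_toy_gsm <- function(spec = toy_spec()) {
  B <- DEFAULT_BOUND * spec$bound_scale
  mets <- tibble::tribble(
    ~id,          ~name,                 ~compartment,
    "photon_e",   "photon (external)",   "e",
    "photon_c",   "photon (absorbed)",   "c",
    "co2_e",      "CO2 (external)",      "e",
    "co2_c",      "CO2 (cytosol)",       "c",
    "o2_e",       "O2 (external)",       "e",
    "o2_c",       "O2 (cytosol)",        "c",
    "nh3_e",      "ammonia (external)",  "e",
    "nh3_c",      "ammonia (cytosol)",   "c",
    "atp_c",      "ATP",                 "c",
    "adp_c",      "ADP",                 "c",
    "nadph_c",    "NADPH",               "c",
    "nadp_c",     "NADP+",               "c",
    "hexose_c",   "hexose phosphate pool", "c"
  )

  rxn <- function(id, stoich, lb, ub, gpr = "", subsystem = "") {
    tibble::tibble(id = id, stoichiometry = list(stoich), lower_bound = lb,
                   upper_bound = ub, gpr = gpr, subsystem = subsystem)
  }
  rows <- list(
    rxn("EX_photon", c(photon_e = -1), -B, B, subsystem = "exchange"),
    rxn("EX_co2", c(co2_e = -1), -B, B, subsystem = "exchange"),
    rxn("EX_o2", c(o2_e = -1), -B, B, subsystem = "exchange"),
    rxn("EX_nh3", c(nh3_e = -1), -B, B, subsystem = "exchange"),
    rxn("photon_uptake", c(photon_e = -1, photon_c = 1), 0, B,
        subsystem = "transport"),
    # reversible: positive flux is uptake (phase-capped), negative is the
    # ever-open export of respiratory CO2; a separate irreversible
    # uptake/export pair would form a closed 2-cycle able to carry
    # unbounded flux
    rxn("co2_uptake", c(co2_e = -1, co2_c = 1), -B, B,
        subsystem = "transport"),
    rxn("o2_transport", c(o2_c = -1, o2_e = 1), -B, B,
        subsystem = "transport"),
    rxn("nh3_uptake", c(nh3_e = -1, nh3_c = 1), 0, B,
        subsystem = "transport"),
    rxn("psII_chain",
        c(photon_c = -4, nadp_c = -2, nadph_c = 2, o2_c = 1), 0, B,
        gpr = "gpsb1 and gpsb2", subsystem = "photosynthesis"),
    rxn("cyclic_photophos", c(photon_c = -1, adp_c = -1, atp_c = 1), 0, B,
        gpr = "gcyc", subsystem = "photosynthesis"),
    rxn("carbon_fixation",
        c(co2_c = -6, nadph_c = -12, atp_c = -18, hexose_c = 1,
          nadp_c = 12, adp_c = 18), 0, B,
        gpr = "grbcL and grbcS", subsystem = "carbon fixation"),
    rxn("oxidative_ppp",
        c(hexose_c = -1, nadp_c = -12, nadph_c = 12, co2_c = 6), 0, B,
        gpr = "gzwf", subsystem = "pentose phosphate"),
    rxn("respiration",
        c(hexose_c = -1, o2_c = -6, adp_c = -30, co2_c = 6, atp_c = 30),
        0, B, gpr = "(gcox1 and gcox2) or gcyd", subsystem = "respiration"),
    rxn("atp_maintenance", c(atp_c = -1, adp_c = 1), 0, B,
        subsystem = "maintenance")
  )

  biomass_stoich <- c(hexose_c = -2, nh3_c = -2, atp_c = -20, adp_c = 20)
  if (spec$include_storage) {
    mets <- dplyr::bind_rows(mets, tibble::tibble(
      id = "glycogen_c", name = "storage polymer (glycogen analogue)",
      compartment = "c"))
    rows <- c(rows, list(
      rxn("glycogen_synthesis",
          c(hexose_c = -6, atp_c = -6, glycogen_c = 1, adp_c = 6), 0, B,
          gpr = "gglgA", subsystem = "storage"),
      rxn("glycogen_degradation", c(glycogen_c = -1, hexose_c = 6), 0, B,
          gpr = "gglgP", subsystem = "storage")
    ))
  }
  if (spec$include_pigment) {
    mets <- dplyr::bind_rows(mets, tibble::tibble(
      id = "chl_c", name = "chlorophyll pool", compartment = "c"))
    rows <- c(rows, list(
      rxn("chl_synthesis", c(hexose_c = -1, atp_c = -1, chl_c = 1,
                             adp_c = 1), 0, B,
          gpr = "gchlB or gchlL", subsystem = "pigment"),
      rxn("chl_degradation", c(chl_c = -1, hexose_c = 1), 0, B,
          subsystem = "pigment")
    ))
    biomass_stoich <- c(biomass_stoich, chl_c = -1)
  }
  rows <- c(rows, list(
    rxn("biomass", biomass_stoich, 0, B, subsystem = "biomass")
  ))
  rx <- dplyr::bind_rows(rows)

  model <- gsm(rx, mets, biomass_reaction_id = "biomass")
  if (spec$include_nif) {
    nif <- make_nif_set()
    model <- gsm(
      dplyr::bind_rows(model$reactions, nif$reactions),
      dplyr::bind_rows(model$metabolites, nif$metabolites),
      biomass_reaction_id = "biomass"
    )
  }
  attr(model, "carbon") <- toy_carbon_counts()
  model
}

#' Assembly configuration matching the toy model's identifiers
#'
#' @param spec The [toy_spec()] the base model was built from.
#' @param ... Overrides forwarded to [tpm_config()].
#' @return A [tpm_config()] wired to the toy reaction/metabolite ids.
#' @export
toy_tpm_config <- function(spec = toy_spec(), ...) {
  defaults <- list(
    n_tpm = spec$n_tpm,
    n_light = spec$n_light,
    transfer_compartments = "c",
    non_transfer_metabolites = "photon_c",
    pigment_metabolite_ids = if (spec$include_pigment) "chl_c" else character(0),
    photosynthesis_reaction_ids =
      if (spec$include_pigment) c("psII_chain", "cyclic_photophos")
      else character(0),
    co2_uptake_id = "co2_uptake",
    photon_uptake_id = "photon_uptake",
    atp_maintenance_id = "atp_maintenance"
  )
  overrides <- list(...)
  do.call(tpm_config, utils::modifyList(defaults, overrides))
}

#' The nitrogen-fixation reaction set
#'
#' Four reactions: dinitrogen exchange with the environment, diffusion
#' transport from the extracellular space into the periplasm and from the
#' periplasm into the cytosol, and the nitrogenase reaction consuming 16 ATP
#' and 8 reducing equivalents (as NADPH) per N2 fixed into two ammonia.
#'
#' @return A list with `reactions` and `metabolites` tibbles in the [gsm()]
#'   layout.
#' @export
make_nif_set <- function() {
  B <- DEFAULT_BOUND
  reactions <- tibble::tibble(
    id = c("EX_n2", "n2_transport_ep", "n2_transport_pc", "n2_fixation"),
    stoichiometry = list(
      c(n2_e = -1),
      c(n2_e = -1, n2_p = 1),
      c(n2_p = -1, n2_c = 1),
      c(n2_c = -1, atp_c = -16, nadph_c = -8,
        nh3_c = 2, adp_c = 16, nadp_c = 8)
    ),
    lower_bound = c(-B, -B, -B, 0),
    upper_bound = c(B, B, B, B),
    gpr = c("", "", "", "gnifH and gnifD and gnifK"),
    subsystem = c("exchange", "transport", "transport", "nitrogen fixation")
  )
  metabolites <- tibble::tibble(
    id = c("n2_e", "n2_p", "n2_c"),
    name = c("dinitrogen (external)", "dinitrogen (periplasm)",
             "dinitrogen (cytosol)"),
    compartment = c("e", "p", "c")
  )
  list(reactions = reactions, metabolites = metabolites)
}

#' Synthetic diel expression pattern
#'
#' @param shape One of `"diel-peak-light"`, `"diel-peak-dark"`,
#'   `"constant"`, `"noisy"`; recycled over genes.
#' @param amplitude Oscillation amplitude on top of the baseline.
#' @param baseline Baseline intensity.
#' @param seed RNG seed (used by `"noisy"`).
#' @return An `expression_pattern` list.
#' @export
expression_pattern <- function(shape = "diel-peak-light", amplitude = 1,
                               baseline = 0.2, seed = 1L) {
  shapes <- c("diel-peak-light", "diel-peak-dark", "constant", "noisy")
  stopifnot(all(shape %in% shapes), amplitude >= 0, baseline >= 0)
  structure(list(shape = shape, amplitude = amplitude, baseline = baseline,
                 seed = as.integer(seed)),
            class = "expression_pattern")
}

#' Generate a synthetic expression series
#'
#' Diel shapes are a sinusoid on a baseline, discretized to TPM midpoints:
#' `baseline + amplitude * (1 + sin(phase)) / 2`, phased so the peak falls
#' mid-light (or mid-dark). All values are non-negative and the series is
#' reproducible under the pattern's seed.
#'
#' @param genes Character vector of gene ids.
#' @param pattern An [expression_pattern()]; its `shape` is recycled over
#'   `genes`.
#' @param n_tpm Number of TPMs.
#' @param n_light Number of light TPMs (phases the sinusoid).
#' @return Tibble `gene`, `tpm`, `value`.
#' @export
make_expression <- function(genes, pattern = expression_pattern(),
                            n_tpm = 12L, n_light = 6L) {
  shapes <- rep_len(pattern$shape, length(genes))
  set.seed(pattern$seed)
  k <- seq_len(n_tpm)
  # peak of sin at phase pi/2 -> centre of the light window
  phase_light <- 2 * pi * (k - 0.5 - (n_light / 2 - 0.5)) / n_tpm
  out <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    values <- switch(
      shapes[g],
      "diel-peak-light" = pattern$baseline +
        pattern$amplitude * (1 + cos(phase_light)) / 2,
      "diel-peak-dark" = pattern$baseline +
        pattern$amplitude * (1 - cos(phase_light)) / 2,
      "constant" = rep(pattern$baseline + pattern$amplitude, n_tpm),
      "noisy" = pattern$baseline +
        abs(stats::rnorm(n_tpm, 0, max(pattern$amplitude, 1e-9)))
    )
    out[[g]] <- tibble::tibble(gene = genes[g], tpm = k, value = values)
  }
  dplyr::bind_rows(out)
}
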