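# Shared fixtures, built once per run and cached, so the solver subprocess
# is not re-invoked for every test that needs the same solved toy.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_k4 <- function() {
  cached("toy_k4", function() {
    spec <- toy_spec(n_tpm = 4, n_light = 2)
    base <- make_toy_gsm(spec)
    config <- toy_tpm_config(spec)
    list(spec = spec, base = base, config = config,
         model = build_diel_model(base, config))
  })
}

toy_k4_cascade <- function() {
  cached("toy_k4_cascade", function() solve_cascade(toy_k4()$model))
}

toy_k4_oracle <- function() {
  cached("toy_k4_oracle", function() {
    fx <- toy_k4()
    oracle_cascade(fx$base, fx$config)
  })
}

# A diazotrophic K=4 toy: ammonia uptake closed so fixed nitrogen is the
# only N source, nif reactions spliced in, exclusion MILP armed.
toy_diazo_k4 <- function() {
  cached("toy_diazo_k4", function() {
    spec <- toy_spec(n_tpm = 4, n_light = 2)
    base <- make_toy_gsm(spec)
    base$reactions$upper_bound[base$reactions$id == "nh3_uptake"] <- 0
    config <- toy_tpm_config(spec)
    model <- build_diel_model(base, config)
    nif <- make_nif_set()
    model <- add_nitrogen_fixation(model, nif$reactions, nif$metabolites)
    model <- add_oxygen_exclusion(model, "n2_fixation", "o2_c")
    # base model carrying the nif set, for the enumeration oracle
    base_nif <- make_toy_gsm(toy_spec(n_tpm = 4, n_light = 2,
                                      include_nif = TRUE))
    base_nif$reactions$upper_bound[base_nif$reactions$id == "nh3_uptake"] <- 0
    # nif metabolites are replicated but not given transfer reactions, so
    # the oracle must exclude them from its transfer enumeration too
    config_oracle <- toy_tpm_config(spec,
                                    non_transfer_metabolites = c("photon_c",
                                                                 "n2_c"))
    list(spec = spec, config = config, config_oracle = config_oracle,
         model = model, base_nif = base_nif)
  })
}

toy_expression <- function(n_tpm = 4, n_light = 2) {
  base <- make_toy_gsm(toy_spec(n_tpm = n_tpm, n_light = n_light))
  genes <- gene_ids(base)
  light_genes <- c("gpsb1", "gpsb2", "gcyc", "grbcL", "grbcS", "gchlB",
                   "gchlL", "gglgA")
  dplyr::bind_rows(
    make_expression(intersect(genes, light_genes),
                    expression_pattern("diel-peak-light", amplitude = 1,
                                       baseline = 0.3, seed = 11),
                    n_tpm = n_tpm, n_light = n_light),
    make_expression(setdiff(genes, light_genes),
                    expression_pattern("diel-peak-dark", amplitude = 1,
                                       baseline = 0.3, seed = 12),
                    n_tpm = n_tpm, n_light = n_light)
  )
}

# Tiny single-pathway model where biomass is exactly proportional to one
# expression-scaled bound: a substrate uptake chain feeding a biomass drain.
linear_chain_model <- function() {
  mets <- tibble::tibble(id = c("s_e", "s_c"), name = c("S (ext)", "S (cyt)"),
                         compartment = c("e", "c"))
  rx <- tibble::tibble(
    id = c("EX_s", "uptake", "biomass"),
    stoichiometry = list(c(s_e = -1), c(s_e = -1, s_c = 1), c(s_c = -1)),
    lower_bound = c(-10000, 0, 0),
    upper_bound = c(10000, 10, 10000),
    gpr = c("", "gup", ""),
    subsystem = ""
  )
  gsm(rx, mets, biomass_reaction_id = "biomass")
}

linear_chain_diel <- function(ratio = 0.5) {
  base <- linear_chain_model()
  config <- tpm_config(n_tpm = 2, n_light = 2, transfer_compartments = "c",
                       pigment_metabolite_ids = character(0),
                       photosynthesis_reaction_ids = character(0),
                       biomass_tpm = 2)
  model <- replicate_tpm(base, config) |>
    add_transfers() |>
    place_biomass()
  ratios <- tibble::tibble(reaction = "uptake", tpm = 1:2, ratio = ratio)
  apply_eflux(model, ratios)
}
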