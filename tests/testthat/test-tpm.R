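mini_base <- function() {
  mets <- tibble::tibble(
    id = c("a_c", "b_c", "p_c", "x_e"),
    name = c("a", "b", "photon", "x ext"),
    compartment = c("c", "c", "c", "e")
  )
  rx <- tibble::tibble(
    id = c("EX_x", "upt", "conv", "sink", "bio"),
    stoichiometry = list(c(x_e = -1), c(x_e = -1, a_c = 1),
                         c(a_c = -1, b_c = 1, p_c = 1), c(p_c = -1),
                         c(b_c = -1)),
    lower_bound = c(-10, 0, 0, 0, 0),
    upper_bound = c(10, 10, 10, 10, 10),
    gpr = "", subsystem = ""
  )
  gsm(rx, mets, biomass_reaction_id = "bio")
}

mini_config <- function(...) {
  tpm_config(n_tpm = 4, n_light = 2, transfer_compartments = "c",
             non_transfer_metabolites = "p_c",
             co2_uptake_id = "upt", photon_uptake_id = "upt",
             atp_maintenance_id = "sink", biomass_tpm = 4, ...)
}

test_that("replication multiplies reactions and metabolites with exact suffixes", {
  base <- mini_base()
  model <- replicate_tpm(base, mini_config())
  expect_equal(nrow(model$reactions), 5 * 4)
  expect_equal(nrow(model$metabolites), 4 * 4)
  expect_true("conv_tpm3" %in% model$reactions$instance_id)
  expect_true("a_c[tpm2]" %in% model$metabolites$instance_id)
  # stoichiometry keys carry the instance suffix of their own TPM
  s <- model$reactions$stoich[[match("conv_tpm2",
                                     model$reactions$instance_id)]]
  expect_setequal(names(s), c("a_c[tpm2]", "b_c[tpm2]", "p_c[tpm2]"))

  # unresolvable configured ids are reported
  bad <- mini_config()
  bad$photosynthesis_reaction_ids <- "no_such_rxn"
  expect_error(replicate_tpm(base, bad), "no_such_rxn")
})

test_that("transfer reactions cover eligible metabolites, boundaries, and wrap", {
  base <- mini_base()
  # eligible: a_c, b_c (p_c excluded as non-transfer, x_e wrong compartment)
  model <- add_transfers(replicate_tpm(base, mini_config()))
  tr <- model$reactions[model$reactions$type == "transfer", ]
  expect_equal(nrow(tr), 2 * 4) # 2 metabolites x 4 boundaries (wrap on)
  expect_true(all(tr$lb == 0))
  expect_true(all(tr$ub == 10000))
  expect_false(any(grepl("p_c", tr$instance_id)))
  expect_false(any(grepl("x_e", tr$instance_id)))
  expect_true("TR_a_c_tpm4_to_tpm1" %in% tr$instance_id)

  # acyclic mode: no closing edge, graph is a path
  acyc <- add_transfers(replicate_tpm(base, mini_config(wrap_around = FALSE)))
  tr2 <- acyc$reactions[acyc$reactions$type == "transfer", ]
  expect_equal(nrow(tr2), 2 * 3)
  expect_false(any(grepl("tpm4_to_tpm1", tr2$instance_id)))

  # the transfer graph over TPMs has only forward edges k -> k+1 (mod K)
  from <- tr$tpm
  to <- as.integer(sub(".*_to_tpm(\\d+)$", "\\1", tr$instance_id))
  expect_true(all(to == ifelse(from == 4, 1, from + 1)))
  expect_error(add_transfers(model), "already added")
})

test_that("phase bounds shut dark uptakes and impose maintenance everywhere", {
  fx <- toy_k4()
  rx <- fx$model$reactions
  co2 <- rx[rx$base_id == "co2_uptake", ]
  expect_equal(co2$ub[co2$tpm <= 2], rep(1.1, 2))
  expect_equal(co2$ub[co2$tpm > 2], rep(0, 2))
  photon <- rx[rx$base_id == "photon_uptake", ]
  expect_equal(photon$ub[photon$tpm <= 2], rep(60, 2))
  expect_equal(photon$ub[photon$tpm > 2], rep(0, 2))
  atpm <- rx[rx$base_id == "atp_maintenance", ]
  expect_equal(atpm$lb, rep(10, 4))

  cfg_missing <- toy_tpm_config(fx$spec)
  cfg_missing$atp_maintenance_id <- NULL
  expect_error(apply_phase_bounds(replicate_tpm(fx$base, cfg_missing),
                                  cfg_missing),
               "atp_maintenance_id")
})

test_that("biomass is active in exactly one configurable TPM", {
  fx <- toy_k4()
  rx <- fx$model$reactions
  bio <- rx[rx$base_id == "biomass", ]
  expect_equal(bio$ub[bio$tpm == 4], 10000)
  expect_true(all(bio$ub[bio$tpm != 4] == 0))
  expect_equal(fx$model$biomass_instance_id, "biomass_tpm4")
  # instances are bounded to zero, not deleted: indices stay aligned
  expect_equal(nrow(bio), 4)

  alt <- build_diel_model(fx$base, toy_tpm_config(fx$spec, biomass_tpm = 2))
  expect_equal(alt$biomass_instance_id, "biomass_tpm2")
  expect_error(toy_tpm_config(fx$spec, biomass_tpm = 13), "biomass_tpm")
})

test_that("pigment coupling rows encode v_photo <= (mc/2) * transfer difference", {
  fx <- toy_k4()
  rows <- fx$model$coupling_rows
  # 2 photosynthesis reactions x 4 TPMs
  expect_equal(nrow(rows), 8)
  r <- rows$coefs[[match("pigment_coupling_psII_chain_tpm2", rows$label)]]
  expect_equal(unname(r["psII_chain_tpm2"]), 1)
  expect_equal(unname(r["TR_chl_c_tpm2_to_tpm3"]), -500)
  expect_equal(unname(r["TR_chl_c_tpm1_to_tpm2"]), 500)
  # out - in = 0.002 with m_c = 1000 caps photosynthesis at 0.5*1000*0.002 = 1.0
  expect_equal(-r[["TR_chl_c_tpm2_to_tpm3"]] * 0.002, 1)
  # the cycle start carries no incoming-pigment term
  r1 <- rows$coefs[[match("pigment_coupling_psII_chain_tpm1", rows$label)]]
  expect_false("TR_chl_c_tpm4_to_tpm1" %in% names(r1))

  # pigment metabolite without a transfer reaction is a configuration error
  spec <- toy_spec(n_tpm = 4, n_light = 2)
  base <- make_toy_gsm(spec)
  cfg <- toy_tpm_config(spec, non_transfer_metabolites = c("photon_c", "chl_c"))
  expect_error(build_diel_model(base, cfg), "pigment")
})

test_that("K=1 diel model with wrap off reproduces the base FBA optimum", {
  spec <- toy_spec(n_tpm = 1, n_light = 1, include_storage = FALSE,
                   include_pigment = FALSE)
  base <- make_toy_gsm(spec)
  config <- toy_tpm_config(spec, wrap_around = FALSE, biomass_tpm = 1)
  diel <- build_diel_model(base, config)
  expect_equal(sum(diel$reactions$type == "transfer"), 0)
  diel_opt <- maximize_biomass(diel)

  # single-compartment FBA of the base model under the same light bounds
  base2 <- base
  base2$reactions$upper_bound[base2$reactions$id == "co2_uptake"] <- 1.1
  base2$reactions$upper_bound[base2$reactions$id == "photon_uptake"] <- 60
  base2$reactions$lower_bound[base2$reactions$id == "atp_maintenance"] <- 10
  lp <- oracle_build(base2, toy_tpm_config(spec, n_tpm = 1, n_light = 1,
                                           wrap_around = FALSE,
                                           biomass_tpm = 1))
  p <- oracle_problem(lp)
  p$objectives <- list(oracle_objective(lp, lp$biomass_col, 1, "max"))
  base_opt <- dielfba:::backend_solve(list(p))[[1]][[1]]

  expect_equal(diel_opt$objective_value, base_opt$objective,
               tolerance = 1e-9)
  expect_gt(diel_opt$objective_value, 0)
})
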