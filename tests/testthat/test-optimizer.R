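test_that("the cascade matches the dense-matrix oracle on the K=4 toy", {
  casc <- toy_k4_cascade()
  orac <- toy_k4_oracle()
  expect_equal(casc$biomass$status, "optimal")
  expect_equal(casc$biomass$objective_value, orac$biomass,
               tolerance = 1e-6)
  expect_equal(casc$f, orac$f, tolerance = 1e-6)
  merged <- dplyr::inner_join(tibble::as_tibble(casc$fva), orac$fva,
                              by = "instance_id",
                              suffix = c("_impl", "_oracle"))
  expect_equal(nrow(merged), nrow(orac$fva))
  expect_equal(merged$min_impl, merged$min_oracle, tolerance = 1e-6)
  expect_equal(merged$max_impl, merged$max_oracle, tolerance = 1e-6)
})

test_that("pFBA keeps biomass at its maximum and FVA envelopes contain it", {
  casc <- toy_k4_cascade()
  bio_flux <- casc$pfba$fluxes$flux[
    casc$pfba$fluxes$instance_id == "biomass_tpm4"]
  expect_equal(bio_flux, casc$biomass$objective_value,
               tolerance = 1e-6 * max(1, abs(bio_flux)))
  # every FVA range contains the pFBA solution's flux for that reaction
  pf <- casc$pfba$fluxes
  merged <- dplyr::inner_join(tibble::as_tibble(casc$fva), pf,
                              by = "instance_id")
  expect_true(all(merged$flux >= merged$min - 1e-6))
  expect_true(all(merged$flux <= merged$max + 1e-6))
  # total transfer flux in the pFBA solution equals the budget
  expect_equal(sum(pf$flux[pf$type == "transfer"]), casc$f,
               tolerance = 1e-6)
})

test_that("loosening the transfer budget never shrinks an FVA range", {
  fx <- toy_k4()
  casc <- toy_k4_cascade()
  wide <- fva(fx$model, casc$biomass$objective_value, 2 * casc$f)
  merged <- dplyr::inner_join(tibble::as_tibble(casc$fva),
                              tibble::as_tibble(wide),
                              by = "instance_id",
                              suffix = c("_tight", "_wide"))
  expect_true(all(merged$min_wide <= merged$min_tight + 1e-7))
  expect_true(all(merged$max_wide >= merged$max_tight - 1e-7))
})

test_that("FVA of fixed or shut reactions gives degenerate ranges", {
  fx <- toy_k4()
  casc <- toy_k4_cascade()
  bm <- casc$biomass$objective_value
  # the biomass instance itself is pinned by the equality
  r <- fva(fx$model, bm, casc$f, targets = "biomass_tpm4")
  expect_equal(r$min, bm, tolerance = 1e-7)
  expect_equal(r$max, bm, tolerance = 1e-7)
  # a dark-phase uptake is bounded to zero
  r0 <- fva(fx$model, bm, casc$f, targets = "co2_uptake_tpm3")
  expect_equal(r0$min, 0, tolerance = 1e-9)
  expect_equal(r0$max, 0, tolerance = 1e-9)
  # unknown targets are rejected
  expect_error(fva(fx$model, bm, casc$f, targets = "nope_tpm1"), "nope")
})

test_that("starving the model is reported as infeasible, never silent zeros", {
  fx <- toy_k4()
  model <- fx$model
  up <- model$reactions$base_id %in% c("co2_uptake", "photon_uptake",
                                       "nh3_uptake")
  model$reactions$ub[up] <- 0
  model$reactions$lb[up] <- 0
  res <- maximize_biomass(model)
  # dark ATP maintenance cannot be met without any carbon or light input
  expect_equal(res$status, "infeasible")
  expect_true(is.na(res$objective_value))
})

test_that("a model without transferable metabolites yields f = 0", {
  spec <- toy_spec(n_tpm = 2, n_light = 2, include_storage = FALSE,
                   include_pigment = FALSE)
  base <- make_toy_gsm(spec)
  config <- toy_tpm_config(spec, transfer_compartments = character(0),
                           biomass_tpm = 2)
  model <- build_diel_model(base, config)
  bm <- maximize_biomass(model)
  expect_equal(bm$status, "optimal")
  pf <- minimize_transfers(model, bm$objective_value)
  expect_equal(pf$f, 0)
})

test_that("carbon entering the system balances carbon leaving it", {
  fx <- toy_k4()
  casc <- toy_k4_cascade()
  carbon <- attr(fx$base, "carbon")
  fluxes <- casc$pfba$fluxes
  # net carbon exchange across the boundary: exchange reactions export their
  # metabolite at positive flux; biomass drains fixed carbon
  carbon_in <- 0
  for (e in fx$base$exchange_ids) {
    s <- fx$base$reactions$stoichiometry[[match(e, fx$base$reactions$id)]]
    flux_sum <- sum(fluxes$flux[fluxes$base_id == e])
    # exchange consumes its metabolite at positive flux (export), so the
    # carbon brought in is flux * stoichiometric coefficient * C
    carbon_in <- carbon_in + flux_sum * s[[1]] * carbon[[names(s)]]
  }
  bio_s <- fx$base$reactions$stoichiometry[[
    match("biomass", fx$base$reactions$id)]]
  bio_c <- -sum(bio_s[bio_s < 0] * carbon[names(bio_s)[bio_s < 0]])
  bio_flux <- sum(fluxes$flux[fluxes$base_id == "biomass"])
  expect_gt(bio_flux, 0)
  expect_equal(carbon_in, bio_c * bio_flux, tolerance = 1e-6)
})

test_that("internal loops are flagged with exchanges closed, loop-free toys are not", {
  spec <- toy_spec(n_tpm = 4, n_light = 2)
  base <- make_toy_gsm(spec)
  expect_identical(check_unbounded_loops(base), character(0))

  # add a 2-reaction reversible cycle: both directions get flagged
  loopy <- base
  loopy$reactions <- dplyr::bind_rows(
    loopy$reactions,
    tibble::tibble(
      id = c("cycle_fwd", "cycle_rev"),
      stoichiometry = list(c(hexose_c = -1, co2_c = 6),
                           c(co2_c = -6, hexose_c = 1)),
      lower_bound = 0, upper_bound = 10000, gpr = "", subsystem = ""))
  loopy <- gsm(loopy$reactions, loopy$metabolites, "biomass")
  flagged <- check_unbounded_loops(loopy)
  expect_true(all(c("cycle_fwd", "cycle_rev") %in% flagged))

  # flagged set is invariant to reaction ordering
  shuffled <- loopy
  set.seed(7)
  ord <- sample(nrow(shuffled$reactions))
  shuffled <- gsm(shuffled$reactions[ord, ], shuffled$metabolites, "biomass")
  expect_identical(check_unbounded_loops(shuffled), flagged)
})

test_that("capacity bounds tighten to attainable ranges without forcing flux", {
  fx <- toy_k4()
  capped <- capacity_bounds(fx$base, fx$config)
  # never enlarges a bound, never forces a reaction on
  expect_true(all(capped$reactions$upper_bound <=
                    fx$base$reactions$upper_bound + 1e-9))
  expect_true(all(capped$reactions$lower_bound <= 1e-9))
  # exchanges and biomass keep their original bounds
  ex <- capped$reactions$id %in% c(fx$base$exchange_ids, "biomass")
  expect_equal(capped$reactions$upper_bound[ex],
               fx$base$reactions$upper_bound[ex])
  # capacities are on the scale of the uptake limits, not the global cap
  cf <- capped$reactions$upper_bound[capped$reactions$id == "carbon_fixation"]
  expect_lt(cf, 100)
  expect_gt(cf, 0)
  # the capped diel model still grows
  bm <- maximize_biomass(build_diel_model(capped, fx$config))
  expect_equal(bm$status, "optimal")
  expect_gt(bm$objective_value, 0)
})
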