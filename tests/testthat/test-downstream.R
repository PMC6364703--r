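test_that("active bounds are flagged only when constricted and attained", {
  model <- linear_chain_diel(ratio = 0.5) # uptake UB 10 -> scaled to 5
  bm <- maximize_biomass(model)
  # both TPMs' scaled uptake bounds feed the single drain: 2 x 5
  expect_equal(bm$objective_value, 10)
  pf <- minimize_transfers(model, bm$objective_value)
  ranges <- fva(model, bm$objective_value, pf$f,
                targets = model$reactions$instance_id[
                  model$reactions$type == "core"])
  active <- find_active_bounds(model, ranges, solution = pf$solution)
  # the scaled uptake instances hit their constricted bound
  expect_true(any(grepl("^uptake_tpm", active$instance_id)))
  # unscaled reactions (ratio 1) are never flagged
  expect_false(any(grepl("^EX_s", active$instance_id)))
  expect_false(any(grepl("^biomass", active$instance_id)))
  expect_equal(attr(active, "n_unique"),
               length(unique(active$base_id)))

  # with ratio 1 nothing is constricted, so nothing is flagged
  ident <- linear_chain_diel(ratio = 1)
  bm1 <- maximize_biomass(ident)
  pf1 <- minimize_transfers(ident, bm1$objective_value)
  r1 <- fva(ident, bm1$objective_value, pf1$f,
            targets = ident$reactions$instance_id[
              ident$reactions$type == "core"])
  expect_equal(nrow(find_active_bounds(ident, r1)), 0)
})

test_that("unique-reaction counting deduplicates instances across TPMs", {
  model <- linear_chain_diel(ratio = 0.5)
  bm <- maximize_biomass(model)
  pf <- minimize_transfers(model, bm$objective_value)
  ranges <- fva(model, bm$objective_value, pf$f,
                targets = c("uptake_tpm1", "uptake_tpm2"))
  active <- find_active_bounds(model, ranges)
  expect_gt(nrow(active), 1)
  expect_equal(attr(active, "n_unique"), 1)
})

test_that("flux control coefficients: proportional control gives 1, slack
           bounds give 0", {
  # biomass is exactly the scaled uptake bound, so tightening the bound by
  # 1% drops biomass by 1%: C = 1
  model <- linear_chain_diel(ratio = 0.5)
  fcc <- flux_control_coefficients(model)
  expect_true(all(c("uptake_tpm1", "uptake_tpm2") %in% fcc$instance_id))
  # both uptake instances feed the single biomass drain; their bounds are
  # both binding, and total control sums to 1
  expect_equal(sum(fcc$coefficient), 1, tolerance = 1e-6)

  # a bound that is slack at the optimum exerts no control: cap the biomass
  # drain far below the (mildly scaled) chain capacity
  loose <- linear_chain_diel(ratio = 0.999)
  loose$reactions$ub[loose$reactions$instance_id == "biomass_tpm2"] <- 1
  fcc_loose <- flux_control_coefficients(loose)
  expect_true(all(fcc_loose$coefficient == 0))
})

test_that("spearman_rho reproduces the printed rank formula, ties included", {
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 4, 9)), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  # tie case against an independent mid-rank computation (Pearson on ranks)
  a <- c(1, 2, 2, 4)
  b <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(a, b),
               stats::cor(rank(a), rank(b), method = "pearson"))
  # and against R's own Spearman estimate
  expect_equal(spearman_rho(a, b),
               unname(stats::cor(a, b, method = "spearman")))
  # invariance under strictly monotone transforms
  set.seed(3)
  x <- stats::runif(10)
  y <- stats::runif(10)
  expect_equal(spearman_rho(exp(x), y^3), spearman_rho(x, y))
})

test_that("mmca normalizes profiles, flags significance, and keeps
           insignificant pairs", {
  profiles <- tibble::tibble(
    metabolite = rep(c("m1", "m2", "m3", "m4"), each = 6),
    tpm = rep(1:6, 4),
    flux = c(1, 2, 3, 4, 5, 6,      # monotone up
             6, 5, 4, 3, 2, 1,      # monotone down
             2, 4, 6, 8, 10, 12,    # same ordering as m1
             0, 0, 0, 0, 0, 0))     # all-zero: excluded
  out <- mmca(profiles)
  expect_setequal(unique(c(out$a, out$b)), c("m1", "m2", "m3"))
  pair <- function(x, y) out[out$a == x & out$b == y | out$a == y & out$b == x, ]
  expect_equal(pair("m1", "m3")$r_s, 1)
  expect_equal(pair("m1", "m2")$r_s, -1)
  expect_true(pair("m1", "m2")$significant)
  expect_true(all(c("r_s", "p_value", "significant") %in% names(out)))

  # an imperfect pair: coefficient and t-approximation p-value match R's
  # Spearman machinery
  with_m5 <- dplyr::bind_rows(profiles, tibble::tibble(
    metabolite = "m5", tpm = 1:6, flux = c(2, 1, 4, 3, 6, 5)))
  out5 <- mmca(with_m5)
  got <- out5[out5$a == "m1" & out5$b == "m5" |
                out5$a == "m5" & out5$b == "m1", ]
  ct <- stats::cor.test(1:6, c(2, 1, 4, 3, 6, 5), method = "spearman",
                        exact = FALSE)
  expect_equal(got$r_s, unname(ct$estimate), tolerance = 1e-9)
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-9)

  expect_error(mmca(dplyr::filter(profiles, tpm <= 2)), "3 TPMs")
})

test_that("category aggregation sums member envelopes and partitions the total", {
  fva_tbl <- structure(tibble::tibble(
    instance_id = paste0("TR_", rep(c("m1", "m2", "m3"), each = 2),
                         "_tpm", rep(1:2, 3), "_to_tpm", rep(2:3, 3)),
    base_id = paste0("TR_", rep(c("m1", "m2", "m3"), each = 2)),
    tpm = rep(1:2, 3), type = "transfer",
    metabolite = rep(c("m1", "m2", "m3"), each = 2),
    min = c(0.5, 1, 1, 2, 0.1, 0.2),
    max = c(1.0, 2.5, 2, 3, 0.4, 0.6),
    status = "optimal"), class = c("fva_result", class(tibble::tibble())))
  annotation <- tibble::tibble(metabolite = c("m1", "m2"),
                               category = "sugars")
  expect_warning(profiles <- aggregate_by_category(fva_tbl, annotation),
                 "m3")
  sugars <- profiles[profiles$category == "sugars", ]
  expect_equal(sugars$max_total[sugars$tpm == 1], 1.0 + 2)
  expect_equal(sugars$max_total[sugars$tpm == 2], 2.5 + 3)
  # the category partition conserves the total transfer profile
  totals <- profiles |>
    dplyr::summarise(s = sum(.data$max_total), .by = "tpm") |>
    dplyr::arrange(.data$tpm)
  expect_equal(totals$s, c(1.0 + 2 + 0.4, 2.5 + 3 + 0.6))
  # order of metabolite enumeration does not matter
  expect_warning(shuffled <- aggregate_by_category(fva_tbl[c(5, 3, 1, 6, 2, 4), ],
                                                   annotation), "m3")
  expect_equal(dplyr::arrange(shuffled, category, tpm),
               dplyr::arrange(profiles, category, tpm))
})

test_that("profile normalization divides by the series maximum", {
  expect_equal(normalize_profile(c(2, 4, 8, 6)), c(0.25, 0.5, 1, 0.75))
  expect_equal(normalize_profile(rep(5, 4)), rep(1, 4))
  expect_equal(max(normalize_profile(stats::runif(12) + 0.1)), 1)
  expect_error(normalize_profile(c(0, 0, 0)), "all-zero")
})
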