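test_that("gsm construction enforces structural invariants", {
  base <- make_toy_gsm(toy_spec())
  expect_s3_class(base, "gsm")
  stats <- model_stats(base)
  expect_equal(stats$n_reactions, nrow(base$reactions))
  expect_equal(stats$n_metabolites, nrow(base$metabolites))
  expect_equal(stats$n_exchanges, 4L)

  # undeclared metabolite in a stoichiometry
  rx <- base$reactions
  rx$stoichiometry[[10]] <- c(ghost_met = -1)
  expect_error(gsm(rx, base$metabolites, "biomass"),
               "undeclared metabolite")

  # inverted bounds
  rx2 <- base$reactions
  rx2$lower_bound[2] <- rx2$upper_bound[2] + 1
  expect_error(gsm(rx2, base$metabolites, "biomass"),
               "lower_bound > upper_bound")

  # missing biomass reaction
  expect_error(gsm(base$reactions, base$metabolites, "not_a_reaction"),
               "biomass")

  # stats are computed on the base model, before any replication
  expect_equal(model_stats(base)$n_reactions,
               model_stats(make_toy_gsm(toy_spec(n_tpm = 12)))$n_reactions)
})

test_that("tabular dialect round-trips models", {
  base <- make_toy_gsm(toy_spec())
  rx_path <- withr::local_tempfile(fileext = ".tsv")
  met_path <- withr::local_tempfile(fileext = ".tsv")
  write_gsm_tsv(base, rx_path, met_path)
  back <- read_gsm_tsv(rx_path, met_path, "biomass")

  expect_equal(back$reactions$id, base$reactions$id)
  expect_equal(back$reactions$lower_bound, base$reactions$lower_bound)
  expect_equal(back$reactions$upper_bound, base$reactions$upper_bound)
  expect_equal(back$reactions$gpr, base$reactions$gpr)
  for (i in seq_len(nrow(base$reactions))) {
    a <- base$reactions$stoichiometry[[i]]
    b <- back$reactions$stoichiometry[[i]]
    expect_mapequal(as.list(b), as.list(a))
  }
})

test_that("equation strings parse and format consistently", {
  s <- c(a = -2, b = -1, c = 1.5)
  expect_mapequal(as.list(parse_equation(format_equation(s))), as.list(s))
  expect_error(parse_equation("a + b c"), "arrow")
  expect_mapequal(as.list(parse_equation("2 a + b --> c")),
                  list(a = -2, b = -1, c = 1))
})

test_that("SBML round-trip preserves structure, bounds, and GPRs", {
  base <- make_toy_gsm(toy_spec())
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(base, path)
  back <- read_sbml(path)

  expect_equal(sort(back$reactions$id), sort(base$reactions$id))
  expect_equal(sort(back$metabolites$id), sort(base$metabolites$id))
  expect_equal(back$biomass_reaction_id, "biomass")
  ord <- match(base$reactions$id, back$reactions$id)
  expect_equal(back$reactions$lower_bound[ord], base$reactions$lower_bound)
  expect_equal(back$reactions$upper_bound[ord], base$reactions$upper_bound)
  for (i in seq_len(nrow(base$reactions))) {
    a <- base$reactions$stoichiometry[[i]]
    b <- back$reactions$stoichiometry[[ord[i]]]
    expect_mapequal(as.list(b), as.list(a))
  }
  # GPRs survive verbatim up to whitespace/parenthesisation equivalence:
  # the parsed trees must be identical
  for (i in seq_len(nrow(base$reactions))) {
    expect_identical(parse_gpr(back$reactions$gpr[[ord[i]]]),
                     parse_gpr(base$reactions$gpr[[i]]))
  }

  # second pass through the writer is byte-stable
  path2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(back, path2)
  expect_identical(parse_gpr(read_sbml(path2)$reactions$gpr[
    match("respiration", read_sbml(path2)$reactions$id)]),
    parse_gpr("(gcox1 and gcox2) or gcyd"))
})

test_that("SBML reader rejects broken documents and refuses degenerate writes", {
  # undeclared species reference, naming the reaction
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfSpecies>',
    '<species id="M_a" compartment="C_c"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R_r1" reversible="false">',
    '<listOfReactants><speciesReference species="M_ghost" stoichiometry="1"/></listOfReactants>',
    '</reaction></listOfReactions></model></sbml>'), bad)
  expect_error(read_sbml(bad, biomass_reaction_id = "r1"), "r1.*ghost")

  # malformed XML errors out at parse time
  mangled <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model></sbml>", mangled)
  expect_error(read_sbml(mangled))

  # no objective and no explicit biomass id -> configuration error
  noobj <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfSpecies><species id="M_a" compartment="C_c"/></listOfSpecies>',
    '<listOfReactions><reaction id="R_r1" reversible="false">',
    '<listOfReactants><speciesReference species="M_a" stoichiometry="1"/></listOfReactants>',
    '</reaction></listOfReactions></model></sbml>'), noobj)
  expect_error(read_sbml(noobj), "objective|biomass")

  # refuse to serialize a model with no reactions
  empty <- structure(list(
    reactions = tibble::tibble(id = character(0), stoichiometry = list(),
                               lower_bound = numeric(0),
                               upper_bound = numeric(0), gpr = character(0),
                               subsystem = character(0)),
    metabolites = tibble::tibble(id = "a", name = "a", compartment = "c"),
    biomass_reaction_id = "none", exchange_ids = character(0)),
    class = "gsm")
  expect_error(write_sbml(empty, tempfile()), "no reactions")
})

test_that("Level 2 note-encoded SBML is read with bounds and gene rules", {
  l2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m">',
    '<listOfSpecies>',
    '<species id="M_a" name="a" compartment="C_c"/>',
    '<species id="M_b" name="b" compartment="C_c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R_conv" reversible="true">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: (g1 and g2) or g3</p>',
    '</body></notes>',
    '<listOfReactants><speciesReference species="M_a" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_b" stoichiometry="2"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-5"/>',
    '<parameter id="UPPER_BOUND" value="7"/>',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="1"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '<reaction id="R_free" reversible="false">',
    '<listOfReactants><speciesReference species="M_b"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), l2)
  model <- read_sbml(l2)
  conv <- model$reactions[model$reactions$id == "conv", ]
  expect_equal(conv$lower_bound, -5)
  expect_equal(conv$upper_bound, 7)
  expect_identical(parse_gpr(conv$gpr), parse_gpr("(g1 and g2) or g3"))
  expect_equal(model$biomass_reaction_id, "conv")
  # unspecified bounds default to the global magnitude; irreversible lb = 0
  free <- model$reactions[model$reactions$id == "free", ]
  expect_equal(free$lower_bound, 0)
  expect_equal(free$upper_bound, 10000)
})
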