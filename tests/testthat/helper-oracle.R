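# Independent dense-matrix LP oracle.
#
# Builds the full diel constraint matrix by direct enumeration from the base
# model tables and the configuration — no reuse of the package's diel-model
# assembly — and solves it through the raw solver interface. Shares only the
# instance-naming convention (part of the interface contract) so results can
# be matched per reaction instance.

oracle_build <- function(base, config, ratios = NULL) {
  K <- config$n_tpm
  rx <- base$reactions
  mets <- base$metabolites

  core_vars <- as.vector(outer(rx$id, seq_len(K),
                               function(j, k) paste0(j, "_tpm", k)))
  eligible <- mets$id[mets$compartment %in% config$transfer_compartments &
                        !(mets$id %in% config$non_transfer_metabolites)]
  boundaries <- if (config$wrap_around) seq_len(K) else seq_len(K - 1L)
  tr_vars <- character(0)
  tr_met <- character(0)
  tr_from <- integer(0)
  for (k in boundaries) {
    k2 <- if (k == K) 1L else k + 1L
    tr_vars <- c(tr_vars, paste0("TR_", eligible, "_tpm", k, "_to_tpm", k2))
    tr_met <- c(tr_met, eligible)
    tr_from <- c(tr_from, rep(k, length(eligible)))
  }
  vars <- c(core_vars, tr_vars)
  nv <- length(vars)

  met_rows <- as.vector(outer(mets$id, seq_len(K),
                              function(i, k) paste0(i, "[tpm", k, "]")))
  A <- matrix(0, nrow = length(met_rows), ncol = nv,
              dimnames = list(met_rows, vars))
  for (r in seq_len(nrow(rx))) {
    s <- rx$stoichiometry[[r]]
    for (k in seq_len(K)) {
      col <- paste0(rx$id[r], "_tpm", k)
      for (m in names(s)) {
        row <- paste0(m, "[tpm", k, "]")
        A[row, col] <- A[row, col] + s[[m]]
      }
    }
  }
  for (t in seq_along(tr_vars)) {
    k <- tr_from[t]
    k2 <- if (k == K) 1L else k + 1L
    A[paste0(tr_met[t], "[tpm", k, "]"), tr_vars[t]] <-
      A[paste0(tr_met[t], "[tpm", k, "]"), tr_vars[t]] - 1
    A[paste0(tr_met[t], "[tpm", k2, "]"), tr_vars[t]] <-
      A[paste0(tr_met[t], "[tpm", k2, "]"), tr_vars[t]] + 1
  }
  row_lb <- rep(0, nrow(A))
  row_ub <- rep(0, nrow(A))

  lb <- stats::setNames(rep(0, nv), vars)
  ub <- stats::setNames(rep(0, nv), vars)
  for (r in seq_len(nrow(rx))) {
    for (k in seq_len(K)) {
      col <- paste0(rx$id[r], "_tpm", k)
      lb[col] <- rx$lower_bound[r]
      ub[col] <- rx$upper_bound[r]
    }
  }
  lb[tr_vars] <- 0
  ub[tr_vars] <- config$transfer_ub

  # phase bounds
  for (k in seq_len(K)) {
    light <- k <= config$n_light
    co2 <- paste0(config$co2_uptake_id, "_tpm", k)
    pho <- paste0(config$photon_uptake_id, "_tpm", k)
    atp <- paste0(config$atp_maintenance_id, "_tpm", k)
    ub[co2] <- if (light) config$co2_uptake_ub else 0
    ub[pho] <- if (light) config$photon_uptake_ub else 0
    lb[co2] <- min(lb[co2], ub[co2])
    lb[pho] <- min(lb[pho], ub[pho])
    lb[atp] <- config$atp_maintenance_lb
  }
  # biomass placement
  for (k in setdiff(seq_len(K), config$biomass_tpm)) {
    col <- paste0(base$biomass_reaction_id, "_tpm", k)
    lb[col] <- 0
    ub[col] <- 0
  }
  # expression scaling of non-exempt core columns
  if (!is.null(ratios)) {
    exempt <- c(base$exchange_ids, base$biomass_reaction_id)
    for (r in seq_len(nrow(ratios))) {
      id <- ratios$reaction[r]
      if (id %in% exempt) next
      col <- paste0(id, "_tpm", ratios$tpm[r])
      base_ub <- rx$upper_bound[match(id, rx$id)]
      ub[col] <- min(ub[col], base_ub * ratios$ratio[r])
      lb[col] <- min(lb[col], ub[col])
    }
  }

  # pigment coupling rows: v_photo,k - mc/2 * (out - in) <= 0, no incoming
  # term at the cycle start
  extra <- list()
  if (length(config$pigment_metabolite_ids) > 0 &&
      length(config$photosynthesis_reaction_ids) > 0) {
    for (k in seq_len(K)) {
      k2 <- if (k == K) 1L else k + 1L
      out_ids <- paste0("TR_", config$pigment_metabolite_ids, "_tpm", k,
                        "_to_tpm", k2)
      in_ids <- if (k == 1L) character(0) else {
        paste0("TR_", config$pigment_metabolite_ids, "_tpm", k - 1L,
               "_to_tpm", k)
      }
      out_ids <- intersect(out_ids, vars)
      in_ids <- intersect(in_ids, vars)
      if (length(out_ids) == 0) next # last TPM in acyclic mode
      for (p in config$photosynthesis_reaction_ids) {
        row <- stats::setNames(rep(0, nv), vars)
        row[paste0(p, "_tpm", k)] <- 1
        row[out_ids] <- row[out_ids] - config$m_c / 2
        row[in_ids] <- row[in_ids] + config$m_c / 2
        extra[[length(extra) + 1L]] <- row
      }
    }
  }
  if (length(extra) > 0) {
    A <- rbind(A, do.call(rbind, extra))
    row_lb <- c(row_lb, rep(-Inf, length(extra)))
    row_ub <- c(row_ub, rep(0, length(extra)))
  }

  list(vars = vars, tr_vars = tr_vars, A = A, row_lb = row_lb,
       row_ub = row_ub, lb = lb, ub = ub,
       biomass_col = paste0(base$biomass_reaction_id, "_tpm",
                            config$biomass_tpm))
}

oracle_problem <- function(lp, extra_rows = NULL, extra_lb = NULL,
                           extra_ub = NULL) {
  A <- lp$A
  row_lb <- lp$row_lb
  row_ub <- lp$row_ub
  if (!is.null(extra_rows)) {
    A <- rbind(A, extra_rows)
    row_lb <- c(row_lb, extra_lb)
    row_ub <- c(row_ub, extra_ub)
  }
  list(n = length(lp$vars), lb = unname(lp$lb), ub = unname(lp$ub),
       A = dielfba:::dense_to_triplets(A),
       row_lb = unname(row_lb), row_ub = unname(row_ub),
       objectives = list())
}

oracle_objective <- function(lp, ids, weights = 1, sense, want_x = FALSE) {
  coef <- stats::setNames(rep(0, length(lp$vars)), lp$vars)
  coef[ids] <- weights
  dielfba:::new_objective(unname(coef), sense, want_x)
}

# Solve the full three-stage cascade on the oracle matrices. Returns the
# biomass optimum, transfer budget f, and FVA ranges over the transfers.
oracle_cascade <- function(base, config, ratios = NULL,
                           fva_targets = NULL) {
  lp <- oracle_build(base, config, ratios)
  p1 <- oracle_problem(lp)
  p1$objectives <- list(oracle_objective(lp, lp$biomass_col, 1, "max"))
  bm <- dielfba:::backend_solve(list(p1))[[1]][[1]]
  if (bm$status != "optimal") {
    return(list(status = bm$status, biomass = NA_real_))
  }

  lp2 <- lp
  lp2$lb[lp$biomass_col] <- bm$objective
  lp2$ub[lp$biomass_col] <- bm$objective
  p2 <- oracle_problem(lp2)
  p2$objectives <- list(oracle_objective(lp2, lp2$tr_vars, 1, "min"))
  pf <- dielfba:::backend_solve(list(p2))[[1]][[1]]

  cap_row <- stats::setNames(rep(0, length(lp$vars)), lp$vars)
  cap_row[lp$tr_vars] <- 1
  p3 <- oracle_problem(lp2, extra_rows = matrix(cap_row, nrow = 1),
                       extra_lb = -Inf, extra_ub = pf$objective)
  targets <- fva_targets
  if (is.null(targets)) targets <- lp$tr_vars
  objs <- list()
  for (t in targets) {
    objs[[length(objs) + 1L]] <- oracle_objective(lp2, t, 1, "min")
    objs[[length(objs) + 1L]] <- oracle_objective(lp2, t, 1, "max")
  }
  p3$objectives <- objs
  res <- dielfba:::backend_solve(list(p3))[[1]]
  ranges <- tibble::tibble(
    instance_id = targets,
    min = vapply(seq_along(targets), function(i) res[[2 * i - 1]]$objective,
                 numeric(1)),
    max = vapply(seq_along(targets), function(i) res[[2 * i]]$objective,
                 numeric(1))
  )
  list(status = "optimal", biomass = bm$objective, f = pf$objective,
       fva = ranges)
}

# Exhaustive-enumeration oracle for the diazotrophy MILP: per TPM the
# (y_n2, y_o2) pair can be (0,0), (1,0), or (0,1); every combination is a
# plain LP with the governed bounds switched, solved in one batched call.
oracle_milp_enumerate <- function(base, config, fixation_id,
                                  o2_metabolite_id) {
  lp <- oracle_build(base, config)
  K <- config$n_tpm
  states <- expand.grid(rep(list(0:2), K)) # 0: both off, 1: fix on, 2: o2 on
  problems <- vector("list", nrow(states))
  for (s in seq_len(nrow(states))) {
    lp_s <- lp
    for (k in seq_len(K)) {
      st <- states[s, k]
      fix_col <- paste0(fixation_id, "_tpm", k)
      k2 <- if (k == K) 1L else k + 1L
      o2_col <- paste0("TR_", o2_metabolite_id, "_tpm", k, "_to_tpm", k2)
      if (st != 1) { # fixation off
        lp_s$lb[fix_col] <- 0
        lp_s$ub[fix_col] <- 0
      }
      if (st != 2) { # o2 carry-over off
        lp_s$lb[o2_col] <- 0
        lp_s$ub[o2_col] <- 0
      }
    }
    p <- oracle_problem(lp_s)
    p$objectives <- list(oracle_objective(lp_s, lp_s$biomass_col, 1, "max"))
    problems[[s]] <- p
  }
  res <- dielfba:::backend_solve(problems)
  objs <- vapply(res, function(r) {
    if (r[[1]]$status == "optimal") r[[1]]$objective else -Inf
  }, numeric(1))
  list(best = max(objs), objectives = objs,
       best_state = unlist(states[which.max(objs), ]))
}

# Independent GPR evaluation oracle: R's own parser evaluates the rule with
# %and%/%or% bound to min/max. Valid only for fully parenthesised rules
# (R gives user operators flat precedence), which the random-tree generator
# guarantees.
oracle_eval_gpr <- function(gpr, ratios) {
  txt <- gsub("\\band\\b", "%and%", gpr, ignore.case = TRUE)
  txt <- gsub("\\bor\\b", "%or%", txt, ignore.case = TRUE)
  env <- new.env(parent = baseenv())
  assign("%and%", function(a, b) min(a, b), envir = env)
  assign("%or%", function(a, b) max(a, b), envir = env)
  for (g in names(ratios)) assign(g, ratios[[g]], envir = env)
  eval(str2lang(txt), envir = env)
}

# Random fully-parenthesised GPR tree over a gene pool.
random_gpr <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    return(sample(genes, 1))
  }
  op <- sample(c("and", "or"), 1)
  n_args <- sample(2:3, 1)
  args <- vapply(seq_len(n_args), function(i) random_gpr(genes, depth - 1),
                 character(1))
  paste0("(", paste(args, collapse = paste0(" ", op, " ")), ")")
}
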