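test_that("a linear chain solves to its closed-form min-capacity optimum", {
  # uptake <= 10, biomass consumes 2 A per unit: growth = 5
  m <- chain_model()
  r <- solve_fba(m)
  expect_equal(r$status, "OPTIMAL")
  expect_equal(r$objective, 5)
  expect_equal(unname(r$fluxes["UPT"]), 10)
})

test_that("two substrate routes with capacities 10 and 4 give objective 14", {
  m <- generate_toy_model(n_branches = 2, capacities = c(10, 4), yields = 1)
  r <- solve_fba(m)
  expect_equal(r$objective, 14)
  expect_equal(attr(m, "closed_form_growth"), 14)
})

test_that("optimal flux vectors are mass balanced and within bounds", {
  for (m in list(chain_model(), futile_cycle_model(),
                 load_model(toy_model_path()))) {
    r <- solve_fba(m)
    expect_equal(r$status, "OPTIMAL")
    S <- stoichiometric_matrix(m)
    v <- r$fluxes
    expect_lte(max(abs(S %*% v)), 1e-9 * max(1, max(abs(v))))
    b <- orthoflux:::reaction_bounds(m)
    expect_true(all(v >= b$lb - 1e-9 & v <= b$ub + 1e-9))
  }
})

test_that("infeasible and unbounded systems are reported as such", {
  # forced uptake above capacity of the consumer
  m <- metabolic_model(
    id = "infeas",
    metabolites = data.frame(id = "A_c", compartment = "c"),
    reactions = list(
      list(id = "IN", stoichiometry = c(A_c = 1),
           lower_bound = 5, upper_bound = 5, gpr = ""),
      list(id = "OUT", stoichiometry = c(A_c = -1),
           lower_bound = 0, upper_bound = 1, gpr = "")),
    biomass = "OUT")
  expect_equal(solve_fba(m)$status, "INFEASIBLE")

  unb <- metabolic_model(
    id = "unb",
    metabolites = data.frame(id = "A_c", compartment = "c"),
    reactions = list(
      list(id = "IN", stoichiometry = c(A_c = 1),
           lower_bound = 0, upper_bound = Inf, gpr = ""),
      list(id = "OUT", stoichiometry = c(A_c = -1),
           lower_bound = 0, upper_bound = Inf, gpr = "")),
    biomass = "OUT")
  expect_equal(solve_fba(unb)$status, "UNBOUNDED")
})

test_that("FBA matches exhaustive vertex enumeration on random small models", {
  for (seed in 1:30) {
    rm <- random_flux_model(n_reactions = sample(4:8, 1), seed = seed)
    got <- orthoflux:::solve_lp(rm$obj, rm$S, rep(0, nrow(rm$S)),
                                rm$lb, rm$ub, maximize = TRUE)
    want <- oracle_lp_max(rm$obj, rm$S, rm$lb, rm$ub)
    if (is.na(want)) {
      expect_equal(got$status, "INFEASIBLE", info = paste("seed", seed))
    } else {
      expect_equal(got$objective, want, tolerance = 1e-7,
                   info = paste("seed", seed))
    }
  }
})

test_that("taxicab minimization preserves the objective and zeroes futile cycles", {
  m <- futile_cycle_model()
  r <- solve_fba(m)
  v <- minimize_taxicab(m, r$objective)
  obj <- orthoflux:::objective_vector(m)
  expect_lte(abs(sum(obj * v) - r$objective), 1e-9)
  # the two loop reactions must carry zero flux at the L1 optimum
  expect_equal(unname(v["L1"]), 0)
  expect_equal(unname(v["L2"]), 0)
  # the loop admits feasible solutions with arbitrary circulation
  S <- stoichiometric_matrix(m)
  spun <- v; spun["L1"] <- spun["L2"] <- 123
  expect_lte(max(abs(S %*% spun)), 1e-9)
})

test_that("the taxicab norm never exceeds the plain FBA norm", {
  for (seed in 1:25) {
    rm <- random_flux_model(n_reactions = 7, seed = 100 + seed)
    mets <- data.frame(id = paste0("m", seq_len(nrow(rm$S))), compartment = "c")
    rxns <- lapply(seq_len(ncol(rm$S)), function(j) {
      st <- rm$S[, j]; st <- stats::setNames(st[st != 0], mets$id[st != 0])
      list(id = paste0("r", j), stoichiometry = st,
           lower_bound = rm$lb[j], upper_bound = rm$ub[j], gpr = "")
    })
    obj_rxn <- paste0("r", which(rm$obj != 0))
    m <- metabolic_model("rand", mets, rxns, biomass = obj_rxn[1],
                         objective = stats::setNames(rm$obj[rm$obj != 0], obj_rxn))
    r <- solve_fba(m)
    if (r$status != "OPTIMAL") next
    v1 <- minimize_taxicab(m, r$objective)
    expect_lte(sum(abs(v1)), sum(abs(r$fluxes)) + 1e-7,
               label = paste("seed", seed))
  }
})
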