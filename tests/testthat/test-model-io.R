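test_that("the packaged toy model loads with a declared biomass", {
  m <- load_model(toy_model_path())
  expect_s3_class(m, "metabolic_model")
  expect_equal(length(m$reactions), 14L)
  expect_equal(m$biomass, "GROWTH")
  expect_true(all(names(m$reactions[["GROWTH"]]$stoichiometry) %in%
                  m$metabolites$id))
})

test_that("undeclared metabolites and genes are validation errors", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    id = "bad",
    metabolites = list(list(id = "A_c", compartment = "c")),
    reactions = list(list(id = "r1", metabolites = list(ghost_c = -1),
                          lower_bound = 0, upper_bound = 10,
                          objective_coefficient = 1)),
    genes = list()), f, auto_unbox = TRUE)
  expect_error(load_model(f), "undeclared metabolite")

  m <- load_model(toy_model_path())
  expect_error(
    metabolic_model("x", m$metabolites,
                    list(list(id = "r", stoichiometry = c(glc_c = -1),
                              lower_bound = 0, upper_bound = 1,
                              gpr = "mystery_gene")),
                    genes = "other_gene", biomass = "r"),
    "not declared")
})

test_that("a model without a designated objective needs an explicit one", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    id = "noobj",
    metabolites = list(list(id = "A_c", compartment = "c")),
    reactions = list(list(id = "r1", metabolites = list(A_c = 1),
                          lower_bound = 0, upper_bound = 10)),
    genes = list()), f, auto_unbox = TRUE)
  expect_error(load_model(f), "no objective")
  m <- load_model(f, objective = "r1")
  expect_equal(m$biomass, "r1")
})

test_that("JSON round trip preserves ids, stoichiometry, bounds and GPRs", {
  m <- load_model(toy_model_path())
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(names(m2$reactions), names(m$reactions))
  expect_equal(m2$metabolites$id, m$metabolites$id)
  for (rid in names(m$reactions)) {
    r1 <- m$reactions[[rid]]; r2 <- m2$reactions[[rid]]
    expect_equal(sort(names(r1$stoichiometry)), sort(names(r2$stoichiometry)))
    expect_equal(r2$stoichiometry[names(r1$stoichiometry)], r1$stoichiometry)
    expect_identical(c(r2$lower_bound, r2$upper_bound),
                     c(r1$lower_bound, r1$upper_bound))
    expect_identical(r2$gpr, r1$gpr)
  }
})

test_that("SBML-FBC round trip preserves the model field by field", {
  m <- load_model(toy_model_path())
  f <- withr::local_tempfile(fileext = ".xml")
  save_model(m, f, dialect = "sbml_fbc")
  m2 <- load_model(f, dialect = "sbml_fbc")
  expect_equal(names(m2$reactions), names(m$reactions))
  expect_equal(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$genes, m$genes)
  expect_equal(m2$biomass, m$biomass)
  for (rid in names(m$reactions)) {
    r1 <- m$reactions[[rid]]; r2 <- m2$reactions[[rid]]
    expect_equal(r2$stoichiometry[names(r1$stoichiometry)], r1$stoichiometry)
    expect_identical(c(r2$lower_bound, r2$upper_bound),
                     c(r1$lower_bound, r1$upper_bound))
    expect_identical(parse_gpr(r2$gpr), parse_gpr(r1$gpr))
  }
  # and the SBML solves to the same optimum
  expect_equal(solve_fba(m2)$objective, solve_fba(m)$objective,
               tolerance = 1e-12)
})

test_that("an external COBRA toolkit reads our SBML and agrees on the optimum", {
  py <- Sys.which("python")
  if (!nzchar(py)) fail("python interpreter unavailable for the cross-check")
  f <- tempfile(fileext = ".xml")
  m <- load_model(toy_model_path())
  save_model(m, f, dialect = "sbml_fbc")
  out <- suppressWarnings(system2(py, c("-c", shQuote(paste0(
    "import cobra; m = cobra.io.read_sbml_model('", f,
    "'); print(round(m.slim_optimize(), 9))"))),
    stdout = TRUE, stderr = FALSE))
  expect_equal(as.numeric(out[length(out)]), 5.4, tolerance = 1e-9)
})
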