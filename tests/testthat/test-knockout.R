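test_that("knockouts zero the right reactions and leave the input untouched", {
  m <- load_model(toy_model_path())
  km <- apply_knockout(m, "rki1")
  expect_equal(attr(km, "disabled_reactions"), "RKI")
  expect_equal(km$reactions$RKI$upper_bound, 0)
  expect_equal(m$reactions$RKI$upper_bound, 1000)   # copy-on-write

  # deleting one isozyme of an OR pair disables nothing
  km2 <- apply_knockout(m, "hxk1")
  expect_equal(attr(km2, "disabled_reactions"), character())

  # reaction-level target zeroes directly
  km3 <- apply_knockout(m, "GLY")
  expect_equal(attr(km3, "disabled_reactions"), "GLY")

  expect_error(apply_knockout(m, "nonexistent"), "unknown target")
})

test_that("a gene absent from every GPR leaves the optimum exactly unchanged", {
  m <- load_model(toy_model_path())
  m$genes <- c(m$genes, "bystander")
  km <- apply_knockout(m, "bystander")
  expect_identical(solve_fba(km)$objective, solve_fba(m)$objective)
})

test_that("no single-gene knockout can exceed the wild-type optimum", {
  for (m in list(load_model(toy_model_path()),
                 generate_toy_model(3, c(5, 3, 2), c(1, 0.5, 2),
                                    include_cofactor_branch = TRUE))) {
    wt <- solve_fba(m)$objective
    for (g in m$genes) {
      r <- solve_fba(apply_knockout(m, g))
      growth <- if (r$status == "OPTIMAL") r$objective else 0
      expect_lte(growth, wt + 1e-9, label = paste("gene", g))
    }
  }
})

test_that("coefficient-mode augmentation with a producible metabolite barely moves growth", {
  m <- load_model(toy_model_path())
  wt <- solve_fba(m)$objective
  aug <- augment_biomass(m, c(hem_c = 5e-4))
  wt_aug <- solve_fba(aug)$objective
  expect_lt(abs(wt_aug - wt) / wt, 0.01)
  expect_lte(wt_aug, wt + 1e-12)  # augmentation can only cost
  expect_match(aug$provenance, "augment", all = FALSE)
})

test_that("augmentation with an unproducible metabolite abolishes growth", {
  m <- generate_toy_model(2, c(10, 4), 1)  # no cofactor branch
  m2 <- metabolic_model(
    "plus_orphan",
    rbind(m$metabolites,
          data.frame(id = "orphan_c", name = "orphan", compartment = "c")),
    c(unname(m$reactions)), biomass = m$biomass)
  aug <- augment_biomass(m2, c(orphan_c = 5e-4))
  r <- solve_fba(aug)
  growth <- if (r$status == "OPTIMAL") r$objective else 0
  expect_lt(growth, 1e-6)
})

test_that("demand-mode augmentation adds a sink with the requirement as floor", {
  m <- load_model(toy_model_path())
  aug <- augment_biomass(m, c(hem_c = 5e-4), mode = "demand")
  expect_true("DM_hem_c" %in% names(aug$reactions))
  expect_equal(aug$reactions$DM_hem_c$lower_bound, 5e-4)
  v <- solve_fba(aug, minimize_l1 = TRUE)$fluxes
  expect_gte(v["DM_hem_c"] + 1e-12, 5e-4)
  expect_error(augment_biomass(m, c(hem_c = -1)), "positive")
})

test_that("the knockout panel reproduces the designed truth table", {
  m <- load_model(toy_model_path())
  panel <- simulate_knockout_panel(
    m, c("rki1", "hem2", "hxk1"),
    augmentations = list(augmented = list(requirements = c(hem_c = 5e-4),
                                          mode = "coefficient")))
  get <- function(tg, var) panel[panel$target == tg &
                                 panel$biomass_variant == var, ]
  # isomerase on the sole pentose branch: lethal under both objectives
  expect_equal(get("rki1", "original")$classification, "NO_GROWTH")
  expect_equal(get("rki1", "augmented")$classification, "NO_GROWTH")
  # cofactor-complex subunit: silent originally, lethal once required
  expect_equal(get("hem2", "original")$classification, "GROWTH")
  expect_equal(get("hem2", "augmented")$classification, "NO_GROWTH")
  # isozyme: silent everywhere
  expect_equal(get("hxk1", "original")$wt_ratio, 1)
  # WT reference rows present once per variant
  expect_equal(sum(panel$target == "WT"), 2L)
  expect_equal(get("WT", "original")$growth_rate, 5.4)
})

test_that("a reaction-level panel mirrors the gene-level isomerase result", {
  m <- load_model(toy_model_path())
  panel <- simulate_knockout_panel(m, "RKI", level = "reaction")
  expect_equal(panel$classification[panel$target == "RKI"], "NO_GROWTH")
})

test_that("an empty target list yields wild-type rows only", {
  m <- load_model(toy_model_path())
  panel <- simulate_knockout_panel(m, character())
  expect_equal(panel$target, "WT")
})
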