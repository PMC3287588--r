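test_that("trophic presets impose the minimal constraint sets", {
  core <- core_fixture()
  mx <- apply_condition(core, "mixotrophic")
  expect_equal(mx$model$reactions[["biomass"]]$lb, 0.066)
  expect_equal(mx$model$reactions[["biomass"]]$ub, 0.066)
  het <- apply_condition(core, "heterotrophic")
  expect_equal(het$model$reactions[["EX_photon"]]$ub, 0)
  expect_equal(het$model$reactions[["EX_photon"]]$lb, 0)
  ## CO2 secretion stays open in the dark (respiration must vent CO2)
  expect_gt(het$model$reactions[["EX_co2"]]$ub, 0)
  expect_equal(het$model$reactions[["EX_co2"]]$lb, 0)
  aut <- apply_condition(core, "autotrophic")
  expect_equal(aut$model$reactions[["EX_ac"]]$lb, 0)    # acetate "-"
  expect_equal(aut$model$reactions[["biomass"]]$lb, 0.059)
  expect_equal(trophic_scenario("heterotrophic")$fixed_growth_rate, 0.035)
  ## maximizing growth (unfixed) under autotrophic bounds is feasible
  mod <- aut$model
  mod$reactions[["biomass"]]$lb <- 0
  mod$reactions[["biomass"]]$ub <- 1000
  expect_gt(solve_fba(mod, "biomass", "max",
                      parsimonious = FALSE)$objective_value, 0)
  ## a missing exchange is a configuration error naming the reaction
  broken <- core
  broken$reactions[["EX_ac"]] <- NULL
  expect_error(apply_condition(broken, "mixotrophic"), "EX_ac")
})

test_that("flux change classification follows the threshold rule", {
  mk <- function(v) structure(
    list(fluxes = v, objective_value = 0, objective_reaction = "x",
         status = "optimal"), class = "flux_distribution")
  ref <- mk(c(a = 1.0, b = 1.0, c = 0.0, d = 2.0))
  tst <- mk(c(a = 1.25, b = 1.0, c = 0.5, d = 1.0))
  cmp <- compare_fluxes(ref, tst, threshold = 0.20)
  cls <- stats::setNames(cmp$class, cmp$reaction)
  expect_identical(cls[["a"]], "increased")
  expect_identical(cls[["b"]], "unchanged")
  expect_identical(cls[["c"]], "increased")   # zero reference, floor rule
  expect_identical(cls[["d"]], "decreased")
  ## property: classes are exclusive and exhaustive over random vectors
  set.seed(11)
  for (k in 1:20) {
    rv <- mk(stats::setNames(runif(10, 0, 2), letters[1:10]))
    tv <- mk(stats::setNames(runif(10, 0, 2), letters[1:10]))
    cc <- compare_fluxes(rv, tv)
    expect_true(all(cc$class %in% c("increased", "decreased", "unchanged")))
    up <- abs(cc$test) > 1.2 * pmax(abs(cc$reference), 1e-6)
    expect_identical(cc$class == "increased", up)
  }
  ## mismatched reaction sets are a usage error listing the difference
  expect_error(compare_fluxes(ref, mk(c(a = 1, zz = 2, b = 1, c = 1))), "zz")
})

test_that("cyclic electron flow disruption boosts mixotrophic H2", {
  core <- core_fixture()
  st <- h2_study(core, "mixotrophic", knockouts = "cef")
  expect_gt(st$knockout_h2, st$baseline_h2)
  expect_gt(st$fold_change, 1)
  dirs <- stats::setNames(st$directions$direction, st$directions$pathway)
  expect_identical(dirs[["light reactions"]], "+")  # linear flow increases
  expect_identical(dirs[["hydrogen production"]], "+")
  ## citrate-cycle throughput never rises in the H2 producer; on this core
  ## network the wild type covers its mixotrophic ATP demand through the
  ## acetate loop, so the flux is flat rather than reduced
  expect_lte(abs(st$knockout$fluxes[["tca"]]),
             abs(st$wild_type$fluxes[["tca"]]) + 1e-6)
  expect_true(dirs[["TCA cycle"]] %in% c("-", "0"))
  ## determinism: bit-identical reports on identical inputs
  st2 <- h2_study(core, "mixotrophic", knockouts = "cef")
  expect_identical(st$knockout$fluxes, st2$knockout$fluxes)
  expect_identical(st$fold_change, st2$fold_change)
})

test_that("dark H2 production routes through PFR and the hydrogenase", {
  core <- core_fixture()
  st <- h2_study(core, "heterotrophic")
  expect_gt(st$baseline_h2, 0)
  fl <- st$baseline$fluxes
  expect_gt(fl[["pfr"]], 1e-6)
  expect_gt(fl[["hyda"]], 1e-6)
  expect_gt(fl[["glyox_cycle"]], 1e-6)
  expect_gt(fl[["gluconeo_c"]], 1e-6)
})

test_that("a hydrogenase-dead model yields zero H2 and fold change one", {
  core <- core_fixture()
  dead <- knockout(core, "hyda")
  st <- h2_study(dead, "mixotrophic", knockouts = "cef")
  expect_equal(st$baseline_h2, 0, tolerance = 1e-9)
  expect_equal(st$knockout_h2, 0, tolerance = 1e-9)
  expect_identical(st$fold_change, 1)
})

test_that("scenario files round-trip through YAML and JSON", {
  sc <- trophic_scenario("mixotrophic")
  fy <- tempfile(fileext = ".yml"); fj <- tempfile(fileext = ".json")
  write_scenario(sc, fy); write_scenario(sc, fj)
  for (f in c(fy, fj)) {
    back <- read_scenario(f)
    expect_identical(back$condition, sc$condition)
    expect_equal(back$fixed_growth_rate, sc$fixed_growth_rate)
    expect_equal(back$bound_overrides[order(names(back$bound_overrides))],
                 lapply(sc$bound_overrides[order(names(sc$bound_overrides))],
                        as.numeric))
    expect_identical(back$substrate, sc$substrate)
  }
  unlink(c(fy, fj))
})
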