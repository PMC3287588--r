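test_that("a bound-limited linear chain attains its uptake cap", {
  m <- chain_model(uptake_cap = 10)
  fd <- solve_fba(m, "dm_b", "max")
  expect_equal(fd$objective_value, 10, tolerance = 1e-9)
  expect_steady_state(fd, m)
  expect_error(solve_fba(m, "nope", "max"), "objective")
})

test_that("solver matches exhaustive vertex enumeration on small networks", {
  ## branched network with one yield-superior branch
  mets <- rbind(metabolite("s_e", is_boundary = TRUE), metabolite("s_c"),
                metabolite("p_c"))
  rxns <- list(
    reaction("EX_s", c(s_e = -1), reversible = TRUE, lb = -5, ub = 0,
             kind = "exchange"),
    reaction("up", c(s_e = -1, s_c = 1), kind = "transport"),
    reaction("low_yield", c(s_c = -1, p_c = 1)),
    reaction("high_yield", c(s_c = -1, p_c = 2)),
    reaction("dm_p", c(p_c = -1), kind = "biomass_drain")
  )
  m <- phyco_model(mets, rxns, biomass_components = "dm_p")
  fd <- expect_matches_vertex_oracle(m, "dm_p", "max")
  expect_equal(fd$objective_value, 10, tolerance = 1e-8)
  ## randomized small networks, both senses
  for (seed in 1:12) {
    rm <- random_small_model(seed)
    expect_matches_vertex_oracle(rm, "dm", "max")
    expect_matches_vertex_oracle(rm, "EX_s", "max")  # minimal uptake
  }
})

test_that("a closed system carries no flux and reports infeasibility cleanly", {
  m <- chain_model()
  m$reactions[["EX_a"]]$lb <- 0
  fd <- solve_fba(m, "dm_b", "max")
  expect_equal(fd$objective_value, 0, tolerance = 1e-9)
  ## demanding positive drain in the closed system is infeasible, not an error
  fd2 <- solve_fba(m, "dm_b", "max",
                   extra_bounds = list(dm_b = c(1, 1)))
  expect_equal(fd2$status, "infeasible")
  expect_true(is.na(fd2$objective_value))
})

test_that("minimized substrate scales linearly with the fixed growth rate", {
  core <- core_fixture()
  sc1 <- trophic_scenario("heterotrophic")
  fd1 <- minimize_substrate(core, sc1, parsimonious = FALSE)
  sc2 <- sc1
  sc2$fixed_growth_rate <- 2 * sc1$fixed_growth_rate
  ## scale the maintenance floor too so the problem is exactly linear
  sc1$bound_overrides$atpm <- c(0, 1000)
  sc2$bound_overrides$atpm <- c(0, 1000)
  f1 <- minimize_substrate(core, sc1, parsimonious = FALSE)
  f2 <- minimize_substrate(core, sc2, parsimonious = FALSE)
  expect_equal(f2$substrate_uptake, 2 * f1$substrate_uptake,
               tolerance = 1e-6)
  expect_equal(fd1$status, "optimal")
  ## zero growth, zero maintenance: no substrate demand
  sc0 <- sc1
  sc0$fixed_growth_rate <- 0
  f0 <- minimize_substrate(core, sc0, parsimonious = FALSE)
  expect_equal(f0$substrate_uptake, 0, tolerance = 1e-9)
})

test_that("product maximization is monotone in the substrate allowance", {
  core <- core_fixture()
  sc <- trophic_scenario("heterotrophic")
  vals <- vapply(c(4, 6, 10), function(cap) {
    sc$bound_overrides$EX_ac <- c(-cap, 1000)
    maximize_product(core, sc, "EX_h2", parsimonious = FALSE)$objective_value
  }, 0)
  expect_true(all(diff(vals) >= -1e-9))
  expect_gt(vals[3], vals[1])
  ## product bounded to zero gives optimum zero
  sc$bound_overrides$EX_h2 <- c(0, 0)
  expect_equal(maximize_product(core, sc, "EX_h2",
                                parsimonious = FALSE)$objective_value,
               0, tolerance = 1e-12)
})

test_that("fixing substrate uptake pins the exchange at its minimum", {
  core <- core_fixture()
  sc <- trophic_scenario("heterotrophic")
  ref <- minimize_substrate(core, sc, parsimonious = FALSE)
  fd <- maximize_product(core, sc, "EX_h2", fix_substrate = "optimum",
                         parsimonious = FALSE)
  expect_equal(fd$status, "optimal")
  expect_equal(fd$fluxes[["EX_ac"]], ref$fluxes[["EX_ac"]], tolerance = 1e-6)
  ## at the exact substrate minimum the core fixture has no spare
  ## electrons, so the H2 optimum collapses to zero; any slack above the
  ## minimum immediately buys hydrogen
  expect_gte(fd$objective_value, 0)
  sc$bound_overrides$EX_ac <- c(ref$fluxes[["EX_ac"]] - 0.5,
                                ref$fluxes[["EX_ac"]])
  slack <- maximize_product(core, sc, "EX_h2", parsimonious = FALSE)
  expect_gt(slack$objective_value, 1e-3)
})

test_that("knockouts zero bounds, record originals, and reverse", {
  m <- chain_model()
  expect_error(knockout(m, "ghost"), "unknown")
  k <- knockout(m, "conv")
  expect_equal(k$reactions[["conv"]]$ub, 0)
  expect_equal(solve_fba(k, "dm_b", "max")$objective_value, 0,
               tolerance = 1e-12)
  ## knocking out an already-disabled reaction is semantically idempotent
  k2 <- knockout(k, "conv")
  expect_equal(solve_fba(k2, "dm_b", "max")$objective_value, 0,
               tolerance = 1e-12)
  r <- restore_knockouts(k2)
  expect_equal(solve_fba(r, "dm_b", "max")$objective_value, 10,
               tolerance = 1e-9)
  ## sole-producer knockout at fixed positive growth is infeasible
  core <- core_fixture()
  ap <- apply_condition(core, "autotrophic")
  ko <- knockout(ap$model, "ss")   # sole starch producer
  fd <- solve_fba(ko, "EX_h2", "max", parsimonious = FALSE)
  expect_equal(fd$status, "infeasible")
})

test_that("knocking out a zero-flux reaction leaves the optimum unchanged", {
  core <- core_fixture()
  ap <- apply_condition(core, "heterotrophic")
  fd <- maximize_product(ap$model, ap$scenario, "EX_h2")
  zero <- names(which(abs(fd$fluxes) < 1e-9))
  zero <- setdiff(zero, c("biomass", ap$scenario$substrate))
  pick <- intersect(c("ldh", "pdc", "rbc_o"), zero)
  expect_gt(length(pick), 0)
  ko <- knockout(ap$model, pick)
  fd2 <- maximize_product(ko, ap$scenario, "EX_h2")
  expect_equal(fd2$objective_value, fd$objective_value, tolerance = 1e-6)
})

test_that("every optimal distribution satisfies the steady-state bound", {
  core <- core_fixture()
  for (cond in c("autotrophic", "heterotrophic", "mixotrophic")) {
    ap <- apply_condition(core, cond)
    fd <- minimize_substrate(ap$model, ap$scenario)
    expect_steady_state(fd, ap$model)
    fx <- maximize_product(ap$model, ap$scenario, "EX_h2")
    expect_steady_state(fx, ap$model)
    ## fluxes respect their bounds
    for (id in names(fx$fluxes)) {
      r <- ap$model$reactions[[id]]
      lo <- if (id %in% names(ap$scenario$bound_overrides))
        ap$scenario$bound_overrides[[id]][1] else r$lb
      hi <- if (id %in% names(ap$scenario$bound_overrides))
        ap$scenario$bound_overrides[[id]][2] else r$ub
      expect_gte(fx$fluxes[[id]], lo - 1e-6)
      expect_lte(fx$fluxes[[id]], hi + 1e-6)
    }
  }
})
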