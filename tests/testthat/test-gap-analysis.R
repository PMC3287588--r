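test_that("the intact fixture has no blocked components in any condition", {
  core <- core_fixture()
  for (cond in c("autotrophic", "heterotrophic", "mixotrophic")) {
    scr <- producibility_screen(core, cond)
    expect_false(any(scr$blocked), label = cond)
    expect_true(all(scr$max_rate > 1e-6))
  }
})

test_that("removing the sole starch producer blocks starch and nothing else", {
  core <- core_fixture()
  m <- core
  m$reactions[["ss"]] <- NULL
  scr <- producibility_screen(m, "autotrophic")
  expect_true(scr$blocked[scr$component == "dm_starch"])
  expect_false(any(scr$blocked[scr$component != "dm_starch"]))
})

test_that("closing the carbon source blocks every component", {
  core <- core_fixture()
  sc <- trophic_scenario("heterotrophic")
  sc$bound_overrides$EX_ac <- c(0, 1000)  # acetate "-": no carbon at all
  scr <- producibility_screen(core, sc)
  expect_true(all(scr$blocked))
})

test_that("dead-end detection respects directionality", {
  mets <- rbind(metabolite("a_c"), metabolite("b_c"))
  m <- phyco_model(mets, list(reaction("src", c(a_c = 1)),
                              reaction("conv", c(a_c = -1, b_c = 1))))
  de <- find_dead_ends(m)
  expect_identical(de$never_consumed, "b_c")
  expect_length(de$never_produced, 0)
  ## reversible isolated pair: both species in both lists? no source/sink,
  ## but either can produce the other, so neither list is empty only when
  ## bounds forbid it
  m2 <- phyco_model(mets, list(reaction("iso", c(a_c = -1, b_c = 1),
                                        reversible = TRUE)))
  de2 <- find_dead_ends(m2)
  expect_length(de2$never_produced, 0)
  expect_length(de2$never_consumed, 0)
  ## the same pair made irreversible: a never produced, b never consumed
  m3 <- phyco_model(mets, list(reaction("one", c(a_c = -1, b_c = 1))))
  de3 <- find_dead_ends(m3)
  expect_identical(de3$never_produced, "a_c")
  expect_identical(de3$never_consumed, "b_c")
  ## intact fixture: no dead ends
  de4 <- find_dead_ends(core_fixture())
  expect_length(de4$never_produced, 0)
  expect_length(de4$never_consumed, 0)
})

test_that("tracing a deleted enzyme reaches its boundary with no_producer", {
  core <- core_fixture()
  m <- core
  m$reactions[["pgm_p"]] <- NULL   # phosphoglucomutase
  tr <- trace_breakpoints(m, "dm_starch", "autotrophic")
  expect_identical(tr$metabolite[1], "starch_p")
  g1p <- tr[tr$metabolite == "g1p_p", ]
  expect_identical(g1p$cause, "no_producer")
  ## every traced metabolite is itself non-producible under the scenario
  S <- stoichiometric_matrix(m)
  bb <- phycoflux:::gap_bounds(m, trophic_scenario("autotrophic"),
                               colnames(S))
  for (met in tr$metabolite)
    expect_lte(phycoflux:::single_drain_max(S, bb$lb, bb$ub, met), 1e-6)
})

test_that("a deleted inter-organelle transporter is classified as such", {
  core <- core_fixture()
  m <- core
  m$reactions[["t_succ_xm"]] <- NULL
  scr <- producibility_screen(m, "heterotrophic")
  expect_true(any(scr$blocked))
  tr <- trace_breakpoints(m, scr$component[scr$blocked][1], "heterotrophic")
  succ <- tr[tr$metabolite == "succ_m", ]
  expect_identical(succ$cause, "missing_transporter")
})

test_that("a flipped reversibility is classified as a conflict", {
  core <- core_fixture()
  m <- core
  m$reactions[["mdh_m"]]$lb <- -1000
  m$reactions[["mdh_m"]]$ub <- 0    # malate dehydrogenase forced backward
  scr <- producibility_screen(m, "heterotrophic")
  expect_true(any(scr$blocked))
  tr <- trace_breakpoints(m, scr$component[scr$blocked][1], "heterotrophic")
  oaa <- tr[tr$metabolite == "oaa_m", ]
  expect_identical(oaa$cause, "irreversibility_conflict")
})

test_that("tracing a producible component is a usage error", {
  expect_error(trace_breakpoints(core_fixture(), "dm_starch", "autotrophic"),
               "producible")
})

test_that("seeded gaps are recovered and re-insertion always unblocks", {
  core <- core_fixture()
  detectable <- 0L; recovered <- 0L
  for (s in 1:50) {
    g <- seed_gaps(core, n = 1, seed = s)
    blocked <- character(0)
    for (cond in c("autotrophic", "heterotrophic")) {
      scr <- producibility_screen(g$model, cond)
      if (any(scr$blocked)) {
        blocked <- scr$component[scr$blocked]
        bcond <- cond
        break
      }
    }
    if (!length(blocked)) next
    detectable <- detectable + 1L
    del_mets <- names(core$reactions[[g$deleted]]$stoich)
    hit <- FALSE
    for (b in blocked) {
      tr <- trace_breakpoints(g$model, b, bcond)
      if (any(tr$metabolite %in% del_mets)) { hit <- TRUE; break }
    }
    if (hit) recovered <- recovered + 1L
    ## re-inserting the deleted reaction always unblocks
    fixed <- g$model
    fixed$reactions[[g$deleted]] <- core$reactions[[g$deleted]]
    used <- unique(unlist(lapply(fixed$reactions,
                                 function(r) names(r$stoich))))
    fixed$metabolites <- core$metabolites[core$metabolites$id %in% used, ]
    scr2 <- producibility_screen(fixed, bcond)
    expect_false(any(scr2$blocked), label = paste("seed", s, g$deleted))
  }
  expect_gte(detectable, 10L)
  expect_gte(recovered / detectable, 0.95)
})
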