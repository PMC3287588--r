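raw_table_model <- function() {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(
    "reaction_id\tname\tequation\tgene_association\tkind\tevidence\tsubsystem",
    "hk\thexokinase\tglc + atp --> g6p + adp\tHXK1\tenzymatic\tnot_applicable\tglycolysis",
    "hk_dup\thexokinase (duplicate label)\talpha-glc + atp --> g6p + adp\tHXK2\tenzymatic\tnot_applicable\tglycolysis",
    "pgi\tphosphoglucose isomerase\tg6p <=> f6p\tPGI1\tenzymatic\tnot_applicable\tglycolysis",
    "starchsyn\tstarch elongation\tstarch(n) + adpglc --> starch(n+1)\tSTA2\tenzymatic\tnot_applicable\tstarch"
  ), tf)
  on.exit(unlink(tf))
  read_reaction_table(tf, compartmentalized = FALSE)
}

test_that("duplicate compounds merge and gene associations OR-combine", {
  m0 <- raw_table_model()
  out <- merge_duplicate_compounds(m0, c("alpha-glc" = "glc"))
  m <- out$model
  expect_false("hk_dup" %in% names(m$reactions))
  expect_identical(m$reactions[["hk"]]$gpr, "HXK1 or HXK2")
  expect_true(any(out$report$type == "reaction" & out$report$from == "hk_dup"))
  ## empty synonym table: identity
  same <- merge_duplicate_compounds(m0, character(0))
  expect_identical(names(same$model$reactions), names(m0$reactions))
  ## chained synonyms are rejected
  expect_error(merge_duplicate_compounds(m0, c(a = "b", b = "c")),
               "idempotent")
})

test_that("merging opposite-side references sums and cancels coefficients", {
  mets <- rbind(metabolite("x_c"), metabolite("x2_c"), metabolite("y_c"))
  ## consumes x, produces x2; after x2 -> x the species cancels entirely
  r <- reaction("cycle", c(x_c = -1, x2_c = 1, y_c = 1))
  m <- phyco_model(mets, list(r))
  out <- merge_duplicate_compounds(m, c(x2_c = "x_c"))
  st <- out$model$reactions[["cycle"]]$stoich
  ## oracle: per-species coefficient summation
  expect_false("x_c" %in% names(st))
  expect_equal(st[["y_c"]], 1)
  ## partial cancellation keeps the net coefficient
  r2 <- reaction("partial", c(x_c = -2, x2_c = 1, y_c = 1))
  out2 <- merge_duplicate_compounds(phyco_model(mets, list(r2)),
                                    c(x2_c = "x_c"))
  expect_equal(out2$model$reactions[["partial"]]$stoich[["x_c"]], -1)
})

test_that("polymer elongation entries rewrite to monomer accumulation", {
  m0 <- raw_table_model()
  m <- expand_polymer_reactions(m0, c(starch = "glcunit"))
  eq <- format_equation(m$reactions[["starchsyn"]])
  expect_identical(eq, "adpglc --> glcunit")
  ## no polymer reactions: unchanged
  m1 <- expand_polymer_reactions(m, c(starch = "glcunit"))
  expect_identical(lapply(m$reactions, `[[`, "stoich"),
                   lapply(m1$reactions, `[[`, "stoich"))
  ## missing mapping is a curation error listing the polymer
  expect_error(expand_polymer_reactions(m0, character(0)), "starch")
  ## generic R-group species are rejected
  mr <- phyco_model(
    rbind(metabolite("acyl_c", formula = "C2H3OR"), metabolite("x_c")),
    list(reaction("racyl", c(acyl_c = -1, x_c = 1))))
  expect_error(expand_polymer_reactions(mr, character(0)), "R-group")
})

test_that("compartment assignment follows literature > homolog > cytosol", {
  m0 <- raw_table_model()
  ev <- data.frame(
    reaction_id = c("hk", "hk", "pgi", "pgi"),
    compartment = c("mitochondrion", "microbody", "plastid", "cytosol"),
    source = c("literature", "homolog", "literature", "literature"),
    citation = "t", stringsAsFactors = FALSE)
  m <- assign_compartments(merge_duplicate_compounds(
    m0, c("alpha-glc" = "glc"))$model, ev)
  ## literature beats homolog
  expect_identical(m$reactions[["hk"]]$evidence, "literature")
  expect_true(all(endsWith(names(m$reactions[["hk"]]$stoich), "_m")))
  ## two literature claims duplicate the reaction, one copy per compartment
  copies <- grep("^pgi", names(m$reactions), value = TRUE)
  expect_setequal(copies, c("pgi_c", "pgi_p"))
  ## no evidence: cytosol by default
  expect_identical(m$reactions[["starchsyn"]]$evidence, "default_cytosol")
  expect_true(all(endsWith(names(m$reactions[["starchsyn"]]$stoich), "_c")))
})

test_that("transporter addition updates the split transporter counts", {
  core <- core_fixture()
  before <- model_statistics(core)
  tt <- data.frame(species_id = c("pyr", "mal"),
                   compartment_a = c("cytosol", "microbody"),
                   compartment_b = c("extracellular", "mitochondrion"),
                   reversible = c(TRUE, FALSE), cotransport = "",
                   stringsAsFactors = FALSE)
  ## pyr_c and mal_m exist; pyr_e and mal_x must first exist or be created
  expect_error(add_transporters(core, tt), "pyr_e")
  m <- add_transporters(core, tt, create = TRUE)
  after <- model_statistics(m)
  expect_equal(after$intercellular_transporters,
               before$intercellular_transporters + 1L)
  expect_equal(after$interorganelle_transporters,
               before$interorganelle_transporters + 1L)
  ## empty table: unchanged
  expect_identical(names(add_transporters(core, tt[0, ])$reactions),
                   names(core$reactions))
})

test_that("the curation pipeline is idempotent", {
  m0 <- raw_table_model()
  syn <- c("alpha-glc" = "glc")
  mono <- c(starch = "glcunit")
  ev <- data.frame(reaction_id = c("pgi", "pgi", "hk"),
                   compartment = c("plastid", "cytosol", "mitochondrion"),
                   source = c("literature", "literature", "homolog"),
                   citation = "t", stringsAsFactors = FALSE)
  once <- reconstruct_model(m0, syn, mono, ev)$model
  twice <- reconstruct_model(once, syn, mono, ev)$model
  expect_identical(lapply(once$reactions, unclass),
                   lapply(twice$reactions, unclass))
  expect_identical(once$metabolites$id, twice$metabolites$id)
})

test_that("curation does not change the balance status of untouched reactions", {
  core <- core_fixture()
  before <- elemental_balance_audit(core)
  out <- merge_duplicate_compounds(core, c(nonexistent_c = "also_absent_c"))
  after <- elemental_balance_audit(out$model)
  expect_identical(before$status, after$status)
})

test_that("after assignment reactions span at most two compartments", {
  core <- core_fixture()
  comp <- stats::setNames(core$metabolites$compartment, core$metabolites$id)
  for (r in core$reactions) {
    if (r$kind %in% c("exchange", "biomass_drain")) next
    k <- length(unique(unname(comp[names(r$stoich)])))
    expect_lte(k, 2)
    if (r$kind == "transport") expect_identical(k, 2L)
  }
})
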