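test_that("SBML round trip preserves every model field", {
  core <- core_fixture()
  f <- tempfile(fileext = ".xml")
  write_sbml(core, f)
  m2 <- read_sbml(f)
  expect_identical(length(xml2::xml_find_all(
    xml2::xml_ns_strip(xml2::read_xml(f)), ".//species")),
    nrow(core$metabolites))
  for (id in names(core$reactions)) {
    a <- core$reactions[[id]]; b <- m2$reactions[[id]]
    expect_false(is.null(b), label = id)
    for (fld in c("name", "reversible", "lb", "ub", "gpr", "kind",
                  "evidence", "subsystem"))
      expect_identical(a[[fld]], b[[fld]], label = paste(id, fld))
    expect_equal(a$stoich[sort(names(a$stoich))],
                 b$stoich[sort(names(b$stoich))], info = id)
  }
  ma <- core$metabolites[order(core$metabolites$id), ]
  mb <- m2$metabolites[order(m2$metabolites$id), ]
  rownames(ma) <- rownames(mb) <- NULL
  expect_identical(ma, mb)
  expect_identical(core$biomass_reaction, m2$biomass_reaction)
  expect_setequal(core$biomass_components, m2$biomass_components)
  unlink(f)
})

test_that("write-read-write is byte identical and statistics are invariant", {
  core <- core_fixture()
  f1 <- tempfile(fileext = ".xml"); f2 <- tempfile(fileext = ".xml")
  write_sbml(core, f1)
  write_sbml(read_sbml(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  expect_identical(unclass(model_statistics(core)),
                   unclass(model_statistics(read_sbml(f1))))
  unlink(c(f1, f2))
})

test_that("statistics counts are order invariant and split transporters", {
  core <- core_fixture()
  s <- model_statistics(core)
  shuffled <- core
  set.seed(1)
  shuffled$reactions <- shuffled$reactions[sample(length(shuffled$reactions))]
  expect_identical(unclass(model_statistics(shuffled)), unclass(s))
  expect_identical(s$compartments, 4L)
  expect_identical(s$biomass_drains, 4L)
  expect_identical(s$gap_reactions, 3L)
  ## shared genes count once per reaction for association entries
  mets <- rbind(metabolite("a_c"), metabolite("b_c"), metabolite("c_c"))
  m <- phyco_model(mets, list(
    reaction("r1", c(a_c = -1, b_c = 1), gpr = "G1 or G2"),
    reaction("r2", c(b_c = -1, c_c = 1), gpr = "G2 and G3")))
  s2 <- model_statistics(m)
  expect_identical(s2$unique_orfs, 3L)
  expect_identical(s2$gene_reaction_associations, 4L)
  ## compartment-collapsed mode merges plastidic/cytosolic copies
  s_id <- model_statistics(core, unique_reactions = "id")
  s_st <- model_statistics(core, unique_reactions = "stoichiometry")
  expect_lt(s_st$unique_reactions, s_id$unique_reactions)
})

test_that("foreign documents are read tolerantly", {
  ## COBRA-style level 2: bounds in the kineticLaw, GPR in notes
  l2 <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="m"><listOfCompartments>',
    '<compartment id="C_c" name="cytoplasm"/>',
    '<compartment id="C_e" name="extracellular space"/>',
    '</listOfCompartments><listOfSpecies>',
    '<species id="A_c" name="A" compartment="C_c"/>',
    '<species id="A_e" name="A" compartment="C_e" boundaryCondition="true"/>',
    "</listOfSpecies><listOfReactions>",
    '<reaction id="up" reversible="true">',
    "<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
    "<p>GENE ASSOCIATION: (g1 and g2) or g3</p></body></notes>",
    '<listOfReactants><speciesReference species="A_e"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A_c"/></listOfProducts>',
    "<kineticLaw><listOfParameters>",
    '<parameter id="LOWER_BOUND" value="-5"/>',
    '<parameter id="UPPER_BOUND" value="8"/>',
    "</listOfParameters></kineticLaw></reaction>",
    '<reaction id="rev_nobounds" reversible="true">',
    '<listOfReactants><speciesReference species="A_c"/></listOfReactants>',
    "</reaction></listOfReactions></model></sbml>")
  f <- tempfile(fileext = ".xml")
  writeLines(l2, f)
  m <- read_sbml(f)
  expect_identical(m$metabolites$compartment,
                   c("cytosol", "extracellular"))
  expect_equal(m$reactions[["up"]]$lb, -5)
  expect_equal(m$reactions[["up"]]$ub, 8)
  expect_identical(m$reactions[["up"]]$gpr, "(g1 and g2) or g3")
  expect_identical(m$reactions[["up"]]$kind, "transport")
  ## reversible flag with no bounds: the stated default box
  expect_equal(m$reactions[["rev_nobounds"]]$lb, -1000)
  expect_equal(m$reactions[["rev_nobounds"]]$ub, 1000)
  unlink(f)
})

test_that("malformed documents fail with a parse error, not a partial model", {
  f <- tempfile(fileext = ".xml")
  full <- write_sbml(core_fixture())
  writeLines(substr(full, 1, nchar(full) %/% 2), f)
  expect_error(read_sbml(f))
  unlink(f)
})

test_that("empty gene associations omit the notes line", {
  doc <- write_sbml(core_fixture())
  x <- xml2::read_xml(doc)
  xml2::xml_ns_strip(x)
  rn <- xml2::xml_find_first(x, './/reaction[@id="t_co2_ec"]')
  lines <- xml2::xml_text(xml2::xml_find_all(rn, ".//p"))
  expect_false(any(grepl("GENE_ASSOCIATION", lines)))
})

test_that("invalid SIds are sanitized deterministically with a mapping", {
  mets <- rbind(metabolite("2pg-x_c", compartment = "cytosol"),
                metabolite("b_c"))
  m <- phyco_model(mets, list(reaction("r+1", c(`2pg-x_c` = -1, b_c = 1))))
  out <- write_sbml(m)
  map <- attr(out, "id_map")
  expect_identical(unname(map[["2pg-x_c"]]), "_2pg_x_c")
  expect_identical(unname(map[["r+1"]]), "r_1")
  expect_true(grepl('id="_2pg_x_c"', out))
})
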