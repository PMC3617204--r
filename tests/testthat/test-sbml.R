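test_that("SBML round trip preserves structure and constants exactly", {
  tmp <- tempfile(fileext = ".xml")
  write_sbml(ref_model, tmp)
  back <- read_sbml(tmp)

  expect_equal(n_species(back), n_species(ref_model))
  expect_equal(n_reactions(back), n_reactions(ref_model))
  expect_equal(n_odes(back), n_odes(ref_model))
  expect_identical(back$species$id, ref_model$species$id)
  expect_identical(back$species$is_boundary, ref_model$species$is_boundary)
  expect_identical(back$species$role, ref_model$species$role)
  expect_equal(back$parameters[names(ref_model$parameters)],
               ref_model$parameters)
  kinds <- function(m) vapply(m$reactions, function(r) r$rate_law$kind, "")
  expect_identical(kinds(back), kinds(ref_model))

  # two writes are byte-identical (diff-stable)
  tmp2 <- tempfile(fileext = ".xml")
  write_sbml(ref_model, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("round-tripped models simulate identically to < 1e-9", {
  tmp <- tempfile(fileext = ".xml")
  write_sbml(ref_model, tmp)
  back <- read_sbml(tmp)
  for (lin in c("Th17", "iTreg")) {
    ep1 <- endpoint_state(simulate_time_course(ref_model,
                                               canonical_recipe(lin),
                                               t_end = 60))
    ep2 <- endpoint_state(simulate_time_course(back, canonical_recipe(lin),
                                               t_end = 60))
    expect_lt(max(abs(ep1 - ep2) / pmax(abs(ep1), 1)), 1e-9)
  }
})

test_that("unsupported SBML constructs are rejected with a clear message", {
  tmp <- tempfile(fileext = ".xml")
  write_sbml(toy_bd(), tmp)
  doc <- readLines(tmp)
  with_event <- sub("</model>",
                    "<listOfEvents><event id=\"e1\"/></listOfEvents></model>",
                    doc)
  tmp2 <- tempfile(fileext = ".xml")
  writeLines(with_event, tmp2)
  expect_error(read_sbml(tmp2), "event")

  with_rule <- sub("</model>",
                   "<listOfRules><algebraicRule/></listOfRules></model>", doc)
  writeLines(with_rule, tmp2)
  expect_error(read_sbml(tmp2), "algebraicRule")
})

test_that("a minimal hand-written SBML file parses via plain mass action", {
  fixture <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '  <model id="mini">',
    '    <listOfCompartments>',
    '      <compartment id="cell" size="1" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="A" compartment="cell" initialConcentration="2" boundaryCondition="false" constant="false"/>',
    '      <species id="B" compartment="cell" initialConcentration="0" boundaryCondition="false" constant="false"/>',
    '    </listOfSpecies>',
    '    <listOfParameters>',
    '      <parameter id="kc" value="0.75" constant="true"/>',
    '    </listOfParameters>',
    '    <listOfReactions>',
    '      <reaction id="conv" reversible="false">',
    '        <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>',
    '        <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '          <apply><times/><ci> kc </ci><ci> A </ci></apply>',
    '        </math></kineticLaw>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>')
  tmp <- tempfile(fileext = ".xml")
  writeLines(fixture, tmp)
  m <- read_sbml(tmp)
  expect_equal(n_species(m), 2)
  expect_equal(n_reactions(m), 1)
  expect_equal(unname(m$parameters["kc"]), 0.75)
  expect_equal(m$reactions[[1]]$rate_law$kind, "mass_action")
  # the parsed model integrates with the expected closed form
  tr <- simulate_time_course(m, t_end = 2, n_points = 50)
  expect_equal(unname(endpoint_state(tr)["B"]), 2 * (1 - exp(-0.75 * 2)),
               tolerance = 1e-7)
})
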