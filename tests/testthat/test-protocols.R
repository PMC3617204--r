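test_that("each canonical recipe reproduces its fate-table row", {
  fixture <- generate_fate_fixture(ref_model)
  expect_length(fixture, 4)
  naive_ep <- endpoint_state(simulate_time_course(
    ref_model, canonical_recipe("naive"), t_end = 100, n_points = 100))
  induced <- lapply(c(Th1 = "Th1", Th2 = "Th2", Th17 = "Th17", iTreg = "iTreg"),
                    function(lin) induce_phenotype(ref_model, lin))
  own_level <- vapply(names(induced), function(lin) {
    master <- lineage_markers()[[lin]][1]
    endpoint_state(induced[[lin]]$trajectory)[[master]]
  }, numeric(1))

  for (row in fixture) {
    res <- induced[[row$lineage]]
    expect_equal(res$call$label, row$lineage)
    ep <- endpoint_state(res$trajectory)
    # stated up-markers rise well above the naive baseline
    expect_true(all(ep[row$up] > naive_ep[row$up] + 0.2))
    # opposing master regulators stay below half their own induced level
    for (master in row$suppressed) {
      lin_of <- names(own_level)[vapply(lineage_markers(), function(m)
        master == m[1], logical(1))]
      expect_lt(ep[[master]], 0.5 * own_level[[lin_of]])
    }
  }
})

test_that("PPARg agonist scan is monotone and converts the top dose to iTreg", {
  sc <- ppar_activation_scan(ref_model)
  expect_equal(length(sc$grid), 10)
  expect_true(all(diff(sc$readouts[, "FOXP3"]) >= -1e-9))
  expect_true(all(diff(sc$readouts[, "IL17_s"]) <= 1e-9))
  expect_true(all(diff(sc$readouts[, "RORgt"]) <= 1e-9))
  expect_true(all(diff(sc$readouts[, "STAT3_P"]) <= 1e-9))
  expect_equal(sc$calls[1], "Th17")
  expect_equal(sc$calls[length(sc$calls)], "iTreg")

  # dose 0 equals the unperturbed committed endpoint
  un <- endpoint_state(simulate_time_course(ref_model, canonical_recipe("Th17"),
                                            t_end = 200))
  expect_equal(unname(sc$readouts[1, ]), unname(un[colnames(sc$readouts)]),
               tolerance = 1e-6)
})

test_that("PPARg knockout raises Th17 markers and abolishes iTreg FOXP3", {
  ko17 <- ppar_knockout_compare(ref_model, "Th17")
  expect_gt(ko17$readouts["knockout", "RORgt"],
            ko17$readouts["wild_type", "RORgt"])
  expect_gt(ko17$readouts["knockout", "IL17_s"],
            ko17$readouts["wild_type", "IL17_s"])

  koT <- ppar_knockout_compare(ref_model, "iTreg")
  expect_lt(koT$readouts["knockout", "FOXP3"],
            koT$readouts["wild_type", "FOXP3"])
})

test_that("knockout of a species with no outgoing edges leaves readouts alone", {
  m_ko <- apply_perturbation(ref_model, knockout("IL10_s"))
  ep_wt <- endpoint_state(simulate_time_course(ref_model,
                                               canonical_recipe("Th17"),
                                               t_end = 50))
  ep_ko <- endpoint_state(simulate_time_course(m_ko, canonical_recipe("Th17"),
                                               t_end = 50))
  keep <- setdiff(names(ep_wt), c("IL10_s", "IL10_pre"))
  expect_equal(ep_wt[keep], ep_ko[keep], tolerance = 1e-10)
})

test_that("agonist clamp at 0 composed with knockout is idempotent", {
  ko <- apply_perturbation(ref_model, knockout("PPARg_a"))
  both <- apply_perturbation(ko, agonist_clamp("PPARg_a", 0))
  ep1 <- endpoint_state(simulate_time_course(ko, canonical_recipe("Th17"),
                                             t_end = 40))
  ep2 <- endpoint_state(simulate_time_course(both, canonical_recipe("Th17"),
                                             t_end = 40))
  expect_identical(ep1, ep2)
})

test_that("plasticity switch flips a committed Th17 cell to iTreg", {
  sw <- plasticity_switch(ref_model)
  expect_true(sw$t_switch > 0 && sw$t_switch < max(sw$time))
  pre <- sw$pre_switch
  post <- endpoint_state(sw)
  expect_gt(post[["FOXP3"]], pre[["FOXP3"]])
  expect_lt(post[["IL17_s"]], pre[["IL17_s"]])
  expect_lt(post[["RORgt"]], pre[["RORgt"]])
  expect_lt(post[["STAT3_P"]], pre[["STAT3_P"]])
  expect_equal(sw$call$label, "iTreg")
})

test_that("zero agonist reproduces the uninterrupted Th17 trajectory", {
  sw0 <- plasticity_switch(ref_model, t_switch = 30, agonist_level = 0,
                           t_end = 100)
  un <- simulate_time_course(ref_model, canonical_recipe("Th17"), t_end = 100)
  expect_equal(endpoint_state(sw0), endpoint_state(un), tolerance = 1e-8)
})

test_that("larger agonist doses give uniformly lower late-time IL-17", {
  doses <- c(0.5, 1, 2, 3)
  finals <- vapply(doses, function(a) {
    endpoint_state(plasticity_switch(ref_model, t_switch = 30,
                                     agonist_level = a,
                                     t_end = 130))[["IL17_s"]]
  }, numeric(1))
  expect_true(all(diff(finals) < 0))
})
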