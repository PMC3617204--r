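test_that("integrator matches the linear-ODE closed form to 1e-6", {
  tr <- simulate_time_course(toy_ab(k = 1), t_end = 5, n_points = 200)
  expect_equal(unname(tr$state[which(tr$time == 1), "B"]), 1 - exp(-1),
               tolerance = 1e-9)
  exact_B <- 1 - exp(-tr$time)
  expect_lt(max(abs(tr$state[, "B"] - exact_B)), 1e-6)
  expect_lt(max(abs(tr$state[, "A"] - exp(-tr$time))), 1e-6)
})

test_that("time grids are validated and trajectories are well-formed", {
  expect_error(simulate_time_course(toy_ab(), t_end = -1), "t_end")
  expect_error(simulate_time_course(toy_ab(), times = c(1, 2)), "times")
  tr <- simulate_time_course(toy_ab(), t_end = 2, n_points = 10)
  expect_s3_class(tr, "cd4_trajectory")
  expect_true(all(diff(tr$time) > 0))
  df <- as.data.frame(tr)
  expect_named(df, c("time", "species", "level"))
  expect_equal(nrow(df), 11 * 2)
})

test_that("zero-dose milieu leaves master regulators at naive baseline", {
  tr <- simulate_time_course(ref_model, canonical_recipe("naive"), t_end = 100,
                             n_points = 100)
  ep <- endpoint_state(tr)
  expect_lt(max(ep[c("Tbet", "GATA3", "RORgt", "FOXP3")]), 1e-6)
  expect_equal(unname(ep["PPARg_a"]), 0.25, tolerance = 1e-6)
})

test_that("Th17 milieu upregulates RORgt, IL-17 and STAT3-P from baseline", {
  tr <- simulate_time_course(ref_model, canonical_recipe("Th17"), t_end = 100)
  ep <- endpoint_state(tr)
  expect_gt(ep[["RORgt"]], 0.3)
  expect_gt(ep[["IL17_s"]], 0.3)
  expect_gt(ep[["STAT3_P"]], 0.3)
  # rising early in the transient (finite difference on the trajectory)
  i <- which(tr$time >= 1)[1]
  expect_gt(tr$state[i + 5, "RORgt"] - tr$state[i, "RORgt"], 0)
})

test_that("no dynamic species goes negative in any shipped scenario", {
  mins <- vapply(c("Th1", "Th2", "Th17", "iTreg"), function(lin) {
    min(simulate_time_course(ref_model, canonical_recipe(lin),
                             t_end = 100, n_points = 200)$state)
  }, numeric(1))
  expect_true(all(mins > -1e-9))
  expect_gt(min(plasticity_switch(ref_model)$state), -1e-9)
})

test_that("halving solver tolerances moves reference endpoints < 0.1%", {
  ep1 <- endpoint_state(simulate_time_course(ref_model, canonical_recipe("Th17")))
  ep2 <- endpoint_state(simulate_time_course(ref_model, canonical_recipe("Th17"),
                                             rtol = 5e-9, atol = 5e-11))
  rel <- abs(ep1 - ep2) / pmax(abs(ep1), 1e-6)
  expect_lt(max(rel), 1e-3)
})

test_that("steady state matches closed form and the long-time limit", {
  ss <- steady_state(toy_bd(k = 2, d = 0.5))
  expect_equal(unname(ss["B"]), 2 / 0.5, tolerance = 1e-8)

  for (lin in c("Th1", "Th2", "Th17", "iTreg")) {
    ss <- steady_state(ref_model, canonical_recipe(lin))
    ep <- endpoint_state(simulate_time_course(ref_model, canonical_recipe(lin),
                                              t_end = 2000, n_points = 100))
    expect_equal(ss, ep, tolerance = 1e-6)
  }
})

test_that("parameter scans cover kinetic constants, doses and clamps", {
  # parameter with no path to the readout: constant readouts
  sc <- parameter_scan(ref_model, canonical_recipe("Th17"), "bind_IL23R.k",
                       grid = c(0.5, 1, 2), readouts = c("RORgt", "FOXP3"),
                       t_end = 40)
  expect_lt(max(abs(sweep(sc$readouts, 2, sc$readouts[1, ]))), 1e-9)

  # grid of length 1 equals a single time course
  sc1 <- parameter_scan(ref_model, canonical_recipe("Th17"), "act_RORgt.vmax",
                        grid = 0.6, readouts = "RORgt", t_end = 40)
  ep <- endpoint_state(simulate_time_course(ref_model, canonical_recipe("Th17"),
                                            t_end = 40))
  expect_equal(unname(sc1$readouts[1, "RORgt"]), unname(ep["RORgt"]),
               tolerance = 1e-10)

  expect_error(parameter_scan(ref_model, NULL, "nope", 1, "RORgt"),
               "unknown scan parameter")
  expect_error(parameter_scan(ref_model, NULL, "act_RORgt.vmax",
                              c(2, 1), "RORgt"), "ascending")

  # dose scan over an external cytokine is monotone in the readout
  sc2 <- parameter_scan(ref_model, NULL, "IL6_e", grid = c(0, 0.5, 1),
                        readouts = "STAT3_P", t_end = 40)
  expect_true(all(diff(sc2$readouts[, "STAT3_P"]) > 0))
})

test_that("scan_time_course returns one trajectory per grid point", {
  trs <- scan_time_course(ref_model, canonical_recipe("Th17"),
                          "clamp:PPARg_a", grid = c(0.5, 0.5), t_end = 20,
                          n_points = 20)
  expect_length(trs, 2)
  expect_identical(trs[[1]]$state, trs[[2]]$state)
})
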