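make_noise_free_dataset <- function(times = c(8, 24, 48)) {
  spec <- generator_spec(
    recipes = list(canonical_recipe("Th17"), canonical_recipe("iTreg")),
    times = times, species = c("RORgt", "FOXP3", "IL17_s"),
    cv = 0, seed = 1)
  generate_calibration_dataset(ref_model, spec)
}

test_that("objective is zero at the generating parameters and scales with weights", {
  ds <- make_noise_free_dataset()
  truth <- get_parameter(ref_model, c("act_RORgt.vmax", "act_FOXP3.vmax"))
  expect_lt(objective(ref_model, truth, ds), 1e-10)

  off <- objective(ref_model, c(act_RORgt.vmax = 0.9), ds)
  expect_gt(off, 1e-4)
  ds2 <- ds
  for (i in seq_along(ds2$experiments)) {
    ds2$experiments[[i]]$observations$weight <- 2
  }
  expect_equal(objective(ref_model, c(act_RORgt.vmax = 0.9), ds2), 2 * off,
               tolerance = 1e-12)
})

test_that("the shipped parameters sit at a local minimum of the objective", {
  ds <- make_noise_free_dataset()
  for (p in c("act_RORgt.vmax", "inact_RORgt.k", "act_FOXP3.vmax")) {
    p0 <- get_parameter(ref_model, p)
    expect_gt(objective(ref_model, stats::setNames(1.5 * p0, p), ds), 1e-6)
    expect_gt(objective(ref_model, stats::setNames(0.5 * p0, p), ds), 1e-6)
  }
})

test_that("dataset validation rejects bad weights, times and species", {
  obs <- data.frame(species = "RORgt", time = 1, value = 1, weight = 0)
  expect_error(calibration_dataset(list(list(recipe = canonical_recipe("Th17"),
                                             observations = obs))),
               "weights")
  obs2 <- data.frame(species = "NOPE", time = 1, value = 1, weight = 1)
  ds <- calibration_dataset(list(list(recipe = canonical_recipe("Th17"),
                                      observations = obs2)))
  expect_error(objective(ref_model, c(), ds), "not dynamic")
})

test_that("the swarm minimizes a convex objective and is seed-reproducible", {
  fn <- function(x) (x[1] - 3)^2 + 2 * (x[2] + 1)^2
  res <- pso_optimize(fn, lower = c(-10, -10), upper = c(10, 10),
                      n_particles = 20, iterations = 120, seed = 5)
  expect_equal(unname(res$par), c(3, -1), tolerance = 1e-3)
  expect_true(all(diff(res$trace) <= 0))

  res2 <- pso_optimize(fn, lower = c(-10, -10), upper = c(10, 10),
                       n_particles = 20, iterations = 120, seed = 5)
  expect_identical(res, res2)
})

test_that("fit_particle_swarm validates inputs and reproduces with a seed", {
  ds <- make_noise_free_dataset(times = c(8, 24))
  expect_error(fit_particle_swarm(ref_model, ds, character(), list()),
               "nonempty")
  expect_error(
    fit_particle_swarm(ref_model, ds, "act_RORgt.vmax",
                       list(lower = c(act_RORgt.vmax = -1),
                            upper = c(act_RORgt.vmax = 2))),
    "positive")

  bounds <- list(lower = c(act_RORgt.vmax = 0.2),
                 upper = c(act_RORgt.vmax = 2))
  f1 <- fit_particle_swarm(ref_model, ds, "act_RORgt.vmax", bounds,
                           swarm_size = 8, iterations = 25, seed = 3)
  f2 <- fit_particle_swarm(ref_model, ds, "act_RORgt.vmax", bounds,
                           swarm_size = 8, iterations = 25, seed = 3)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$trace, f2$trace)
  expect_true(all(diff(f1$trace) <= 0))
  expect_equal(unname(f1$par), 0.6, tolerance = 0.05)
})
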