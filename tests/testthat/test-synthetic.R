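test_that("zero-noise datasets reproduce the simulation exactly", {
  spec <- generator_spec(recipes = list(canonical_recipe("Th17")),
                         times = c(8, 24), species = c("RORgt", "IL17_s"),
                         cv = 0, seed = 1)
  ds <- generate_calibration_dataset(ref_model, spec)
  expect_equal(ds$provenance$source, "synthetic")
  expect_lt(objective(ref_model, c(), ds), 1e-10)
})

test_that("noise has the requested coefficient of variation and no log bias", {
  dyn <- dynamic_species(ref_model)
  obs_species <- c("RORgt", "FOXP3", "IL17_s", "STAT3_P", "SMAD3_P",
                   "IL21_s", "TGFb_s", "IL6R_c", "TGFbR_c", "STAT5_P")
  spec <- generator_spec(recipes = list(canonical_recipe("Th17"),
                                        canonical_recipe("iTreg")),
                         times = seq(5, 100, length.out = 15),
                         species = obs_species, cv = 0.05, seed = 9)
  noisy <- generate_calibration_dataset(ref_model, spec)
  spec0 <- spec; spec0$cv <- 0
  clean <- generate_calibration_dataset(ref_model, spec0)

  ratio <- unlist(lapply(seq_along(noisy$experiments), function(i) {
    v1 <- noisy$experiments[[i]]$observations$value
    v0 <- clean$experiments[[i]]$observations$value
    keep <- v0 > 1e-6
    v1[keep] / v0[keep]
  }))
  expect_gt(length(ratio), 150)
  expect_gt(stats::sd(ratio), 0.04)
  expect_lt(stats::sd(ratio), 0.06)
  sigma <- sqrt(log(1 + 0.05^2))
  expect_lt(abs(mean(log(ratio))), 3 * sigma / sqrt(length(ratio)))
})

test_that("generation is byte-identical for a fixed seed and leaves RNG alone", {
  spec <- generator_spec(recipes = list(canonical_recipe("iTreg")),
                         times = c(10, 20), species = "FOXP3",
                         cv = 0.1, seed = 77)
  set.seed(123); before <- runif(1)
  d1 <- generate_calibration_dataset(ref_model, spec)
  d2 <- generate_calibration_dataset(ref_model, spec)
  expect_identical(d1, d2)
  set.seed(123)
  expect_identical(runif(1), before)
})

test_that("observation times beyond the horizon are rejected", {
  expect_error(generator_spec(recipes = list(canonical_recipe("Th17")),
                              times = c(10, 150), species = "RORgt",
                              cv = 0, seed = 1, t_end = 100),
               "horizon")
  expect_error(generator_spec(recipes = list(), times = 1, species = "x",
                              cv = -0.1, seed = 1), "cv")
})

test_that("the fate fixture is model-derived with four complete rows", {
  fx <- generate_fate_fixture(ref_model)
  expect_length(fx, 4)
  expect_setequal(vapply(fx, `[[`, "", "lineage"),
                  c("Th1", "Th2", "Th17", "iTreg"))
  th17 <- fx[[which(vapply(fx, `[[`, "", "lineage") == "Th17")]]
  expect_setequal(th17$up, c("RORgt", "IL17_s", "STAT3_P"))
  expect_setequal(th17$suppressed, c("Tbet", "GATA3", "FOXP3"))
  itreg <- fx[[which(vapply(fx, `[[`, "", "lineage") == "iTreg")]]
  expect_true("FOXP3" %in% itreg$up)

  tmp <- tempfile(fileext = ".json")
  write_fate_fixture_json(fx, tmp)
  expect_length(jsonlite::read_json(tmp), 4)
})

test_that("dataset CSV round-trips recipes and observations", {
  spec <- generator_spec(recipes = list(canonical_recipe("Th17")),
                         times = c(8, 24), species = c("RORgt", "FOXP3"),
                         cv = 0.05, seed = 4)
  ds <- generate_calibration_dataset(ref_model, spec)
  tmp <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, tmp)
  back <- read_dataset_csv(tmp)
  expect_length(back$experiments, 1)
  expect_equal(back$experiments[[1]]$recipe$doses,
               ds$experiments[[1]]$recipe$doses)
  o1 <- ds$experiments[[1]]$observations
  o2 <- back$experiments[[1]]$observations
  o1 <- o1[order(o1$species, o1$time), ]
  o2 <- o2[order(o2$species, o2$time), ]
  expect_equal(o1$value, o2$value)
  expect_equal(o1$time, o2$time)
})
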