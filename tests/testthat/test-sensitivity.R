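test_that("control coefficients of B* = k/d are exactly +1 and -1", {
  s <- local_sensitivities(toy_bd(k = 2, d = 0.5), readouts = "B",
                           t_eval = 200)
  expect_equal(s$coefficients["B", "syn.k"], 1, tolerance = 1e-4)
  expect_equal(s$coefficients["B", "deg.k"], -1, tolerance = 1e-4)
  expect_false(any(s$unnormalized))
})

test_that("MCA summation theorems hold on a linear chain to 1e-4", {
  # Concentration control coefficients of X* = k1*A/k2 sum to 0;
  # flux control coefficients of J = k2*X* (so C_J[k2] = 1 + C_X[k2])
  # sum to 1 (classical summation theorem).
  s <- local_sensitivities(toy_chain(), readouts = "X", t_eval = 400)
  cx <- s$coefficients["X", c("s1.k", "s2.k")]
  expect_equal(unname(sum(cx)), 0, tolerance = 1e-4)
  cj <- c(cx[["s1.k"]], 1 + cx[["s2.k"]])
  expect_equal(sum(cj), 1, tolerance = 1e-4)
})

test_that("parameters with no path to the readout have zero coefficient", {
  s <- local_sensitivities(ref_model, canonical_recipe("Th17"),
                           readouts = "RORgt",
                           parameters = c("bind_IL23R.k", "act_RORgt.vmax"),
                           t_eval = 50)
  expect_equal(s$coefficients["RORgt", "bind_IL23R.k"], 0, tolerance = 1e-8)
  expect_gt(abs(s$coefficients["RORgt", "act_RORgt.vmax"]), 0.05)
})

test_that("zero-baseline readouts fall back to unnormalized derivatives", {
  s <- local_sensitivities(ref_model, canonical_recipe("naive"),
                           readouts = "Tbet", parameters = "act_Tbet.vmax",
                           t_eval = 20)
  expect_true(s$unnormalized["Tbet", "act_Tbet.vmax"])
  expect_true(is.finite(s$coefficients["Tbet", "act_Tbet.vmax"]))
})

test_that("ranking orders by max |C| with stable name tie-break", {
  rep1 <- list(coefficients = matrix(c(1, -1, 0), nrow = 1,
                                     dimnames = list("y", c("b", "a", "c"))))
  rk <- rank_parameters(rep1)
  expect_equal(rk$parameter, c("a", "b", "c"))
  expect_equal(rk$score, c(1, 1, 0))

  rep2 <- list(coefficients = matrix(2.5, 1, 1,
                                     dimnames = list("y", "only")))
  expect_equal(rank_parameters(rep2)$parameter, "only")
})

test_that("top-5 ranking is stable under a 10x smaller step", {
  params <- c("act_RORgt.vmax", "inact_RORgt.k", "act_FOXP3.vmax",
              "act_STAT3_P.vmax", "inact_IL17_s.k", "bind_IL6R.k",
              "act_IL17_s.km", "act_PPARg_a.vmax")
  s1 <- local_sensitivities(ref_model, canonical_recipe("Th17"),
                            readouts = c("RORgt", "IL17_s"),
                            parameters = params, t_eval = 60)
  s2 <- local_sensitivities(ref_model, canonical_recipe("Th17"),
                            readouts = c("RORgt", "IL17_s"),
                            parameters = params, t_eval = 60,
                            delta_factor = 1e-5)
  top1 <- head(rank_parameters(s1)$parameter, 5)
  top2 <- head(rank_parameters(s2)$parameter, 5)
  expect_setequal(top1, top2)
  # well-conditioned coefficients agree within 1% relative
  big <- abs(s1$coefficients) > 0.05
  rel <- abs(s1$coefficients[big] - s2$coefficients[big]) /
    abs(s1$coefficients[big])
  expect_lt(max(rel), 0.01)
})
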