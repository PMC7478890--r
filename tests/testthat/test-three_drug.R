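three_drug_fixture <- function(model = "loewe", alpha = 0,
                               drugs = NULL, seed = 1L) {
  drugs <- drugs %||% list(OSM = sim_drug(-26/3), BAY = sim_drug(-17/3),
                           RMC = sim_drug(-20/3))
  des <- three_drug_design(names(drugs)[1:2], names(drugs)[3],
                           build_ladder(drugs[[1]]$log_ec50, drug = names(drugs)[1]),
                           build_ladder(drugs[[2]]$log_ec50, drug = names(drugs)[2]),
                           build_ladder(drugs[[3]]$log_ec50, drug = names(drugs)[3]))
  cfg <- noiseless_config(model, alpha = alpha, drugs = drugs, seed = seed)
  tab <- normalize_viability(simulate_combination(cfg, des))
  list(design = des, table = tab)
}

test_that("the design reproduces the printed volume triples and conserves volume", {
  fx <- three_drug_fixture()
  m <- fx$design$mixes
  expect_equal(m$label, c("(1+1):1", "(1+1):2", "(1+1):4"))
  expect_equal(m$vol_a, c(33, 25, 17))
  expect_equal(m$vol_b, c(33, 25, 17))
  expect_equal(m$vol_c, c(34, 50, 66))
  expect_equal(rowSums(m[, c("vol_a", "vol_b", "vol_c")]), rep(100, 3))
  # pair + third fractions sum to 1 in the analysis output
  res <- analyze_three_drug(fx$table, fx$design)
  expect_equal(res$mixes$pair_fraction + res$mixes$third_fraction, rep(1, 3))
})

test_that("CI formulas: additivity midpoints give exactly 1, zero denominators error", {
  expect_equal(three_drug_ci_vs_pair(1e-9, 2e-9, 2e-6, 4e-6), 1)
  expect_equal(three_drug_ci_independent(c(1, 2, 3) / 3, c(1, 2, 3)), 1)
  expect_error(three_drug_ci_vs_pair(1e-9, 0, 1e-6, 1e-6), "positive")
  expect_error(three_drug_ci_independent(c(1, 1, 1), c(1, 0, 1)), "positive")
  # permutation invariance given consistent fractions
  p <- sample(3)
  expect_equal(three_drug_ci_independent(c(.2, .3, .4)[p], c(1, 2, 3)[p]),
               three_drug_ci_independent(c(.2, .3, .4), c(1, 2, 3)))
})

test_that("a noiseless additive three-drug surface gives CI ~ 1 in both families", {
  fx <- three_drug_fixture("loewe")
  res <- analyze_three_drug(fx$table, fx$design)
  expect_true(all(abs(res$mixes$ci_vs_pair - 1) < 0.05))
  expect_true(all(abs(res$mixes$ci_independent - 1) < 0.05))
})

test_that("a three-way sham (one drug with itself twice) gives CI = 1", {
  drugs <- list(X1 = sim_drug(-8), X2 = sim_drug(-8), X3 = sim_drug(-8))
  fx <- three_drug_fixture("loewe", drugs = drugs)
  res <- analyze_three_drug(fx$table, fx$design)
  expect_true(all(abs(res$mixes$ci_vs_pair - 1) < 0.05))
  expect_true(all(abs(res$mixes$ci_independent - 1) < 0.05))
})

test_that("injected three-agent synergy drives the independent CI below 0.8", {
  fx <- three_drug_fixture("bliss", alpha = 1.5)
  res <- analyze_three_drug(fx$table, fx$design)
  # (1+1):2 is the 1:1:... dose-equivalent three-way mix
  expect_lt(res$mixes$ci_independent[res$mixes$label == "(1+1):2"], 0.8)
  expect_lt(res$mixes$ci_vs_pair[res$mixes$label == "(1+1):2"], 1)
})

test_that("an inert third drug is flagged instead of yielding a CI", {
  drugs <- list(OSM = sim_drug(-26/3), BAY = sim_drug(-17/3),
                INERT = sim_drug(-20/3, top = 1, bottom = 0.98))
  fx <- suppressWarnings(three_drug_fixture("loewe", drugs = drugs))
  expect_error(analyze_three_drug(fx$table, fx$design),
               "did not converge.*INERT|INERT.*did not converge")
})

test_that("the printed-variant independent CI uses the pair EC50 as first denominator", {
  fx <- three_drug_fixture("loewe")
  res_alone <- analyze_three_drug(fx$table, fx$design)
  res_pair <- analyze_three_drug(fx$table, fx$design,
                                 independent_denominator = "pair_5050")
  # on the additive sham-like surface the pair EC50 on the A axis equals the
  # alone EC50, so the two variants agree; both must be finite and positive
  expect_true(all(res_pair$mixes$ci_independent > 0))
  expect_equal(res_pair$mixes$ci_independent, res_alone$mixes$ci_independent,
               tolerance = 0.05)
})
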