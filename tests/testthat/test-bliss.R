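test_that("effect conversion clips to [0, 1] and rejects negative viability", {
  expect_equal(effect_from_viability(1), 0)
  expect_equal(effect_from_viability(0), 1)
  expect_equal(effect_from_viability(1.07), 0)  # noise above untreated
  expect_equal(effect_from_viability(0.25), 0.75)
  expect_error(effect_from_viability(-0.1), "nonnegative")
})

test_that("expected Bliss effect: arithmetic, identity and absorbing elements", {
  expect_equal(expected_bliss(0.5, 0.5), 0.75)
  x <- seq(0, 1, by = 0.1)
  expect_equal(expected_bliss(rep(0, 11), x), x)   # 0 is the identity
  expect_equal(expected_bliss(rep(1, 11), x), rep(1, 11))  # 1 absorbs
  expect_error(expected_bliss(1.2, 0.5), "\\[0, 1\\]")
})

test_that("Bliss Index and excess over Bliss on constructed triples", {
  expect_equal(bliss_index(0.3, 0.3, 0.6), 0.51 / 0.6)  # 0.85
  expect_equal(excess_over_bliss(0.3, 0.3, 0.6), 9.0)
  expect_equal(excess_over_bliss(0.5, 0.5, 0.5), -25.0)
  # exact additivity: BI = 1, excess = 0
  e_mix <- expected_bliss(0.4, 0.5)
  expect_identical(bliss_index(0.4, 0.5, e_mix), 1)
  expect_identical(excess_over_bliss(0.4, 0.5, e_mix), 0)
  # zero observed effect is an NA sentinel, not an error
  expect_true(is.na(bliss_index(0.2, 0.2, 0)))
})

test_that("Bliss identities hold as properties over random effect triples", {
  set.seed(42)
  e_a <- runif(300); e_b <- runif(300); e_mix <- runif(300)
  exp_e <- expected_bliss(e_a, e_b)
  # symmetric, within [0,1], monotone in each argument
  expect_equal(exp_e, expected_bliss(e_b, e_a))
  expect_true(all(exp_e >= 0 & exp_e <= 1))
  expect_true(all(expected_bliss(pmin(e_a + 0.05, 1), e_b) >= exp_e))
  # BI * actual = expected wherever defined
  bi <- bliss_index(e_a, e_b, e_mix)
  ok <- !is.na(bi)
  expect_equal(bi[ok] * e_mix[ok], exp_e[ok])
  # excess > 0 <=> BI < 1 (for positive observed effect)
  eob <- excess_over_bliss(e_a, e_b, e_mix)
  expect_equal(eob[ok] > 0, bi[ok] < 1)
})

test_that("a noiseless Bliss-independent 10x10 matrix scores BI = 1 everywhere", {
  plan <- bliss_matrix_plan(osm_ladder(), bay_ladder(),
                            drug_a = "OSM", drug_b = "BAY")
  tab <- normalize_viability(
    simulate_combination(noiseless_config("bliss"), plan))
  grid <- analyze_bliss_matrix(tab)
  expect_equal(nrow(grid$cells), 100)
  expect_true(all(abs(grid$cells$bliss_index - 1) < 1e-9))
  expect_true(all(abs(grid$cells$excess_over_bliss) < 1e-7))
  expect_false(any(grid$cells$synergy))
  expect_equal(dim(grid$matrices$bliss_index), c(10, 10))
  expect_identical(rownames(grid$matrices$bliss_index)[1], "-11")
})

test_that("a mid-dose synergy boost is flagged only inside the boosted region", {
  window <- list(OSM = c(-9.8, -8.4), BAY = c(-6.8, -5.4))
  cfg <- noiseless_config("bliss", alpha = 1.5, window = window)
  plan <- bliss_matrix_plan(osm_ladder(), bay_ladder(),
                            drug_a = "OSM", drug_b = "BAY")
  tab <- normalize_viability(simulate_combination(cfg, plan))
  grid <- analyze_bliss_matrix(tab, threshold = 0.85)
  in_window <- grid$cells$log_dose_a >= window$OSM[1] &
    grid$cells$log_dose_a <= window$OSM[2] &
    grid$cells$log_dose_b >= window$BAY[1] &
    grid$cells$log_dose_b <= window$BAY[2]
  expect_true(any(grid$cells$synergy))
  expect_true(all(in_window[grid$cells$synergy]))
  expect_false(any(grid$cells$synergy[!in_window]))
})

test_that("DEQ band designs are scored like matrices, with shifted marginals present", {
  plan <- bliss_band_plan(osm_ladder(), bay_ladder(),
                          drug_a = "OSM", drug_b = "BAY")
  tab <- normalize_viability(
    simulate_combination(noiseless_config("bliss"), plan))
  grid <- analyze_bliss_matrix(tab)
  expect_equal(nrow(grid$cells), 30)
  expect_true(all(abs(grid$cells$bliss_index - 1) < 1e-9))
})

test_that("a combination without its single-agent marginal raises a named error", {
  plan <- bliss_matrix_plan(osm_ladder(), bay_ladder(),
                            drug_a = "OSM", drug_b = "BAY")
  tab <- normalize_viability(
    simulate_combination(noiseless_config("bliss"), plan))
  pruned <- tab[!(tab$ratio_label == "alone" & !is.na(tab$log_dose_a) &
                    abs(tab$log_dose_a - (-11)) < 1e-9), ]
  class(pruned) <- c("plate_table", "data.frame")
  attr(pruned, "normalized") <- TRUE
  expect_error(analyze_bliss_matrix(pruned), "OSM at log dose -11")
})

test_that("Loewe and Bliss references differ: steep identical drugs give BI <= 1 below the EC50", {
  # for steep curves a dose-additive (Loewe) pair beats the Bliss
  # expectation at sub-EC50 doses, so the Bliss Index dips below 1
  drugs <- list(X1 = sim_drug(-8, hill = 2), X2 = sim_drug(-8, hill = 2))
  l1 <- build_ladder(-8, drug = "X1"); l2 <- build_ladder(-8, drug = "X2")
  plan <- bliss_matrix_plan(l1, l2, drug_a = "X1", drug_b = "X2")
  tab <- normalize_viability(
    simulate_combination(noiseless_config("loewe", drugs = drugs), plan))
  grid <- analyze_bliss_matrix(tab)
  sub_ec50 <- grid$cells$log_dose_a <= -8 + 1e-9 &
    grid$cells$log_dose_b <= -8 + 1e-9
  expect_true(all(grid$cells$bliss_index[sub_ec50] <= 1 + 1e-9))
  expect_true(any(grid$cells$bliss_index[sub_ec50] < 0.95))
})
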