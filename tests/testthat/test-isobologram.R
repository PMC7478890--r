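test_that("fractional EC50 correction reproduces the printed corrected contributions", {
  # 4:1 mixture: 80% osimertinib, 20% BAY-293
  expect_equal(fractional_ec50(0.84e-9, 0.8), 0.672e-9)
  expect_equal(round(fractional_ec50(0.84e-9, 0.8) / 1e-9, 2), 0.67)
  expect_equal(round(fractional_ec50(1.01e-6, 0.2) / 1e-6, 2), 0.20)
  # 1:4 mixture: 20% osimertinib
  expect_equal(round(fractional_ec50(1.19e-9, 0.2) / 1e-9, 2), 0.24)
  expect_equal(fractional_ec50(3e-9, 1), 3e-9)
  expect_error(fractional_ec50(1e-9, 0), "fraction")
  expect_error(fractional_ec50(1e-9, 1.2), "fraction")
  expect_error(fractional_ec50(-1e-9, 0.5), "positive")
})

test_that("combination index arithmetic, symmetry and unit invariance", {
  # contributions each exactly half their alone EC50s
  expect_equal(combination_index(1e-9, 2e-6, 2e-9, 4e-6), 1)
  # printed 1:1 worked-example values -> 0.4723
  ci <- combination_index(0.46e-9, 0.54e-6, 2.62e-9, 1.82e-6)
  expect_equal(ci, 0.46 / 2.62 + 0.54 / 1.82, tolerance = 1e-12)
  expect_equal(ci, 0.4723, tolerance = 1e-4)
  # relabeling (A,B) -> (B,A)
  expect_equal(combination_index(0.54e-6, 0.46e-9, 1.82e-6, 2.62e-9), ci)
  # per-drug unit changes cancel
  expect_equal(combination_index(0.46, 0.54, 2.62, 1.82), ci)
  expect_error(combination_index(1e-9, 1e-9, 0, 1e-9), "positive")
})

test_that("CI classification uses 0.8/1.2 cutoffs with inclusive additive band", {
  cls <- classify_ci(c(0.79, 0.8, 1.0, 1.2, 1.21))
  expect_equal(as.character(cls),
               c("synergy", "additive", "additive", "additive", "antagonism"))
  expect_error(classify_ci(0), "positive")
})

test_that("noiseless Loewe-additive surfaces give CI ~ 1 and points on the isobole", {
  plan <- two_drug_mixture_plan(osm_ladder(), bay_ladder(),
                                drug_a = "OSM", drug_b = "BAY")
  tab <- normalize_viability(
    simulate_combination(noiseless_config("loewe"), plan))
  res <- analyze_isobologram(tab, plan)
  expect_true(all(res$ratios$ci > 0.95 & res$ratios$ci < 1.05))
  expect_equal(res$ratios$isobole_x + res$ratios$isobole_y,
               res$ratios$ci, tolerance = 1e-12)
})

test_that("a sham self-combination lies on the additivity isobole with CI = 1", {
  lad <- osm_ladder()
  lad2 <- build_ladder(lad$anchor, drug = "OSM2")
  drugs <- list(OSM = sim_drug(-26/3), OSM2 = sim_drug(-26/3))
  plan <- two_drug_mixture_plan(lad, lad2, drug_a = "OSM", drug_b = "OSM2")
  tab <- normalize_viability(
    simulate_combination(noiseless_config("loewe", drugs = drugs), plan))
  res <- analyze_isobologram(tab, plan)
  expect_true(all(abs(res$ratios$ci - 1) < 0.05))
  expect_true(all(abs(res$ratios$isobole_x + res$ratios$isobole_y - 1) < 0.05))
})

test_that("injected synergy produces CI below the synergy cutoff at 1:1", {
  plan <- two_drug_mixture_plan(osm_ladder(), bay_ladder(),
                                drug_a = "OSM", drug_b = "BAY")
  tab <- normalize_viability(
    simulate_combination(noiseless_config("loewe", alpha = 1), plan))
  res <- analyze_isobologram(tab, plan)
  ci_11 <- res$ratios$ci[res$ratios$ratio_label == "1:1"]
  expect_lt(ci_11, 0.8)
  expect_equal(res$ratios$synergy_class[res$ratios$ratio_label == "1:1"],
               "synergy")
})

test_that("the parallelism gate blocks unsuitable pairs and advises Bliss analysis", {
  drugs <- list(OSM = sim_drug(-26/3),
                WEAK = sim_drug(-17/3, bottom = 0.55))  # max effect 0.45
  lad_w <- build_ladder(-17/3, drug = "WEAK")
  plan <- two_drug_mixture_plan(osm_ladder(), lad_w,
                                drug_a = "OSM", drug_b = "WEAK")
  # combination effects leave the weak drug's range: boundary warnings expected
  tab <- suppressWarnings(normalize_viability(
    simulate_combination(noiseless_config("loewe", drugs = drugs), plan)))
  expect_error(analyze_isobologram(tab, plan), "Bliss")
  res <- analyze_isobologram(tab, plan, override_gate = TRUE)
  expect_false(res$gate$suitable_for_isobologram)
})

test_that("missing mixture arms are reported by ratio label", {
  plan <- two_drug_mixture_plan(osm_ladder(), bay_ladder(),
                                drug_a = "OSM", drug_b = "BAY")
  tab <- normalize_viability(
    simulate_combination(noiseless_config("loewe"), plan))
  dropped <- tab[tab$ratio_label != "1:2", ]
  class(dropped) <- c("plate_table", "data.frame")
  attr(dropped, "normalized") <- TRUE
  expect_error(analyze_isobologram(dropped, plan), "1:2")
})

test_that("per-experiment analysis summarizes CI across experiments", {
  cfg <- simulation_config(
    drugs = list(OSM = sim_drug(-26/3), BAY = sim_drug(-17/3)),
    reference_model = "loewe", noise_cv = 0.05, experiment_cv = 0.05,
    n_technical = 3L, n_experiments = 3L, seed = 99L
  )
  plan <- two_drug_mixture_plan(osm_ladder(), bay_ladder(),
                                drug_a = "OSM", drug_b = "BAY")
  tab <- normalize_viability(simulate_combination(cfg, plan))
  res <- analyze_isobologram(tab, plan, by_experiment = TRUE)
  expect_length(res$by_experiment, 3)
  expect_equal(nrow(res$experiment_summary), 5)
  expect_true(all(res$experiment_summary$ci_mean > 0.8 &
                    res$experiment_summary$ci_mean < 1.2))
})
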