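# Shared fixtures: the two-drug ladder geometry of the worked example
# (anchors -8.67 and -5.67) and simulator configs built in code.

osm_ladder <- function() build_ladder(snap_to_grid(-8.57), drug = "OSM")
bay_ladder <- function() build_ladder(snap_to_grid(-5.73), drug = "BAY")
# anchored at the published equivalence dose -6.67 (a design input; -6.84 is
# actually nearer to -7.0 on the grid)
rmc_ladder <- function() build_ladder(-20/3, drug = "RMC")

# noiseless single-replicate config: ground truth passes through unchanged
noiseless_config <- function(model = "loewe", alpha = 0, window = NULL,
                             drugs = NULL, seed = 1L) {
  drugs <- drugs %||% list(OSM = sim_drug(-26/3), BAY = sim_drug(-17/3))
  simulation_config(
    drugs = drugs, reference_model = model,
    synergy_alpha = alpha, synergy_window = window,
    noise_cv = 0, experiment_cv = 0,
    n_technical = 1L, n_experiments = 1L, seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small hand-built plate data frame for IO tests
tiny_plate_df <- function() {
  data.frame(
    plate_id = "P1",
    well = c("B2", "B3", "B4", "B5"),
    drug_a = c("X", "X", "X", NA),
    log_dose_a = c(-9, -8, -7, NA),
    drug_b = NA_character_, log_dose_b = NA_real_,
    drug_c = NA_character_, log_dose_c = NA_real_,
    ratio_label = c("alone", "alone", "alone", "untreated"),
    technical_rep = 1L, experiment = 1L,
    luminescence = c(9000, 5000, 1000, 10000),
    stringsAsFactors = FALSE
  )
}
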