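# Plate-data simulator with known ground truth.
#
# Emulates the viability assay the analyses expect: 96-well plates using the
# inner 60 wells, 10-point 1/3-log ladders, single agents plus combination
# arms, technical replicates within a plate and independent experiments
# across plates, CellTiter-Glo-like luminescence with multiplicative
# lognormal noise, untreated wells for normalization.

#' Define a simulated drug
#'
#' @param log_ec50 log10 molar EC50 of the true curve.
#' @param hill Hill slope (> 0: viability decreases with dose).
#' @param top,bottom viability asymptotes.
#' @return named list of 4PL parameters.
#' @export
sim_drug <- function(log_ec50, hill = 1, top = 1, bottom = 0) {
  stopifnot(is.finite(log_ec50), hill > 0, top > bottom)
  list(top = top, bottom = bottom, log_ec50 = log_ec50, hill = hill)
}

#' Simulation configuration
#'
#' @param drugs named list of [sim_drug()] parameter sets; names are the drug
#'   labels used in designs and plate tables.
#' @param reference_model `"loewe"` or `"bliss"`: the additivity model that
#'   generates expected combination viabilities.
#' @param synergy_alpha dose-potentiation factor for combinations: effective
#'   doses are multiplied by `1 + synergy_alpha` before the reference surface
#'   is evaluated. 0 reproduces the reference model exactly.
#' @param synergy_window optional named list (per drug) of `c(lo, hi)` log10
#'   molar windows; when given, the potentiation applies only to combination
#'   wells whose delivered doses all fall inside their drug's window.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   well noise (mean 1).
#' @param experiment_cv CV of the per-experiment lognormal scale factor
#'   emulating independent experiments.
#' @param n_technical technical replicates per condition within a plate.
#' @param n_experiments independent experiments (one plate set each).
#' @param untreated_lum_mean expected luminescence of an untreated well.
#' @param seed integer seed; together with the config it fully determines
#'   the simulated table.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(drugs,
                              reference_model = c("loewe", "bliss"),
                              synergy_alpha = 0,
                              synergy_window = NULL,
                              noise_cv = 0.1,
                              experiment_cv = 0.05,
                              n_technical = 3L,
                              n_experiments = 3L,
                              untreated_lum_mean = 1e4,
                              seed = 1L) {
  reference_model <- match.arg(reference_model)
  stopifnot(is.list(drugs), length(drugs) >= 1, !is.null(names(drugs)),
            synergy_alpha >= 0, noise_cv >= 0, experiment_cv >= 0,
            n_technical >= 1, n_experiments >= 1, untreated_lum_mean > 0)
  for (d in drugs) {
    stopifnot(all(c("top", "bottom", "log_ec50", "hill") %in% names(d)))
  }
  structure(
    list(drugs = drugs, reference_model = reference_model,
         synergy_alpha = synergy_alpha, synergy_window = synergy_window,
         noise_cv = noise_cv, experiment_cv = experiment_cv,
         n_technical = as.integer(n_technical),
         n_experiments = as.integer(n_experiments),
         untreated_lum_mean = untreated_lum_mean, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Expected viability of a (possibly combined) treatment
#'
#' Evaluates the configured reference surface at the delivered molar doses.
#' Bliss: independent effects compose as `1 - prod(1 - E_i)` (two-drug form
#' `E_A + E_B - E_A E_B`, extended by inclusion-exclusion for three drugs).
#' Loewe: the viability `v` solving `sum(d_i / D_i(v)) = 1`, where `D_i(v)`
#' is the iso-effective single-agent dose, found by bisection on `v` to an
#' interval tolerance of 1e-10. Combinations whose effect falls outside the
#' joint single-agent range are assigned the nearer boundary viability with
#' a warning. Synergy potentiation multiplies doses of multi-drug wells by
#' `1 + synergy_alpha` (inside the `synergy_window`, if set) before surface
#' evaluation; single-agent wells are never potentiated, so the injected
#' interaction is purely a combination effect.
#'
#' @param config a [simulation_config()].
#' @param doses named numeric vector of delivered molar doses (subset of
#'   `names(config$drugs)`; zeros/absent drugs may be omitted).
#' @return expected viability (untreated scale, 1 = untreated).
#' @export
expected_viability <- function(config, doses) {
  doses <- doses[doses > 0]
  if (length(doses) == 0) return(1)
  pars <- config$drugs[names(doses)]
  if (anyNA(names(doses)) || any(vapply(pars, is.null, logical(1)))) {
    stop("doses must be named by configured drugs")
  }
  if (length(doses) >= 2 && config$synergy_alpha > 0 &&
      synergy_applies(config, doses)) {
    doses <- doses * (1 + config$synergy_alpha)
  }
  if (length(doses) == 1) {
    p <- pars[[1]]
    return(viability_4pl(log10(doses), p$top, p$bottom, p$log_ec50, p$hill))
  }
  if (config$reference_model == "bliss") {
    surv <- vapply(seq_along(doses), function(i) {
      p <- pars[[i]]
      v <- viability_4pl(log10(doses[i]), p$top, p$bottom, p$log_ec50, p$hill)
      1 - clip01(1 - v)
    }, numeric(1))
    return(prod(surv))
  }
  loewe_viability(doses, pars)
}

synergy_applies <- function(config, doses) {
  w <- config$synergy_window
  if (is.null(w)) return(TRUE)
  all(vapply(names(doses), function(nm) {
    if (is.null(w[[nm]])) return(TRUE)
    x <- log10(doses[[nm]])
    x >= w[[nm]][1] & x <= w[[nm]][2]
  }, logical(1)))
}

# Loewe-additive viability for >= 2 drugs: bisection on viability
loewe_viability <- function(doses, pars, tol = 1e-10) {
  v_lo <- max(vapply(pars, `[[`, numeric(1), "bottom"))
  v_hi <- min(vapply(pars, `[[`, numeric(1), "top"))
  if (v_lo >= v_hi) stop("single-agent viability ranges do not overlap")
  eps <- 1e-9 * (v_hi - v_lo)
  f <- function(v) {
    sum(vapply(seq_along(doses), function(i) {
      p <- pars[[i]]
      doses[[i]] / inverse_4pl(v, p$top, p$bottom, p$log_ec50, p$hill)
    }, numeric(1))) - 1
  }
  lo <- v_lo + eps
  hi <- v_hi - eps
  if (f(hi) < 0) {
    warning("combination effect below the single-agent range; ",
            "using the upper boundary viability")
    return(v_hi)
  }
  if (f(lo) > 0) {
    warning("combination effect beyond the single-agent range; ",
            "using the lower boundary viability")
    return(v_lo)
  }
  # f is increasing in v: root bracketed in [lo, hi]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# inner 60 wells of a 96-well plate (rows B-G, columns 2-11)
inner_wells <- function() {
  as.vector(t(outer(LETTERS[2:7], 2:11, paste0)))
}

# multiplicative lognormal noise factors with mean 1 and the given CV
noise_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Expand per-condition expectations into a well-level plate table.
# `conditions` must have drug_a..log_dose_c, ratio_label, true_viability.
assemble_plate_table <- function(config, conditions) {
  set.seed(config$seed)
  scale_e <- noise_factors(config$n_experiments, config$experiment_cv)
  wells <- inner_wells()
  capacity <- length(wells) - config$n_technical  # reserve untreated wells
  untreated_row <- data.frame(
    drug_a = NA_character_, log_dose_a = NA_real_,
    drug_b = NA_character_, log_dose_b = NA_real_,
    drug_c = NA_character_, log_dose_c = NA_real_,
    ratio_label = "untreated", true_viability = 1,
    stringsAsFactors = FALSE
  )
  out <- vector("list", config$n_experiments)
  for (e in seq_len(config$n_experiments)) {
    reps <- conditions[rep(seq_len(nrow(conditions)), each = config$n_technical), ]
    reps$technical_rep <- rep(seq_len(config$n_technical), nrow(conditions))
    n_plates <- ceiling(nrow(reps) / capacity)
    plates <- vector("list", n_plates)
    for (p in seq_len(n_plates)) {
      idx <- ((p - 1) * capacity + 1):min(p * capacity, nrow(reps))
      block <- reps[idx, ]
      untr <- untreated_row[rep(1, config$n_technical), ]
      untr$technical_rep <- seq_len(config$n_technical)
      block <- rbind(block, untr)
      block$plate_id <- sprintf("E%d-P%d", e, p)
      block$well <- wells[seq_len(nrow(block))]
      block$experiment <- e
      plates[[p]] <- block
    }
    df <- do.call(rbind, plates)
    df$luminescence <- config$untreated_lum_mean * scale_e[e] *
      df$true_viability * noise_factors(nrow(df), config$noise_cv)
    out[[e]] <- df
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  truth <- df$true_viability
  df$true_viability <- NULL
  df <- df[, PLATE_COLUMNS]
  pt <- plate_table(df)
  attr(pt, "truth") <- truth
  pt
}

# build a single-agent condition block on a given drug slot ("a", "b", "c")
alone_conditions <- function(drug, log_doses, slot = "a") {
  n <- length(log_doses)
  df <- data.frame(
    drug_a = NA_character_, log_dose_a = NA_real_,
    drug_b = NA_character_, log_dose_b = NA_real_,
    drug_c = NA_character_, log_dose_c = NA_real_,
    ratio_label = "alone", stringsAsFactors = FALSE
  )[rep(1, n), ]
  df[[paste0("drug_", slot)]] <- drug
  df[[paste0("log_dose_", slot)]] <- log_doses
  df
}

#' Simulate a single-agent dose-response plate
#'
#' One arm: the drug alone along its ladder, plus untreated wells on every
#' plate. Luminescence is `untreated_lum_mean * scale_experiment *
#' true_viability * noise`.
#'
#' @param config a [simulation_config()].
#' @param ladder a [build_ladder()] object.
#' @param drug drug label; defaults to the ladder's drug, else the first
#'   configured drug.
#' @return an unnormalized [plate_table()]; the true per-well viabilities are
#'   stored in the `truth` attribute.
#' @export
simulate_single_agent <- function(config, ladder, drug = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(ladder, "dose_ladder"))
  drug <- drug %||% ladder$drug %||% names(config$drugs)[1]
  if (is.null(config$drugs[[drug]])) stop("drug not in config: ", drug)
  cond <- alone_conditions(drug, ladder$doses, "a")
  cond$true_viability <- vapply(ladder$doses, function(x) {
    expected_viability(config, stats::setNames(10^x, drug))
  }, numeric(1))
  assemble_plate_table(config, cond)
}

#' Simulate a combination experiment
#'
#' Dispatches on the design: [two_drug_mixture_plan()] (single-agent arms at
#' full dose plus DEQ mixture arms at volume-reduced doses),
#' [bliss_band_plan()] / [bliss_matrix_plan()] (full-dose combinations plus
#' the single-agent margins every Bliss grid point needs), or
#' [three_drug_design()] (three single agents, the 1:1 pseudo-drug pair, and
#' the three-drug mixes). Expected viabilities come from
#' [expected_viability()] under the configured reference model.
#'
#' @param config a [simulation_config()].
#' @param design one of the design objects above.
#' @return an unnormalized [plate_table()] with a `truth` attribute.
#' @export
simulate_combination <- function(config, design) {
  stopifnot(inherits(config, "simulation_config"))
  UseMethod("simulate_combination", design)
}

#' @export
simulate_combination.mixture_plan <- function(config, design) {
  a <- design$drug_a; b <- design$drug_b
  cond_a <- alone_conditions(a, design$ladder_a$doses, "a")
  cond_b <- alone_conditions(b, design$ladder_b$doses, "b")
  mix <- lapply(design$mixtures, function(m) {
    cd <- m$component_doses
    df <- data.frame(
      drug_a = a, log_dose_a = cd$log_dose_a,
      drug_b = b, log_dose_b = cd$log_dose_b,
      drug_c = NA_character_, log_dose_c = NA_real_,
      ratio_label = m$ratio_label, stringsAsFactors = FALSE
    )
    df$.delivered_a <- cd$delivered_a
    df$.delivered_b <- cd$delivered_b
    df
  })
  cond_a$.delivered_a <- 10^cond_a$log_dose_a
  cond_a$.delivered_b <- 0
  cond_b$.delivered_a <- 0
  cond_b$.delivered_b <- 10^cond_b$log_dose_b
  cond <- rbind(cond_a, cond_b, do.call(rbind, mix))
  cond$true_viability <- vapply(seq_len(nrow(cond)), function(i) {
    expected_viability(config, stats::setNames(
      c(cond$.delivered_a[i], cond$.delivered_b[i]), c(a, b)))
  }, numeric(1))
  cond$.delivered_a <- NULL
  cond$.delivered_b <- NULL
  assemble_plate_table(config, cond)
}

two_drug_fulldose_conditions <- function(config, design, pairs) {
  a <- design$drug_a; b <- design$drug_b
  doses_a <- sort(unique(pairs$log_dose_a))
  doses_b <- sort(unique(pairs$log_dose_b))
  cond_a <- alone_conditions(a, doses_a, "a")
  cond_b <- alone_conditions(b, doses_b, "b")
  combo <- data.frame(
    drug_a = a, log_dose_a = pairs$log_dose_a,
    drug_b = b, log_dose_b = pairs$log_dose_b,
    drug_c = NA_character_, log_dose_c = NA_real_,
    ratio_label = pairs$ratio_label, stringsAsFactors = FALSE
  )
  cond <- rbind(cond_a, cond_b, combo)
  cond$true_viability <- vapply(seq_len(nrow(cond)), function(i) {
    d <- c(if (!is.na(cond$log_dose_a[i])) 10^cond$log_dose_a[i] else 0,
           if (!is.na(cond$log_dose_b[i])) 10^cond$log_dose_b[i] else 0)
    expected_viability(config, stats::setNames(d, c(a, b)))
  }, numeric(1))
  cond
}

#' @export
simulate_combination.band_plan <- function(config, design) {
  pairs <- do.call(rbind, lapply(names(design$bands), function(lbl) {
    cbind(design$bands[[lbl]], ratio_label = lbl, stringsAsFactors = FALSE)
  }))
  assemble_plate_table(config,
                       two_drug_fulldose_conditions(config, design, pairs))
}

#' @export
simulate_combination.matrix_plan <- function(config, design) {
  pairs <- cbind(design$grid, ratio_label = "matrix", stringsAsFactors = FALSE)
  assemble_plate_table(config,
                       two_drug_fulldose_conditions(config, design, pairs))
}

#' @export
simulate_combination.three_drug_design <- function(config, design) {
  a <- design$pair[1]; b <- design$pair[2]; cc <- design$third
  la <- design$ladder_a$doses; lb <- design$ladder_b$doses
  lc <- design$ladder_c$doses
  n <- length(la)

  cond_a <- alone_conditions(a, la, "a")
  cond_b <- alone_conditions(b, lb, "b")
  cond_c <- alone_conditions(cc, lc, "c")
  add_delivered <- function(df, da, db, dc) {
    df$.da <- da; df$.db <- db; df$.dc <- dc; df
  }
  cond_a <- add_delivered(cond_a, 10^la, 0, 0)
  cond_b <- add_delivered(cond_b, 0, 10^lb, 0)
  cond_c <- add_delivered(cond_c, 0, 0, 10^lc)

  pair_df <- data.frame(
    drug_a = a, log_dose_a = la, drug_b = b, log_dose_b = lb,
    drug_c = NA_character_, log_dose_c = NA_real_,
    ratio_label = "1:1", stringsAsFactors = FALSE
  )
  pair_df <- add_delivered(pair_df, 0.5 * 10^la, 0.5 * 10^lb, 0)

  mixes <- lapply(seq_len(nrow(design$mixes)), function(i) {
    mx <- design$mixes[i, ]
    df <- data.frame(
      drug_a = a, log_dose_a = la, drug_b = b, log_dose_b = lb,
      drug_c = cc, log_dose_c = lc,
      ratio_label = mx$label, stringsAsFactors = FALSE
    )
    add_delivered(df, mx$vol_a / 100 * 10^la, mx$vol_b / 100 * 10^lb,
                  mx$vol_c / 100 * 10^lc)
  })

  cond <- rbind(cond_a, cond_b, cond_c, pair_df, do.call(rbind, mixes))
  cond$true_viability <- vapply(seq_len(nrow(cond)), function(i) {
    expected_viability(config, stats::setNames(
      c(cond$.da[i], cond$.db[i], cond$.dc[i]), c(a, b, cc)))
  }, numeric(1))
  cond$.da <- NULL; cond$.db <- NULL; cond$.dc <- NULL
  assemble_plate_table(config, cond)
}
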