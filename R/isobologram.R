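# Loewe-additivity isobologram analysis.
#
# Each DEQ mixture's dose-response is fit on each drug's NOMINAL ladder axis;
# the fitted EC50 is then multiplied by that drug's volume fraction to give
# its contribution to the mixture EC50 (equivalent to fitting on delivered
# dose). The Combination Index sums the fractional contributions relative to
# the single-agent EC50s; on the isobologram plot the pair
# (contrib_a / EC50_a_alone, contrib_b / EC50_b_alone) is one point, and the
# straight isobole x + y = 1 is the additivity reference.

#' Volume-fraction correction of a mixture EC50
#'
#' A mixture curve fit on drug X's nominal ladder axis overstates how much of
#' X was delivered: a 4:1 mixture is only 80% drug A, so drug A's fitted
#' mixture EC50 is multiplied by 0.8 to obtain its contribution to the
#' overall mixture EC50.
#'
#' @param mixture_fit_ec50 EC50 (molar) fit on the nominal dose axis.
#' @param fraction volume fraction of the drug in the mixture, in (0, 1].
#' @return the fraction-corrected EC50 contribution (molar).
#' @examples
#' fractional_ec50(0.84e-9, 0.8)  # 0.672 nM, prints as 0.67
#' @export
fractional_ec50 <- function(mixture_fit_ec50, fraction) {
  if (any(mixture_fit_ec50 <= 0)) stop("EC50 must be positive")
  if (any(fraction <= 0 | fraction > 1)) {
    stop("fraction must be in (0, 1]")
  }
  fraction * mixture_fit_ec50
}

#' Combination Index of a two-drug mixture
#'
#' \deqn{CI = \frac{EC_{50,A,mix}}{EC_{50,A,alone}} +
#'            \frac{EC_{50,B,mix}}{EC_{50,B,alone}}}
#' where the numerators are the fraction-corrected contributions of each drug
#' to the mixture EC50. CI is symmetric in the two drugs and invariant to a
#' common change of units per drug.
#'
#' @param contrib_a,contrib_b fraction-corrected contributions (molar).
#' @param ec50_a_alone,ec50_b_alone single-agent EC50s (molar).
#' @return the Combination Index (dimensionless, > 0).
#' @examples
#' combination_index(0.46e-9, 0.54e-6, 2.62e-9, 1.82e-6)  # 0.472
#' @export
combination_index <- function(contrib_a, contrib_b,
                              ec50_a_alone, ec50_b_alone) {
  if (any(ec50_a_alone <= 0) || any(ec50_b_alone <= 0)) {
    stop("single-agent EC50s must be positive")
  }
  if (any(contrib_a < 0) || any(contrib_b < 0)) {
    stop("contributions must be nonnegative")
  }
  contrib_a / ec50_a_alone + contrib_b / ec50_b_alone
}

#' Classify a Combination Index
#'
#' CI below `synergy_cutoff` is synergy, above `antagonism_cutoff` is
#' antagonism, and the closed band between them (boundaries included) is
#' additive.
#'
#' @param ci Combination Index values (> 0).
#' @param synergy_cutoff,antagonism_cutoff class boundaries
#'   (defaults 0.8 and 1.2).
#' @return factor with levels `synergy`, `additive`, `antagonism`.
#' @export
classify_ci <- function(ci, synergy_cutoff = 0.8, antagonism_cutoff = 1.2) {
  if (any(ci <= 0)) stop("CI must be positive")
  cls <- ifelse(ci < synergy_cutoff, "synergy",
                ifelse(ci > antagonism_cutoff, "antagonism", "additive"))
  factor(cls, levels = c("synergy", "additive", "antagonism"))
}

fit_axis <- function(rows, axis_col, drug, control) {
  fit_4pl(rows[[axis_col]], rows$viability, drug = drug, control = control)
}

# core of analyze_isobologram on one table subset
isobologram_core <- function(table, plan, control, override_gate,
                             synergy_cutoff, antagonism_cutoff, gate_options) {
  df <- as.data.frame(table)
  a <- plan$drug_a; b <- plan$drug_b

  alone_a <- df[df$ratio_label == "alone" & !is.na(df$drug_a) &
                  df$drug_a == a & is.na(df$log_dose_b), ]
  alone_b <- df[df$ratio_label == "alone" & !is.na(df$drug_b) &
                  df$drug_b == b & is.na(df$log_dose_a), ]
  if (nrow(alone_a) == 0) stop("missing single-agent arm for drug: ", a)
  if (nrow(alone_b) == 0) stop("missing single-agent arm for drug: ", b)
  fit_a <- fit_axis(alone_a, "log_dose_a", a, control)
  fit_b <- fit_axis(alone_b, "log_dose_b", b, control)

  gate <- do.call(parallelism_gate, c(list(fit_a, fit_b), gate_options))
  if (!gate$suitable_for_isobologram && !override_gate) {
    stop("drug pair unsuitable for linear isobologram analysis (",
         gate$reason, "); consider Bliss independence analysis instead, ",
         "or set override_gate = TRUE")
  }

  per_ratio <- lapply(plan$mixtures, function(m) {
    rows <- df[df$ratio_label == m$ratio_label, ]
    if (nrow(rows) == 0) stop("missing mixture arm for ratio: ", m$ratio_label)
    mix_fit_a <- fit_axis(rows, "log_dose_a", a, control)
    mix_fit_b <- fit_axis(rows, "log_dose_b", b, control)
    if (!mix_fit_a$converged || !mix_fit_b$converged) {
      stop("mixture dose-response fit did not converge for ratio: ",
           m$ratio_label)
    }
    contrib_a <- fractional_ec50(mix_fit_a$ec50, m$fraction_a)
    contrib_b <- fractional_ec50(mix_fit_b$ec50, m$fraction_b)
    ci <- combination_index(contrib_a, contrib_b, fit_a$ec50, fit_b$ec50)
    data.frame(
      ratio_label = m$ratio_label,
      fraction_a = m$fraction_a, fraction_b = m$fraction_b,
      mixture_ec50_a = mix_fit_a$ec50, mixture_ec50_b = mix_fit_b$ec50,
      contrib_a = contrib_a, contrib_b = contrib_b,
      isobole_x = contrib_a / fit_a$ec50, isobole_y = contrib_b / fit_b$ec50,
      ci = ci,
      synergy_class = as.character(
        classify_ci(ci, synergy_cutoff, antagonism_cutoff)),
      stringsAsFactors = FALSE
    )
  })
  ratios <- do.call(rbind, per_ratio)
  rownames(ratios) <- NULL

  structure(
    list(
      drug_a = a, drug_b = b,
      fit_a = fit_a, fit_b = fit_b,
      ec50_a_alone = fit_a$ec50, ec50_b_alone = fit_b$ec50,
      gate = gate, ratios = ratios,
      ci_mean = mean(ratios$ci), ci_sd = stats::sd(ratios$ci),
      synergy_cutoff = synergy_cutoff, antagonism_cutoff = antagonism_cutoff
    ),
    class = "isobologram_result"
  )
}

#' Loewe-additivity isobologram analysis of a DEQ mixture experiment
#'
#' Fits the single-agent curves, gates the pair for linear isobologram
#' suitability ([parallelism_gate()]), then for every mixture ratio fits one
#' curve per drug's nominal dose axis, applies the volume-fraction
#' correction, and computes the Combination Index, synergy class, and
#' isobole point.
#'
#' @param table a normalized [plate_table()] containing `"alone"` arms for
#'   both drugs and one arm per mixture ratio in the plan.
#' @param plan a [two_drug_mixture_plan()].
#' @param control fit control list passed to [fit_4pl()].
#' @param override_gate proceed despite a failing parallelism gate.
#' @param by_experiment if `TRUE`, run the analysis separately per
#'   experiment and additionally return the per-experiment CI summary
#'   (mean +/- sd across experiments per ratio).
#' @param synergy_cutoff,antagonism_cutoff CI class boundaries.
#' @param gate_options named list of arguments for [parallelism_gate()].
#' @return object of class `isobologram_result`: single-agent fits and
#'   EC50s, the gate verdict, a `ratios` data frame (mixture EC50s per axis,
#'   fraction-corrected contributions, isobole points, CI, synergy class),
#'   and the CI mean/sd across ratios. With `by_experiment = TRUE` also
#'   `by_experiment` (per-experiment results) and `experiment_summary`.
#' @export
analyze_isobologram <- function(table, plan, control = list(),
                                override_gate = FALSE,
                                by_experiment = FALSE,
                                synergy_cutoff = 0.8,
                                antagonism_cutoff = 1.2,
                                gate_options = list()) {
  stopifnot(inherits(table, "plate_table"), inherits(plan, "mixture_plan"))
  if (!isTRUE(attr(table, "normalized"))) {
    stop("table must be normalized first (see normalize_viability)")
  }
  res <- isobologram_core(table, plan, control, override_gate,
                          synergy_cutoff, antagonism_cutoff, gate_options)
  if (by_experiment) {
    exps <- sort(unique(table$experiment))
    per <- lapply(exps, function(e) {
      sub <- table[table$experiment == e, ]
      attr(sub, "normalized") <- TRUE
      class(sub) <- c("plate_table", "data.frame")
      isobologram_core(sub, plan, control, override_gate = TRUE,
                       synergy_cutoff, antagonism_cutoff, gate_options)
    })
    names(per) <- paste0("experiment_", exps)
    ci_mat <- do.call(cbind, lapply(per, function(r) r$ratios$ci))
    res$by_experiment <- per
    res$experiment_summary <- data.frame(
      ratio_label = res$ratios$ratio_label,
      ci_mean = rowMeans(ci_mat),
      ci_sd = apply(ci_mat, 1, stats::sd)
    )
  }
  res
}

#' @export
print.isobologram_result <- function(x, ...) {
  cat(sprintf("Isobologram analysis: %s + %s\n", x$drug_a, x$drug_b))
  cat(sprintf("  alone EC50s: %s = %.3g M, %s = %.3g M\n",
              x$drug_a, x$ec50_a_alone, x$drug_b, x$ec50_b_alone))
  cat("  gate:", x$gate$reason, "\n")
  print(x$ratios[, c("ratio_label", "contrib_a", "contrib_b",
                     "ci", "synergy_class")], row.names = FALSE)
  cat(sprintf("  CI across ratios: %.3f +/- %.3f\n", x$ci_mean, x$ci_sd))
  invisible(x)
}
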