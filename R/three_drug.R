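# Three-drug vertical-inhibition analysis.
#
# A 1:1 DEQ two-drug mixture is treated as a single pseudo-drug and the
# third drug is combined with it at dose-equivalent ratios. Two CI families
# are reported per mix: the CI of the third drug against the pseudo-drug
# (the 50:50 pair plays the role of a single agent), and the independent CI
# summing all three single-drug contributions. The pseudo-drug has no single
# molar concentration; its dose axis is the nominal ladder of the first pair
# component, reported alongside both component doses.

#' Design a three-drug dose-equivalent experiment
#'
#' The two `pair` drugs are mixed 1:1 (50/50 volumes) as the pseudo-drug;
#' the `third` drug joins at the three printed volume triples per 100 uL:
#' `(1+1):1` = 33/33/34, `(1+1):2` = 25/25/50, `(1+1):4` = 17/17/66.
#'
#' @param pair character vector of the two pseudo-drug component labels.
#' @param third label of the third drug.
#' @param ladder_a,ladder_b,ladder_c [build_ladder()] objects for the two
#'   pair components and the third drug (equal lengths).
#' @return object of class `three_drug_design` with the `mixes` volume table.
#' @export
three_drug_design <- function(pair, third, ladder_a, ladder_b, ladder_c) {
  stopifnot(length(pair) == 2, length(third) == 1,
            inherits(ladder_a, "dose_ladder"),
            inherits(ladder_b, "dose_ladder"),
            inherits(ladder_c, "dose_ladder"))
  if (length(unique(c(length(ladder_a$doses), length(ladder_b$doses),
                      length(ladder_c$doses)))) != 1) {
    stop("ladders must have the same number of points")
  }
  mixes <- data.frame(
    label = c("(1+1):1", "(1+1):2", "(1+1):4"),
    vol_a = c(33, 25, 17),
    vol_b = c(33, 25, 17),
    vol_c = c(34, 50, 66),
    stringsAsFactors = FALSE
  )
  stopifnot(all(rowSums(mixes[, c("vol_a", "vol_b", "vol_c")]) == 100))
  structure(
    list(pair = pair, third = third, mixes = mixes,
         ladder_a = ladder_a, ladder_b = ladder_b, ladder_c = ladder_c),
    class = "three_drug_design"
  )
}

#' Combination Index of a third drug versus a 1:1 pair pseudo-drug
#'
#' \deqn{CI = \frac{EC_{50,pair,3drug}}{EC_{50,pair,50:50}} +
#'            \frac{EC_{50,third,3drug}}{EC_{50,third,alone}}}
#' Contributions are fraction-corrected exactly as in the two-drug case: the
#' pair fraction is its combined volume / 100, the third drug's its volume /
#' 100.
#'
#' @param pair_contrib fraction-corrected pair contribution, on the pair's
#'   DEQ axis.
#' @param pair_ec50_5050 EC50 of the 50:50 pair alone on the same axis.
#' @param third_contrib fraction-corrected third-drug contribution (molar).
#' @param third_ec50_alone single-agent EC50 of the third drug (molar).
#' @return Combination Index (dimensionless).
#' @export
three_drug_ci_vs_pair <- function(pair_contrib, pair_ec50_5050,
                                  third_contrib, third_ec50_alone) {
  if (any(pair_ec50_5050 <= 0) || any(third_ec50_alone <= 0)) {
    stop("denominator EC50s must be positive")
  }
  pair_contrib / pair_ec50_5050 + third_contrib / third_ec50_alone
}

#' Independent three-drug Combination Index
#'
#' Sum of the three contribution / alone-EC50 ratios, each drug's
#' contribution being its volume fraction times the mixture EC50 on its
#' nominal axis. Symmetric under permutation of the drugs.
#'
#' @param contribs numeric vector of three fraction-corrected contributions.
#' @param alone_ec50s numeric vector of the three single-agent EC50s.
#' @return Combination Index (dimensionless).
#' @export
three_drug_ci_independent <- function(contribs, alone_ec50s) {
  stopifnot(length(contribs) == length(alone_ec50s))
  if (any(alone_ec50s <= 0)) stop("alone EC50s must be positive")
  sum(contribs / alone_ec50s)
}

#' Analyze a three-drug dose-equivalent experiment
#'
#' Fits the three single-agent curves, the 50:50 pair baseline as a
#' pseudo-drug (on the first pair component's nominal axis), and each
#' three-drug mix on every nominal axis; then reports, per mix, the CI
#' versus the pair and the independent three-way CI, plus isobole points
#' with the pair on one axis and the third drug on the other. Any required
#' fit that fails to converge (e.g. an inert third drug with a flat
#' dose-response) aborts with an error naming the arm rather than reporting
#' a CI.
#'
#' @param table a normalized [plate_table()] with all arms of the design.
#' @param design a [three_drug_design()].
#' @param control fit control list passed to [fit_4pl()].
#' @param independent_denominator `"alone"` (default) uses all three
#'   single-agent EC50s as denominators of the independent CI;
#'   `"pair_5050"` substitutes, for the first pair component, its EC50
#'   measured from the 50:50 pair arm on its own axis.
#' @return object of class `three_drug_result`: per-mix data frame with both
#'   CI families and isobole points, the pseudo-drug baseline EC50, and the
#'   underlying fits.
#' @export
analyze_three_drug <- function(table, design, control = list(),
                               independent_denominator = c("alone",
                                                           "pair_5050")) {
  stopifnot(inherits(table, "plate_table"),
            inherits(design, "three_drug_design"))
  independent_denominator <- match.arg(independent_denominator)
  if (!isTRUE(attr(table, "normalized"))) {
    stop("table must be normalized first (see normalize_viability)")
  }
  df <- as.data.frame(table)
  a <- design$pair[1]; b <- design$pair[2]; cc <- design$third

  need_fit <- function(rows, axis, label) {
    if (nrow(rows) == 0) stop("missing arm: ", label)
    fit <- fit_axis(rows, axis, label, control)
    if (!fit$converged) {
      stop("dose-response fit did not converge for arm: ", label,
           "; cannot report a Combination Index")
    }
    fit
  }

  alone <- function(drug, slot) {
    col <- paste0("drug_", slot)
    other <- setdiff(c("log_dose_a", "log_dose_b", "log_dose_c"),
                     paste0("log_dose_", slot))
    rows <- df[df$ratio_label == "alone" & !is.na(df[[col]]) &
                 df[[col]] == drug &
                 is.na(df[[other[1]]]) & is.na(df[[other[2]]]), ]
    need_fit(rows, paste0("log_dose_", slot), paste(drug, "alone"))
  }
  fit_a <- alone(a, "a")
  fit_b <- alone(b, "b")
  fit_c <- alone(cc, "c")

  pair_rows <- df[df$ratio_label == "1:1" & !is.na(df$log_dose_a) &
                    !is.na(df$log_dose_b) & is.na(df$log_dose_c), ]
  fit_pair_a <- need_fit(pair_rows, "log_dose_a",
                         paste0(a, "+", b, " 50:50 pair"))
  fit_pair_b <- need_fit(pair_rows, "log_dose_b",
                         paste0(a, "+", b, " 50:50 pair (", b, " axis)"))

  per_mix <- lapply(seq_len(nrow(design$mixes)), function(i) {
    mx <- design$mixes[i, ]
    rows <- df[df$ratio_label == mx$label, ]
    fit_mix_a <- need_fit(rows, "log_dose_a", paste(mx$label, "mix,", a, "axis"))
    fit_mix_b <- need_fit(rows, "log_dose_b", paste(mx$label, "mix,", b, "axis"))
    fit_mix_c <- need_fit(rows, "log_dose_c", paste(mx$label, "mix,", cc, "axis"))

    pair_fraction <- (mx$vol_a + mx$vol_b) / 100
    third_fraction <- mx$vol_c / 100
    # the pair's mixture EC50 on its DEQ axis is the a-axis fit
    pair_contrib <- fractional_ec50(fit_mix_a$ec50, pair_fraction)
    third_contrib <- fractional_ec50(fit_mix_c$ec50, third_fraction)
    ci_pair <- three_drug_ci_vs_pair(pair_contrib, fit_pair_a$ec50,
                                     third_contrib, fit_c$ec50)

    contribs <- c(fractional_ec50(fit_mix_a$ec50, mx$vol_a / 100),
                  fractional_ec50(fit_mix_b$ec50, mx$vol_b / 100),
                  third_contrib)
    denoms <- c(if (independent_denominator == "pair_5050") fit_pair_a$ec50
                else fit_a$ec50,
                fit_b$ec50, fit_c$ec50)
    ci_indep <- three_drug_ci_independent(contribs, denoms)

    data.frame(
      label = mx$label,
      pair_fraction = pair_fraction, third_fraction = third_fraction,
      pair_mixture_ec50 = fit_mix_a$ec50, pair_contrib = pair_contrib,
      third_mixture_ec50 = fit_mix_c$ec50, third_contrib = third_contrib,
      isobole_x = pair_contrib / fit_pair_a$ec50,
      isobole_y = third_contrib / fit_c$ec50,
      ci_vs_pair = ci_pair, ci_independent = ci_indep,
      stringsAsFactors = FALSE
    )
  })
  mixes <- do.call(rbind, per_mix)
  rownames(mixes) <- NULL

  structure(
    list(pair = design$pair, third = cc,
         baseline_pair_ec50 = fit_pair_a$ec50,
         alone_ec50s = c(fit_a$ec50, fit_b$ec50, fit_c$ec50),
         fits = list(alone_a = fit_a, alone_b = fit_b, alone_c = fit_c,
                     pair_a_axis = fit_pair_a, pair_b_axis = fit_pair_b),
         mixes = mixes,
         independent_denominator = independent_denominator),
    class = "three_drug_result"
  )
}

#' @export
print.three_drug_result <- function(x, ...) {
  cat(sprintf("Three-drug analysis: [%s + %s] 1:1 pair vs %s\n",
              x$pair[1], x$pair[2], x$third))
  cat(sprintf("  pair baseline EC50 (on %s axis): %.3g M\n",
              x$pair[1], x$baseline_pair_ec50))
  print(x$mixes[, c("label", "ci_vs_pair", "ci_independent")],
        row.names = FALSE)
  invisible(x)
}
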