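# Bliss independence analysis.
#
# Viability is converted to a probabilistic effect in [0, 1] (0 = no effect,
# 1 = no viable cells). If two drugs act independently the expected combined
# effect is E_A + E_B - E_A*E_B; the Bliss Index is expected/actual (< 1
# indicates synergy; the operational heatmap cutoff is 0.85) and the excess
# over Bliss is 100 * (actual - expected) percentage points. Unlike the
# isobologram design, combinations use FULL doses of both drugs.

#' Convert viability to drug effect
#'
#' `effect = 1 - viability`, clipped to [0, 1]: a well noisier than the
#' untreated reference (viability > 1) has effect 0, never a negative
#' effect.
#'
#' @param viability nonnegative normalized viabilities.
#' @return effects in [0, 1].
#' @export
effect_from_viability <- function(viability) {
  if (any(!is.finite(viability)) || any(viability < 0)) {
    stop("viability must be finite and nonnegative")
  }
  clip01(1 - viability)
}

check_effect <- function(e, what) {
  if (any(!is.finite(e)) || any(e < 0 | e > 1)) {
    stop(what, " must be in [0, 1]")
  }
}

#' Expected effect under Bliss independence
#'
#' @param e_a,e_b single-agent effects in [0, 1].
#' @return `e_a + e_b - e_a * e_b`, in [0, 1].
#' @export
expected_bliss <- function(e_a, e_b) {
  check_effect(e_a, "e_a"); check_effect(e_b, "e_b")
  e_a + e_b - e_a * e_b
}

#' Bliss Index
#'
#' Ratio of the Bliss-expected effect to the observed mixture effect.
#' 1 means the drugs combine exactly as independent events; < 1 indicates
#' synergy. Undefined (returned as `NA`) when the observed mixture effect is
#' zero; such cells are excluded from summaries rather than raising errors.
#'
#' @param e_a,e_b single-agent effects in [0, 1].
#' @param e_mix observed mixture effect in [0, 1].
#' @return `(e_a + e_b - e_a*e_b) / e_mix`, or `NA` where `e_mix` is 0.
#' @export
bliss_index <- function(e_a, e_b, e_mix) {
  check_effect(e_mix, "e_mix")
  expected <- expected_bliss(e_a, e_b)
  ifelse(e_mix == 0, NA_real_, expected / e_mix)
}

#' Excess over Bliss
#'
#' `100 * (observed - expected)` in percentage points: positive values
#' indicate synergy, negative antagonism, 0 exact independence.
#'
#' @inheritParams bliss_index
#' @return excess over Bliss in percentage points.
#' @export
excess_over_bliss <- function(e_a, e_b, e_mix) {
  check_effect(e_mix, "e_mix")
  100 * (e_mix - expected_bliss(e_a, e_b))
}

#' Bliss independence analysis over a dose matrix or DEQ bands
#'
#' Averages replicate viabilities per condition (across technical replicates
#' and experiments), converts them to effects, and scores every combination
#' well against its two single-agent marginals: expected effect, Bliss
#' Index, excess over Bliss, and a synergy call (`BI < threshold`). Works on
#' a full factorial checkerboard or any subset of dose pairs (e.g. the three
#' DEQ bands), as long as each combination's marginal single-agent doses are
#' present in the table.
#'
#' @param table a normalized [plate_table()] with single-agent rows for both
#'   drugs and combination rows.
#' @param threshold Bliss Index below which a cell is called synergistic
#'   (default 0.85, the operational heatmap cutoff; BI < 1 is nominal
#'   synergy).
#' @return object of class `bliss_grid`: `cells` (one row per dose pair with
#'   viability, `e_a`, `e_b`, `e_mix`, `expected`, `bliss_index`,
#'   `excess_over_bliss`, `synergy`), the marginal dose axes with their
#'   single-agent effects, and — when the pairs form a complete factorial —
#'   matrices (`viability`, `effect`, `expected`, `bliss_index`, `excess`,
#'   `synergy`) with rendered doses as dimnames (rows: drug A, columns:
#'   drug B).
#' @export
analyze_bliss_matrix <- function(table, threshold = 0.85) {
  stopifnot(inherits(table, "plate_table"))
  if (!isTRUE(attr(table, "normalized"))) {
    stop("table must be normalized first (see normalize_viability)")
  }
  df <- as.data.frame(table)
  df <- df[df$ratio_label != "untreated", ]
  key <- paste(dose_key(df$log_dose_a), dose_key(df$log_dose_b), sep = "|")
  mean_v <- tapply(df$viability, key, mean)
  first <- !duplicated(key)
  cond <- data.frame(
    log_dose_a = df$log_dose_a[first], log_dose_b = df$log_dose_b[first],
    viability = as.numeric(mean_v[key[first]]), stringsAsFactors = FALSE
  )

  is_a <- !is.na(cond$log_dose_a) & is.na(cond$log_dose_b)
  is_b <- is.na(cond$log_dose_a) & !is.na(cond$log_dose_b)
  is_mix <- !is.na(cond$log_dose_a) & !is.na(cond$log_dose_b)
  drug_a <- unique(df$drug_a[!is.na(df$drug_a)])[1]
  drug_b <- unique(df$drug_b[!is.na(df$drug_b)])[1]

  e_a_by_dose <- stats::setNames(effect_from_viability(cond$viability[is_a]),
                                 dose_key(cond$log_dose_a[is_a]))
  e_b_by_dose <- stats::setNames(effect_from_viability(cond$viability[is_b]),
                                 dose_key(cond$log_dose_b[is_b]))

  cells <- cond[is_mix, ]
  ka <- dose_key(cells$log_dose_a)
  kb <- dose_key(cells$log_dose_b)
  if (any(!(ka %in% names(e_a_by_dose)))) {
    stop("no single-agent wells for ", drug_a, " at log dose ",
         paste(render_log_dose(unique(
           cells$log_dose_a[!(ka %in% names(e_a_by_dose))])), collapse = ", "))
  }
  if (any(!(kb %in% names(e_b_by_dose)))) {
    stop("no single-agent wells for ", drug_b, " at log dose ",
         paste(render_log_dose(unique(
           cells$log_dose_b[!(kb %in% names(e_b_by_dose))])), collapse = ", "))
  }
  cells$e_a <- as.numeric(e_a_by_dose[ka])
  cells$e_b <- as.numeric(e_b_by_dose[kb])
  cells$e_mix <- effect_from_viability(cells$viability)
  cells$expected <- expected_bliss(cells$e_a, cells$e_b)
  cells$bliss_index <- bliss_index(cells$e_a, cells$e_b, cells$e_mix)
  cells$excess_over_bliss <- excess_over_bliss(cells$e_a, cells$e_b,
                                               cells$e_mix)
  cells$synergy <- !is.na(cells$bliss_index) & cells$bliss_index < threshold
  rownames(cells) <- NULL

  doses_a <- sort(unique(cells$log_dose_a))
  doses_b <- sort(unique(cells$log_dose_b))
  matrices <- NULL
  if (nrow(cells) == length(doses_a) * length(doses_b)) {
    to_mat <- function(col) {
      m <- matrix(NA_real_, length(doses_a), length(doses_b),
                  dimnames = list(render_log_dose(doses_a),
                                  render_log_dose(doses_b)))
      i <- match(dose_key(cells$log_dose_a), dose_key(doses_a))
      j <- match(dose_key(cells$log_dose_b), dose_key(doses_b))
      m[cbind(i, j)] <- cells[[col]]
      m
    }
    matrices <- list(
      viability = to_mat("viability"), effect = to_mat("e_mix"),
      expected = to_mat("expected"), bliss_index = to_mat("bliss_index"),
      excess = to_mat("excess_over_bliss"),
      synergy = to_mat("synergy") > 0
    )
  }

  structure(
    list(drug_a = drug_a, drug_b = drug_b,
         doses_a = doses_a, doses_b = doses_b,
         effect_a = e_a_by_dose, effect_b = e_b_by_dose,
         cells = cells, matrices = matrices, threshold = threshold),
    class = "bliss_grid"
  )
}

#' @export
print.bliss_grid <- function(x, ...) {
  cat(sprintf("Bliss independence analysis: %s x %s (%d combinations)\n",
              x$drug_a, x$drug_b, nrow(x$cells)))
  bi <- x$cells$bliss_index
  cat(sprintf("  Bliss Index: median %.3f, %d/%d cells < %.2f (synergy)\n",
              stats::median(bi, na.rm = TRUE), sum(x$cells$synergy),
              nrow(x$cells), x$threshold))
  cat(sprintf("  excess over Bliss: min %.1f, max %.1f percentage points\n",
              min(x$cells$excess_over_bliss), max(x$cells$excess_over_bliss)))
  invisible(x)
}
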