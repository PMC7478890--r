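# Dose-equivalent (DEQ) design construction.
#
# Doses live on a 1/3-log10 grid anchored at integer log10 molar values.
# Each drug's fitted log EC50 is snapped to the nearest grid point; a 10-point
# ladder is laid out around that anchor (7 points below, 2 above, anchor 8th)
# so both the top and bottom of the curve are represented. DEQ mixtures pair
# ladder points of equal rank across drugs.

# volume fractions for the standard two-drug mixing table
# (per 100 uL total: 80/20, 66/34, 50/50, 34/66, 20/80)
MIXTURE_FRACTIONS <- data.frame(
  ratio_label = c("4:1", "2:1", "1:1", "1:2", "1:4"),
  fraction_a  = c(0.80, 0.66, 0.50, 0.34, 0.20),
  fraction_b  = c(0.20, 0.34, 0.50, 0.66, 0.80),
  stringsAsFactors = FALSE
)

#' Snap a log EC50 to the nearest 1/3-log grid point
#'
#' The grid is the set of integer multiples of `step` log10 units, which for
#' the default 1/3 step contains every integer log10 dose. Ties are broken
#' toward the lower (more negative, i.e. more conservative) dose.
#'
#' @param log_ec50 numeric vector of log10 molar EC50s.
#' @param step grid spacing in log10 units (default 1/3).
#' @return numeric vector of grid points.
#' @examples
#' snap_to_grid(-8.57)  # -8.67
#' snap_to_grid(-5.73)  # -5.67
#' @export
snap_to_grid <- function(log_ec50, step = 1/3) {
  if (!all(is.finite(log_ec50))) stop("log_ec50 must be finite")
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("step must be a single positive number")
  }
  k_lo <- floor(log_ec50 / step)
  k_hi <- ceiling(log_ec50 / step)
  d_lo <- log_ec50 - k_lo * step
  d_hi <- k_hi * step - log_ec50
  # ties (within float fuzz) go to the lower dose
  k <- ifelse(d_lo <= d_hi + 1e-12, k_lo, k_hi)
  k * step
}

#' Build a 10-point DEQ dose ladder around an anchor grid point
#'
#' The ladder spans `anchor - n_below*step` to `anchor + n_above*step` so the
#' anchor (the grid-snapped EC50) sits at position `n_below + 1` — the 8th of
#' 10 points under the defaults, leaving two points above the EC50 to pin the
#' bottom of the curve.
#'
#' @param anchor log10 molar grid point (see [snap_to_grid()]).
#' @param step grid spacing in log10 units.
#' @param n_below,n_above number of ladder points below/above the anchor.
#' @param drug optional drug label carried along for bookkeeping.
#' @return an object of class `dose_ladder`: list with `drug`, `anchor`,
#'   `step`, and `doses` (length `n_below + n_above + 1`, strictly increasing).
#' @examples
#' build_ladder(snap_to_grid(-8.57))$doses  # -11 ... -8
#' @export
build_ladder <- function(anchor, step = 1/3, n_below = 7L, n_above = 2L,
                         drug = NULL) {
  k <- round(anchor / step)
  if (abs(anchor - k * step) > 1e-9) {
    stop("anchor is not on the grid; snap it with snap_to_grid() first")
  }
  doses <- (k + seq.int(-n_below, n_above)) * step
  structure(
    list(drug = drug, anchor = k * step, step = step, doses = doses),
    class = "dose_ladder"
  )
}

#' @export
print.dose_ladder <- function(x, ...) {
  cat("DEQ dose ladder", if (!is.null(x$drug)) paste0("for ", x$drug), "\n")
  cat("  anchor:", render_log_dose(x$anchor),
      " step:", signif(x$step, 4), "log10 units\n")
  cat("  doses: ", paste(render_log_dose(x$doses), collapse = " "), "\n")
  invisible(x)
}

#' Plan two-drug DEQ mixtures at fixed volume ratios
#'
#' At each ladder rank i the mixture delivers `fraction_a` of drug A's full
#' ladder dose and `fraction_b` of drug B's; the nominal per-drug dose axes
#' remain the full ladders, so an additive pair produces an unchanged
#' composite curve. Fractions follow the integer-microliter mixing table
#' (80/66/50/34/20 per 100 uL).
#'
#' @param ladder_a,ladder_b [build_ladder()] objects of equal length.
#' @param ratios subset of `"4:1" "2:1" "1:1" "1:2" "1:4"`.
#' @param drug_a,drug_b drug labels (defaults taken from the ladders).
#' @return object of class `mixture_plan`: drug labels, the two ladders, and
#'   `mixtures`, a named list of specs with `ratio_label`, `fraction_a`,
#'   `fraction_b` and a `component_doses` data frame (nominal log doses and
#'   delivered molar doses per ladder rank).
#' @export
two_drug_mixture_plan <- function(ladder_a, ladder_b,
                                  ratios = c("4:1", "2:1", "1:1", "1:2", "1:4"),
                                  drug_a = NULL, drug_b = NULL) {
  stopifnot(inherits(ladder_a, "dose_ladder"), inherits(ladder_b, "dose_ladder"))
  if (length(ladder_a$doses) != length(ladder_b$doses)) {
    stop("ladders must have the same number of points")
  }
  unknown <- setdiff(ratios, MIXTURE_FRACTIONS$ratio_label)
  if (length(unknown) > 0) {
    stop("unknown ratio label(s): ", paste(unknown, collapse = ", "),
         "; valid labels are: ",
         paste(MIXTURE_FRACTIONS$ratio_label, collapse = ", "))
  }
  drug_a <- drug_a %||% ladder_a$drug %||% "A"
  drug_b <- drug_b %||% ladder_b$drug %||% "B"
  mixtures <- lapply(ratios, function(r) {
    fr <- MIXTURE_FRACTIONS[MIXTURE_FRACTIONS$ratio_label == r, ]
    list(
      ratio_label = r,
      fraction_a = fr$fraction_a,
      fraction_b = fr$fraction_b,
      component_doses = data.frame(
        log_dose_a = ladder_a$doses,
        log_dose_b = ladder_b$doses,
        delivered_a = fr$fraction_a * 10^ladder_a$doses,
        delivered_b = fr$fraction_b * 10^ladder_b$doses
      )
    )
  })
  names(mixtures) <- ratios
  structure(
    list(drug_a = drug_a, drug_b = drug_b,
         ladder_a = ladder_a, ladder_b = ladder_b, mixtures = mixtures),
    class = "mixture_plan"
  )
}

#' Plan the three dose-equivalent bands for Bliss analysis
#'
#' Bliss independence uses full doses of both drugs (no volume reduction).
#' The 1:1 band pairs equal ladder ranks; the 2:1 band shifts drug A's doses
#' up one grid step and the 1:2 band shifts them down one step, while drug B's
#' doses are held constant.
#'
#' @inheritParams two_drug_mixture_plan
#' @return object of class `band_plan` with `bands`: a named list
#'   (`"1:2"`, `"1:1"`, `"2:1"`) of data frames with `log_dose_a`,
#'   `log_dose_b` columns.
#' @export
bliss_band_plan <- function(ladder_a, ladder_b, drug_a = NULL, drug_b = NULL) {
  stopifnot(inherits(ladder_a, "dose_ladder"), inherits(ladder_b, "dose_ladder"))
  shift <- function(s) (round(ladder_a$doses / ladder_a$step) + s) * ladder_a$step
  bands <- list(
    "1:2" = data.frame(log_dose_a = shift(-1L), log_dose_b = ladder_b$doses),
    "1:1" = data.frame(log_dose_a = shift(0L),  log_dose_b = ladder_b$doses),
    "2:1" = data.frame(log_dose_a = shift(1L),  log_dose_b = ladder_b$doses)
  )
  structure(
    list(drug_a = drug_a %||% ladder_a$drug %||% "A",
         drug_b = drug_b %||% ladder_b$drug %||% "B",
         ladder_a = ladder_a, ladder_b = ladder_b, bands = bands),
    class = "band_plan"
  )
}

#' Plan a full factorial dose matrix for Bliss analysis
#'
#' Every pairwise combination of the two ladders at full dose (the 10 x 10
#' checkerboard), plus the single-agent margins.
#'
#' @inheritParams two_drug_mixture_plan
#' @return object of class `matrix_plan` with `grid`: a data frame of all
#'   dose pairs.
#' @export
bliss_matrix_plan <- function(ladder_a, ladder_b, drug_a = NULL, drug_b = NULL) {
  stopifnot(inherits(ladder_a, "dose_ladder"), inherits(ladder_b, "dose_ladder"))
  grid <- expand.grid(log_dose_a = ladder_a$doses, log_dose_b = ladder_b$doses,
                      KEEP.OUT.ATTRS = FALSE)
  structure(
    list(drug_a = drug_a %||% ladder_a$drug %||% "A",
         drug_b = drug_b %||% ladder_b$drug %||% "B",
         ladder_a = ladder_a, ladder_b = ladder_b, grid = grid),
    class = "matrix_plan"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
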