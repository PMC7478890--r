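# Four-parameter logistic (variable-slope) dose-response fitting.

#' Four-parameter logistic viability curve
#'
#' `viability_4pl()` evaluates
#' \deqn{v(x) = bottom + \frac{top - bottom}{1 + 10^{hill (x - ec50)}}}
#' where `x` is log10 molar dose. With `hill > 0` viability decreases with
#' dose (an inhibitor); at `x = log_ec50` the response is exactly
#' `(top + bottom) / 2`.
#'
#' @param log_dose numeric vector of log10 molar doses.
#' @param top,bottom upper/lower viability asymptotes (untreated viability is
#'   1 by normalization, so `top` is near 1).
#' @param log_ec50 log10 molar dose of half-maximal effect.
#' @param hill Hill slope (dimensionless, positive for inhibitors).
#' @return numeric vector of viabilities.
#' @export
viability_4pl <- function(log_dose, top, bottom, log_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log_dose - log_ec50)))
}

# molar dose at which the single-agent curve reaches viability v
# (defined for v strictly between bottom and top)
inverse_4pl <- function(v, top, bottom, log_ec50, hill) {
  10^(log_ec50 + log10((top - v) / (v - bottom)) / hill)
}

default_fit_control <- function() {
  list(
    n_starts = 5L,
    top_bounds = c(0.5, 1.5),
    bottom_bounds = c(-0.1, 1.0),
    hill_bounds = c(0.05, 20),
    ec50_margin = 2,      # optimizer box beyond the dose range, log10 units
    converged_margin = 1  # log_ec50 within dose range +/- this, else flagged
  )
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of [viability_4pl()] by Levenberg-Marquardt
#' (`minpack.lm::nlsLM`) with box constraints and multi-start initialization:
#' `log_ec50` starting points are spread across the observed dose range and
#' the best residual sum of squares wins. All replicate points are fit
#' jointly (unweighted). A fit whose optimizer fails everywhere, or whose
#' `log_ec50` lands outside the dose range plus `converged_margin`, is
#' returned with `converged = FALSE` rather than failing silently.
#'
#' @param log_dose numeric vector of log10 molar doses (>= 5 distinct values).
#' @param viability numeric vector of normalized viabilities, same length.
#' @param drug optional drug label stored on the fit.
#' @param control optional list overriding entries of the default control
#'   (`n_starts`, `top_bounds`, `bottom_bounds`, `hill_bounds`,
#'   `ec50_margin`, `converged_margin`).
#' @return object of class `dr_fit`: `drug`, `top`, `bottom`, `log_ec50`,
#'   `hill`, `ec50` (molar), `rss`, `n_points`, `converged`, and the fitting
#'   data.
#' @examples
#' lad <- build_ladder(-8 - 2/3)
#' v <- viability_4pl(lad$doses, 1, 0, -8 - 2/3, 1)
#' fit_4pl(lad$doses, v)
#' @export
fit_4pl <- function(log_dose, viability, drug = NULL, control = list()) {
  ctl <- utils::modifyList(default_fit_control(), control)
  if (length(log_dose) != length(viability)) {
    stop("log_dose and viability must have the same length")
  }
  keep <- is.finite(log_dose) & is.finite(viability)
  x <- log_dose[keep]
  v <- viability[keep]
  if (length(unique(x)) < 5L) {
    stop("need at least 5 distinct doses to fit a four-parameter curve")
  }

  lower <- c(top = ctl$top_bounds[1], bottom = ctl$bottom_bounds[1],
             log_ec50 = min(x) - ctl$ec50_margin, hill = ctl$hill_bounds[1])
  upper <- c(top = ctl$top_bounds[2], bottom = ctl$bottom_bounds[2],
             log_ec50 = max(x) + ctl$ec50_margin, hill = ctl$hill_bounds[2])
  clamp <- function(val, lo, hi) min(max(val, lo), hi)
  top0 <- clamp(max(v), ctl$top_bounds[1], ctl$top_bounds[2])
  bottom0 <- clamp(min(v), ctl$bottom_bounds[1], ctl$bottom_bounds[2])
  ec50_starts <- seq(min(x), max(x), length.out = ctl$n_starts)

  df <- data.frame(x = x, v = v)
  rss_of <- function(p) {
    sum((v - viability_4pl(x, p[1], p[2], p[3], p[4]))^2)
  }

  best <- NULL
  any_ok <- FALSE
  for (e0 in ec50_starts) {
    start <- c(top = top0, bottom = bottom0,
               log_ec50 = clamp(e0, lower[3], upper[3]), hill = 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + 10^(hill * (x - log_ec50))),
        data = df, start = as.list(start),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) next
    p <- stats::coef(fit)[c("top", "bottom", "log_ec50", "hill")]
    r <- rss_of(p)
    any_ok <- TRUE
    if (is.null(best) || r < best$rss) best <- list(par = p, rss = r)
  }

  if (!any_ok) {
    # fall back to bounded quasi-Newton on the same objective
    for (e0 in ec50_starts) {
      start <- c(top0, bottom0, clamp(e0, lower[3], upper[3]), 1)
      opt <- tryCatch(
        stats::optim(start, rss_of, method = "L-BFGS-B",
                     lower = lower, upper = upper),
        error = function(e) NULL
      )
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$rss) {
        best <- list(par = stats::setNames(
          opt$par, c("top", "bottom", "log_ec50", "hill")), rss = opt$value)
        any_ok <- TRUE
      }
    }
  }

  if (is.null(best)) {
    best <- list(par = c(top = top0, bottom = bottom0,
                         log_ec50 = mean(range(x)), hill = 1),
                 rss = rss_of(c(top0, bottom0, mean(range(x)), 1)))
    any_ok <- FALSE
  }

  p <- best$par
  in_window <- p[["log_ec50"]] >= min(x) - ctl$converged_margin &&
    p[["log_ec50"]] <= max(x) + ctl$converged_margin
  # a near-flat response leaves the EC50 unidentified
  identifiable <- (p[["top"]] - p[["bottom"]]) >= 0.1
  structure(
    list(
      drug = drug,
      top = p[["top"]], bottom = p[["bottom"]],
      log_ec50 = p[["log_ec50"]], hill = p[["hill"]],
      ec50 = 10^p[["log_ec50"]],
      rss = best$rss, n_points = length(x),
      converged = any_ok && in_window && identifiable,
      data = df
    ),
    class = "dr_fit"
  )
}

#' @export
coef.dr_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom,
    log_ec50 = object$log_ec50, hill = object$hill)
}

#' Predict viability from a fitted dose-response curve
#'
#' @param object a `dr_fit`.
#' @param log_dose doses at which to predict; defaults to the fitting doses.
#' @param ... unused.
#' @export
predict.dr_fit <- function(object, log_dose = NULL, ...) {
  x <- log_dose %||% object$data$x
  viability_4pl(x, object$top, object$bottom, object$log_ec50, object$hill)
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("4PL dose-response fit", if (!is.null(x$drug)) paste0("for ", x$drug), "\n")
  cat(sprintf("  top = %.4f  bottom = %.4f  log EC50 = %.4f  hill = %.4f\n",
              x$top, x$bottom, x$log_ec50, x$hill))
  cat(sprintf("  EC50 = %.3g M  rss = %.3g  n = %d  converged: %s\n",
              x$ec50, x$rss, x$n_points, x$converged))
  invisible(x)
}

#' Gate a drug pair for linear isobologram suitability
#'
#' Linear (straight-isobole) isobologram analysis assumes approximately
#' parallel dose-response curves with similar maximal effects. The gate
#' passes only when (in this order of reporting) each drug's maximal effect
#' `top - bottom` reaches `min_effect`, the Hill-slope ratio lies within
#' `hill_ratio_bounds`, and the gap between the two maximal effects does not
#' exceed `max_effect_gap`. A drug showing at most a 50% viability reduction
#' at high doses fails the first gate and should be assessed by Bliss
#' independence instead.
#'
#' @param fit_a,fit_b converged `dr_fit` objects.
#' @param hill_ratio_bounds allowed range for `hill_a / hill_b`.
#' @param max_effect_gap allowed absolute difference in maximal effects.
#' @param min_effect minimal maximal effect required of each drug.
#' @return object of class `parallelism_verdict`: `drug_pair`, `hill_ratio`,
#'   `max_effect_gap`, `suitable_for_isobologram`, `reason` (first failing
#'   gate, or `"ok"`).
#' @export
parallelism_gate <- function(fit_a, fit_b,
                             hill_ratio_bounds = c(0.5, 2),
                             max_effect_gap = 0.2,
                             min_effect = 0.5) {
  stopifnot(inherits(fit_a, "dr_fit"), inherits(fit_b, "dr_fit"))
  if (!fit_a$converged || !fit_b$converged) {
    stop("parallelism gate requires converged fits")
  }
  eff_a <- fit_a$top - fit_a$bottom
  eff_b <- fit_b$top - fit_b$bottom
  hill_ratio <- fit_a$hill / fit_b$hill
  gap <- abs(eff_a - eff_b)

  reason <- "ok"
  if (min(eff_a, eff_b) < min_effect) {
    reason <- sprintf("max effect below %.2g (%s)", min_effect,
                      if (eff_a < min_effect && eff_b < min_effect) "both drugs"
                      else if (eff_a < min_effect) "drug A" else "drug B")
  } else if (hill_ratio < hill_ratio_bounds[1] ||
             hill_ratio > hill_ratio_bounds[2]) {
    reason <- sprintf("hill ratio %.3g outside [%.3g, %.3g]", hill_ratio,
                      hill_ratio_bounds[1], hill_ratio_bounds[2])
  } else if (gap > max_effect_gap) {
    reason <- sprintf("max effect gap %.3g exceeds %.3g", gap, max_effect_gap)
  }

  structure(
    list(
      drug_pair = c(fit_a$drug %||% "A", fit_b$drug %||% "B"),
      hill_ratio = hill_ratio,
      max_effect_gap = gap,
      suitable_for_isobologram = identical(reason, "ok"),
      reason = reason
    ),
    class = "parallelism_verdict"
  )
}

#' @export
print.parallelism_verdict <- function(x, ...) {
  cat("Parallelism gate for", paste(x$drug_pair, collapse = " vs "), "\n")
  cat(sprintf("  hill ratio = %.3g  max effect gap = %.3g\n",
              x$hill_ratio, x$max_effect_gap))
  cat("  suitable for isobologram analysis:",
      x$suitable_for_isobologram, paste0("(", x$reason, ")"), "\n")
  invisible(x)
}
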