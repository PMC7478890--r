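# Well-level viability tables: read/write, validation, normalization.
#
# The long CSV format has one row per well:
#   plate_id, well, drug_a, log_dose_a, drug_b, log_dose_b, drug_c,
#   log_dose_c, ratio_label, technical_rep, experiment, luminescence
# Doses are log10 molar; an absent/untreated dose is an empty cell (NA),
# never -Inf. Untreated wells carry ratio_label "untreated" and no doses.

PLATE_COLUMNS <- c("plate_id", "well", "drug_a", "log_dose_a",
                   "drug_b", "log_dose_b", "drug_c", "log_dose_c",
                   "ratio_label", "technical_rep", "experiment",
                   "luminescence")

#' Construct a plate table from a data frame
#'
#' Validates the well-level invariants: all required columns present,
#' nonnegative luminescence, unique (plate_id, well), and untreated wells
#' carrying no doses.
#'
#' @param df data frame with the columns listed above (a `viability` column
#'   is allowed and preserved).
#' @param normalized whether `df` already carries normalized viability.
#' @return object of class `plate_table` (a data frame with attributes
#'   `normalized` and `normalization_reference`).
#' @export
plate_table <- function(df, normalized = FALSE) {
  missing_cols <- setdiff(PLATE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("log_dose_a", "log_dose_b", "log_dose_c", "luminescence")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$technical_rep <- as.integer(df$technical_rep)
  df$experiment <- as.integer(df$experiment)

  bad_lum <- which(!is.na(df$luminescence) & df$luminescence < 0)
  if (length(bad_lum) > 0) {
    stop("negative luminescence at row(s): ",
         paste(utils::head(bad_lum, 5), collapse = ", "))
  }
  if (anyNA(df$luminescence)) {
    stop("missing luminescence at row(s): ",
         paste(utils::head(which(is.na(df$luminescence)), 5), collapse = ", "))
  }
  key <- paste(df$plate_id, df$well, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (plate_id, well) at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  untr <- df$ratio_label == "untreated"
  dosed <- !is.na(df$log_dose_a) | !is.na(df$log_dose_b) | !is.na(df$log_dose_c)
  if (any(untr & dosed)) {
    stop("untreated well(s) carry doses at row(s): ",
         paste(utils::head(which(untr & dosed), 5), collapse = ", "))
  }

  structure(df, class = c("plate_table", "data.frame"),
            normalized = normalized, normalization_reference = NULL)
}

#' Read a well-level viability table from CSV
#'
#' Comma-separated, UTF-8, header row required; empty dose cells mean the
#' drug is absent. Row order is preserved and all table invariants are
#' checked on read.
#'
#' @param path path to the CSV file.
#' @return a [plate_table()].
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = c("NA", ""))
  has_viab <- "viability" %in% names(df)
  pt <- plate_table(df, normalized = has_viab)
  pt
}

#' Write a plate table to CSV
#'
#' @param table a [plate_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(table, path) {
  stopifnot(inherits(table, "plate_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Normalize raw luminescence to untreated controls
#'
#' Each well's viability is its reading divided by the maximum luminescence
#' among the untreated wells of its group (default grouping: plate x
#' experiment), so the brightest untreated well maps to viability 1.0.
#' Viability is not clipped here: noisy wells may exceed 1; clipping to the
#' [0, 1] effect scale is deferred to the Bliss module. Normalizing an
#' already-normalized table is a no-op (the untreated maximum of a normalized
#' group is exactly 1).
#'
#' @param table a [plate_table()].
#' @param scope character vector of grouping columns (default
#'   `c("plate_id", "experiment")`).
#' @return the table with a `viability` column, `normalized` attribute set,
#'   and per-group references stored in the `normalization_reference`
#'   attribute.
#' @export
normalize_viability <- function(table, scope = c("plate_id", "experiment")) {
  stopifnot(inherits(table, "plate_table"))
  df <- as.data.frame(table)
  value <- if (isTRUE(attr(table, "normalized"))) df$viability else df$luminescence
  group <- interaction(df[scope], drop = TRUE, sep = " / ")
  refs <- numeric(0)
  viability <- numeric(nrow(df))
  for (g in levels(group)) {
    idx <- which(group == g)
    untr <- idx[df$ratio_label[idx] == "untreated"]
    if (length(untr) == 0) {
      stop("no untreated wells in group: ", g)
    }
    ref <- max(value[untr])
    if (!is.finite(ref) || ref <= 0) {
      stop("untreated reference is not positive in group: ", g)
    }
    viability[idx] <- value[idx] / ref
    refs[g] <- ref
  }
  df$viability <- viability
  out <- structure(df, class = c("plate_table", "data.frame"),
                   normalized = TRUE,
                   normalization_reference = data.frame(
                     group = names(refs), reference = unname(refs)))
  out
}

#' @export
print.plate_table <- function(x, ...) {
  cat(sprintf("Plate table: %d wells, %d plate(s), %d experiment(s)%s\n",
              nrow(x), length(unique(x$plate_id)),
              length(unique(x$experiment)),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
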