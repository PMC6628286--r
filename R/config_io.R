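#' Read a food-parameter reference table
#'
#' The parameter reference carries, for each food parameter (nutrient or
#' food component) entering the E-DII, the global mean and standard
#' deviation of its per-1000 kcal density across reference populations,
#' and its literature-derived inflammatory effect score (positive =
#' pro-inflammatory, negative = anti-inflammatory, 0 = null).  The full
#' published schema has 45 parameters; any subset is accepted (studies
#' commonly have 25-35 available).
#'
#' @param path path to a delimited text file with header columns
#'   \code{parameter_name}, \code{global_mean}, \code{global_sd},
#'   \code{effect_score}.
#' @param tsv logical; read tab-separated instead of comma-separated.
#' @return a \code{parameter_reference} data frame.
#' @seealso [default_parameter_reference()] for the synthetic 30-parameter
#'   fixture shipped with the package.
#' @export
load_parameter_reference <- function(path, tsv = FALSE) {
  if (!file.exists(path)) abort("parameter reference file not found: %s", path)
  df <- read_delim_file(path, tsv)
  required <- c("parameter_name", "global_mean", "global_sd", "effect_score")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort("parameter reference is missing column(s) %s; expected header: %s",
          paste(missing, collapse = ", "), paste(required, collapse = ", "))
  }
  df <- df[required]
  df$parameter_name <- as.character(df$parameter_name)
  dup <- df$parameter_name[duplicated(df$parameter_name)]
  if (length(dup) > 0) {
    abort("duplicate parameter name(s) in reference: %s",
          paste(unique(dup), collapse = ", "))
  }
  bad_sd <- !is.finite(df$global_sd) | df$global_sd <= 0
  if (any(bad_sd)) {
    abort("non-positive global_sd for parameter(s): %s",
          paste(df$parameter_name[bad_sd], collapse = ", "))
  }
  if (any(!is.finite(df$global_mean)) || any(!is.finite(df$effect_score))) {
    abort("non-finite global_mean or effect_score in reference table")
  }
  if (nrow(df) > 45) {
    abort("reference has %d rows; the parameter schema holds at most 45", nrow(df))
  }
  class(df) <- c("parameter_reference", "data.frame")
  df
}

#' Read a subject intake table
#'
#' Wide-format table: one row per subject with \code{subject_id},
#' \code{energy_kcal}, optionally \code{alcohol_g}, then one column per
#' food parameter holding the raw daily intake in the parameter's native
#' units.  Parameter columns are matched against the reference by name;
#' unmatched columns are reported and ignored.  Subjects violating basic
#' validity (non-positive energy, negative intake) are excluded row-wise
#' and recorded in the attached exclusion manifest, mirroring per-subject
#' exclusion practice in epidemiologic analysis.
#'
#' @param path delimited text file as described above.
#' @param reference a \code{parameter_reference}.
#' @param tsv logical; tab-separated input.
#' @return data frame of valid subjects (columns \code{subject_id},
#'   \code{energy_kcal}, \code{alcohol_g} and the matched parameter
#'   columns) with attributes \code{ignored_columns} (character) and
#'   \code{exclusions} (data frame \code{subject_id}, \code{reason}).
#' @export
load_intake_table <- function(path, reference, tsv = FALSE) {
  if (!file.exists(path)) abort("intake table not found: %s", path)
  stopifnot(inherits(reference, "parameter_reference"))
  df <- read_delim_file(path, tsv)
  for (col in c("subject_id", "energy_kcal")) {
    if (!col %in% names(df)) abort("intake table lacks required column '%s'", col)
  }
  id_cols <- intersect(c("subject_id", "energy_kcal", "alcohol_g"), names(df))
  param_cols <- intersect(setdiff(names(df), id_cols), reference$parameter_name)
  ignored <- setdiff(names(df), c(id_cols, param_cols))
  if (length(ignored) > 0) {
    message("ignoring ", length(ignored), " column(s) absent from reference: ",
            paste(ignored, collapse = ", "))
  }
  df <- df[c(id_cols, param_cols)]

  reason <- rep(NA_character_, nrow(df))
  bad_energy <- !is.finite(df$energy_kcal) | df$energy_kcal <= 0
  reason[bad_energy] <- "non-positive energy_kcal"
  if (length(param_cols) > 0) {
    intake_mat <- as.matrix(df[param_cols])
    neg <- rowSums(!is.na(intake_mat) & intake_mat < 0) > 0
    reason[is.na(reason) & neg] <- "negative parameter intake"
  }
  if ("alcohol_g" %in% names(df)) {
    bad_alc <- is.finite(df$alcohol_g) & df$alcohol_g < 0
    reason[is.na(reason) & bad_alc] <- "negative alcohol_g"
  }
  excl <- data.frame(subject_id = as.character(df$subject_id[!is.na(reason)]),
                     reason = reason[!is.na(reason)],
                     stringsAsFactors = FALSE)
  keep <- df[is.na(reason), , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "ignored_columns") <- ignored
  attr(keep, "exclusions") <- excl
  keep
}

#' Read a TEAC food-content table
#'
#' TEAC (Trolox equivalent antioxidant capacity) content of food items in
#' mmol Trolox equivalents per kg of edible food, with a flag marking
#' coffee items so NEAC can be computed with and without coffee.
#'
#' @param path delimited text with columns \code{item_name},
#'   \code{teac_content}, \code{is_coffee} (logical or 0/1).
#' @param tsv logical; tab-separated input.
#' @return a \code{teac_table} data frame.
#' @export
load_teac_table <- function(path, tsv = FALSE) {
  if (!file.exists(path)) abort("TEAC table not found: %s", path)
  df <- read_delim_file(path, tsv)
  required <- c("item_name", "teac_content", "is_coffee")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort("TEAC table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  df <- df[required]
  df$item_name <- as.character(df$item_name)
  df$is_coffee <- as.logical(df$is_coffee)
  if (nrow(df) == 0) {
    warning("TEAC table is empty; NEAC cannot be scored against it")
  }
  dup <- df$item_name[duplicated(df$item_name)]
  if (length(dup) > 0) {
    abort("duplicate item(s) in TEAC table: %s", paste(unique(dup), collapse = ", "))
  }
  if (any(!is.finite(df$teac_content) | df$teac_content < 0)) {
    abort("negative or non-finite teac_content in TEAC table")
  }
  class(df) <- c("teac_table", "data.frame")
  df
}

#' Read a food-item gram-intake table
#'
#' Wide format: \code{subject_id} then one column per food item with
#' grams consumed per day.  Negative gram intakes exclude the row.
#'
#' @param path delimited text file.
#' @param tsv logical; tab-separated input.
#' @return data frame with attribute \code{exclusions}.
#' @export
load_item_table <- function(path, tsv = FALSE) {
  if (!file.exists(path)) abort("item table not found: %s", path)
  df <- read_delim_file(path, tsv)
  if (!"subject_id" %in% names(df)) abort("item table lacks column 'subject_id'")
  item_cols <- setdiff(names(df), "subject_id")
  reason <- rep(NA_character_, nrow(df))
  if (length(item_cols) > 0) {
    m <- as.matrix(df[item_cols])
    reason[rowSums(!is.na(m) & m < 0) > 0] <- "negative gram intake"
  }
  excl <- data.frame(subject_id = as.character(df$subject_id[!is.na(reason)]),
                     reason = reason[!is.na(reason)],
                     stringsAsFactors = FALSE)
  keep <- df[is.na(reason), , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "exclusions") <- excl
  keep
}

#' Write a table as delimited text
#'
#' Deterministic writer used for all package outputs: UTF-8, header row,
#' "." decimal, full double precision (values survive a write/read
#' round-trip to better than 1e-12 relative error).
#'
#' @param df data frame to write.
#' @param path destination file.
#' @param tsv logical; write tab-separated.
#' @return \code{path}, invisibly.
#' @export
write_table_file <- function(df, path, tsv = FALSE) {
  utils::write.table(df, path, sep = if (tsv) "\t" else ",",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an exclusion manifest
#'
#' @param exclusions data frame with columns \code{subject_id},
#'   \code{reason} (as attached by the loaders).
#' @param path destination CSV.
#' @return \code{path}, invisibly.
#' @export
write_exclusion_manifest <- function(exclusions, path) {
  if (is.null(exclusions)) {
    exclusions <- data.frame(subject_id = character(), reason = character())
  }
  write_table_file(exclusions, path)
}

# internal reader shared by all loaders
read_delim_file <- function(path, tsv = FALSE) {
  utils::read.table(path, header = TRUE, sep = if (tsv) "\t" else ",",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Synthetic 30-parameter E-DII reference fixture
#'
#' Loads the parameter reference shipped with the package: the 30 food
#' parameters for which FFQ data were available in the motivating study
#' (macronutrients, vitamins, minerals, flavonoid classes, garlic and
#' onion).  Effect scores follow the published DII literature weights;
#' the global per-1000 kcal density means and SDs are synthetic
#' placeholders (the real energy-adjusted global database is proprietary
#' and must be supplied by the user for real analyses).
#'
#' @return a \code{parameter_reference} with 30 rows.
#' @export
default_parameter_reference <- function() {
  load_parameter_reference(
    system.file("extdata", "synthetic_parameter_reference.csv",
                package = "inflamdiet", mustWork = TRUE))
}

#' Synthetic TEAC content fixture
#'
#' Loads the food-item TEAC table shipped with the package: plausible
#' mmol TE/kg contents for common antioxidant-bearing food groups, with
#' coffee flagged.  Synthetic placeholder values; real analyses should
#' supply published food-composition TEAC tables.
#'
#' @return a \code{teac_table}.
#' @export
default_teac_table <- function() {
  load_teac_table(
    system.file("extdata", "synthetic_teac_values.csv",
                package = "inflamdiet", mustWork = TRUE))
}
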