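#' Energy-adjusted nutrient density
#'
#' Converts a raw daily intake to an amount per 1000 kcal of total energy
#' intake, the energy adjustment underlying the E-DII.
#'
#' @param raw_intake daily intake in the parameter's native units, >= 0.
#' @param energy_kcal total daily energy intake in kcal, > 0.
#' @return density in units per 1000 kcal.
#' @examples
#' energy_density(20, 2000)  # 10
#' @export
energy_density <- function(raw_intake, energy_kcal) {
  if (any(!is.finite(energy_kcal)) || any(energy_kcal <= 0)) {
    abort("energy_kcal must be finite and > 0")
  }
  if (any(!is.finite(raw_intake)) || any(raw_intake < 0)) {
    abort("raw_intake must be finite and >= 0")
  }
  raw_intake * 1000 / energy_kcal
}

#' Per-parameter inflammatory contribution
#'
#' One food parameter's contribution to the E-DII: the density is
#' standardized against the global reference (z-score), mapped to a
#' proportion in (0, 1) via the standard normal CDF, centered to (-1, 1)
#' by doubling and subtracting one, and weighted by the parameter's
#' inflammatory effect score.  The contribution is therefore strictly
#' bounded by the absolute effect score at any finite density, and is
#' exactly 0 at the global mean density.
#'
#' @param density per-1000 kcal density.
#' @param global_mean,global_sd reference density moments (\code{global_sd > 0}).
#' @param effect_score inflammatory weight (+ pro-, - anti-inflammatory).
#' @param percentile_fn transform from z-score to proportion; the default
#'   is the standard normal CDF (the established DII construction).  An
#'   empirical-percentile alternative can be injected here.
#' @return signed contribution in \code{(-|effect_score|, |effect_score|)}.
#' @examples
#' parameter_score(14, 10, 2, -0.5)  # -0.47725 = -0.5 * (2*pnorm(2) - 1)
#' @export
parameter_score <- function(density, global_mean, global_sd, effect_score,
                            percentile_fn = stats::pnorm) {
  if (any(!is.finite(density)) || any(!is.finite(global_mean)) ||
      any(!is.finite(global_sd)) || any(!is.finite(effect_score))) {
    abort("parameter_score requires finite inputs")
  }
  if (any(global_sd <= 0)) abort("global_sd must be > 0")
  z <- (density - global_mean) / global_sd
  p <- percentile_fn(z)
  (2 * p - 1) * effect_score
}

#' Compute one subject's E-DII score
#'
#' Densifies the subject's raw intakes to per-1000 kcal amounts, scores
#' each food parameter that resolves against the reference, and sums the
#' contributions into the overall E-DII.  Higher scores indicate a more
#' pro-inflammatory diet.  Parameters present in the reference but absent
#' from the subject contribute nothing (absence is not imputed as zero
#' intake) and are counted in the coverage report.
#'
#' @param subject a list or one-row data frame with \code{subject_id},
#'   \code{energy_kcal} and named parameter intakes (either as extra
#'   fields/columns or as a named \code{parameter_intakes} vector).
#' @param reference a \code{parameter_reference}.
#' @return list of class \code{edii_result}: \code{subject_id},
#'   \code{edii_total}, \code{contributions} (named), \code{densities}
#'   (named), \code{n_parameters_used}, \code{missing_parameters}.
#' @export
compute_edii <- function(subject, reference) {
  stopifnot(inherits(reference, "parameter_reference"))
  intakes <- extract_parameter_intakes(subject)
  energy <- as.numeric(subject[["energy_kcal"]])
  used <- intersect(reference$parameter_name, names(intakes))
  used <- used[is.finite(unlist(intakes[used]))]
  if (length(used) == 0) {
    abort("subject %s: no parameter resolves against the reference",
          as.character(subject[["subject_id"]]))
  }
  ref <- reference[match(used, reference$parameter_name), ]
  dens <- energy_density(as.numeric(unlist(intakes[used])), energy)
  contrib <- parameter_score(dens, ref$global_mean, ref$global_sd,
                             ref$effect_score)
  names(dens) <- used
  names(contrib) <- used
  structure(list(
    subject_id = as.character(subject[["subject_id"]]),
    edii_total = sum(contrib),
    contributions = contrib,
    densities = dens,
    n_parameters_used = length(used),
    missing_parameters = setdiff(reference$parameter_name, used)
  ), class = "edii_result")
}

#' Score a whole intake table
#'
#' Vectorized E-DII over a wide intake table (as returned by
#' \code{\link{load_intake_table}} or \code{\link{generate_intakes}}).
#' Input row order is preserved; subjects failing to score are dropped
#' into the attached exclusion manifest rather than aborting the batch.
#'
#' @param intakes wide data frame: \code{subject_id}, \code{energy_kcal},
#'   parameter columns.
#' @param reference a \code{parameter_reference}.
#' @param contributions logical; attach per-parameter contribution columns.
#' @return data frame \code{subject_id}, \code{edii_total},
#'   \code{n_parameters_used} (plus contribution columns if requested),
#'   with attribute \code{exclusions}.
#' @export
batch_edii <- function(intakes, reference, contributions = FALSE) {
  stopifnot(inherits(reference, "parameter_reference"))
  if (nrow(intakes) == 0) {
    out <- data.frame(subject_id = character(), edii_total = numeric(),
                      n_parameters_used = integer())
    attr(out, "exclusions") <- data.frame(subject_id = character(),
                                          reason = character())
    return(out)
  }
  used <- intersect(reference$parameter_name, names(intakes))
  if (length(used) == 0) abort("no intake column resolves against the reference")
  ref <- reference[match(used, reference$parameter_name), ]
  raw <- as.matrix(intakes[used])
  energy <- as.numeric(intakes$energy_kcal)
  ok <- is.finite(energy) & energy > 0
  dens <- sweep(raw[ok, , drop = FALSE], 1, 1000 / energy[ok], `*`)
  z <- sweep(sweep(dens, 2, ref$global_mean, `-`), 2, ref$global_sd, `/`)
  contrib <- sweep(2 * stats::pnorm(z) - 1, 2, ref$effect_score, `*`)
  n_used <- rowSums(is.finite(contrib))
  total <- rowSums(contrib, na.rm = TRUE)
  out <- data.frame(subject_id = as.character(intakes$subject_id[ok]),
                    edii_total = total,
                    n_parameters_used = n_used,
                    stringsAsFactors = FALSE)
  if (contributions) {
    cn <- paste0("contrib_", used)
    cm <- as.data.frame(contrib)
    names(cm) <- cn
    out <- cbind(out, cm)
  }
  excl <- data.frame(
    subject_id = as.character(intakes$subject_id[!ok]),
    reason = rep("non-positive energy_kcal", sum(!ok)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

# internal: pull named parameter intakes out of the flexible subject input
extract_parameter_intakes <- function(subject) {
  if (!is.null(subject[["parameter_intakes"]])) {
    return(as.list(subject[["parameter_intakes"]]))
  }
  s <- as.list(subject)
  s[setdiff(names(s), c("subject_id", "energy_kcal", "alcohol_g",
                        "item_grams", "parameter_intakes"))]
}
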