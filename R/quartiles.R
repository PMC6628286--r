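#' Control-based quartile cutpoints
#'
#' Empirical 25th/50th/75th percentiles of an exposure computed on
#' control subjects only (cases never enter cutpoint estimation), using
#' linear interpolation between order statistics (quantile type 7).
#'
#' @param values exposure values of the controls in one group.
#' @param group_key label of the group the scheme applies to (a sex level
#'   or \code{"all"}).
#' @return list of class \code{quartile_scheme}: \code{group_key},
#'   \code{cutpoints} (named q25/q50/q75), \code{source_n}.
#' @examples
#' quartile_cutpoints(1:8)$cutpoints  # 2.75 4.50 6.25
#' @export
quartile_cutpoints <- function(values, group_key = "all") {
  values <- values[is.finite(values)]
  if (length(values) < 4) {
    abort("quartile scheme for group '%s' needs >= 4 control values, got %d",
          group_key, length(values))
  }
  cp <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (any(diff(cp) <= 0)) {
    warning(sprintf("degenerate quartile cutpoints in group '%s' (ties saturate)",
                    group_key))
  }
  structure(list(group_key = as.character(group_key),
                 cutpoints = c(q25 = cp[1], q50 = cp[2], q75 = cp[3]),
                 source_n = length(values)),
            class = "quartile_scheme")
}

#' Assign quartiles under the closed-above convention
#'
#' Q1 iff value <= q25; Q2 iff q25 < value <= q50; Q3 iff q50 < value <=
#' q75; Q4 iff value > q75 — the convention readable from printed
#' quartile bounds of the form "<= a" / "> c".
#'
#' @param value numeric vector of finite exposure values.
#' @param scheme a \code{quartile_scheme}.
#' @return integer vector in 1..4.
#' @export
assign_quartile <- function(value, scheme) {
  stopifnot(inherits(scheme, "quartile_scheme"))
  if (any(!is.finite(value))) abort("assign_quartile requires finite values")
  cp <- scheme$cutpoints
  1L + (value > cp[1]) + (value > cp[2]) + (value > cp[3])
}

#' Combined inflammatory-antioxidant profile score
#'
#' The 0-6 profile summing an ascending E-DII quartile code (Q1..Q4 ->
#' 0..3; higher = more inflammatory) and a descending NEAC quartile code
#' (Q1..Q4 -> 3..0; higher NEAC = more antioxidant).  0 = least
#' inflammatory and most antioxidant diet; 6 = most inflammatory and
#' least antioxidant.
#'
#' @param edii_q,neac_q integer quartiles in 1..4.
#' @return integer profile in 0..6.
#' @examples
#' edii_neac_profile(4, 1)  # 6
#' edii_neac_profile(1, 4)  # 0
#' @export
edii_neac_profile <- function(edii_q, neac_q) {
  q <- c(edii_q, neac_q)
  if (any(!is.finite(q)) || any(q < 1) || any(q > 4) || any(q != round(q))) {
    abort("quartiles must be integers in 1..4")
  }
  as.integer((edii_q - 1L) + (4L - neac_q))
}

#' Median-split combined E-DII/NEAC category
#'
#' Cross-classifies subjects by control-based medians of E-DII and NEAC
#' into four categories.  The reference category is low inflammatory /
#' high antioxidant (E-DII <= median and NEAC > median); the opposite
#' corner is high inflammatory / low antioxidant.  Boundaries follow the
#' closed-above rule, so a value exactly at the median counts as "low".
#'
#' @param edii,neac numeric exposure vectors.
#' @param edii_median,neac_median group medians (computed on controls).
#' @return factor with levels \code{lowDII_highNEAC} (reference),
#'   \code{lowDII_lowNEAC}, \code{highDII_highNEAC}, \code{highDII_lowNEAC}.
#' @export
combined_median_category <- function(edii, neac, edii_median, neac_median) {
  if (!is.finite(edii_median) || !is.finite(neac_median)) {
    abort("combined_median_category requires finite group medians")
  }
  hi_dii <- edii > edii_median
  hi_neac <- neac > neac_median
  lev <- c("lowDII_highNEAC", "lowDII_lowNEAC",
           "highDII_highNEAC", "highDII_lowNEAC")
  out <- ifelse(!hi_dii & hi_neac, lev[1],
         ifelse(!hi_dii & !hi_neac, lev[2],
         ifelse(hi_dii & hi_neac, lev[3], lev[4])))
  factor(out, levels = lev)
}

#' Build (sex-specific) quartile schemes from a study table
#'
#' Computes quartile schemes for one exposure column using control
#' subjects only, either a single scheme (\code{by = NULL}; used when the
#' study is single-sex) or one per level of a grouping column (sex-specific
#' schemes for mixed-sex studies).
#'
#' @param study data frame with \code{case_status} (0/1), the exposure
#'   column, and the grouping column if \code{by} is given.
#' @param exposure name of the exposure column.
#' @param by optional name of the grouping column (e.g. \code{"sex"}).
#' @return named list of \code{quartile_scheme}s (name = group level, or
#'   \code{"all"}).
#' @export
build_quartile_schemes <- function(study, exposure, by = NULL) {
  stopifnot(exposure %in% names(study), "case_status" %in% names(study))
  controls <- study[study$case_status == 0, , drop = FALSE]
  if (is.null(by)) {
    return(list(all = quartile_cutpoints(controls[[exposure]], "all")))
  }
  stopifnot(by %in% names(study))
  groups <- sort(unique(as.character(study[[by]])))
  schemes <- lapply(groups, function(g) {
    quartile_cutpoints(controls[[exposure]][as.character(controls[[by]]) == g], g)
  })
  names(schemes) <- groups
  schemes
}

# internal: quartile assignment routed through a per-group scheme list
assign_quartile_grouped <- function(value, group, schemes) {
  q <- integer(length(value))
  if (length(schemes) == 1 && identical(names(schemes), "all")) {
    return(assign_quartile(value, schemes$all))
  }
  for (g in names(schemes)) {
    idx <- as.character(group) == g
    if (any(idx)) q[idx] <- assign_quartile(value[idx], schemes[[g]])
  }
  q
}

#' Attach quartiles, profile and combined category to a study table
#'
#' Convenience wrapper that builds control-based quartile schemes for the
#' E-DII and NEAC columns (sex-specific when \code{by} is given), assigns
#' quartiles, and derives the 0-6 profile and the median-split combined
#' category for every subject.
#'
#' @param study data frame with \code{case_status}, E-DII and NEAC
#'   columns (and the grouping column when \code{by} is given).
#' @param edii,neac names of the exposure columns.
#' @param by optional grouping column name for sex-specific schemes.
#' @return \code{study} with added columns \code{edii_quartile},
#'   \code{neac_quartile}, \code{profile}, \code{combined_category};
#'   attribute \code{schemes} holds the cutpoint schemes and control
#'   medians.
#' @export
add_profile <- function(study, edii = "edii", neac = "neac", by = NULL) {
  es <- build_quartile_schemes(study, edii, by)
  ns <- build_quartile_schemes(study, neac, by)
  grp <- if (is.null(by)) rep("all", nrow(study)) else as.character(study[[by]])
  study$edii_quartile <- assign_quartile_grouped(study[[edii]], grp, es)
  study$neac_quartile <- assign_quartile_grouped(study[[neac]], grp, ns)
  study$profile <- edii_neac_profile(study$edii_quartile, study$neac_quartile)

  controls <- study[study$case_status == 0, , drop = FALSE]
  meds <- lapply(unique(grp), function(g) {
    idx <- grp[study$case_status == 0] == g
    list(edii = stats::median(controls[[edii]][idx]),
         neac = stats::median(controls[[neac]][idx]))
  })
  names(meds) <- unique(grp)
  cc <- character(nrow(study))
  for (g in names(meds)) {
    idx <- grp == g
    cc[idx] <- as.character(combined_median_category(
      study[[edii]][idx], study[[neac]][idx], meds[[g]]$edii, meds[[g]]$neac))
  }
  study$combined_category <- factor(cc, levels = c(
    "lowDII_highNEAC", "lowDII_lowNEAC", "highDII_highNEAC", "highDII_lowNEAC"))
  attr(study, "schemes") <- list(edii = es, neac = ns, medians = meds)
  study
}

#' Export a cutpoint table
#'
#' Flattens a list of quartile schemes into a data frame suitable for the
#' cutpoint side artifact.
#'
#' @param schemes named list of \code{quartile_scheme}s.
#' @return data frame \code{group_key}, \code{q25}, \code{q50},
#'   \code{q75}, \code{source_n}.
#' @export
cutpoint_table <- function(schemes) {
  do.call(rbind, lapply(schemes, function(s) {
    data.frame(group_key = s$group_key, q25 = s$cutpoints[["q25"]],
               q50 = s$cutpoints[["q50"]], q75 = s$cutpoints[["q75"]],
               source_n = s$source_n, stringsAsFactors = FALSE)
  }))
}
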