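#' TEAC intake from one food item
#'
#' Daily Trolox-equivalent antioxidant intake from a single item:
#' grams/day converted to kg/day times the item's TEAC content in
#' mmol TE per kg.
#'
#' @param grams_per_day daily consumption in grams, >= 0.
#' @param teac_content_per_kg TEAC content, mmol TE/kg, >= 0.
#' @return mmol TE per day.
#' @examples
#' item_teac(200, 15)  # 3.0
#' @export
item_teac <- function(grams_per_day, teac_content_per_kg) {
  if (any(!is.finite(grams_per_day)) || any(grams_per_day < 0) ||
      any(!is.finite(teac_content_per_kg)) || any(teac_content_per_kg < 0)) {
    abort("item_teac requires finite non-negative inputs")
  }
  grams_per_day / 1000 * teac_content_per_kg
}

#' Compute one subject's dietary NEAC
#'
#' Total non-enzymatic antioxidant capacity of the diet on the TEAC
#' scale: the sum of \code{\link{item_teac}} over the subject's food
#' items that match the TEAC table.  Computed both with and without
#' coffee-flagged items; the no-coffee total is the conventional main
#' exposure.  Items absent from the table are skipped and counted.
#'
#' @param subject list or one-row data frame carrying a named
#'   \code{item_grams} vector (grams/day per food item).
#' @param teac_table a \code{teac_table}.
#' @return list of class \code{neac_result}: \code{subject_id},
#'   \code{teac_total} (with coffee), \code{teac_total_no_coffee},
#'   \code{n_items_matched}, \code{n_items_unmatched}.
#' @export
compute_neac <- function(subject, teac_table) {
  stopifnot(inherits(teac_table, "teac_table"))
  grams <- subject[["item_grams"]]
  if (is.null(grams)) abort("subject has no item_grams")
  grams <- unlist(grams)
  matched <- intersect(names(grams), teac_table$item_name)
  if (length(matched) == 0) {
    abort("subject %s: no food item matches the TEAC table",
          as.character(subject[["subject_id"]]))
  }
  tt <- teac_table[match(matched, teac_table$item_name), ]
  per_item <- item_teac(as.numeric(grams[matched]), tt$teac_content)
  structure(list(
    subject_id = as.character(subject[["subject_id"]]),
    teac_total = sum(per_item),
    teac_total_no_coffee = sum(per_item[!tt$is_coffee]),
    n_items_matched = length(matched),
    n_items_unmatched = length(grams) - length(matched)
  ), class = "neac_result")
}

#' Score a whole item-gram table
#'
#' Vectorized NEAC over a wide food-item table (\code{subject_id} plus
#' one grams/day column per item).  Unmatched item columns are skipped
#' with a message.
#'
#' @param items wide data frame of gram intakes.
#' @param teac_table a \code{teac_table}.
#' @return data frame \code{subject_id}, \code{teac_total},
#'   \code{teac_total_no_coffee}, \code{n_items_matched}.
#' @export
batch_neac <- function(items, teac_table) {
  stopifnot(inherits(teac_table, "teac_table"))
  item_cols <- setdiff(names(items), "subject_id")
  matched <- intersect(item_cols, teac_table$item_name)
  if (nrow(items) == 0) {
    return(data.frame(subject_id = character(), teac_total = numeric(),
                      teac_total_no_coffee = numeric(),
                      n_items_matched = integer()))
  }
  if (length(matched) == 0) abort("no item column matches the TEAC table")
  unmatched <- setdiff(item_cols, matched)
  if (length(unmatched) > 0) {
    message("skipping ", length(unmatched), " item(s) absent from TEAC table: ",
            paste(unmatched, collapse = ", "))
  }
  tt <- teac_table[match(matched, teac_table$item_name), ]
  g <- as.matrix(items[matched])
  per_item <- sweep(g / 1000, 2, tt$teac_content, `*`)
  data.frame(
    subject_id = as.character(items$subject_id),
    teac_total = rowSums(per_item),
    teac_total_no_coffee = rowSums(per_item[, !tt$is_coffee, drop = FALSE]),
    n_items_matched = rowSums(is.finite(per_item)),
    stringsAsFactors = FALSE)
}
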