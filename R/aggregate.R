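#' Aggregate parcel scores to a census geography level
#'
#' The area lead risk score of a unit is the sum of final parcel scores
#' divided by the count of *all* residential parcels in the unit -- post-ban
#' parcels count in the denominator with score 0, so a neighborhood of mostly
#' new housing dilutes the risk of its few old houses. Units that have
#' children recorded but no residential parcels are emitted as "No Data";
#' units with neither parcels nor children are dropped.
#'
#' @param scores Score table from [score_parcels()] carrying a geography id
#'   column for the requested level (`block_id`, `block_group_id` or
#'   `tract_id`), or an explicit `geo_id` column.
#' @param level One of `"block"`, `"block_group"`, `"tract"`.
#' @param known_geos Optional character vector of valid unit ids at this
#'   level; parcels referencing an unknown id raise a validation error
#'   listing the offenders.
#' @param child_geos Optional character vector of unit ids that have resident
#'   children; those without parcels are emitted with `NA` score and
#'   category "No Data".
#' @return data.frame `geo_id`, `level`, `parcel_count`, `score_sum`,
#'   `mean_score`, `category`.
#' @export
aggregate_scores <- function(scores, level = c("block", "block_group", "tract"),
                             known_geos = NULL, child_geos = NULL) {
  level <- match.arg(level)
  idcol <- if ("geo_id" %in% names(scores)) "geo_id" else paste0(level, "_id")
  if (!(idcol %in% names(scores))) {
    stop("score table has no '", idcol, "' column for level ", level)
  }
  gid <- as.character(scores[[idcol]])
  if (!is.null(known_geos)) {
    bad <- unique(gid[!(gid %in% known_geos)])
    if (length(bad) > 0) {
      stop("parcel(s) reference unknown ", level, " id(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
  }
  if (nrow(scores) > 0) {
    cnt <- tapply(scores$final_score, gid, length)
    s <- tapply(scores$final_score, gid, sum)
    out <- data.frame(geo_id = names(cnt), level = level,
                      parcel_count = as.integer(cnt),
                      score_sum = as.numeric(s),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(geo_id = character(0), level = character(0),
                      parcel_count = integer(0), score_sum = numeric(0),
                      stringsAsFactors = FALSE)
  }
  nodata <- setdiff(as.character(child_geos), out$geo_id)
  if (length(nodata) > 0) {
    out <- rbind(out, data.frame(geo_id = nodata, level = level,
                                 parcel_count = 0L, score_sum = NA_real_,
                                 stringsAsFactors = FALSE))
  }
  out$mean_score <- ifelse(out$parcel_count > 0,
                           out$score_sum / out$parcel_count, NA_real_)
  out$category <- classify_risk(out$mean_score, style = "area")
  out <- out[order(out$geo_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
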