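#' Risk category labels
#'
#' Area and childcare scores share one partition of the non-negative reals:
#' exactly 0 is Very Low, (0, 1) is Low, \[1, 2) is Moderate, \[2, 3) is
#' High, and 3 or more is Very High. Childcare outputs relabel Very High as
#' "Highest". Units with no residential parcels are "No Data".
#'
#' @param style `"area"` (Very High ... Very Low) or `"childcare"`
#'   (Highest ... Very Low).
#' @return Character vector of labels ordered from highest risk to lowest,
#'   followed by `"No Data"`.
#' @export
risk_levels <- function(style = c("area", "childcare")) {
  style <- match.arg(style)
  top <- if (style == "childcare") "Highest" else "Very High"
  c(top, "High", "Moderate", "Low", "Very Low", "No Data")
}

#' Classify a mean risk score into a category
#'
#' @param mean_score Numeric vector of non-negative area or buffer scores;
#'   `NA` is allowed and maps to "No Data" (a unit with children but no
#'   residential parcels).
#' @param style Label style, see [risk_levels()].
#' @return Factor with levels `risk_levels(style)`.
#' @export
#' @examples
#' classify_risk(c(0, 0.005, 1, 2, 3.2))
#' # Very Low, Low, Moderate, High, Very High
classify_risk <- function(mean_score, style = c("area", "childcare")) {
  style <- match.arg(style)
  x <- as.numeric(mean_score)
  if (any(!is.na(x) & (x < 0 | !is.finite(x)))) {
    stop("mean_score must be finite and >= 0")
  }
  lev <- risk_levels(style)
  out <- rep(NA_character_, length(x))
  out[is.na(x)] <- "No Data"
  out[!is.na(x) & x == 0] <- "Very Low"
  out[!is.na(x) & x > 0 & x < 1] <- "Low"
  out[!is.na(x) & x >= 1 & x < 2] <- "Moderate"
  out[!is.na(x) & x >= 2 & x < 3] <- "High"
  out[!is.na(x) & x >= 3] <- lev[1]
  factor(out, levels = lev)
}

#' Count areas per risk category
#'
#' @param areas data.frame with columns `level` and `category` (as produced
#'   by [aggregate_scores()]).
#' @return data.frame `category` x one column per level, counts summing to
#'   the number of units at that level.
#' @export
category_counts <- function(areas) {
  lev <- risk_levels("area")
  if (nrow(areas) == 0) {
    return(data.frame(category = factor(lev, levels = lev)))
  }
  tab <- table(factor(areas$category, levels = lev), areas$level)
  out <- data.frame(category = factor(lev, levels = lev))
  for (l in colnames(tab)) out[[l]] <- as.integer(tab[, l])
  out
}
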