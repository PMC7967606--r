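#' Program types of certified childcare providers
#'
#' The closed enumeration of provider types appearing in state childcare
#' registries: licensed centers, type A/B family childcare homes, education
#' department licensed preschool and school-age programs, in-home aides, and
#' registered day camps.
#'
#' @return Character vector of the seven program types.
#' @export
program_types <- function() {
  c("In Home Aide",
    "Licensed Childcare Center",
    "Licensed Type A Family Childcare Home",
    "Licensed Type B Family Childcare Home",
    "ODE Licensed Preschool",
    "ODE Licensed School Age Childcare",
    "Registered Day Camp")
}

#' Score childcare centers by buffered community risk
#'
#' Each center receives the normalized lead risk of the residential parcels
#' within a planar half-mile buffer: the sum of final parcel scores within
#' the closed disc divided by the count of all parcels there (post-ban
#' parcels counting as zero). The score is classified with the same
#' partition as area scores but labeled Highest...Very Low; a center with no
#' parcel in its buffer is flagged "No Data", not an error.
#'
#' @param centers data.frame with `center_id`, `program_type`, `x`, `y`
#'   (planar miles, same frame as the parcels).
#' @param scores Score table from [score_parcels()] carrying `x`, `y`.
#' @param radius Buffer radius in miles (default 0.5); parcels at exactly
#'   `radius` are included.
#' @return data.frame `center_id`, `program_type`, `n_parcels_in_buffer`,
#'   `score_sum`, `score`, `priority`.
#' @export
score_centers <- function(centers, scores, radius = 0.5) {
  stopifnot(is.data.frame(centers), is.data.frame(scores), radius >= 0)
  for (col in c("x", "y")) {
    if (!(col %in% names(scores))) {
      stop("score table needs parcel coordinates ('x', 'y') for buffering")
    }
  }
  n <- nrow(centers)
  cnt <- integer(n); ssum <- numeric(n)
  px <- scores$x; py <- scores$y; fs <- scores$final_score
  r2 <- radius^2
  for (i in seq_len(n)) {
    d2 <- (px - centers$x[i])^2 + (py - centers$y[i])^2
    inside <- d2 <= r2
    cnt[i] <- sum(inside)
    ssum[i] <- sum(fs[inside])
  }
  score <- ifelse(cnt > 0, ssum / cnt, NA_real_)
  data.frame(center_id = as.character(centers$center_id),
             program_type = as.character(centers$program_type),
             n_parcels_in_buffer = cnt,
             score_sum = ifelse(cnt > 0, ssum, NA_real_),
             score = score,
             priority = classify_risk(score, style = "childcare"),
             stringsAsFactors = FALSE)
}

#' Tabulate childcare centers by program type and priority
#'
#' @param center_risks Output of [score_centers()].
#' @return data.frame, one row per program type plus a Total row; one column
#'   per priority level plus `Grand.Total`. Row and column margins sum to the
#'   number of centers.
#' @export
tabulate_by_type <- function(center_risks) {
  lev <- risk_levels("childcare")
  types <- sort(unique(c(program_types(),
                         as.character(center_risks$program_type))))
  tab <- table(factor(center_risks$program_type, levels = types),
               factor(center_risks$priority, levels = lev))
  out <- as.data.frame.matrix(tab)
  out <- cbind(program_type = rownames(out), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$Grand.Total <- as.integer(rowSums(out[, lev, drop = FALSE]))
  total <- out[1, , drop = FALSE]
  total$program_type <- "Total"
  for (l in c(lev, "Grand.Total")) total[[l]] <- sum(out[[l]])
  rbind(out, total)
}
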