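#' Score a single parcel
#'
#' Combines the age tier (1-3), value tier (1-3) and grade modifier into the
#' final parcel lead risk score: `(age_score + value_score) * modifier`.
#' Parcels built after the exclusion year carry a final score of 0 -- they are
#' retained, not dropped, because area scores divide by *all* residential
#' parcels in a unit.
#'
#' @param year_built Construction year.
#' @param appraised_value Appraised value in USD.
#' @param grade Building grade label (see [grade_levels()]).
#' @param rules A [tier_rules()] object.
#' @param modifiers A [grade_modifier_table()].
#' @return A one-row data.frame with columns `excluded`, `age_score`,
#'   `value_score`, `cumulative`, `modifier`, `final_score`.
#' @export
#' @examples
#' score_parcel(1943, 60000, "D+")  # final score 4.5
#' score_parcel(1985, 156000, "B")  # excluded, final score 0
score_parcel <- function(year_built, appraised_value, grade,
                         rules = tier_rules(),
                         modifiers = default_modifiers()) {
  stopifnot(length(year_built) == 1, length(appraised_value) == 1,
            length(grade) == 1)
  df <- data.frame(parcel_id = "p", year_built = year_built,
                   appraised_value = appraised_value, grade = grade,
                   stringsAsFactors = FALSE)
  res <- score_parcels(df, rules = rules, modifiers = modifiers)
  if (nrow(res$rejects) > 0) stop("invalid parcel: ", res$rejects$reason[1])
  res$scores[, setdiff(names(res$scores), "parcel_id")]
}

#' Score a table of parcels
#'
#' Vectorized scoring of a parcel table. Rows with a missing or unparseable
#' year, a negative or missing value, or a missing grade are routed to a
#' rejects report (with the offending row number and a reason) rather than
#' silently dropped; `nrow(scores) + nrow(rejects) == nrow(parcels)`.
#' A grade that is present but absent from the modifier table is an error,
#' never a silent default.
#'
#' @param parcels data.frame with columns `year_built`, `appraised_value`,
#'   `grade`, and optionally `parcel_id` (generated if absent). Extra columns
#'   (coordinates, geography ids) are carried through to the score table.
#' @param rules A [tier_rules()] object.
#' @param modifiers A [grade_modifier_table()].
#' @return List with `scores` (one row per valid parcel, order-preserving:
#'   carried columns plus `excluded`, `age_score`, `value_score`,
#'   `cumulative`, `modifier`, `final_score`) and `rejects` (`row`, `parcel_id`,
#'   `reason`).
#' @export
score_parcels <- function(parcels, rules = tier_rules(),
                          modifiers = default_modifiers()) {
  stopifnot(is.data.frame(parcels))
  needed <- c("year_built", "appraised_value", "grade")
  miss <- setdiff(needed, names(parcels))
  if (length(miss) > 0) {
    stop("parcel table is missing column(s): ", paste(miss, collapse = ", "))
  }
  n <- nrow(parcels)
  if (!("parcel_id" %in% names(parcels))) {
    parcels$parcel_id <- sprintf("P%06d", seq_len(n))
  }
  if (n == 0) {
    return(list(scores = cbind(parcels,
                               excluded = logical(0), age_score = integer(0),
                               value_score = integer(0), cumulative = integer(0),
                               modifier = numeric(0), final_score = numeric(0)),
                rejects = data.frame(row = integer(0), parcel_id = character(0),
                                     reason = character(0),
                                     stringsAsFactors = FALSE)))
  }

  year <- suppressWarnings(as.numeric(parcels$year_built))
  value <- suppressWarnings(parse_currency(parcels$appraised_value))
  grade <- normalize_grade(parcels$grade)

  this_year <- as.integer(format(Sys.Date(), "%Y"))
  reason <- rep(NA_character_, n)
  reason[is.na(year)] <- "missing or non-numeric year_built"
  ok <- is.na(reason)
  reason[ok & (year < 1850 | year > this_year)] <- "implausible year_built"
  ok <- is.na(reason)
  reason[ok & is.na(value)] <- "missing or non-numeric appraised_value"
  ok <- is.na(reason)
  reason[ok & value < 0] <- "negative appraised_value"
  ok <- is.na(reason)
  reason[ok & (is.na(grade) | grade == "")] <- "missing grade"
  ok <- is.na(reason)

  rejects <- data.frame(row = which(!ok),
                        parcel_id = parcels$parcel_id[!ok],
                        reason = reason[!ok],
                        stringsAsFactors = FALSE)

  keep <- parcels[ok, , drop = FALSE]
  year <- year[ok]; value <- value[ok]; grade <- grade[ok]
  excluded <- year > rules$exclusion_after
  age_score <- score_age(year, rules)
  value_score <- score_value(value, rules)
  modifier <- rep(NA_real_, sum(ok))
  if (any(!excluded)) {
    modifier[!excluded] <- lookup_modifier(modifiers, grade[!excluded])
  }
  cumulative <- ifelse(excluded, NA_integer_, age_score + value_score)
  final_score <- ifelse(excluded, 0, cumulative * modifier)
  age_score[excluded] <- NA_integer_
  value_score[excluded] <- NA_integer_

  scores <- cbind(keep,
                  data.frame(excluded = excluded, age_score = age_score,
                             value_score = value_score, cumulative = cumulative,
                             modifier = modifier, final_score = final_score,
                             stringsAsFactors = FALSE))
  rownames(scores) <- NULL
  list(scores = scores, rejects = rejects)
}

#' Exclusion rate of a scored parcel table
#'
#' Share of valid parcels excluded from scoring because they postdate the
#' residential lead paint ban.
#'
#' @param scores The `scores` element of [score_parcels()].
#' @return Proportion in `[0, 1]`.
#' @export
exclusion_rate <- function(scores) {
  if (nrow(scores) == 0) return(NA_real_)
  mean(scores$excluded)
}

# "$1,234" -> 1234; plain numerics pass through
parse_currency <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- gsub("[$,[:space:]]", "", as.character(x))
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}
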