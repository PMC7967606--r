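#' Child population exposure by risk category
#'
#' Joins child counts to the risk category of their geography and tabulates
#' how many children under 5 and under 18 live in each risk tier, as counts
#' and percentage shares, together with the combined High + Very High share
#' -- the headline exposure figure. Units classified "No Data" (children but
#' no residential parcels) are tallied separately and excluded from the
#' shares.
#'
#' @param areas Output of [aggregate_scores()] for the level at which the
#'   children are counted (`geo_id`, `category`).
#' @param children data.frame with `geo_id`, `under5_total`, `under18_total`
#'   (one row per unit at the same level).
#' @return data.frame, one row per risk category plus a Total row, columns
#'   `under5_count`, `under5_share`, `under18_count`, `under18_share`
#'   (shares in percent). Attributes: `high_risk` (named vector of combined
#'   High + Very High percent shares), `no_data` (counts in No Data units),
#'   `level`.
#' @export
exposure_table <- function(areas, children) {
  stopifnot(all(c("geo_id", "category") %in% names(areas)),
            all(c("geo_id", "under5_total", "under18_total") %in% names(children)))
  idx <- match(as.character(children$geo_id), as.character(areas$geo_id))
  if (anyNA(idx)) {
    bad <- unique(children$geo_id[is.na(idx)])
    stop("child record(s) reference unit(s) with no risk classification: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  cat5 <- risk_levels("area")[1:5]
  category <- factor(as.character(areas$category[idx]), levels = cat5)
  nodata <- is.na(category)
  u5 <- tapply(children$under5_total[!nodata], category[!nodata], sum,
               default = 0)
  u18 <- tapply(children$under18_total[!nodata], category[!nodata], sum,
                default = 0)
  u5[is.na(u5)] <- 0; u18[is.na(u18)] <- 0
  tot5 <- sum(u5); tot18 <- sum(u18)
  out <- data.frame(
    category = factor(c(cat5, "Total"), levels = c(cat5, "Total")),
    under5_count = c(as.integer(u5), as.integer(tot5)),
    under5_share = 100 * c(u5, tot5) / tot5,
    under18_count = c(as.integer(u18), as.integer(tot18)),
    under18_share = 100 * c(u18, tot18) / tot18
  )
  high <- c(under5 = 100 * sum(u5[c("Very High", "High")]) / tot5,
            under18 = 100 * sum(u18[c("Very High", "High")]) / tot18)
  structure(out,
            high_risk = high,
            no_data = c(under5 = sum(children$under5_total[nodata]),
                        under18 = sum(children$under18_total[nodata])),
            level = if (length(unique(areas$level)) == 1)
              as.character(areas$level[1]) else NA_character_)
}

race_cols <- function() c("white", "black", "asian", "hispanic", "other")

validate_race <- function(children) {
  rc <- race_cols()
  miss <- setdiff(c("geo_id", "under5_total", rc), names(children))
  if (length(miss) > 0) {
    stop("tract child table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- abs(rowSums(children[, rc, drop = FALSE]) - children$under5_total) > 1e-8
  if (any(bad)) {
    stop("under-5 race counts do not sum to under5_total in tract(s): ",
         paste(utils::head(children$geo_id[bad], 10), collapse = ", "))
  }
  invisible(children)
}

#' Distribution of under-5 children across risk tiers, by race
#'
#' For each racial group, tabulates the counts and percentage shares of
#' children under 5 across the five risk categories, the combined share
#' living in High or Very High risk tracts, and each group's share of all
#' children living at high risk.
#'
#' @param areas Tract-level output of [aggregate_scores()].
#' @param children Tract-level child table with race columns `white`,
#'   `black`, `asian`, `hispanic`, `other` summing to `under5_total`.
#' @return List with `counts` (race x category data.frame), `shares`
#'   (row percentages), `high_risk_share` (percent of each race's children
#'   in High + Very High tracts), and `share_of_high_risk` (each race's
#'   percent of all High + Very High children).
#' @export
race_risk_distribution <- function(areas, children) {
  validate_race(children)
  idx <- match(as.character(children$geo_id), as.character(areas$geo_id))
  if (anyNA(idx)) {
    stop("child record(s) reference unclassified tract(s): ",
         paste(utils::head(children$geo_id[is.na(idx)], 10), collapse = ", "))
  }
  cat5 <- risk_levels("area")[1:5]
  category <- factor(as.character(areas$category[idx]), levels = cat5)
  keep <- !is.na(category)
  rc <- race_cols()
  counts <- sapply(cat5, function(cl) {
    colSums(children[keep & category == cl, rc, drop = FALSE])
  })
  counts <- as.data.frame(counts)  # race x category
  totals <- rowSums(counts)
  shares <- 100 * sweep(counts, 1, pmax(totals, 1), "/")
  highn <- counts[["Very High"]] + counts[["High"]]
  high_share <- 100 * highn / pmax(totals, 1)
  names(high_share) <- rc
  share_of_high <- 100 * highn / max(sum(highn), 1)
  names(share_of_high) <- rc
  list(counts = counts, shares = shares,
       high_risk_share = high_share, share_of_high_risk = share_of_high)
}

#' Non-white share of tracts, banded, by risk stratum
#'
#' For strata of tracts defined by risk category (by default the combined
#' Very High + High stratum and each single category), reports the fraction
#' of tracts whose under-5 non-white share falls in each band. The default
#' bands nest: ">50%" contains ">75%"; the nesting is declared in the
#' `nesting` attribute rather than resolved away.
#'
#' @param areas Tract-level output of [aggregate_scores()].
#' @param children Tract-level child table with race columns.
#' @param strata Named list mapping stratum label to the risk categories it
#'   pools.
#' @param bands Named list of predicate intervals; each element is
#'   `c(lower, upper)` on the non-white proportion with the convention
#'   lower exclusive / upper inclusive, except a lower bound of 0 which is
#'   inclusive.
#' @return data.frame `stratum`, `band`, `n_tracts`, `fraction` (percent).
#'   Strata with no tracts are omitted and listed in the `empty_strata`
#'   attribute.
#' @export
nonwhite_crosstab <- function(areas, children,
                              strata = list(
                                "Very High+High" = c("Very High", "High"),
                                "Moderate" = "Moderate",
                                "Low" = "Low",
                                "Very Low" = "Very Low"),
                              bands = list("<=10%" = c(0, 0.10),
                                           "10-50%" = c(0.10, 0.50),
                                           ">50%" = c(0.50, 1),
                                           ">75%" = c(0.75, 1))) {
  validate_race(children)
  idx <- match(as.character(children$geo_id), as.character(areas$geo_id))
  if (anyNA(idx)) {
    stop("child record(s) reference unclassified tract(s): ",
         paste(utils::head(children$geo_id[is.na(idx)], 10), collapse = ", "))
  }
  category <- as.character(areas$category[idx])
  nw <- nonwhite_share(children)
  rows <- list(); empty <- character(0)
  for (s in names(strata)) {
    in_s <- category %in% strata[[s]] & !is.na(nw)
    n <- sum(in_s)
    if (n == 0) { empty <- c(empty, s); next }
    for (b in names(bands)) {
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      hit <- if (lo == 0) nw[in_s] >= lo & nw[in_s] <= hi
             else nw[in_s] > lo & nw[in_s] <= hi
      rows[[length(rows) + 1]] <- data.frame(
        stratum = s, band = b, n_tracts = sum(hit),
        fraction = 100 * sum(hit) / n, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(stratum = character(0), band = character(0),
               n_tracts = integer(0), fraction = numeric(0))
  structure(out,
            nesting = "band '>75%' is a subset of band '>50%'",
            empty_strata = empty)
}

#' Non-white share of under-5 children per tract
#'
#' Defined as `1 - white / under5_total`; tracts with no under-5 children
#' get `NA`.
#'
#' @param children Tract-level child table with race columns.
#' @return Numeric vector aligned with `children` rows.
#' @export
nonwhite_share <- function(children) {
  ifelse(children$under5_total > 0,
         1 - children$white / children$under5_total, NA_real_)
}

#' Association between tract risk score and non-white child share
#'
#' Rank correlation (Spearman) between the tract mean lead risk score and
#' the non-white share of under-5 children, the package's summary of the
#' equity gradient; significance via `stats::cor.test`.
#'
#' @param areas Tract-level output of [aggregate_scores()].
#' @param children Tract-level child table with race columns.
#' @return List `estimate` (rho), `p_value`, `n_tracts`.
#' @export
nonwhite_association <- function(areas, children) {
  validate_race(children)
  idx <- match(as.character(children$geo_id), as.character(areas$geo_id))
  nw <- nonwhite_share(children)
  score <- areas$mean_score[idx]
  keep <- !is.na(nw) & !is.na(score)
  ct <- suppressWarnings(
    stats::cor.test(score[keep], nw[keep], method = "spearman"))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n_tracts = sum(keep))
}

#' Linear association between tract risk and an opportunity index
#'
#' Ordinary least squares of each opportunity index (child opportunity,
#' health opportunity) on the tract mean lead risk score; reports slope,
#' intercept, and R-squared. Pairing is by tract id; unmatched tracts are
#' dropped and counted.
#'
#' @param areas Tract-level output of [aggregate_scores()].
#' @param opportunity data.frame `tract_id`, plus one column per index
#'   (default `coi`, `hoi`).
#' @param indices Character vector of index column names to fit.
#' @return data.frame `index`, `slope`, `intercept`, `r_squared`,
#'   `n_tracts`; attribute `n_unmatched`.
#' @export
opportunity_association <- function(areas, opportunity,
                                    indices = intersect(c("coi", "hoi"),
                                                        names(opportunity))) {
  stopifnot("tract_id" %in% names(opportunity), length(indices) > 0)
  idx <- match(as.character(opportunity$tract_id), as.character(areas$geo_id))
  unmatched <- sum(is.na(idx))
  score <- areas$mean_score[idx]
  rows <- lapply(indices, function(nm) {
    y <- opportunity[[nm]]
    keep <- !is.na(score) & !is.na(y)
    if (sum(keep) < 3) stop("need >= 3 paired tracts to fit index '", nm, "'")
    if (stats::var(score[keep]) == 0) {
      stop("tract risk scores have zero variance; fit undefined")
    }
    fit <- stats::lm(y[keep] ~ score[keep])
    # for simple OLS with intercept, R^2 is the squared Pearson correlation
    data.frame(index = toupper(nm),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = stats::cor(score[keep], y[keep])^2,
               n_tracts = sum(keep), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), n_unmatched = unmatched)
}
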