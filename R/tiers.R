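#' Age and value tier rules
#'
#' The parcel-level risk score is built from two three-level tiers. Age:
#' houses built before 1940 score 3, 1940-1959 score 2, 1960 through the
#' 1978 residential lead paint ban score 1; anything built after 1978 is
#' excluded (scored 0) because the hazard cannot be present. Value: parcels
#' appraised under $100,000 score 3, $100,000-$200,000 (inclusive) score 2,
#' above $200,000 score 1 -- low valuation proxies disinvestment and
#' deferred maintenance.
#'
#' @param oldest_before Year below which the age tier scores 3. Default 1940.
#' @param newer_after Year at and above which (up to the exclusion year) the
#'   age tier scores 1. Default 1960.
#' @param exclusion_after Houses built strictly after this year are excluded.
#'   Default 1978.
#' @param low_below Appraised value (USD) below which the value tier scores 3.
#'   Default 100000.
#' @param high_above Appraised value above which the value tier scores 1.
#'   Default 200000. Values equal to either break fall in the moderate tier.
#' @return An object of class `tier_rules`.
#' @export
#' @examples
#' r <- tier_rules()
#' score_age(c(1910, 1943, 1961, 1985), r)   # 3 2 1 NA (excluded)
#' score_value(c(50000, 130000, 275000), r)  # 3 2 1
tier_rules <- function(oldest_before = 1940, newer_after = 1960,
                       exclusion_after = 1978,
                       low_below = 100000, high_above = 200000) {
  if (!(oldest_before < newer_after && newer_after <= exclusion_after)) {
    stop("age breaks must satisfy oldest_before < newer_after <= exclusion_after")
  }
  if (!(low_below < high_above)) {
    stop("value breaks must satisfy low_below < high_above")
  }
  structure(
    list(oldest_before = oldest_before, newer_after = newer_after,
         exclusion_after = exclusion_after,
         low_below = low_below, high_above = high_above),
    class = "tier_rules"
  )
}

#' @export
print.tier_rules <- function(x, ...) {
  cat("Tier rules\n",
      "  age:   <", x$oldest_before, " -> 3;  [", x$oldest_before, ",",
      x$newer_after, ") -> 2;  [", x$newer_after, ",", x$exclusion_after,
      "] -> 1;  >", x$exclusion_after, " excluded\n",
      "  value: <$", format(x$low_below, big.mark = ","), " -> 3;  [$",
      format(x$low_below, big.mark = ","), ", $",
      format(x$high_above, big.mark = ","), "] -> 2;  >$",
      format(x$high_above, big.mark = ","), " -> 1\n", sep = "")
  invisible(x)
}

#' Age tier score
#'
#' @param year_built Integer vector of construction years.
#' @param rules A [tier_rules()] object.
#' @return Integer vector in \{1, 2, 3\}, with `NA` for excluded
#'   (post-exclusion-year) parcels.
#' @export
score_age <- function(year_built, rules = tier_rules()) {
  stopifnot(inherits(rules, "tier_rules"))
  y <- as.numeric(year_built)
  bad <- !is.na(y) & (y < 1850 | y > as.integer(format(Sys.Date(), "%Y")))
  if (any(bad)) {
    stop("implausible year_built: ", paste(utils::head(y[bad], 5), collapse = ", "))
  }
  out <- rep(NA_integer_, length(y))
  out[y < rules$oldest_before] <- 3L
  out[y >= rules$oldest_before & y < rules$newer_after] <- 2L
  out[y >= rules$newer_after & y <= rules$exclusion_after] <- 1L
  out
}

#' Value tier score
#'
#' @param appraised_value Numeric vector of appraised values (USD, >= 0).
#' @param rules A [tier_rules()] object.
#' @return Integer vector in \{1, 2, 3\}.
#' @export
score_value <- function(appraised_value, rules = tier_rules()) {
  stopifnot(inherits(rules, "tier_rules"))
  v <- as.numeric(appraised_value)
  if (any(!is.na(v) & v < 0)) stop("appraised_value must be >= 0")
  out <- rep(NA_integer_, length(v))
  out[v < rules$low_below] <- 3L
  out[v >= rules$low_below & v <= rules$high_above] <- 2L
  out[v > rules$high_above] <- 1L
  out
}
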