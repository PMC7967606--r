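# shared fixtures and independent reference implementations

# random parcel table (valid rows only)
random_parcels <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    parcel_id = sprintf("R%05d", seq_len(n)),
    year_built = sample(1850:2015, n, replace = TRUE),
    appraised_value = round(stats::rlnorm(n, log(150000), 0.8)),
    grade = sample(grade_levels(), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# naive per-row reference scorer, written independently of score_parcels
naive_score <- function(year, value, grade, mods = default_modifiers()) {
  if (year > 1978) return(0)
  a <- if (year < 1940) 3 else if (year < 1960) 2 else 1
  v <- if (value < 100000) 3 else if (value <= 200000) 2 else 1
  (a + v) * as.numeric(mods)[match(normalize_grade(grade), names(mods))]
}

# the ten worked example properties with their published score columns
worked_examples <- function() {
  data.frame(
    parcel_id = paste("Property", 1:10),
    year_built = c(1985, 1971, 1965, 1961, 1955, 1951, 1943, 1932, 1927, 1910),
    appraised_value = c(156000, 275000, 130000, 70000, 270000, 145000,
                        60000, 265000, 130000, 50000),
    grade = c("B", "B", "C", "C-", "B-", "C--", "D+", "A-", "C++", "D"),
    age_score = c(NA, 1, 1, 1, 2, 2, 2, 3, 3, 3),
    value_score = c(NA, 1, 2, 3, 1, 2, 3, 1, 2, 3),
    cumulative = c(NA, 2, 3, 4, 3, 4, 5, 4, 5, 6),
    final_score = c(0, 0.2, 1.5, 2.4, 0.6, 2.8, 4.5, 0.1, 1.5, 6),
    stringsAsFactors = FALSE)
}

# small county used across integration-style tests
small_county <- function(seed = 11, n_parcels = 4000) {
  simulate_county(synthetic_config(n_parcels = n_parcels, seed = seed))
}
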