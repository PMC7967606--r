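test_that("the ten worked example properties reproduce every score column", {
  ex <- worked_examples()
  res <- score_parcels(ex[, 1:4])
  expect_equal(nrow(res$rejects), 0)
  expect_true(res$scores$excluded[1])
  expect_equal(res$scores$age_score, ex$age_score)
  expect_equal(res$scores$value_score, ex$value_score)
  expect_equal(res$scores$cumulative, ex$cumulative)
  expect_equal(res$scores$final_score, ex$final_score)

  # packaged fixture carries the same ten properties
  fix <- score_parcels(example_parcels())
  expect_equal(fix$scores$final_score, ex$final_score)
})

test_that("tier boundaries follow the documented half-open bins", {
  r <- tier_rules()
  # age: [<1940] -> 3, [1940,1960) -> 2, [1960,1978] -> 1, >1978 excluded
  expect_equal(score_age(c(1939, 1940, 1959, 1960, 1978), r), c(3, 2, 2, 1, 1))
  expect_true(is.na(score_age(1979, r)))
  # value: both break points belong to the moderate tier
  expect_equal(score_value(c(99999, 100000, 200000, 200001), r), c(3, 2, 2, 1))
})

test_that("default modifiers reproduce the nine anchored ratios and are monotone", {
  m <- default_modifiers()
  anchors <- c("B" = 0.1, "B-" = 0.2, "C++" = 0.3, "C" = 0.5, "C-" = 0.6,
               "C--" = 0.7, "D+" = 0.9, "D" = 1.0, "A-" = 0.025)
  expect_equal(as.numeric(m)[match(names(anchors), names(m))],
               unname(anchors))
  # full table non-increasing as quality improves (best -> worst ordering)
  expect_true(all(diff(as.numeric(m)) >= 0))
  expect_setequal(names(m), grade_levels())
})

test_that("modifier table validation rejects broken inputs and unknown grades", {
  expect_error(grade_modifier_table(c(A = 0.02, B = 0.01)), "non-increasing")
  expect_error(grade_modifier_table(c(Z = 0.5)), "unknown grade")
  expect_error(grade_modifier_table(c(A = -1)), "> 0")
  small <- grade_modifier_table(c(C = 0.5))
  expect_error(lookup_modifier(small, "D+"), "D\\+")
})

test_that("final score is monotone over the full (year, value, grade) lattice", {
  years <- 1900:1978
  values <- seq(25000, 400000, by = 25000)
  grades <- grade_levels()
  lat <- expand.grid(year_built = years, appraised_value = values,
                     grade = grades, stringsAsFactors = FALSE)
  res <- score_parcels(lat)$scores
  expect_true(all(res$cumulative %in% 2:6))
  arr <- array(res$final_score, dim = c(length(years), length(values),
                                        length(grades)))
  # non-increasing in year built (other two fixed)
  expect_true(all(apply(arr, c(2, 3), function(v) all(diff(v) <= 0))))
  # non-increasing in appraised value
  expect_true(all(apply(arr, c(1, 3), function(v) all(diff(v) <= 0))))
  # non-increasing in grade quality: grades indexed best -> worst
  expect_true(all(apply(arr, c(1, 2), function(v) all(diff(v) >= 0))))
})

test_that("vectorized scoring matches a naive per-row reference on random parcels", {
  p <- random_parcels(10000, seed = 42)
  res <- score_parcels(p)
  expect_equal(nrow(res$rejects), 0)
  ref <- mapply(naive_score, p$year_built, p$appraised_value, p$grade)
  expect_equal(res$scores$final_score, unname(ref))
})

test_that("malformed rows go to the rejects report and accounting balances", {
  p <- data.frame(year_built = c("1950", "196o", "1970", "", "1930"),
                  appraised_value = c(50000, 60000, -5, 70000, 80000),
                  grade = c("C", "C", "C", "C", NA),
                  stringsAsFactors = FALSE)
  res <- score_parcels(p)
  expect_equal(nrow(res$scores) + nrow(res$rejects), nrow(p))
  expect_equal(nrow(res$scores), 1)  # only the first row is fully valid
  expect_match(res$rejects$reason[res$rejects$row == 2], "year_built")
  expect_match(res$rejects$reason[res$rejects$row == 3], "negative")
  expect_match(res$rejects$reason[res$rejects$row == 5], "grade")

  empty <- score_parcels(p[0, ])
  expect_equal(nrow(empty$scores), 0)
  expect_equal(nrow(empty$rejects), 0)
})

test_that("post-ban parcels score 0 but stay in the table", {
  p <- data.frame(year_built = c(1979, 1990, 2010),
                  appraised_value = c(10, 1e6, 150000),
                  grade = c("E--", "A++", "C"))
  res <- score_parcels(p)
  expect_equal(res$scores$final_score, c(0, 0, 0))
  expect_true(all(res$scores$excluded))
  expect_equal(exclusion_rate(res$scores), 1)
})

test_that("currency-formatted values and unicode minus grades are parsed", {
  p <- data.frame(year_built = 1950, appraised_value = "$1,234",
                  grade = "A−", stringsAsFactors = FALSE)
  res <- score_parcels(p)
  expect_equal(res$scores$value_score, 3L)  # $1,234 -> 1234 -> low tier
  expect_equal(res$scores$modifier, 0.025)  # A− normalized to A-
})
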