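# areas helper: one unit per category with a chosen mean score
areas_by_category <- function() {
  data.frame(geo_id = c("vh", "h", "m", "l", "vl"),
             level = "block_group",
             parcel_count = 1L,
             score_sum = c(3.5, 2.5, 1.5, 0.5, 0),
             mean_score = c(3.5, 2.5, 1.5, 0.5, 0),
             category = classify_risk(c(3.5, 2.5, 1.5, 0.5, 0)))
}

test_that("exposure table arithmetic: counts, shares, and the high-risk rollup", {
  children <- data.frame(geo_id = c("vh", "h", "m", "l", "vl"),
                         under5_total = c(9526, 15361, 17320, 45780, 2494),
                         under18_total = c(30569, 50084, 52944, 157185, 6789))
  tab <- exposure_table(areas_by_category(), children)
  expect_equal(tab$under5_count[tab$category == "Total"], 90481L)
  expect_equal(tab$under18_count[tab$category == "Total"], 297571L)
  expect_equal(round(tab$under5_share[1:5], 1), c(10.5, 17.0, 19.1, 50.6, 2.8))
  expect_equal(tab$under5_share[tab$category == "Total"], 100)
  hr <- attr(tab, "high_risk")
  expect_equal(round(hr[["under5"]], 1), 27.5)
  expect_equal(round(hr[["under18"]], 1), 27.1)
  # shares are exact ratios of the count columns
  expect_equal(tab$under5_share[1:5], 100 * tab$under5_count[1:5] / 90481)
})

test_that("exposure table handles degenerate and invalid inputs", {
  areas <- areas_by_category()
  one_cat <- data.frame(geo_id = "h", under5_total = 50, under18_total = 120)
  tab <- exposure_table(areas, one_cat)
  expect_equal(tab$under5_share[tab$category == "High"], 100)
  expect_equal(sum(tab$under5_count[1:5]), 50L)

  expect_error(exposure_table(areas, data.frame(geo_id = "zzz",
                                                under5_total = 1,
                                                under18_total = 1)),
               "no risk classification")

  # No Data units are tallied separately, not in the shares
  areas_nd <- rbind(areas, data.frame(geo_id = "nd", level = "block_group",
                                      parcel_count = 0L, score_sum = NA,
                                      mean_score = NA,
                                      category = classify_risk(NA)))
  children <- data.frame(geo_id = c("h", "nd"), under5_total = c(10, 7),
                         under18_total = c(20, 9))
  tab2 <- exposure_table(areas_nd, children)
  expect_equal(tab2$under5_count[tab2$category == "Total"], 10L)
  expect_equal(attr(tab2, "no_data")[["under5"]], 7)
})

test_that("race distribution recovers the Black share of high-risk children", {
  areas <- areas_by_category()
  children <- data.frame(
    geo_id = c("h", "l"), under5_total = c(24486, 40000),
    white = c(13002, 36000), black = c(11484, 1500),
    asian = c(0, 1500), hispanic = c(0, 800), other = c(0, 200))
  rr <- race_risk_distribution(areas, children)
  expect_equal(round(rr$share_of_high_risk[["black"]], 1), 46.9)
  expect_equal(rr$counts["black", "High"], 11484)
  expect_equal(rr$high_risk_share[["black"]], 100 * 11484 / (11484 + 1500))
  # per-race shares sum to 100
  expect_equal(unname(rowSums(rr$shares)), rep(100, 5))
})

test_that("a single-race population reproduces the overall distribution", {
  areas <- areas_by_category()
  children <- data.frame(geo_id = c("vh", "m", "l"),
                         under5_total = c(30, 50, 20),
                         white = 0, black = c(30, 50, 20),
                         asian = 0, hispanic = 0, other = 0)
  rr <- race_risk_distribution(areas, children)
  overall <- c(30, 0, 50, 20, 0) / 100
  expect_equal(unname(unlist(rr$shares["black", ])), 100 * overall)
  expect_error(race_risk_distribution(
    areas, transform(children, black = black + 1)), "do not sum")
})

test_that("non-white crosstab bands tracts correctly and flags empty strata", {
  areas <- areas_by_category()
  # 4 high-risk tracts with non-white shares {0.6, 0.7, 0.4, 0.9}
  children <- data.frame(
    geo_id = c("vh", "vh2", "h", "h2"),
    under5_total = c(10, 10, 10, 10),
    white = c(4, 3, 6, 1), black = c(6, 7, 4, 9),
    asian = 0, hispanic = 0, other = 0)
  areas2 <- rbind(areas, within(areas[1:2, ], geo_id <- c("vh2", "h2")))
  ct <- nonwhite_crosstab(areas2, children)
  hi <- ct[ct$stratum == "Very High+High", ]
  expect_equal(hi$fraction[hi$band == ">50%"], 75)
  expect_equal(hi$fraction[hi$band == ">75%"], 25)
  expect_true(all(c("Moderate", "Low", "Very Low") %in%
                    attr(ct, "empty_strata")))

  # all tracts fully non-white -> >50% band is 100% everywhere observed
  allnw <- transform(children, white = 0, black = 10)
  ct2 <- nonwhite_crosstab(areas2, allnw)
  expect_true(all(ct2$fraction[ct2$band == ">50%"] == 100))
})

test_that("opportunity association matches the closed-form R-squared oracle", {
  # noiseless line: R^2 exactly 1, negative slope recovered
  areas <- data.frame(geo_id = sprintf("T%d", 1:6), level = "tract",
                      mean_score = c(0.2, 0.8, 1.4, 2.1, 2.9, 3.4))
  opp <- data.frame(tract_id = areas$geo_id,
                    coi = 70 - 15 * areas$mean_score,
                    hoi = 55 - 10 * areas$mean_score)
  fit <- opportunity_association(areas, opp)
  expect_equal(fit$r_squared, c(1, 1))
  expect_equal(fit$slope, c(-15, -10))

  # five hand-picked noisy points vs squared Pearson correlation
  x <- c(0.5, 1.2, 1.9, 2.6, 3.1)
  y <- c(61, 47, 52, 30, 24)
  areas5 <- data.frame(geo_id = letters[1:5], level = "tract", mean_score = x)
  fit5 <- opportunity_association(areas5,
                                  data.frame(tract_id = letters[1:5], coi = y),
                                  indices = "coi")
  expect_equal(fit5$r_squared, cor(x, y)^2, tolerance = 1e-9)
  expect_equal(sign(fit5$slope), sign(cor(x, y)))

  # R^2 invariant under affine rescaling of the index
  fit_scaled <- opportunity_association(
    areas5, data.frame(tract_id = letters[1:5], coi = 3.7 * y + 100),
    indices = "coi")
  expect_equal(fit_scaled$r_squared, fit5$r_squared, tolerance = 1e-12)

  expect_error(opportunity_association(areas5[1:2, ],
                                       data.frame(tract_id = letters[1:2],
                                                  coi = y[1:2])),
               ">= 3")
  flat <- data.frame(geo_id = letters[1:5], level = "tract", mean_score = 1)
  expect_error(opportunity_association(flat,
                                       data.frame(tract_id = letters[1:5],
                                                  coi = y)),
               "zero variance")
})
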