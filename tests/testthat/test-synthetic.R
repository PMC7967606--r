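test_that("geography counts are forced by the grid configuration", {
  g1 <- generate_geographies(synthetic_config(grid_blocks = c(2, 2),
                                              blocks_per_block_group = 2,
                                              block_groups_per_tract = 2))
  expect_equal(nrow(g1$blocks), 4)
  expect_equal(nrow(g1$block_groups), 2)
  expect_equal(nrow(g1$tracts), 1)

  g2 <- generate_geographies(synthetic_config(grid_blocks = c(4, 4),
                                              blocks_per_block_group = 4,
                                              block_groups_per_tract = 2))
  expect_equal(nrow(g2$blocks), 16)
  expect_equal(nrow(g2$block_groups), 4)
  expect_equal(nrow(g2$tracts), 2)

  # block squares tile the county rectangle exactly: total area matches and
  # no two blocks share a lower-left corner
  area <- sum((g2$blocks$xmax - g2$blocks$xmin) *
                (g2$blocks$ymax - g2$blocks$ymin))
  expect_equal(area, 16)
  expect_equal(anyDuplicated(g2$blocks[, c("xmin", "ymin")]), 0)

  expect_error(synthetic_config(grid_blocks = c(2, 2),
                                blocks_per_block_group = 5),
               "smaller than one block group")
  expect_error(synthetic_config(grid_blocks = c(1, 5)), "at least 2 x 2")
})

test_that("generators are bit-for-bit reproducible for a fixed seed", {
  cfg <- synthetic_config(n_parcels = 1500, n_centers = 40, seed = 99)
  a <- simulate_county(cfg)
  b <- simulate_county(cfg)
  expect_identical(a$parcels, b$parcels)
  expect_identical(a$children, b$children)
  expect_identical(a$childcare, b$childcare)
  expect_identical(a$opportunity, b$opportunity)
})

test_that("parcel marginals match the configuration at n = 20000", {
  cfg <- synthetic_config(n_parcels = 20000, seed = 1)
  geo <- generate_geographies(cfg)
  p <- generate_parcels(cfg, geo)
  expect_equal(nrow(p), 20000)

  # post-ban share within 3 binomial SDs of the configured 0.474
  share <- mean(p$year_built > 1978)
  tol <- 3 * sqrt(0.474 * (1 - 0.474) / 20000)
  expect_lt(abs(share - 0.474), tol)

  # grade frequencies conditional on value tier within 3 Monte-Carlo SDs
  tier <- c("high", "moderate", "low")[score_value(p$appraised_value)]
  for (tr in c("low", "moderate", "high")) {
    sel <- tier == tr
    n_t <- sum(sel)
    freq <- table(factor(p$grade[sel], levels = grade_levels())) / n_t
    expected <- cfg$grade_distribution[tr, ]
    sds <- sqrt(pmax(expected * (1 - expected), 1e-12) / n_t)
    expect_true(all(abs(freq - expected) <= 3 * sds + 1e-9))
  }

  # roughly a third of pre-ban parcels in each value tier
  pre_tier <- table(score_value(p$appraised_value[p$year_built <= 1978]))
  expect_true(all(pre_tier / sum(pre_tier) > 0.2 &
                    pre_tier / sum(pre_tier) < 0.5))
})

test_that("the radial gradient couples age to distance and Inf removes it", {
  cfg <- synthetic_config(n_parcels = 20000, seed = 2)
  geo <- generate_geographies(cfg)
  p <- generate_parcels(cfg, geo)
  cx <- mean(geo$bounds[c("xmin", "xmax")])
  cy <- mean(geo$bounds[c("ymin", "ymax")])
  d <- sqrt((p$x - cx)^2 + (p$y - cy)^2)
  # housing age falls with distance: tract mean age (years since built)
  # correlates negatively with distance from the center
  tract_age <- tapply(2020 - p$year_built, p$tract_id, mean)
  tract_d <- tapply(d, p$tract_id, mean)
  expect_lt(cor(tract_age, tract_d), -0.3)

  flat <- synthetic_config(n_parcels = 20000, center_decay = Inf, seed = 2)
  pf <- generate_parcels(flat, geo)
  df <- sqrt((pf$x - cx)^2 + (pf$y - cy)^2)
  expect_lt(abs(cor(pf$year_built, df)), 0.05)
})

test_that("parcel coordinates fall inside their assigned block polygon", {
  county <- small_county(seed = 4, n_parcels = 3000)
  blocks <- county$geographies$blocks
  idx <- sample(nrow(county$parcels), 100)
  for (i in idx) {
    b <- blocks[blocks$block_id == county$parcels$block_id[i], ]
    ring <- cbind(c(b$xmin, b$xmax, b$xmax, b$xmin),
                  c(b$ymin, b$ymin, b$ymax, b$ymax))
    expect_true(point_in_polygon(county$parcels$x[i], county$parcels$y[i],
                                 ring))
    # containment hierarchy is consistent with the block's parents
    expect_equal(county$parcels$block_group_id[i], b$block_group_id)
    expect_equal(county$parcels$tract_id[i], b$tract_id)
  }
})

test_that("child counts respect construction invariants and the race gradient", {
  county <- small_county(seed = 6, n_parcels = 8000)
  ch <- county$children
  expect_true(all(ch$under5_total >= 0))
  expect_true(all(ch$under18_total >= ch$under5_total))
  tr <- ch[ch$level == "tract", ]
  expect_equal(rowSums(tr[, c("white", "black", "asian", "hispanic", "other")]),
               tr$under5_total, ignore_attr = TRUE)
  bg <- ch[ch$level == "block_group", ]
  expect_true(all(is.na(bg$white)))
  # tract under-5 totals are sums of their block groups
  bgs <- county$geographies$block_groups
  bysum <- tapply(bg$under5_total[match(bgs$block_group_id, bg$geo_id)],
                  bgs$tract_id, sum)
  expect_equal(as.integer(bysum[tr$geo_id]), tr$under5_total)

  # race_gradient = 0 decouples race from housing age
  cfg0 <- synthetic_config(n_parcels = 8000, race_gradient = 0, seed = 6)
  county0 <- simulate_county(cfg0)
  tr0 <- county0$children[county0$children$level == "tract", ]
  age0 <- tapply(county0$parcels$year_built, county0$parcels$tract_id, mean)
  r0 <- cor(age0[tr0$geo_id], nonwhite_share(tr0), method = "spearman")
  expect_lt(abs(r0), 0.35)
})

test_that("childcare centers follow the registry type mix and center density", {
  county <- small_county(seed = 8, n_parcels = 2000)
  cc <- county$childcare
  expect_equal(nrow(cc), 250)
  expect_true(all(cc$program_type %in% program_types()))
  # licensed centers are the modal type
  expect_equal(names(which.max(table(cc$program_type))),
               "Licensed Childcare Center")
  # inside county bounds
  b <- county$geographies$bounds
  expect_true(all(cc$x >= b["xmin"] & cc$x <= b["xmax"] &
                    cc$y >= b["ymin"] & cc$y <= b["ymax"]))

  cfg0 <- synthetic_config(n_centers = 0, seed = 8)
  empty <- generate_childcare(cfg0, generate_geographies(cfg0))
  expect_equal(nrow(empty), 0)
})

test_that("opportunity indices hit R^2 = 1 when noiseless and refuse tiny inputs", {
  cfg <- synthetic_config(opp_index_noise_sd = 0, seed = 12)
  scores <- data.frame(geo_id = sprintf("T%03d", 1:20), level = "tract",
                       mean_score = seq(0.1, 3.5, length.out = 20))
  opp <- generate_opportunity(cfg, scores)
  fit <- opportunity_association(scores, opp)
  expect_equal(fit$r_squared, c(1, 1), tolerance = 1e-12)
  expect_true(all(fit$slope < 0))
  expect_error(generate_opportunity(cfg, scores[1:2, ]), "at least 3")
})
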