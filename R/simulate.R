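#' Configuration for the synthetic county generator
#'
#' Defines a square-grid county in planar mile units whose housing stock,
#' child population, childcare centers, and opportunity indices carry the
#' statistical structure the hazard analysis assumes: older, cheaper,
#' lower-grade parcels concentrate near the county center, and the non-white
#' share of young children rises with neighborhood housing age.
#'
#' @param n_parcels Number of residential parcels (default 20000).
#' @param grid_blocks `c(rows, cols)` of 1-mile-square census blocks
#'   (default `c(20, 20)`).
#' @param blocks_per_block_group Consecutive blocks pooled into one block
#'   group (default 4).
#' @param block_groups_per_tract Block groups pooled into one tract
#'   (default 2). The defaults give 400 blocks, 100 block groups, 50 tracts.
#' @param frac_post1978 Marginal share of parcels built after the 1978 lead
#'   paint ban (default 0.474, the share observed in the county that
#'   motivated the method).
#' @param center_decay Length scale (miles) of the radial gradient: mean
#'   year built and mean value rise with distance from the county center as
#'   `1 - exp(-d / center_decay)`. `Inf` switches the gradient off.
#' @param value_lognormal_params `c(meanlog, sdlog)` of appraised value; the
#'   default puts roughly a third of pre-1979 parcels in each value tier.
#' @param grade_distribution 3 x 17 matrix of grade probabilities, rows
#'   `low`/`moderate`/`high` value tier, columns [grade_levels()]; each row
#'   sums to 1. Cheaper parcels draw worse grades.
#' @param n_centers Number of childcare centers (default 250).
#' @param race_gradient Log-odds increase in tract non-white under-5 share
#'   per standard deviation of tract mean housing age (default 1.5; 0
#'   decouples race from risk).
#' @param opp_target_r2 Named vector: target regression R-squared of the
#'   generated opportunity indices on tract risk (default `coi` 0.62,
#'   `hoi` 0.53, the associations the index comparison emulates).
#' @param opp_index_noise_sd Optional residual SD override for both indices;
#'   `NULL` (default) calibrates the SD from `opp_target_r2` via
#'   `sd = sqrt(var(signal) * (1 - R2) / R2)`.
#' @param seed Integer RNG seed; each generator draws from an independent
#'   substream derived from it, so adding a generator never perturbs
#'   earlier draws.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_parcels = 20000,
                             grid_blocks = c(20, 20),
                             blocks_per_block_group = 4,
                             block_groups_per_tract = 2,
                             frac_post1978 = 0.474,
                             center_decay = 5,
                             value_lognormal_params = c(meanlog = log(140000),
                                                        sdlog = 0.7),
                             grade_distribution = default_grade_distribution(),
                             n_centers = 250,
                             race_gradient = 1.5,
                             opp_target_r2 = c(coi = 0.62, hoi = 0.53),
                             opp_index_noise_sd = NULL,
                             seed = 1) {
  stopifnot(n_parcels >= 1, length(grid_blocks) == 2)
  if (any(grid_blocks < 2)) stop("grid_blocks must be at least 2 x 2")
  if (frac_post1978 < 0 || frac_post1978 > 1) {
    stop("frac_post1978 must be a proportion in [0, 1]")
  }
  if (center_decay <= 0) stop("center_decay must be positive")
  if (prod(grid_blocks) < blocks_per_block_group) {
    stop("grid smaller than one block group")
  }
  gd <- as.matrix(grade_distribution)
  if (!identical(dim(gd), c(3L, length(grade_levels()))) ||
      any(abs(rowSums(gd) - 1) > 1e-9) || any(gd < 0)) {
    stop("grade_distribution must be 3 x ", length(grade_levels()),
         " with non-negative rows summing to 1")
  }
  rownames(gd) <- c("low", "moderate", "high")
  colnames(gd) <- grade_levels()
  if (any(opp_target_r2 <= 0 | opp_target_r2 >= 1)) {
    stop("opp_target_r2 values must lie in (0, 1)")
  }
  structure(
    list(n_parcels = as.integer(n_parcels),
         grid_blocks = as.integer(grid_blocks),
         blocks_per_block_group = as.integer(blocks_per_block_group),
         block_groups_per_tract = as.integer(block_groups_per_tract),
         frac_post1978 = frac_post1978,
         center_decay = center_decay,
         value_lognormal_params = value_lognormal_params,
         grade_distribution = gd,
         n_centers = as.integer(n_centers),
         race_gradient = race_gradient,
         opp_target_r2 = opp_target_r2,
         opp_index_noise_sd = opp_index_noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Default grade probabilities by value tier
#'
#' Cheaper housing draws worse grades: the low-value tier is centered on
#' C-/D grades with a tail into E, the moderate tier on C, and the
#' high-value tier on B with a tail into A.
#'
#' @return 3 x 17 probability matrix, rows `low`/`moderate`/`high` value
#'   tier, columns [grade_levels()].
#' @export
default_grade_distribution <- function() {
  g <- grade_levels()
  low <- c(0, 0, 0, 0.002, 0.008, 0.02, 0.03, 0.06, 0.09, 0.16, 0.17,
           0.15, 0.14, 0.09, 0.05, 0.02, 0.01)
  moderate <- c(0, 0, 0.005, 0.015, 0.04, 0.07, 0.09, 0.13, 0.15, 0.22,
                0.13, 0.08, 0.04, 0.02, 0.007, 0.002, 0.001)
  high <- c(0.02, 0.03, 0.06, 0.08, 0.12, 0.18, 0.15, 0.12, 0.09, 0.08,
            0.04, 0.02, 0.006, 0.004, 0, 0, 0)
  m <- rbind(low = low, moderate = moderate, high = high)
  colnames(m) <- g
  m
}

# independent substreams from one seed; k indexes the generator
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)
}

#' Generate the census geography grid
#'
#' Lays out a rows x cols grid of 1-mile-square census blocks, pools
#' consecutive blocks (row-major) into block groups and consecutive block
#' groups into tracts. Deterministic: no random draws. Block polygons tile
#' the county rectangle exactly and the containment hierarchy is total.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `county_geography`: list with `blocks` (block_id,
#'   block_group_id, bbox), `block_groups` (block_group_id, tract_id),
#'   `tracts` (tract_id), and `bounds` (county rectangle, miles).
#' @export
generate_geographies <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nr <- config$grid_blocks[1]; nc <- config$grid_blocks[2]
  n_blocks <- nr * nc
  i <- seq_len(n_blocks)
  row <- (i - 1) %/% nc
  col <- (i - 1) %% nc
  bg_index <- (i - 1) %/% config$blocks_per_block_group
  tract_index <- bg_index %/% config$block_groups_per_tract
  blocks <- data.frame(
    block_id = sprintf("B%04d", i),
    block_group_id = sprintf("G%03d", bg_index + 1),
    tract_id = sprintf("T%03d", tract_index + 1),
    xmin = col, ymin = row, xmax = col + 1, ymax = row + 1,
    stringsAsFactors = FALSE)
  block_groups <- unique(blocks[, c("block_group_id", "tract_id")])
  rownames(block_groups) <- NULL
  tracts <- data.frame(tract_id = unique(block_groups$tract_id),
                       stringsAsFactors = FALSE)
  structure(list(blocks = blocks, block_groups = block_groups,
                 tracts = tracts, bounds = c(xmin = 0, ymin = 0,
                                             xmax = nc, ymax = nr)),
            class = "county_geography")
}

# radial gradient in [0, 1): 0 at the county center, saturating outward;
# identically 0 when center_decay = Inf (no gradient)
radial_gradient <- function(x, y, geographies, center_decay) {
  cx <- mean(geographies$bounds[c("xmin", "xmax")])
  cy <- mean(geographies$bounds[c("ymin", "ymax")])
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  if (is.infinite(center_decay)) rep(0, length(d)) else 1 - exp(-d / center_decay)
}

#' Generate residential parcels
#'
#' Parcels are placed uniformly across blocks; year built, appraised value
#' and grade follow the radial disinvestment gradient: near the center the
#' stock is older, cheaper and worse-graded. The marginal post-ban share is
#' held at `frac_post1978` by solving the intercept of a logistic-in-distance
#' exclusion probability. Bit-for-bit reproducible for a fixed config.
#'
#' @param config A [synthetic_config()].
#' @param geographies Output of [generate_geographies()].
#' @return data.frame of parcels: `parcel_id`, `year_built`,
#'   `appraised_value`, `grade`, `x`, `y`, `block_id`, `block_group_id`,
#'   `tract_id`.
#' @export
generate_parcels <- function(config, geographies) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(geographies, "county_geography"))
  set.seed(substream_seed(config$seed, 1))
  n <- config$n_parcels
  blocks <- geographies$blocks
  bi <- sample.int(nrow(blocks), n, replace = TRUE)
  x <- blocks$xmin[bi] + stats::runif(n)
  y <- blocks$ymin[bi] + stats::runif(n)
  g <- radial_gradient(x, y, geographies, config$center_decay)

  # exclusion probability: rises with distance, marginal mean pinned to target
  p_post <- if (config$frac_post1978 %in% c(0, 1)) {
    rep(config$frac_post1978, n)
  } else {
    z <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else rep(0, n)
    a <- stats::uniroot(function(a) mean(stats::plogis(a + 1.5 * z)) -
                          config$frac_post1978,
                        interval = c(-30, 30))$root
    stats::plogis(a + 1.5 * z)
  }
  post <- stats::runif(n) < p_post

  gmax <- max(g)
  gn <- if (gmax > 0) g / gmax else g
  year <- integer(n)
  year[post] <- sample(1979:2015, sum(post), replace = TRUE)
  pre_mean <- 1915 + 55 * gn[!post]
  year[!post] <- pmin(1978, pmax(1850,
                                 round(pre_mean + stats::rnorm(sum(!post), 0, 15))))

  meanlog <- config$value_lognormal_params[[1]] + 0.9 * (gn - mean(gn))
  value <- round(stats::rlnorm(n, meanlog, config$value_lognormal_params[[2]]))

  vt <- score_value(value, tier_rules())  # 3 = low, 2 = moderate, 1 = high
  tier_row <- c("high", "moderate", "low")[vt]
  grade <- character(n)
  for (tr in c("low", "moderate", "high")) {
    k <- tier_row == tr
    if (any(k)) {
      grade[k] <- sample(grade_levels(), sum(k), replace = TRUE,
                         prob = config$grade_distribution[tr, ])
    }
  }

  data.frame(parcel_id = sprintf("P%06d", seq_len(n)),
             year_built = year,
             appraised_value = value,
             grade = grade,
             x = x, y = y,
             block_id = blocks$block_id[bi],
             block_group_id = blocks$block_group_id[bi],
             tract_id = blocks$tract_id[bi],
             stringsAsFactors = FALSE)
}

#' Generate child population counts
#'
#' Block-group records carry under-5 and under-18 totals only (mirroring the
#' survey tables, which do not disaggregate by race below tract level);
#' tract records add the under-5 decomposition into White, Black, Asian,
#' Hispanic and Other, with the non-white share rising with tract mean
#' housing age at strength `race_gradient`. Race counts are multinomial
#' draws, so they sum exactly to the tract under-5 total.
#'
#' @param config A [synthetic_config()].
#' @param geographies Output of [generate_geographies()].
#' @param parcels Output of [generate_parcels()].
#' @return data.frame `geo_id`, `level`, `under5_total`, `under18_total`,
#'   `white`, `black`, `asian`, `hispanic`, `other` (race columns `NA` on
#'   block-group rows).
#' @export
generate_children <- function(config, geographies, parcels) {
  set.seed(substream_seed(config$seed, 2))
  bgs <- geographies$block_groups
  n_in_bg <- table(factor(parcels$block_group_id, levels = bgs$block_group_id))
  under5_bg <- stats::rpois(nrow(bgs), lambda = 5 + 0.12 * as.integer(n_in_bg))
  under18_bg <- under5_bg + stats::rpois(nrow(bgs), lambda = 2.2 * under5_bg + 8)

  tracts <- geographies$tracts$tract_id
  under5_tr <- as.integer(tapply(under5_bg, bgs$tract_id, sum)[tracts])
  under18_tr <- as.integer(tapply(under18_bg, bgs$tract_id, sum)[tracts])

  mean_year <- tapply(parcels$year_built, factor(parcels$tract_id,
                                                 levels = tracts), mean)
  age <- -as.numeric(mean_year)          # older stock = larger age signal
  age[is.na(age)] <- mean(age, na.rm = TRUE)
  z <- if (stats::sd(age) > 0) (age - mean(age)) / stats::sd(age) else age * 0
  share_nw <- stats::plogis(stats::qlogis(0.35) + config$race_gradient * z)

  race <- matrix(0L, nrow = length(tracts), ncol = 5,
                 dimnames = list(NULL, race_cols()))
  split_nw <- c(black = 0.58, asian = 0.12, hispanic = 0.18, other = 0.12)
  for (i in seq_along(tracts)) {
    p <- c(white = 1 - share_nw[i], split_nw * share_nw[i])
    race[i, ] <- as.integer(stats::rmultinom(1, under5_tr[i],
                                             p[race_cols()]))
  }

  bg_rows <- data.frame(geo_id = bgs$block_group_id, level = "block_group",
                        under5_total = under5_bg, under18_total = under18_bg,
                        white = NA_integer_, black = NA_integer_,
                        asian = NA_integer_, hispanic = NA_integer_,
                        other = NA_integer_, stringsAsFactors = FALSE)
  tr_rows <- data.frame(geo_id = tracts, level = "tract",
                        under5_total = under5_tr, under18_total = under18_tr,
                        stringsAsFactors = FALSE)
  tr_rows <- cbind(tr_rows, as.data.frame(race))
  rbind(bg_rows, tr_rows)
}

#' Generate childcare centers
#'
#' Program types follow the marginal mix observed across a county registry
#' (licensed centers dominate); locations are denser toward the county
#' center, where more families live.
#'
#' @param config A [synthetic_config()].
#' @param geographies Output of [generate_geographies()].
#' @return data.frame `center_id`, `program_type`, `x`, `y`.
#' @export
generate_childcare <- function(config, geographies) {
  set.seed(substream_seed(config$seed, 3))
  n <- config$n_centers
  if (n == 0) {
    return(data.frame(center_id = character(0), program_type = character(0),
                      x = numeric(0), y = numeric(0), stringsAsFactors = FALSE))
  }
  blocks <- geographies$blocks
  bx <- (blocks$xmin + blocks$xmax) / 2
  by <- (blocks$ymin + blocks$ymax) / 2
  w <- 1 - radial_gradient(bx, by, geographies, config$center_decay)
  w <- w + 0.05  # floor so outlying blocks can host a center
  bi <- sample.int(nrow(blocks), n, replace = TRUE, prob = w)
  type_mix <- c(2, 636, 3, 216, 129, 69, 20)
  data.frame(center_id = sprintf("CC%04d", seq_len(n)),
             program_type = sample(program_types(), n, replace = TRUE,
                                   prob = type_mix / sum(type_mix)),
             x = blocks$xmin[bi] + stats::runif(n),
             y = blocks$ymin[bi] + stats::runif(n),
             stringsAsFactors = FALSE)
}

#' Generate tract opportunity indices
#'
#' Each index (child opportunity, health opportunity) is a negative linear
#' function of the tract mean risk score plus Gaussian noise. The residual
#' SD is calibrated in closed form so that the expected regression
#' R-squared equals the configured target:
#' `sd = sqrt(var(slope * score) * (1 - R2) / R2)`.
#'
#' @param config A [synthetic_config()].
#' @param tract_scores data.frame `geo_id`, `mean_score` (tract risk), e.g.
#'   from [aggregate_scores()].
#' @return data.frame `tract_id`, `coi`, `hoi`.
#' @export
generate_opportunity <- function(config, tract_scores) {
  set.seed(substream_seed(config$seed, 4))
  s <- tract_scores$mean_score
  keep <- !is.na(s)
  if (sum(keep) < 3) stop("need at least 3 tracts to generate opportunity indices")
  n <- length(s)
  out <- data.frame(tract_id = as.character(tract_scores$geo_id),
                    stringsAsFactors = FALSE)
  slopes <- c(coi = -14, hoi = -11)
  intercepts <- c(coi = 65, hoi = 60)
  for (nm in c("coi", "hoi")) {
    signal <- intercepts[[nm]] + slopes[[nm]] * s
    sd_noise <- if (!is.null(config$opp_index_noise_sd)) {
      config$opp_index_noise_sd
    } else {
      r2 <- config$opp_target_r2[[nm]]
      sqrt(stats::var(signal[keep]) * (1 - r2) / r2)
    }
    out[[nm]] <- signal + stats::rnorm(n, 0, sd_noise)
  }
  out
}

#' Simulate a complete synthetic county
#'
#' Runs all generators off independent substreams of `config$seed` and
#' scores the parcels internally (default tier rules and modifiers) to
#' obtain the tract risk scores the opportunity generator conditions on.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_county`: list with `config`,
#'   `geographies`, `parcels`, `children`, `childcare`, `opportunity`.
#' @export
#' @examples
#' county <- simulate_county(synthetic_config(n_parcels = 2000, seed = 7))
#' nrow(county$parcels)
simulate_county <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  geographies <- generate_geographies(config)
  parcels <- generate_parcels(config, geographies)
  children <- generate_children(config, geographies, parcels)
  childcare <- generate_childcare(config, geographies)
  scored <- score_parcels(parcels)
  tract_scores <- aggregate_scores(scored$scores, "tract",
                                   known_geos = geographies$tracts$tract_id)
  opportunity <- generate_opportunity(config, tract_scores)
  structure(list(config = config, geographies = geographies,
                 parcels = parcels, children = children,
                 childcare = childcare, opportunity = opportunity),
            class = "synthetic_county")
}

#' @export
print.synthetic_county <- function(x, ...) {
  cat("Synthetic county (seed ", x$config$seed, ")\n",
      "  blocks: ", nrow(x$geographies$blocks),
      ", block groups: ", nrow(x$geographies$block_groups),
      ", tracts: ", nrow(x$geographies$tracts), "\n",
      "  parcels: ", nrow(x$parcels),
      " (post-1978 share ", round(mean(x$parcels$year_built > 1978), 3), ")\n",
      "  childcare centers: ", nrow(x$childcare), "\n", sep = "")
  invisible(x)
}
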