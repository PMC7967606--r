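#' Neighborhood lead paint hazard analysis
#'
#' The umbrella analysis: scores every residential parcel (age tier + value
#' tier, times the grade modifier; post-ban parcels 0), aggregates the
#' scores to census blocks, block groups and tracts with the five-category
#' classification, scores childcare centers by their half-mile community
#' buffer, and computes the equity tables -- child exposure by risk tier,
#' under-5 race distribution across tiers, the banded non-white crosstab,
#' the rank association between tract risk and non-white share, and the
#' linear association with the opportunity indices.
#'
#' @param county A `synthetic_county` from [simulate_county()], a list from
#'   [read_county()], or any list with elements `geographies`, `parcels`,
#'   `children`, `childcare`, `opportunity` (the last three optional).
#' @param rules [tier_rules()] for the age/value tiers.
#' @param modifiers [grade_modifier_table()] for the grade multiplier.
#' @param radius Childcare buffer radius in miles (default 0.5).
#' @param exposure_level Geography level for the child exposure table
#'   (default `"block_group"`, the finest level with child counts).
#' @return Object of class `lead_hazard` with elements `parcel_scores`,
#'   `rejects`, `areas` (list by level), `childcare_risk`,
#'   `childcare_by_type`, `exposure`, `race_risk`, `nonwhite_crosstab`,
#'   `nonwhite_assoc`, `opportunity_fit`, `n_centers_out_of_area`, `call`.
#' @export
#' @examples
#' county <- simulate_county(synthetic_config(n_parcels = 2000, seed = 7))
#' fit <- lead_hazard(county)
#' summary(fit)
lead_hazard <- function(county, rules = tier_rules(),
                        modifiers = default_modifiers(), radius = 0.5,
                        exposure_level = c("block_group", "tract", "block")) {
  exposure_level <- match.arg(exposure_level)
  geo <- county$geographies
  scored <- score_parcels(county$parcels, rules = rules, modifiers = modifiers)

  children <- county$children
  child_geos <- function(level) {
    if (is.null(children)) NULL else children$geo_id[children$level == level]
  }
  known <- list(block = geo$blocks$block_id,
                block_group = geo$block_groups$block_group_id,
                tract = geo$tracts$tract_id)
  areas <- lapply(stats::setNames(nm = c("block", "block_group", "tract")),
                  function(lev) {
                    aggregate_scores(scored$scores, lev,
                                     known_geos = known[[lev]],
                                     child_geos = child_geos(lev))
                  })

  n_out <- 0L; childcare_risk <- NULL; childcare_by_type <- NULL
  if (!is.null(county$childcare) && nrow(county$childcare) >= 0) {
    cc <- county$childcare
    inb <- cc$x >= geo$bounds["xmin"] & cc$x <= geo$bounds["xmax"] &
      cc$y >= geo$bounds["ymin"] & cc$y <= geo$bounds["ymax"]
    n_out <- sum(!inb)
    if (n_out > 0) {
      message(n_out, " childcare center(s) outside the county bounds excluded")
    }
    childcare_risk <- score_centers(cc[inb, , drop = FALSE], scored$scores,
                                    radius = radius)
    childcare_by_type <- tabulate_by_type(childcare_risk)
  }

  exposure <- NULL; race_risk <- NULL; nw_cross <- NULL; nw_assoc <- NULL
  if (!is.null(children)) {
    exposure <- exposure_table(areas[[exposure_level]],
                               children[children$level == exposure_level, ])
    tr_children <- children[children$level == "tract", ]
    if (nrow(tr_children) > 0 && !all(is.na(tr_children$white))) {
      race_risk <- race_risk_distribution(areas$tract, tr_children)
      nw_cross <- nonwhite_crosstab(areas$tract, tr_children)
      nw_assoc <- nonwhite_association(areas$tract, tr_children)
    }
  }

  opp_fit <- if (!is.null(county$opportunity)) {
    opportunity_association(areas$tract, county$opportunity)
  }

  structure(list(parcel_scores = scored$scores, rejects = scored$rejects,
                 areas = areas, childcare_risk = childcare_risk,
                 childcare_by_type = childcare_by_type,
                 exposure = exposure, race_risk = race_risk,
                 nonwhite_crosstab = nw_cross, nonwhite_assoc = nw_assoc,
                 opportunity_fit = opp_fit,
                 n_centers_out_of_area = n_out,
                 rules = rules, modifiers = modifiers, radius = radius,
                 exposure_level = exposure_level,
                 geographies = geo, call = match.call()),
            class = "lead_hazard")
}

#' @export
print.lead_hazard <- function(x, ...) {
  n <- nrow(x$parcel_scores)
  cat("Neighborhood lead paint hazard analysis\n")
  cat(sprintf("  parcels scored: %d (%d excluded post-1978, %d rejected)\n",
              n, sum(x$parcel_scores$excluded), nrow(x$rejects)))
  cat(sprintf("  geographies: %d blocks, %d block groups, %d tracts\n",
              nrow(x$areas$block), nrow(x$areas$block_group),
              nrow(x$areas$tract)))
  if (!is.null(x$childcare_risk)) {
    cat(sprintf("  childcare centers: %d (buffer %.2f mi)\n",
                nrow(x$childcare_risk), x$radius))
  }
  if (!is.null(x$exposure)) {
    hr <- attr(x$exposure, "high_risk")
    cat(sprintf("  children under 5 in High/Very High areas: %.1f%%\n",
                hr[["under5"]]))
  }
  invisible(x)
}

#' @export
summary.lead_hazard <- function(object, ...) {
  structure(object, class = c("summary.lead_hazard", "lead_hazard"))
}

#' @export
print.summary.lead_hazard <- function(x, ...) {
  print.lead_hazard(x)
  cat("\nArea risk categories (units per level):\n")
  print(category_counts(do.call(rbind, x$areas)), row.names = FALSE)
  if (!is.null(x$exposure)) {
    cat("\nChild exposure by risk category (", x$exposure_level, "):\n", sep = "")
    e <- x$exposure
    e$under5_share <- round(e$under5_share, 1)
    e$under18_share <- round(e$under18_share, 1)
    print(e, row.names = FALSE)
  }
  if (!is.null(x$race_risk)) {
    cat("\nUnder-5 high-risk share by race (%):\n")
    print(round(x$race_risk$high_risk_share, 1))
  }
  if (!is.null(x$nonwhite_assoc)) {
    cat(sprintf("\nTract risk vs non-white share: Spearman rho = %.2f (p = %.2g, n = %d)\n",
                x$nonwhite_assoc$estimate, x$nonwhite_assoc$p_value,
                x$nonwhite_assoc$n_tracts))
  }
  if (!is.null(x$opportunity_fit)) {
    cat("\nOpportunity index association (OLS on tract risk):\n")
    f <- x$opportunity_fit
    f$slope <- round(f$slope, 2); f$intercept <- round(f$intercept, 2)
    f$r_squared <- round(f$r_squared, 3)
    print(f, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a lead hazard choropleth
#'
#' Base-graphics choropleth of the area risk categories on the grid
#' geographies: red shades for High/Very High, blues for Low/Very Low, grey
#' for No Data.
#'
#' @param x A `lead_hazard` object.
#' @param level Geography level to draw (default `"block"`).
#' @param ... Passed to `plot.default` for the canvas.
#' @return `x`, invisibly.
#' @export
plot.lead_hazard <- function(x, level = c("block", "block_group", "tract"),
                             ...) {
  level <- match.arg(level)
  areas <- x$areas[[level]]
  b <- x$geographies$blocks
  idcol <- switch(level, block = "block_id", block_group = "block_group_id",
                  tract = "tract_id")
  pal <- c("Very High" = "#99000d", "High" = "#ef3b2c",
           "Moderate" = "#fdae6b", "Low" = "#9ecae1",
           "Very Low" = "#deebf7", "No Data" = "#bdbdbd")
  col <- pal[as.character(areas$category)[match(b[[idcol]], areas$geo_id)]]
  col[is.na(col)] <- "white"
  graphics::plot(NA, xlim = x$geographies$bounds[c("xmin", "xmax")],
                 ylim = x$geographies$bounds[c("ymin", "ymax")],
                 asp = 1, xlab = "miles", ylab = "miles",
                 main = sprintf("Lead risk by %s", gsub("_", " ", level)), ...)
  graphics::rect(b$xmin, b$ymin, b$xmax, b$ymax, col = col, border = NA)
  graphics::legend("topright", legend = names(pal), fill = pal, cex = 0.7,
                   bg = "white")
  invisible(x)
}
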