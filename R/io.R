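#' Read a parcel table
#'
#' CSV with a header row; column order immaterial. Mandatory columns:
#' `parcel_id`, `year_built`, `appraised_value`, `grade`; a missing one is a
#' fatal error naming the column. Currency formatting on the value column
#' (`"$1,234"`) is tolerated. Malformed rows are not dropped here -- they are
#' routed to the rejects report by [score_parcels()].
#'
#' @param path Path to `parcels.csv`.
#' @return data.frame of parcels.
#' @export
read_parcels <- function(path) {
  if (!file.exists(path)) stop("parcels file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("parcel_id", "year_built", "appraised_value", "grade")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("parcels file is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  df$appraised_value <- parse_currency(df$appraised_value)
  df
}

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(what, " file is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Read child population, childcare, and opportunity tables
#'
#' Thin CSV readers with mandatory-column validation against the package's
#' standard schemas (see [write_county()]).
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_children <- function(path) {
  read_table_checked(path, c("geo_id", "level", "under5_total",
                             "under18_total"), "children")
}

#' @rdname read_children
#' @export
read_childcare <- function(path) {
  read_table_checked(path, c("center_id", "program_type", "x", "y"),
                     "childcare")
}

#' @rdname read_children
#' @export
read_opportunity <- function(path) {
  read_table_checked(path, c("tract_id", "coi", "hoi"), "opportunity")
}

#' Write a synthetic county to its five standard input files
#'
#' Writes `parcels.csv`, `geographies.geojson`, `children.csv`,
#' `childcare.csv` and `opportunity.csv` under `dir` (UTF-8, comma
#' delimiter, '.' decimal separator, header row; GeoJSON per RFC 7946).
#'
#' @param county A `synthetic_county` from [simulate_county()], or any list
#'   with the same elements.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five paths, invisibly.
#' @export
write_county <- function(county, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(parcels = file.path(dir, "parcels.csv"),
             geographies = file.path(dir, "geographies.geojson"),
             children = file.path(dir, "children.csv"),
             childcare = file.path(dir, "childcare.csv"),
             opportunity = file.path(dir, "opportunity.csv"))
  utils::write.csv(county$parcels, paths["parcels"], row.names = FALSE)
  write_geographies_geojson(county$geographies, paths["geographies"])
  utils::write.csv(county$children, paths["children"], row.names = FALSE)
  utils::write.csv(county$childcare, paths["childcare"], row.names = FALSE)
  utils::write.csv(county$opportunity, paths["opportunity"], row.names = FALSE)
  invisible(paths)
}

#' Read a county back from its five standard input files
#'
#' @param dir Directory containing the files written by [write_county()].
#' @return List with `geographies`, `parcels`, `children`, `childcare`,
#'   `opportunity` (and `config = NULL`).
#' @export
read_county <- function(dir) {
  list(config = NULL,
       geographies = read_geographies_geojson(file.path(dir, "geographies.geojson")),
       parcels = read_parcels(file.path(dir, "parcels.csv")),
       children = read_children(file.path(dir, "children.csv")),
       childcare = read_childcare(file.path(dir, "childcare.csv")),
       opportunity = read_opportunity(file.path(dir, "opportunity.csv")))
}

#' Run the full pipeline and write every artifact
#'
#' Executes simulate (optional) -> score -> aggregate (block, block group,
#' tract) -> childcare -> equity, writing all tables under `out_dir` plus a
#' `manifest.json` recording input file hashes, the seed, key parameters and
#' the package version. The same inputs and seed reproduce byte-identical
#' CSV outputs. Any stage failure aborts with a stage-named error.
#'
#' @param out_dir Output directory.
#' @param input_dir Directory with the five standard input files; `NULL`
#'   (default) simulates a county instead.
#' @param config A [synthetic_config()] used when simulating.
#' @param rules,modifiers,radius Scoring parameters, see [lead_hazard()].
#' @return The fitted [lead_hazard()] object, invisibly.
#' @export
run_pipeline <- function(out_dir, input_dir = NULL,
                         config = synthetic_config(),
                         rules = tier_rules(),
                         modifiers = default_modifiers(),
                         radius = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  county <- if (is.null(input_dir)) {
    stage("simulate", simulate_county(config))
  } else {
    stage("read", read_county(input_dir))
  }
  input_paths <- write_county(county, file.path(out_dir, "inputs"))
  fit <- stage("analyze", lead_hazard(county, rules = rules,
                                      modifiers = modifiers, radius = radius))

  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  stage("write", {
    w(fit$parcel_scores, "parcel_scores.csv")
    w(fit$rejects, "rejects.csv")
    for (lev in names(fit$areas)) {
      w(fit$areas[[lev]], sprintf("area_scores_%s.csv", lev))
      write_choropleth_geojson(fit$areas[[lev]], county$geographies,
                               file.path(out_dir,
                                         sprintf("area_scores_%s.geojson", lev)))
    }
    w(fit$childcare_risk, "childcare_risk.csv")
    w(fit$childcare_by_type, "childcare_by_type.csv")
    w(as.data.frame(fit$exposure), "exposure_table.csv")
    w(fit$race_risk$counts, "race_risk.csv")
    w(fit$nonwhite_crosstab, "nonwhite_crosstab.csv")
    jsonlite::write_json(fit$opportunity_fit, file.path(out_dir, "opportunity_fit.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("leadhazard")),
    seed = if (is.null(input_dir)) config$seed else NA,
    simulated = is.null(input_dir),
    radius_miles = radius,
    inputs = {
      h <- tools::md5sum(unname(input_paths))
      stats::setNames(as.list(unname(h)), basename(names(h)))
    },
    records = list(parcels_in = nrow(county$parcels),
                   parcels_scored = nrow(fit$parcel_scores),
                   parcels_rejected = nrow(fit$rejects),
                   parcels_excluded = sum(fit$parcel_scores$excluded),
                   childcare_centers = nrow(fit$childcare_risk)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}
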