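#' Point-in-polygon test
#'
#' Even-odd (ray casting) membership of points in a single closed planar
#' ring. Points exactly on an edge may fall on either side at floating-point
#' resolution; the package's grid geographies assign parcels by construction
#' and only use this test for verification.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param ring Two-column matrix of ring vertices (closed or open).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, ring) {
  ring <- as.matrix(ring)
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

block_ring <- function(b) {
  cbind(c(b$xmin, b$xmax, b$xmax, b$xmin, b$xmin),
        c(b$ymin, b$ymin, b$ymax, b$ymax, b$ymin))
}

#' Write geographies as GeoJSON
#'
#' One RFC 7946 FeatureCollection covering all three levels. Blocks are
#' square Polygons; block groups and tracts are MultiPolygons of their
#' member blocks. Each feature carries properties `id`, `level`
#' (`block` / `block_group` / `tract`) and `parent_id` (empty for tracts).
#'
#' @param geographies A `county_geography` from [generate_geographies()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geographies_geojson <- function(geographies, path) {
  b <- geographies$blocks
  feat <- function(id, level, parent, coords, type) {
    list(type = "Feature",
         properties = list(id = id, level = level, parent_id = parent),
         geometry = list(type = type, coordinates = coords))
  }
  features <- list()
  for (i in seq_len(nrow(b))) {
    ring <- block_ring(b[i, ])
    features[[length(features) + 1]] <-
      feat(b$block_id[i], "block", b$block_group_id[i], list(ring), "Polygon")
  }
  for (g in geographies$block_groups$block_group_id) {
    members <- b[b$block_group_id == g, , drop = FALSE]
    polys <- lapply(seq_len(nrow(members)),
                    function(i) list(block_ring(members[i, ])))
    parent <- members$tract_id[1]
    features[[length(features) + 1]] <-
      feat(g, "block_group", parent, polys, "MultiPolygon")
  }
  for (tr in geographies$tracts$tract_id) {
    members <- b[b$tract_id == tr, , drop = FALSE]
    polys <- lapply(seq_len(nrow(members)),
                    function(i) list(block_ring(members[i, ])))
    features[[length(features) + 1]] <-
      feat(tr, "tract", "", polys, "MultiPolygon")
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read geographies from GeoJSON
#'
#' Inverse of [write_geographies_geojson()] for the package's grid schema:
#' block features must be axis-aligned squares; block-group and tract
#' membership is reconstructed from `parent_id`.
#'
#' @param path GeoJSON file written by [write_geographies_geojson()].
#' @return A `county_geography` object.
#' @export
read_geographies_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  blocks <- list(); bg_parent <- character(0)
  for (f in fc$features) {
    lev <- f$properties$level
    if (identical(lev, "block")) {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                    function(p) unlist(p)))
      blocks[[length(blocks) + 1]] <- data.frame(
        block_id = f$properties$id,
        block_group_id = f$properties$parent_id,
        xmin = min(ring[, 1]), ymin = min(ring[, 2]),
        xmax = max(ring[, 1]), ymax = max(ring[, 2]),
        stringsAsFactors = FALSE)
    } else if (identical(lev, "block_group")) {
      bg_parent[f$properties$id] <- f$properties$parent_id
    }
  }
  b <- do.call(rbind, blocks)
  b$tract_id <- unname(bg_parent[b$block_group_id])
  block_groups <- unique(b[, c("block_group_id", "tract_id")])
  rownames(block_groups) <- NULL
  structure(list(blocks = b, block_groups = block_groups,
                 tracts = data.frame(tract_id = unique(block_groups$tract_id),
                                     stringsAsFactors = FALSE),
                 bounds = c(xmin = min(b$xmin), ymin = min(b$ymin),
                            xmax = max(b$xmax), ymax = max(b$ymax))),
            class = "county_geography")
}

#' Write an area-score choropleth as GeoJSON
#'
#' Joins area scores to their polygons and writes a FeatureCollection whose
#' features carry `id`, `level`, `mean_score` and `category` -- a plain
#' choropleth export, ready for any GeoJSON viewer; no cartographic styling.
#'
#' @param areas Output of [aggregate_scores()].
#' @param geographies A `county_geography`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_choropleth_geojson <- function(areas, geographies, path) {
  b <- geographies$blocks
  level <- as.character(areas$level[1])
  idcol <- switch(level, block = "block_id", block_group = "block_group_id",
                  tract = "tract_id")
  features <- lapply(seq_len(nrow(areas)), function(i) {
    members <- b[b[[idcol]] == areas$geo_id[i], , drop = FALSE]
    polys <- lapply(seq_len(nrow(members)),
                    function(j) list(block_ring(members[j, ])))
    list(type = "Feature",
         properties = list(id = areas$geo_id[i], level = level,
                           mean_score = areas$mean_score[i],
                           category = as.character(areas$category[i])),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
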