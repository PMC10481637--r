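#' Region polygon geometries
#'
#' A `region_geometry_set` is a named list (one element per region) of
#' polygon coordinate rings: each region holds a list of parts, each part a
#' list of rings, each ring a two-column matrix of planar `(x, y)` vertex
#' coordinates with the first vertex repeated at the end (closed ring). This
#' mirrors the GeoJSON Polygon / MultiPolygon nesting.
#'
#' @param rings_by_region named list as described above.
#' @return an object of class `region_geometry_set`.
#' @export
region_geometry_set <- function(rings_by_region) {
  ids <- names(rings_by_region)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stopf("geometries must be a named list with unique, non-empty region ids")
  }
  for (id in ids) {
    for (part in rings_by_region[[id]]) {
      for (ring in part) {
        if (!is.matrix(ring) || ncol(ring) != 2L || nrow(ring) < 4L) {
          stopf("region %s: each ring must be a matrix of >= 4 (x, y) rows", id)
        }
        if (any(ring[1, ] != ring[nrow(ring), ])) {
          stopf("region %s: ring not closed (first vertex != last)", id)
        }
      }
    }
  }
  structure(rings_by_region, class = "region_geometry_set")
}

#' @export
print.region_geometry_set <- function(x, ...) {
  cat(sprintf("Region geometry set: %d polygons\n", length(x)))
  invisible(x)
}

#' Read region polygons from GeoJSON
#'
#' Reads an RFC 7946 FeatureCollection of Polygon / MultiPolygon features.
#' Coordinate order `(x, y)` is preserved as stored.
#'
#' @param path GeoJSON file path.
#' @param id_property name of the feature property holding the region id.
#' @param panel optional [indicator_panel()]; when given, the region id sets
#'   must match exactly, otherwise the symmetric difference is reported.
#' @return a [region_geometry_set()].
#' @export
read_geometry <- function(path, id_property = "region_id", panel = NULL) {
  if (!file.exists(path)) stopf("geometry file not found: %s", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stopf("expected a GeoJSON FeatureCollection, got type %s",
          gj$type %||% "<none>")
  }
  out <- list()
  for (feat in gj$features) {
    id <- feat$properties[[id_property]]
    if (is.null(id)) {
      stopf("feature without property \"%s\" (the region id)", id_property)
    }
    id <- as.character(id)
    geom <- feat$geometry
    coords <- geom$coordinates
    parts <- switch(geom$type,
      Polygon = list(coords),
      MultiPolygon = coords,
      stopf("region %s: unsupported geometry type %s", id, geom$type))
    out[[id]] <- lapply(parts, function(part) {
      lapply(part, function(ring) {
        m <- do.call(rbind, lapply(ring, function(pt) {
          as.numeric(unlist(pt)[1:2])
        }))
        m
      })
    })
  }
  geoms <- region_geometry_set(out)
  if (!is.null(panel)) check_geometry_ids(geoms, panel)
  geoms
}

check_geometry_ids <- function(geoms, panel) {
  gid <- names(geoms)
  pid <- panel$region_ids
  only_g <- setdiff(gid, pid)
  only_p <- setdiff(pid, gid)
  if (length(only_g) || length(only_p)) {
    stopf("geometry / panel region-id mismatch: in geometry only {%s}; in panel only {%s}",
          paste(only_g, collapse = ", "), paste(only_p, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write region polygons (with optional per-region properties) as GeoJSON
#'
#' @param geoms a [region_geometry_set()].
#' @param path output file path.
#' @param properties optional data frame of per-region properties; must have
#'   a `region_id` column matching `names(geoms)`.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geoms, path, properties = NULL) {
  stopifnot(inherits(geoms, "region_geometry_set"))
  if (!is.null(properties)) {
    stopifnot("region_id" %in% names(properties))
    rownames(properties) <- properties$region_id
  }
  features <- lapply(names(geoms), function(id) {
    parts <- geoms[[id]]
    coords <- lapply(parts, function(part) {
      lapply(part, function(ring) {
        lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
      })
    })
    if (length(parts) == 1L) {
      geometry <- list(type = "Polygon", coordinates = coords[[1]])
    } else {
      geometry <- list(type = "MultiPolygon", coordinates = coords)
    }
    props <- list(region_id = id)
    if (!is.null(properties) && id %in% rownames(properties)) {
      for (cn in setdiff(names(properties), "region_id")) {
        props[[cn]] <- properties[id, cn]
      }
    }
    list(type = "Feature", properties = props, geometry = geometry)
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}
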