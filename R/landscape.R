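#' Land-sea classification mask
#'
#' A total classifier of geographic points into landscape classes. The mask
#' holds an ordered list of polygons (first match wins) over a default class,
#' so typically: island and tidal-flat polygons drawn over open sea, and a
#' mainland polygon to the south. Points within `colony_buffer_km` of the
#' colony classify as `"colony"`.
#'
#' @param polygons Named list; each element is a closed or open ring given as
#'   a two-column matrix of lon/lat vertices, and the element name is its
#'   class label (one of `"island"`, `"tidal_flat"`, `"mainland"`, or any
#'   label). Earlier polygons take precedence.
#' @param colony_lonlat Length-2 numeric, colony position (lon, lat).
#' @param default_class Class assigned to points in no polygon (`"sea"`).
#' @param colony_buffer_km Radius around the colony classified as colony.
#' @return An object of class `landscape_mask`.
#' @export
landscape_mask <- function(polygons, colony_lonlat, default_class = "sea",
                           colony_buffer_km = 0.5) {
  stopifnot(is.list(polygons), length(colony_lonlat) == 2,
            colony_buffer_km >= 0)
  if (length(polygons) && is.null(names(polygons)))
    stop("polygons must be a named list (names are class labels)")
  for (p in polygons) {
    if (!is.matrix(p) || ncol(p) != 2)
      stop("each polygon must be a two-column lon/lat matrix")
  }
  structure(list(polygons = polygons,
                 colony = as.numeric(colony_lonlat),
                 default_class = default_class,
                 colony_buffer_km = colony_buffer_km),
            class = "landscape_mask")
}

#' Classify points against a landscape mask
#'
#' @param mask A [landscape_mask()].
#' @param lon,lat Coordinate vectors (decimal degrees).
#' @param use_colony If `TRUE` (default), points within the mask's colony
#'   buffer are returned as `"colony"` before polygon lookup.
#' @return Character vector of class labels, same length as `lon`.
#' @export
classify_points <- function(mask, lon, lat, use_colony = TRUE) {
  stopifnot(inherits(mask, "landscape_mask"), length(lon) == length(lat))
  out <- rep(mask$default_class, length(lon))
  pts <- cbind(lon, lat)
  assigned <- rep(FALSE, length(lon))
  for (i in seq_along(mask$polygons)) {
    todo <- which(!assigned)
    if (!length(todo)) break
    inside <- mgcv::in.out(mask$polygons[[i]], pts[todo, , drop = FALSE])
    out[todo[inside]] <- names(mask$polygons)[i]
    assigned[todo[inside]] <- TRUE
  }
  if (use_colony && mask$colony_buffer_km > 0) {
    d <- gc_dist_km(mask$colony[1], mask$colony[2], lon, lat)
    out[d <= mask$colony_buffer_km] <- "colony"
  }
  out
}

#' Distance from the colony (km)
#'
#' @param mask A [landscape_mask()] (carries the colony position).
#' @param lon,lat Coordinate vectors.
#' @return Great-circle distances in km.
#' @export
colony_distance_km <- function(mask, lon, lat) {
  gc_dist_km(mask$colony[1], mask$colony[2], lon, lat)
}

#' @export
print.landscape_mask <- function(x, ...) {
  cat("Landscape mask\n")
  cat("  colony: ", sprintf("%.4f E, %.4f N", x$colony[1], x$colony[2]),
      " (buffer ", x$colony_buffer_km, " km)\n", sep = "")
  cat("  polygon classes:", paste(names(x$polygons), collapse = ", "), "\n")
  cat("  default class:", x$default_class, "\n")
  invisible(x)
}

#' Write a landscape mask to GeoJSON
#'
#' Polygons are written as a `FeatureCollection` with a `class` property;
#' the colony is a Point feature with `class = "colony"`.
#'
#' @param mask A [landscape_mask()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_geojson <- function(mask, path) {
  close_ring <- function(m) {
    if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
    m
  }
  feats <- lapply(seq_along(mask$polygons), function(i) {
    ring <- close_ring(mask$polygons[[i]])
    list(type = "Feature",
         properties = list(class = names(mask$polygons)[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(ring))))
  })
  feats <- c(feats, list(list(
    type = "Feature",
    properties = list(class = "colony",
                      buffer_km = mask$colony_buffer_km,
                      default_class = mask$default_class),
    geometry = list(type = "Point", coordinates = mask$colony))))
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 10), path)
  invisible(path)
}

#' Read a landscape mask from GeoJSON
#'
#' Inverse of [write_mask_geojson()]: expects Polygon features with a
#' `class` property and a Point feature carrying the colony.
#'
#' @param path GeoJSON file path.
#' @return A [landscape_mask()].
#' @export
read_mask_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  polygons <- list()
  colony <- NULL; buffer <- 0.5; default_class <- "sea"
  for (f in gj$features) {
    cls <- f$properties$class
    if (identical(f$geometry$type, "Point")) {
      colony <- unlist(f$geometry$coordinates)
      if (!is.null(f$properties$buffer_km)) buffer <- f$properties$buffer_km
      if (!is.null(f$properties$default_class))
        default_class <- f$properties$default_class
    } else if (identical(f$geometry$type, "Polygon")) {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
      polygons[[length(polygons) + 1L]] <- ring
      names(polygons)[length(polygons)] <- cls
    }
  }
  if (is.null(colony)) stop("mask file has no colony Point feature: ", path)
  landscape_mask(polygons, colony, default_class, buffer)
}

#' Terrestrial habitat grid
#'
#' A regular grid of square parcels over the mainland, each labelled with a
#' habitat type. The grid lives on the local azimuthal-equidistant plane
#' centred on the colony, so that 500-m feeding-spot cells and habitat
#' parcels share one origin (the colony); the origin can be shifted via
#' `origin_offset_km`.
#'
#' @param colony_lonlat Projection origin (lon, lat).
#' @param cell_km Parcel edge length in km.
#' @param x_range_km,y_range_km Length-2 numeric, grid extent in projected km.
#' @param labels Character matrix of habitat labels, `ny` rows by `nx`
#'   columns (row 1 = southernmost row).
#' @param origin_offset_km Length-2 shift of the grid origin (km).
#' @return An object of class `habitat_grid`.
#' @export
habitat_grid <- function(colony_lonlat, cell_km, x_range_km, y_range_km,
                         labels, origin_offset_km = c(0, 0)) {
  nx <- as.integer(round(diff(x_range_km) / cell_km))
  ny <- as.integer(round(diff(y_range_km) / cell_km))
  stopifnot(is.matrix(labels), nrow(labels) == ny, ncol(labels) == nx)
  structure(list(colony = as.numeric(colony_lonlat), cell_km = cell_km,
                 x0 = x_range_km[1], y0 = y_range_km[1],
                 nx = nx, ny = ny, labels = labels,
                 origin_offset = origin_offset_km),
            class = "habitat_grid")
}

#' Habitat label at geographic points
#'
#' @param grid A [habitat_grid()].
#' @param lon,lat Coordinate vectors.
#' @return Character vector of habitat labels; `NA` outside the grid.
#' @export
habitat_at <- function(grid, lon, lat) {
  xy <- project_local(lon, lat, grid$colony)
  ix <- floor((xy[, 1] - grid$x0 - grid$origin_offset[1]) / grid$cell_km) + 1L
  iy <- floor((xy[, 2] - grid$y0 - grid$origin_offset[2]) / grid$cell_km) + 1L
  ok <- ix >= 1L & ix <= grid$nx & iy >= 1L & iy <= grid$ny
  out <- rep(NA_character_, length(lon))
  out[ok] <- grid$labels[cbind(iy[ok], ix[ok])]
  out
}

#' @export
print.habitat_grid <- function(x, ...) {
  cat("Habitat grid: ", x$nx, " x ", x$ny, " parcels of ",
      x$cell_km, " km\n", sep = "")
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat("  habitats:", paste(names(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write a habitat grid to GeoJSON
#'
#' Each parcel becomes a Polygon feature with a `habitat` property. For
#' large grids this is bulky; intended for small exports and map overlays.
#'
#' @param grid A [habitat_grid()].
#' @param path Output file path.
#' @param max_cells Refuse to write more than this many parcels.
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(grid, path, max_cells = 20000) {
  ncell <- grid$nx * grid$ny
  if (ncell > max_cells)
    stop("grid has ", ncell, " parcels; raise max_cells to write anyway")
  feats <- vector("list", ncell)
  k <- 0L
  for (iy in seq_len(grid$ny)) for (ix in seq_len(grid$nx)) {
    x0 <- grid$x0 + grid$origin_offset[1] + (ix - 1L) * grid$cell_km
    y0 <- grid$y0 + grid$origin_offset[2] + (iy - 1L) * grid$cell_km
    corners <- rbind(c(x0, y0), c(x0 + grid$cell_km, y0),
                     c(x0 + grid$cell_km, y0 + grid$cell_km),
                     c(x0, y0 + grid$cell_km), c(x0, y0))
    ring <- unproject_local(corners[, 1], corners[, 2], grid$colony)
    k <- k + 1L
    feats[[k]] <- list(type = "Feature",
                       properties = list(habitat = grid$labels[iy, ix]),
                       geometry = list(type = "Polygon",
                                       coordinates = list(unname(ring))))
  }
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 8), path)
  invisible(path)
}
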