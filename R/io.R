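## File formats: single-band float32 rasters in the ENVI flat-binary
## layout (data file + plain-text .hdr, readable by GDAL), GeoJSON
## polygon collections for fire perimeters and regions, and YAML
## configuration snapshots. Nodata is carried as NaN in the data file.

hdr_path <- function(path) paste0(path, ".hdr")

#' Write a single-band float32 raster
#'
#' Writes the matrix as ENVI flat binary (band-sequential, row-major,
#' little-endian float32) with a text header carrying the grid contract
#' (rows, cols, pixel size). `NA` values are stored as NaN.
#'
#' @param x Numeric matrix.
#' @param path Output data-file path (header written to `<path>.hdr`).
#' @param pixel_size Pixel side in metres, recorded in the header.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, pixel_size = 30) {
  v <- as.numeric(t(x))
  v[is.na(v)] <- NaN
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = 4L, endian = "little")
  writeLines(c(
    "ENVI",
    sprintf("samples = %d", ncol(x)),
    sprintf("lines = %d", nrow(x)),
    "bands = 1",
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    sprintf("pixel size = %g", pixel_size)
  ), hdr_path(path))
  invisible(path)
}

parse_hdr <- function(path) {
  lines <- readLines(hdr_path(path))
  get <- function(key) {
    ln <- grep(paste0("^", key, " *="), lines, value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    as.numeric(sub(".*= *", "", ln[1]))
  }
  list(samples = get("samples"), lines = get("lines"),
       data_type = get("data type"), pixel_size = get("pixel size"))
}

#' Read a single-band float32 raster
#'
#' @param path Data-file path written by [write_raster()].
#' @param expect_shape Optional `(rows, cols)`; a mismatch against this
#'   reference grid is an error reporting both shapes.
#' @return Numeric matrix with NaN restored to `NA`; `pixel_size` attached
#'   as an attribute.
#' @export
read_raster <- function(path, expect_shape = NULL) {
  h <- parse_hdr(path)
  if (!identical(h$data_type, 4)) stop("unsupported data type (expected float32)", call. = FALSE)
  n <- h$samples * h$lines
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  v[is.nan(v)] <- NA_real_
  x <- matrix(v, nrow = h$lines, ncol = h$samples, byrow = TRUE)
  if (!is.null(expect_shape) && !identical(dim(x), as.integer(expect_shape))) {
    stop(sprintf("raster shape %s does not match reference grid %s",
                 paste(dim(x), collapse = "x"),
                 paste(expect_shape, collapse = "x")), call. = FALSE)
  }
  attr(x, "pixel_size") <- h$pixel_size
  x
}

ring_to_coords <- function(ring) {
  r <- ring
  if (r[1, 1] != r[nrow(r), 1] || r[1, 2] != r[nrow(r), 2]) {
    r <- rbind(r, r[1, , drop = FALSE])  # GeoJSON rings are closed
  }
  lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
}

#' Write fire perimeters to GeoJSON
#'
#' One Polygon feature per fire, with a `year` property; coordinates are
#' grid (pixel) coordinates.
#'
#' @param fires List of fires (`polygon` = list of rings, `year`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fires_geojson <- function(fires, path) {
  features <- lapply(fires, function(f) {
    rings <- if (is.matrix(f$polygon)) list(f$polygon) else f$polygon
    list(
      type = "Feature",
      properties = list(year = as.integer(f$year)),
      geometry = list(type = "Polygon",
                      coordinates = lapply(rings, ring_to_coords))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read dated polygons from GeoJSON
#'
#' Reads a FeatureCollection of Polygon/MultiPolygon features; every
#' feature must carry a `year` property (coerced to integer) when
#' `require_year` is set. Holes (additional rings) are preserved and
#' respected by the even-odd rasterization.
#'
#' @param path GeoJSON path.
#' @param require_year Demand a `year` property per feature?
#' @return List of features: `polygon` (list of rings), `year`,
#'   `properties`. An empty collection returns an empty list with a
#'   warning.
#' @export
read_vectors <- function(path, require_year = TRUE) {
  g <- jsonlite::read_json(path)
  feats <- g$features %||% list()
  if (length(feats) == 0) {
    warning("empty feature collection")
    return(list())
  }
  out <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    yr <- f$properties$year
    if (require_year && is.null(yr))
      stop(sprintf("feature %d: missing 'year' property", i), call. = FALSE)
    geom <- f$geometry
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    stop(sprintf("feature %d: unsupported geometry '%s'", i, geom$type),
                         call. = FALSE))
    rings <- lapply(polys[[1]], function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    })
    out[[i]] <- list(polygon = rings,
                     year = if (is.null(yr)) NA_integer_ else as.integer(yr),
                     properties = f$properties)
  }
  out
}

#' Write / read a pipeline configuration snapshot
#'
#' @param config Named list.
#' @param path YAML path.
#' @return `path` / the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
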