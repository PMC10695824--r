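## Planar polygon utilities. Geometry lives in grid (pixel) coordinates: the
## centre of the pixel at row r, column c is (x, y) = (c - 0.5, r - 0.5).
## Polygons are lists of rings; each ring is an n x 2 matrix of (x, y)
## vertices. Ring 1 is the outer shell; additional rings are holes,
## interpreted with the even-odd rule.

#' Even-odd point-in-polygon test
#'
#' Tests pixel-centre style points against a polygon (outer ring plus
#' optional holes) with the even-odd (ray casting) rule. Points on an edge
#' follow the half-open convention of the crossing test and are assigned
#' deterministically.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param polygon A list of rings; each ring an `n x 2` matrix of vertices.
#' @return Logical vector: `TRUE` where the point is inside.
#' @export
point_in_polygon <- function(px, py, polygon) {
  if (is.matrix(polygon)) polygon <- list(polygon)
  crossings <- integer(length(px))
  for (ring in polygon) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    ## drop explicit closing vertex if present
    if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
      x <- x[-n]; y <- y[-n]; n <- n - 1L
    }
    j <- c(n, seq_len(n - 1L))
    for (i in seq_len(n)) {
      xi <- x[i]; yi <- y[i]; xj <- x[j[i]]; yj <- y[j[i]]
      hit <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      crossings <- crossings + as.integer(hit)
    }
  }
  crossings %% 2L == 1L
}

## Rasterize one polygon onto a grid by pixel-centre inclusion.
pip_mask <- function(polygon, grid_shape) {
  if (is.matrix(polygon)) polygon <- list(polygon)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  allv <- do.call(rbind, polygon)
  cmin <- max(1L, floor(min(allv[, 1]) + 0.5))
  cmax <- min(nc, ceiling(max(allv[, 1]) + 0.5))
  rmin <- max(1L, floor(min(allv[, 2]) + 0.5))
  rmax <- min(nr, ceiling(max(allv[, 2]) + 0.5))
  out <- matrix(FALSE, nr, nc)
  if (cmin > cmax || rmin > rmax) return(out)
  rows <- rmin:rmax; cols <- cmin:cmax
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  inside <- point_in_polygon(px, py, polygon)
  out[rows, cols] <- inside
  out
}

polygon_bbox_valid <- function(polygon, grid_shape) {
  if (is.matrix(polygon)) polygon <- list(polygon)
  any(pip_mask(polygon, grid_shape))
}

## Irregular star-convex polygon around a centre; used by the fire generator.
## Caller controls RNG state.
random_blob_polygon <- function(cx, cy, radius, n_vertices = 12L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- radius * runif(n_vertices, 0.55, 1.45)
  cbind(x = cx + r * cos(theta), y = cy + r * sin(theta))
}
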