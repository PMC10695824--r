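## Seasonal compositing and the 36-layer predictor stack.
##
## Layer registry: for each season, the six reflectance bands followed by
## the five vegetation indices, then the three terrain layers. The order is
## frozen so fitted models remain portable across runs.

INDICES <- c("ndvi", "ndwi", "savi", "vari", "evi")
TERRAIN <- c("slope", "elevation", "aspect")

#' Frozen feature-layer registry
#'
#' @return Character vector of the 36 layer names in canonical order:
#'   `<season>_<band>`, `<season>_<index>` for spring/summer/fall, then
#'   `slope`, `elevation`, `aspect`.
#' @export
layer_registry <- function() {
  c(unlist(lapply(SEASONS, function(s) paste(s, c(BANDS, INDICES), sep = "_"))),
    TERRAIN)
}

ndvi_of <- function(bands) {
  den <- bands$nir + bands$red
  out <- (bands$nir - bands$red) / den
  out[den == 0] <- NA_real_
  out
}

#' Median-NDVI seasonal composite
#'
#' For each pixel, selects among its valid dates the one whose NDVI is the
#' lower median (for an even number of valid dates the lower of the two
#' middle values) and copies that date's six band values into the
#' composite. Selecting a whole date, rather than per-band medians, keeps
#' the composited spectrum physically coherent. Pixels with no valid date
#' are masked out.
#'
#' @param stack A `reflectance_stack` from [render_reflectance()], or any
#'   list with `dates` of `bands` + `valid`.
#' @param season Season id recorded on the output (defaults to the
#'   stack's own).
#' @return Object of class `seasonal_composite`: `season`, `bands` (named
#'   list of 6 matrices, `NA` where masked) and logical `valid_mask`.
#' @export
median_composite <- function(stack, season = NULL) {
  dates <- stack$dates
  if (length(dates) < 1) stop("need at least one date", call. = FALSE)
  season <- season %||% stack$season
  gs <- dim(dates[[1]]$bands[[1]])
  for (d in dates) {
    check_same_shape(d$bands[[1]], dates[[1]]$bands[[1]])
    check_same_shape(d$valid, dates[[1]]$bands[[1]])
  }
  nd <- length(dates)
  npx <- prod(gs)
  ndvi <- matrix(NA_real_, npx, nd)
  for (i in seq_len(nd)) {
    v <- ndvi_of(dates[[i]]$bands)
    v[!dates[[i]]$valid] <- NA_real_
    ndvi[, i] <- as.vector(v)
  }
  ## index of the lower-median valid date per pixel (0 = none valid)
  pick <- apply(ndvi, 1, function(x) {
    ok <- which(!is.na(x))
    n <- length(ok)
    if (n == 0) return(0L)
    k <- floor((n + 1) / 2)  # lower median
    ok[order(x[ok])[k]]
  })
  valid <- matrix(pick > 0, gs[1], gs[2])
  bands <- lapply(setNames(BANDS, BANDS), function(b) {
    out <- matrix(NA_real_, gs[1], gs[2])
    for (i in seq_len(nd)) {
      sel <- pick == i
      out[sel] <- dates[[i]]$bands[[b]][sel]
    }
    out
  })
  structure(list(season = season, bands = bands, valid_mask = valid),
            class = "seasonal_composite")
}

#' Vegetation indices from a seasonal composite
#'
#' Computes NDVI, NDWI (NIR/SWIR1 moisture variant), SAVI (L = 0.5), VARI
#' and EVI (G = 2.5, C1 = 6, C2 = 7.5, L = 1) from the six composite
#' bands. Pixels where an index denominator is exactly zero are set `NA`.
#'
#' @param composite A `seasonal_composite`.
#' @return Named list of 5 index matrices.
#' @export
compute_indices <- function(composite) {
  b <- composite$bands
  for (name in BANDS) {
    if (is.null(b[[name]])) stop(sprintf("missing band '%s'", name), call. = FALSE)
  }
  safe_ratio <- function(num, den) {
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
  list(
    ndvi = safe_ratio(b$nir - b$red, b$nir + b$red),
    ndwi = safe_ratio(b$nir - b$swir1, b$nir + b$swir1),
    savi = safe_ratio(1.5 * (b$nir - b$red), b$nir + b$red + 0.5),
    vari = safe_ratio(b$green - b$red, b$green + b$red - b$blue),
    evi = safe_ratio(2.5 * (b$nir - b$red), b$nir + 6 * b$red - 7.5 * b$blue + 1)
  )
}

#' Slope, elevation and aspect from a DEM
#'
#' Slope and aspect by Horn's 3x3 third-order finite difference on an
#' edge-replicated grid, both in degrees; aspect is compass-style
#' (0 = north, clockwise) with flat cells assigned 0 by convention.
#' Elevation passes through unchanged.
#'
#' @param dem Elevation matrix (metres), at least 3x3.
#' @param pixel_size Grid spacing in metres.
#' @return Named list of matrices `slope`, `elevation`, `aspect`.
#' @export
terrain_layers <- function(dem, pixel_size = 30) {
  if (nrow(dem) < 3 || ncol(dem) < 3) stop("DEM must be at least 3x3", call. = FALSE)
  if (any(!is.finite(dem))) stop("DEM must be finite", call. = FALSE)
  nr <- nrow(dem); nc <- ncol(dem)
  up <- c(1L, seq_len(nr - 1L)); dn <- c(seq_len(nr - 1L) + 1L, nr)
  lf <- c(1L, seq_len(nc - 1L)); rt <- c(seq_len(nc - 1L) + 1L, nc)
  ## Horn stencil: z1..z9 west-to-east, north(top)-to-south rows
  z1 <- dem[up, lf]; z2 <- dem[up, ]; z3 <- dem[up, rt]
  z4 <- dem[, lf]; z6 <- dem[, rt]
  z7 <- dem[dn, lf]; z8 <- dem[dn, ]; z9 <- dem[dn, rt]
  dzdx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * pixel_size)
  dzdy <- ((z7 + 2 * z8 + z9) - (z1 + 2 * z2 + z3)) / (8 * pixel_size)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- (atan2(dzdx, -dzdy) * 180 / pi) %% 360
  aspect[slope == 0] <- 0
  list(slope = slope, elevation = dem, aspect = aspect)
}

#' Assemble the 36-layer feature stack
#'
#' Stacks the three seasonal composites (bands + indices) and the terrain
#' layers in registry order, and records the two validity masks:
#' `complete_mask` (all three seasons valid; index `NA`s count as invalid)
#' and `summer_mask` (summer valid).
#'
#' @param spring,summer,fall `seasonal_composite` objects.
#' @param terrain Named list from [terrain_layers()].
#' @param epoch Nominal year tag.
#' @return Object of class `feature_stack` with `layers` (named list of 36
#'   matrices), `complete_mask`, `summer_mask`, `epoch`.
#' @export
assemble_stack <- function(spring, summer, fall, terrain, epoch = NA_integer_) {
  comps <- list(spring = spring, summer = summer, fall = fall)
  ref <- comps$spring$bands[[1]]
  layers <- list()
  season_valid <- list()
  for (s in SEASONS) {
    comp <- comps[[s]]
    if (!identical(comp$season, s))
      stop(sprintf("composite passed as '%s' is tagged '%s'", s, comp$season), call. = FALSE)
    idx <- compute_indices(comp)
    v <- comp$valid_mask
    for (b in BANDS) {
      check_same_shape(comp$bands[[b]], ref)
      layers[[paste(s, b, sep = "_")]] <- comp$bands[[b]]
    }
    for (i in INDICES) {
      layers[[paste(s, i, sep = "_")]] <- idx[[i]]
      v <- v & !is.na(idx[[i]])
    }
    season_valid[[s]] <- v
  }
  for (t in TERRAIN) {
    check_same_shape(terrain[[t]], ref)
    layers[[t]] <- terrain[[t]]
  }
  layers <- layers[layer_registry()]
  stopifnot(length(layers) == 36L, !anyDuplicated(names(layers)))
  structure(list(
    epoch = epoch, layers = layers,
    complete_mask = season_valid$spring & season_valid$summer & season_valid$fall,
    summer_mask = season_valid$summer
  ), class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> epoch %s, %d layers, %d x %d px, %.1f%% complete / %.1f%% summer\n",
              x$epoch, length(x$layers), nrow(x$layers[[1]]), ncol(x$layers[[1]]),
              100 * mean(x$complete_mask), 100 * mean(x$summer_mask)))
  invisible(x)
}

#' Sample stack pixels into a feature table
#'
#' @param stack A `feature_stack`.
#' @param n Number of pixels to sample from the complete mask.
#' @param seed Integer seed.
#' @return Data frame of sampled feature rows (columns = layer names).
#' @export
sample_stack_pixels <- function(stack, n = 1000L, seed = 1L) {
  idx <- which(stack$complete_mask)
  withr::with_seed(seed, {
    take <- sample(idx, min(n, length(idx)))
    as.data.frame(lapply(stack$layers, function(m) m[take]))
  })
}

#' Extract feature rows at pixel coordinates
#'
#' @param stack A `feature_stack`.
#' @param row,col Integer pixel coordinates.
#' @return Data frame of feature values, one row per coordinate.
#' @export
extract_features <- function(stack, row, col) {
  idx <- cbind(row, col)
  as.data.frame(lapply(stack$layers, function(m) m[idx]))
}

#' Greedy correlation pruning of feature layers
#'
#' Scans layers in registry order and drops a layer iff its absolute
#' Pearson correlation with any already-retained layer exceeds
#' `threshold`, computed over the supplied pixel sample. Zero-variance
#' layers are retained with a message (correlation undefined).
#'
#' @param stack A `feature_stack`.
#' @param samples Data frame of sampled pixels (e.g.
#'   [sample_stack_pixels()]); needs >= 2 rows.
#' @param threshold Absolute-correlation cutoff (default 0.95).
#' @return Character vector of retained layer names.
#' @export
prune_correlated <- function(stack, samples, threshold = 0.95) {
  if (nrow(samples) < 2) stop("need at least 2 sample pixels", call. = FALSE)
  keep <- character(0)
  for (name in names(stack$layers)) {
    x <- samples[[name]]
    if (sd(x) == 0) {
      message(sprintf("layer '%s' has zero variance in the sample; retained", name))
      keep <- c(keep, name)
      next
    }
    drop <- FALSE
    for (k in keep) {
      if (sd(samples[[k]]) == 0) next
      if (abs(cor(x, samples[[k]])) > threshold) { drop <- TRUE; break }
    }
    if (!drop) keep <- c(keep, name)
  }
  keep
}
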