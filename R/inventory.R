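## Inventory plot handling: deciduous-fraction response, binned
## under-sampling to balance the response distribution, train/validation
## splitting, and grid thinning of validation plots against spatial
## autocorrelation.

#' Deciduous fraction of a plot
#'
#' Ratio of deciduous tree basal area to total tree basal area, the
#' response variable of the cover models.
#'
#' @param deciduous_ba,evergreen_ba Basal areas (m^2), vectorised.
#' @return Fractions in \[0, 1\].
#' @export
deciduous_fraction <- function(deciduous_ba, evergreen_ba) {
  if (any(deciduous_ba < 0 | evergreen_ba < 0))
    stop("basal areas must be non-negative", call. = FALSE)
  total <- deciduous_ba + evergreen_ba
  if (any(total == 0))
    stop("plot with zero total basal area: deciduous fraction undefined", call. = FALSE)
  deciduous_ba / total
}

#' Attach the deciduous-fraction response to a plot table
#'
#' Plots with zero total basal area are dropped with a message (their
#' response is undefined) rather than treated as zero deciduous fraction.
#'
#' @param plots Data frame with `deciduous_ba` and `evergreen_ba`.
#' @return The table with a `dec_fraction` column, zero-total rows removed.
#' @export
plot_response <- function(plots) {
  total <- plots$deciduous_ba + plots$evergreen_ba
  bad <- total == 0
  if (any(bad)) {
    message(sprintf("dropping %d plot(s) with zero total basal area", sum(bad)))
    plots <- plots[!bad, , drop = FALSE]
  }
  plots$dec_fraction <- plots$deciduous_ba / (plots$deciduous_ba + plots$evergreen_ba)
  plots
}

response_bins <- function(x, bin_width) {
  nb <- round(1 / bin_width)
  if (abs(nb * bin_width - 1) > 1e-9)
    stop_cfg("bin_width", "must divide 1 evenly")
  pmin(floor(x / bin_width), nb - 1) + 1L
}

#' Binned under-sampling of the response distribution
#'
#' Balances a skewed response by retaining at most `target` records per
#' response bin (default: the smallest non-empty bin count), drawn by
#' seeded sampling without replacement. With the default target the
#' balanced histogram is exactly uniform over occupied bins.
#'
#' @param records Data frame with a `dec_fraction` (or `response_col`)
#'   column.
#' @param bin_width Bin width dividing 1 evenly (default 0.1).
#' @param target Per-bin cap; `NULL` for the smallest non-empty bin count.
#' @param seed Integer seed.
#' @param response_col Name of the response column.
#' @return The balanced subset (row order follows bin order).
#' @export
binned_undersample <- function(records, bin_width = 0.1, target = NULL,
                               seed = 1L, response_col = "dec_fraction") {
  if (nrow(records) == 0) stop("empty record set", call. = FALSE)
  bins <- response_bins(records[[response_col]], bin_width)
  counts <- table(bins)
  tgt <- target %||% min(counts)
  withr::with_seed(seed, {
    keep <- unlist(lapply(sort(unique(bins)), function(b) {
      idx <- which(bins == b)
      if (length(idx) > tgt) sample(idx, tgt) else idx
    }), use.names = FALSE)
  })
  records[keep, , drop = FALSE]
}

#' Seeded 70/30 train/validation split
#'
#' Shuffle-split with `floor(train_fraction * n)` training records; labels
#' are exhaustive and disjoint.
#'
#' @param records Data frame (>= 10 rows).
#' @param train_fraction Training share (default 0.70).
#' @param seed Integer seed.
#' @return The table with a `split` column in `{train, validation}`.
#' @export
split_train_validation <- function(records, train_fraction = 0.70, seed = 1L) {
  n <- nrow(records)
  if (n < 10) stop("need at least 10 records to split", call. = FALSE)
  n_train <- floor(train_fraction * n)
  withr::with_seed(seed, {
    idx <- sample.int(n)
  })
  split <- rep("validation", n)
  split[idx[seq_len(n_train)]] <- "train"
  records$split <- split
  records
}

#' Grid thinning of validation plots
#'
#' Overlays a square grid of cell side `min_distance` and keeps one
#' seeded-random record per occupied cell, reducing spatial
#' autocorrelation among validation plots.
#'
#' @param records Data frame with pixel coordinates `row`, `col`.
#' @param min_distance Cell side in metres (default 1000).
#' @param pixel_size Pixel size in metres.
#' @param seed Integer seed.
#' @return Thinned subset, one record per occupied cell.
#' @export
thin_for_validation <- function(records, min_distance = 1000, pixel_size = 30,
                                seed = 1L) {
  if (min_distance <= 0) stop_cfg("min_distance", "must be positive")
  if (nrow(records) == 0) return(records)
  cell <- paste(
    floor((records$col - 0.5) * pixel_size / min_distance),
    floor((records$row - 0.5) * pixel_size / min_distance)
  )
  withr::with_seed(seed, {
    keep <- vapply(split(seq_len(nrow(records)), cell), function(idx) {
      if (length(idx) == 1) idx else sample(idx, 1)
    }, integer(1))
  })
  records[sort(unname(keep)), , drop = FALSE]
}
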