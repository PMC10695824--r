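## Epoch-to-epoch change classification, significance screening, fire-age
## stratification, area accounting and Table-style report assembly.

#' Classify per-pixel change
#'
#' A pixel is "unchanged" iff its delta rounds to 0.00 at two decimal
#' digits under round-half-away-from-zero (i.e. |delta| < 0.005);
#' otherwise the sign of the delta decides increase/decrease.
#'
#' @param delta Numeric matrix of epoch differences.
#' @return Integer matrix: `+1` increase, `-1` decrease, `0` unchanged,
#'   `NA` propagated.
#' @export
classify_change <- function(delta) {
  out <- matrix(NA_integer_, nrow(delta), ncol(delta))
  ok <- !is.na(delta)
  rounded <- sign(delta[ok]) * floor(abs(delta[ok]) * 100 + 0.5)
  out[ok] <- ifelse(rounded == 0, 0L, ifelse(delta[ok] > 0, 1L, -1L))
  out
}

#' Per-pixel significance of change
#'
#' A stand-in z-screen for statistically significant change: significant
#' iff `|delta| > z * sqrt(sd_start^2 + sd_end^2)`, propagating the two
#' epochs' per-pixel model uncertainties. Pixels with both uncertainties
#' zero are significant iff the delta is non-zero.
#'
#' @param delta Numeric matrix of differences.
#' @param sd_start,sd_end Per-pixel uncertainty matrices (>= 0).
#' @param z Critical value (default 1.96).
#' @return Logical matrix (`NA` propagated).
#' @export
significance <- function(delta, sd_start, sd_end, z = 1.96) {
  check_same_shape(delta, sd_start); check_same_shape(delta, sd_end)
  if (any(sd_start < 0, na.rm = TRUE) || any(sd_end < 0, na.rm = TRUE))
    stop("uncertainty layers must be non-negative", call. = FALSE)
  abs(delta) > z * sqrt(sd_start^2 + sd_end^2)
}

#' Fire-age class of a fire year
#'
#' Disjoint chronosequence classes partitioning 1950-2018:
#' old 1950-1978, intermediate 1979-1998, recent 1999-2018.
#'
#' @param year Integer vector of fire years.
#' @return Character vector in `{old, intermediate, recent}` (`NA`
#'   propagated).
#' @export
fire_age_class <- function(year) {
  out <- rep(NA_character_, length(year))
  out[!is.na(year) & year <= 1978] <- "old"
  out[!is.na(year) & year >= 1979 & year <= 1998] <- "intermediate"
  out[!is.na(year) & year >= 1999 & year <= 2018] <- "recent"
  out
}

#' Rasterize dated fire perimeters
#'
#' Assigns each pixel (by pixel-centre-in-polygon, even-odd rule with
#' holes) the year of the most recent fire covering it, and derives the
#' fire-age class raster.
#'
#' @param fires List of fires, each a list with `polygon` (list of rings)
#'   and integer `year` in \[1950, 2018\].
#' @param grid_shape `(rows, cols)` of the target grid.
#' @return List with integer matrix `year` (`NA` unburned) and character
#'   matrix `class`.
#' @export
rasterize_fires <- function(fires, grid_shape) {
  year <- matrix(NA_integer_, grid_shape[1], grid_shape[2])
  for (i in seq_along(fires)) {
    f <- fires[[i]]
    if (is.null(f$polygon) || is.null(f$year))
      stop(sprintf("fire %d: missing polygon or year", i), call. = FALSE)
    if (f$year < 1950 || f$year > 2018)
      stop(sprintf("fire %d: year %d outside [1950, 2018]", i, f$year), call. = FALSE)
    rings <- if (is.matrix(f$polygon)) list(f$polygon) else f$polygon
    for (r in rings) {
      if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 3)
        stop(sprintf("fire %d: invalid geometry (ring must be an n x 2 matrix, n >= 3)", i),
             call. = FALSE)
    }
    m <- pip_mask(rings, grid_shape)
    upd <- m & (is.na(year) | year < f$year)
    year[upd] <- f$year
  }
  cls <- matrix(fire_age_class(year), grid_shape[1], grid_shape[2])
  list(year = year, class = cls)
}

#' Pixels burned between two epochs
#'
#' @param fire_year Most-recent-fire-year raster.
#' @param epoch_start,epoch_end Epoch years.
#' @return Logical matrix: burned strictly after `epoch_start` and at or
#'   before `epoch_end`.
#' @export
burned_between <- function(fire_year, epoch_start, epoch_end) {
  !is.na(fire_year) & fire_year > epoch_start & fire_year <= epoch_end
}

#' Tree-dominated analysis mask
#'
#' A pixel enters the analysis iff its canopy cover is at or above the
#' threshold in either epoch, or it exceeded the threshold in the earlier
#' epoch and burned between the epochs (so fire-killed stands stay in the
#' analysis). Rule provenance is recorded per pixel.
#'
#' @param cover_start,cover_end Canopy cover matrices (or `cover_map`s).
#' @param burned Logical matrix of pixels burned between the epochs.
#' @param threshold Cover threshold (default 0.25).
#' @return List with logical `mask` and character `provenance`
#'   (`cover_ge_threshold` / `prefire_inclusion` / `NA`).
#' @export
analysis_mask <- function(cover_start, cover_end, burned, threshold = 0.25) {
  cs <- cover_values(cover_start); ce <- cover_values(cover_end)
  check_same_shape(cs, ce); check_same_shape(cs, burned)
  by_threshold <- (!is.na(cs) & cs >= threshold) | (!is.na(ce) & ce >= threshold)
  prefire <- !is.na(cs) & cs > threshold & burned &
    !is.na(ce) & ce < threshold
  mask <- by_threshold | prefire
  prov <- matrix(NA_character_, nrow(cs), ncol(cs))
  prov[mask] <- "cover_ge_threshold"
  ## fire-killed stands: qualified before burning, below threshold after
  prov[prefire] <- "prefire_inclusion"
  list(mask = mask, provenance = prov)
}

#' Pixel-count area accounting
#'
#' Converts class counts on the mask into areas in millions of hectares:
#' a 30 m pixel is 0.09 ha.
#'
#' @param class_raster Integer matrix from [classify_change()].
#' @param mask Logical analysis mask.
#' @param pixel_size Pixel side in metres.
#' @return Named numeric: `increase`, `decrease`, `unchanged`, `total`
#'   (Mha).
#' @export
area_accounting <- function(class_raster, mask, pixel_size = 30) {
  ha_per_px <- pixel_size^2 / 1e4
  v <- class_raster[mask]
  to_mha <- function(n) n * ha_per_px / 1e6
  c(increase = to_mha(sum(v == 1L, na.rm = TRUE)),
    decrease = to_mha(sum(v == -1L, na.rm = TRUE)),
    unchanged = to_mha(sum(v == 0L, na.rm = TRUE)),
    total = to_mha(sum(!is.na(v))))
}

mean_sd_n <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(mean = NA_real_, sd = NA_real_, n = 0))
  c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0, n = length(x))
}

## One report row for the pixels at linear indices `idx`.
summarize_stratum <- function(label, idx, deltas, sigs, albedo_deltas, forcings,
                              pixel_size) {
  ha_per_px <- pixel_size^2 / 1e4
  to_mha <- function(n) n * ha_per_px / 1e6
  row <- list(stratum = label, n_pixels = length(idx))
  for (resp in names(deltas)) {
    d <- deltas[[resp]][idx]
    cls <- classify_change(matrix(d, ncol = 1))
    sig <- if (!is.null(sigs[[resp]])) sigs[[resp]][idx] else rep(NA, length(idx))
    row[[paste0(resp, "_area_increase_Mha")]] <- to_mha(sum(cls == 1L, na.rm = TRUE))
    row[[paste0(resp, "_area_decrease_Mha")]] <- to_mha(sum(cls == -1L, na.rm = TRUE))
    row[[paste0(resp, "_area_unchanged_Mha")]] <- to_mha(sum(cls == 0L, na.rm = TRUE))
    row[[paste0(resp, "_area_sig_increase_Mha")]] <- to_mha(sum(cls == 1L & sig, na.rm = TRUE))
    row[[paste0(resp, "_area_sig_decrease_Mha")]] <- to_mha(sum(cls == -1L & sig, na.rm = TRUE))
    ms <- mean_sd_n(d)
    row[[paste0(resp, "_delta_mean")]] <- ms[["mean"]]
    row[[paste0(resp, "_delta_sd")]] <- ms[["sd"]]
  }
  for (s in names(albedo_deltas)) {
    ms <- mean_sd_n(albedo_deltas[[s]][idx])
    row[[paste0(s, "_albedo_delta_mean")]] <- ms[["mean"]]
    row[[paste0(s, "_albedo_delta_sd")]] <- ms[["sd"]]
  }
  for (s in names(forcings)) {
    f <- forcings[[s]]
    f <- if (inherits(f, "forcing_map")) f$forcing else f
    v <- f[idx]
    all_ms <- mean_sd_n(v)
    warm <- mean_sd_n(v[!is.na(v) & v > 0])
    cool <- mean_sd_n(v[!is.na(v) & v < 0])
    row[[paste0(s, "_forcing_mean")]] <- all_ms[["mean"]]
    row[[paste0(s, "_forcing_sd")]] <- all_ms[["sd"]]
    row[[paste0(s, "_forcing_n")]] <- all_ms[["n"]]
    row[[paste0(s, "_warming_mean")]] <- warm[["mean"]]
    row[[paste0(s, "_warming_sd")]] <- warm[["sd"]]
    row[[paste0(s, "_warming_n")]] <- warm[["n"]]
    row[[paste0(s, "_cooling_mean")]] <- cool[["mean"]]
    row[[paste0(s, "_cooling_sd")]] <- cool[["sd"]]
    row[[paste0(s, "_cooling_n")]] <- cool[["n"]]
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Stratified change report
#'
#' Produces one row per stratum (plus a pooled `domain` row over the whole
#' mask): change/significant-change areas and mean +/- sd deltas for each
#' response, seasonal albedo-change statistics, and seasonal forcing
#' statistics split into warming (positive-forcing pixels) and cooling
#' (negative-forcing pixels) with pixel counts. Area conservation
#' (increase + decrease + unchanged = stratum area) holds exactly by
#' construction and is asserted.
#'
#' @param deltas Named list of response delta matrices (e.g. `dec`,
#'   `cover`).
#' @param sigs Named list of logical significance matrices (same names;
#'   entries may be `NULL`).
#' @param albedo_deltas Named list (by season) of albedo delta matrices.
#' @param forcings Named list (by season) of `forcing_map`s or matrices.
#' @param strata Character matrix of stratum labels (`NA` = unstratified;
#'   such pixels appear only in the domain row).
#' @param mask Logical analysis mask.
#' @param pixel_size Pixel side in metres.
#' @return Object of class `change_report` (a data frame).
#' @export
stratified_summary <- function(deltas, sigs = list(), albedo_deltas = list(),
                               forcings = list(), strata = NULL, mask,
                               pixel_size = 30) {
  for (d in deltas) check_same_shape(d, mask, "delta and mask")
  idx_domain <- which(mask)
  rows <- list(summarize_stratum("domain", idx_domain, deltas, sigs,
                                 albedo_deltas, forcings, pixel_size))
  if (!is.null(strata)) {
    check_same_shape(strata, mask, "strata and mask")
    labels <- sort(unique(strata[mask][!is.na(strata[mask])]))
    for (lab in labels) {
      idx <- which(mask & !is.na(strata) & strata == lab)
      rows[[length(rows) + 1L]] <-
        summarize_stratum(lab, idx, deltas, sigs, albedo_deltas, forcings, pixel_size)
    }
  }
  report <- do.call(rbind, rows)
  ## exact conservation: partition of each stratum's masked area
  ha_per_px <- pixel_size^2 / 1e4
  for (resp in names(deltas)) {
    n_classified <- (report[[paste0(resp, "_area_increase_Mha")]] +
                       report[[paste0(resp, "_area_decrease_Mha")]] +
                       report[[paste0(resp, "_area_unchanged_Mha")]]) * 1e6 / ha_per_px
    n_valid <- vapply(seq_len(nrow(report)), function(i) {
      lab <- report$stratum[i]
      idx <- if (lab == "domain") idx_domain else which(mask & !is.na(strata) & strata == lab)
      sum(!is.na(deltas[[resp]][idx]))
    }, numeric(1))
    stopifnot(isTRUE(all.equal(n_classified, n_valid)))
  }
  class(report) <- c("change_report", class(report))
  report
}

#' Rasterize a region partition
#'
#' @param regions List of regions, each a list with `name` and `polygon`
#'   (list of rings). Overlapping regions are an error: the set must be a
#'   partition (gaps become `NA` / "unassigned").
#' @param grid_shape `(rows, cols)`.
#' @return Character matrix of region names (`NA` where unassigned).
#' @export
rasterize_regions <- function(regions, grid_shape) {
  out <- matrix(NA_character_, grid_shape[1], grid_shape[2])
  for (reg in regions) {
    m <- pip_mask(reg$polygon, grid_shape)
    if (any(!is.na(out[m])))
      stop(sprintf("region '%s' overlaps another region: regions must form a partition",
                   reg$name), call. = FALSE)
    out[m] <- reg$name
  }
  out
}

#' Per-region change report
#'
#' Same statistics as [stratified_summary()], one row per region zone
#' (plus the pooled domain row); masked pixels outside every region are
#' reported under `unassigned`.
#'
#' @inheritParams stratified_summary
#' @param regions List of regions (see [rasterize_regions()]).
#' @return A `change_report` with one row per region.
#' @export
regional_summary <- function(regions, deltas, sigs = list(), albedo_deltas = list(),
                             forcings = list(), mask, pixel_size = 30) {
  strata <- rasterize_regions(regions, dim(mask))
  strata[is.na(strata) & mask] <- "unassigned"
  stratified_summary(deltas, sigs, albedo_deltas, forcings, strata, mask,
                     pixel_size)
}
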