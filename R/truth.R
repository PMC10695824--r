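## Synthetic landscape ground truth: long-term composition fields, fire
## history, succession parameters, spectral endmembers, seasonal albedo
## coefficients and terrain. Everything downstream (compositing, cover
## mapping, albedo modelling, change analysis) can be exercised against
## these known fields.

SEASONS <- c("spring", "summer", "fall")
BANDS <- c("blue", "green", "red", "nir", "swir1", "swir2")

#' Default spectral endmember table
#'
#' Reflectance endmembers for the three-component linear mixture
#' (deciduous canopy, evergreen canopy, background) by season and band.
#' The table encodes the phenology contrast the mapping relies on: in
#' summer the deciduous near-infrared reflectance clearly exceeds the
#' evergreen one, and the contrast shrinks in spring when deciduous
#' canopies are leaf-off. The spring/fall background is brightened to
#' mimic partial snow and senescent ground cover.
#'
#' @return A 3 x 3 x 6 array (member x season x band) of reflectances in
#'   \[0, 1\].
#' @export
default_endmembers <- function() {
  e <- array(NA_real_, dim = c(3, 3, 6),
             dimnames = list(member = c("deciduous", "evergreen", "background"),
                             season = SEASONS, band = BANDS))
  #                         blue  green  red   nir  swir1 swir2
  e["deciduous", "spring", ] <- c(0.050, 0.070, 0.080, 0.240, 0.150, 0.090)
  e["evergreen", "spring", ] <- c(0.030, 0.050, 0.040, 0.210, 0.130, 0.070)
  e["background", "spring", ] <- c(0.300, 0.320, 0.330, 0.350, 0.200, 0.120)
  e["deciduous", "summer", ] <- c(0.030, 0.060, 0.040, 0.450, 0.220, 0.120)
  e["evergreen", "summer", ] <- c(0.020, 0.040, 0.030, 0.280, 0.150, 0.080)
  e["background", "summer", ] <- c(0.060, 0.090, 0.100, 0.250, 0.280, 0.200)
  e["deciduous", "fall", ] <- c(0.050, 0.080, 0.100, 0.300, 0.200, 0.120)
  e["evergreen", "fall", ] <- c(0.025, 0.045, 0.035, 0.260, 0.140, 0.075)
  e["background", "fall", ] <- c(0.080, 0.100, 0.120, 0.240, 0.260, 0.180)
  e
}

#' Default seasonal albedo coefficients
#'
#' Per-season coefficients of the bilinear albedo forward model
#' `alpha = b0 + b_d * d + b_c * c + b_dc * d * c`, with `d` the deciduous
#' fraction and `c` the tree canopy cover. The spring intercept is high
#' (snow-covered open ground); the canopy coefficient `b_c` is negative
#' every season because canopy masks the bright background, and its
#' magnitude is largest in spring when the background is snow. The
#' deciduous coefficient `b_d` is positive every season.
#'
#' @return Named list of per-season coefficient lists `{b0, b_d, b_c, b_dc}`.
#' @export
default_albedo_coeffs <- function() {
  list(
    spring = list(b0 = 0.55, b_d = 0.12, b_c = -0.40, b_dc = 0.08),
    summer = list(b0 = 0.14, b_d = 0.06, b_c = -0.02, b_dc = 0.02),
    fall   = list(b0 = 0.35, b_d = 0.09, b_c = -0.22, b_dc = 0.05)
  )
}

#' Default generation parameters for the synthetic landscape
#'
#' The defaults define the study conditions every test and the acceptance
#' run use: a 256 x 256 grid of 30 m pixels, smooth base fields for
#' long-term deciduous fraction and mature canopy cover, a dozen dated
#' fires spread over 1950-2018, and succession time constants of 25 years
#' (canopy closure) and 15 years (deciduous pulse peak).
#'
#' @return A named list of generation parameters; override entries via the
#'   `config` argument of [generate_truth()].
#' @export
default_truth_config <- function() {
  list(
    grid_shape = c(256L, 256L),
    pixel_size = 30,
    n_fires = 12L,
    fire_year_range = c(1950L, 2018L),
    fire_radius_px = c(15, 45),
    dec_base_mean = 0.35, dec_base_sd = 0.22,
    cover_base_mean = 0.65, cover_base_sd = 0.18,
    cover_base_min = 0.05,
    field_range_px = 24,
    dem_mean = 300, dem_sd = 120, dem_range_px = 48,
    succession_params = list(tau_c = 25, tau_d = 15, d_peak = 0.75, d_late = 0.10),
    endmembers = default_endmembers(),
    albedo_coeffs = default_albedo_coeffs()
  )
}

#' Generate a seeded synthetic landscape truth
#'
#' Builds spatially autocorrelated base fields for long-term deciduous
#' fraction and mature canopy cover (Gaussian-blurred seeded noise), a
#' terrain model, and a set of dated irregular fire polygons. Identical
#' `config` and `seed` always produce identical truth.
#'
#' @param config Named list of overrides of [default_truth_config()].
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `landscape_truth`.
#' @export
generate_truth <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(default_truth_config(), config)
  gs <- as.integer(cfg$grid_shape)
  if (length(gs) != 2 || any(gs < 1)) stop_cfg("grid_shape", "must be two positive integers")
  sp <- cfg$succession_params
  if (sp$d_late < 0 || sp$d_peak > 1 || sp$d_late > sp$d_peak)
    stop_cfg("succession_params", "requires 0 <= d_late <= d_peak <= 1")
  if (sp$tau_c <= 0 || sp$tau_d <= 0)
    stop_cfg("succession_params", "requires positive tau_c and tau_d")
  if (any(cfg$endmembers < 0 | cfg$endmembers > 1))
    stop_cfg("endmembers", "must lie in [0, 1]")
  yr <- cfg$fire_year_range
  if (yr[1] < 1950 || yr[2] > 2018 || yr[1] > yr[2])
    stop_cfg("fire_year_range", "must lie within [1950, 2018]")

  truth <- withr::with_seed(seed, {
    dec_base <- clamp01(cfg$dec_base_mean +
                          cfg$dec_base_sd * smooth_field(gs[1], gs[2], cfg$field_range_px))
    cover_base <- clamp(cfg$cover_base_mean +
                          cfg$cover_base_sd * smooth_field(gs[1], gs[2], cfg$field_range_px),
                        cfg$cover_base_min, 0.98)
    dem <- cfg$dem_mean + cfg$dem_sd * smooth_field(gs[1], gs[2], cfg$dem_range_px)
    fires <- list()
    if (cfg$n_fires > 0) {
      for (i in seq_len(cfg$n_fires)) {
        cx <- runif(1, 0, gs[2]); cy <- runif(1, 0, gs[1])
        rad <- runif(1, cfg$fire_radius_px[1], cfg$fire_radius_px[2])
        poly <- list(random_blob_polygon(cx, cy, rad))
        year <- as.integer(round(runif(1, yr[1], yr[2])))
        if (polygon_bbox_valid(poly, gs)) {
          fires[[length(fires) + 1L]] <- list(polygon = poly, year = year)
        }
      }
    }
    list(dec_base = dec_base, cover_base = cover_base, dem = dem, fires = fires)
  })

  fire_masks <- lapply(truth$fires, function(f) pip_mask(f$polygon, gs))

  structure(list(
    grid_shape = gs, pixel_size = cfg$pixel_size,
    dec_base = truth$dec_base, cover_base = truth$cover_base, dem = truth$dem,
    fires = truth$fires, fire_masks = fire_masks,
    succession_params = sp,
    endmembers = cfg$endmembers, albedo_coeffs = cfg$albedo_coeffs,
    seed = as.integer(seed), config = cfg
  ), class = "landscape_truth")
}

#' @export
print.landscape_truth <- function(x, ...) {
  cat(sprintf("<landscape_truth> %d x %d pixels (%g m), %d fires, seed %d\n",
              x$grid_shape[1], x$grid_shape[2], x$pixel_size,
              length(x$fires), x$seed))
  invisible(x)
}

#' Most recent fire year per pixel
#'
#' @param truth A `landscape_truth`.
#' @param year Evaluation year; fires after `year` are ignored.
#' @return Integer matrix of the most recent fire year at or before `year`,
#'   `NA` where unburned.
#' @export
last_fire_year <- function(truth, year) {
  out <- matrix(NA_integer_, truth$grid_shape[1], truth$grid_shape[2])
  if (length(truth$fires) == 0) return(out)
  ord <- order(vapply(truth$fires, function(f) f$year, integer(1)))
  for (i in ord) {
    f <- truth$fires[[i]]
    if (f$year > year) next
    m <- truth$fire_masks[[i]]
    out[m] <- f$year
  }
  out
}

## Deciduous succession pulse: d_late + (d_peak - d_late) * (t/tau) * e^(1 - t/tau).
## Peaks at t = tau (value d_peak), decays to d_late.
succession_dec <- function(t, sp) {
  u <- t / sp$tau_d
  sp$d_late + (sp$d_peak - sp$d_late) * u * exp(1 - u)
}

succession_cover <- function(t, c0, sp) {
  c0 * (1 - exp(-t / sp$tau_c))
}

#' Evaluate true composition fields for a year
#'
#' Applies the post-fire succession model: canopy cover recovers as a
#' saturating exponential towards its mature value, and deciduous fraction
#' follows a pulse that peaks `tau_d` years after fire at `d_peak` and then
#' declines towards `d_late` (relay floristics: early deciduous dominance
#' replaced by evergreen conifers). Unburned pixels carry the base fields.
#' Multiple fires reset the clock at the most recent fire at or before
#' `year`.
#'
#' @param truth A `landscape_truth`.
#' @param year Evaluation year (>= 1950; earlier years are treated as
#'   unburned everywhere).
#' @return List with matrices `dec` and `cover`, both in \[0, 1\].
#' @export
evaluate_composition <- function(truth, year) {
  dec <- truth$dec_base
  cover <- truth$cover_base
  fy <- last_fire_year(truth, year)
  burned <- !is.na(fy)
  if (any(burned)) {
    t <- year - fy[burned]
    sp <- truth$succession_params
    dec[burned] <- succession_dec(t, sp)
    cover[burned] <- succession_cover(t, truth$cover_base[burned], sp)
  }
  list(dec = clamp01(dec), cover = clamp01(cover))
}
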