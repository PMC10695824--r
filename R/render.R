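## Forward models: multi-date reflectance stacks, inventory plot tables,
## coarse seasonal albedo and radiative-kernel fields, all derived from a
## landscape_truth. These are the stand-ins for the satellite, inventory
## and reanalysis inputs of the real-data path.

check_season <- function(season) {
  if (!season %in% SEASONS)
    stop(sprintf("unknown season '%s' (expected one of %s)",
                 season, paste(SEASONS, collapse = ", ")), call. = FALSE)
  season
}

## Linear three-component mixture for one season, all bands.
mixture_reflectance <- function(dec, cover, endmembers, season) {
  lapply(setNames(BANDS, BANDS), function(b) {
    e_dec <- endmembers["deciduous", season, b]
    e_eve <- endmembers["evergreen", season, b]
    e_bg <- endmembers["background", season, b]
    cover * (dec * e_dec + (1 - dec) * e_eve) + (1 - cover) * e_bg
  })
}

#' Render a multi-date seasonal reflectance stack
#'
#' Simulates `n_dates` cloud-screened acquisitions of six spectral bands
#' for one season of one year. Per-pixel reflectance is the linear mixture
#' `c * (d * E_dec + (1 - d) * E_eve) + (1 - c) * E_bg` of the seasonal
#' endmember spectra, plus Gaussian noise, clipped to \[0, 1\]. Clouds are
#' spatially coherent seeded masks covering about `cloud_fraction` of each
#' date.
#'
#' @param truth A `landscape_truth`.
#' @param year Acquisition year (composition evaluated with
#'   [evaluate_composition()]).
#' @param season One of `"spring"`, `"summer"`, `"fall"`.
#' @param n_dates Number of acquisition dates (>= 1).
#' @param cloud_fraction Fraction of pixels flagged invalid per date.
#' @param noise_sd Gaussian reflectance noise standard deviation.
#' @param seed Integer seed.
#' @return Object of class `reflectance_stack`: list with `season`, `year`
#'   and `dates`, each date a list of `bands` (named list of 6 matrices)
#'   and a logical `valid` mask.
#' @export
render_reflectance <- function(truth, year, season, n_dates = 6L,
                               cloud_fraction = 0.15, noise_sd = 0.01,
                               seed = 1L) {
  check_season(season)
  if (n_dates < 1) stop_cfg("n_dates", "must be >= 1")
  comp <- evaluate_composition(truth, year)
  gs <- truth$grid_shape
  dates <- withr::with_seed(seed, {
    lapply(seq_len(n_dates), function(i) {
      ## date-to-date brightness jitter keeps NDVI distinct across dates;
      ## scales with noise_sd so the zero-noise limit is exact
      jitter <- rnorm(1, 0, noise_sd)
      bands <- mixture_reflectance(comp$dec, comp$cover, truth$endmembers, season)
      bands <- lapply(bands, function(m) {
        if (noise_sd > 0 || jitter != 0) {
          m <- m + jitter + matrix(rnorm(length(m), 0, noise_sd), gs[1], gs[2])
        }
        clamp01(m)
      })
      valid <- matrix(TRUE, gs[1], gs[2])
      if (cloud_fraction > 0) {
        cf <- smooth_field(gs[1], gs[2], 16)
        valid <- cf > quantile(cf, cloud_fraction)
      }
      list(bands = bands, valid = valid)
    })
  })
  structure(list(season = season, year = year, dates = dates),
            class = "reflectance_stack")
}

#' Sample forest inventory plots
#'
#' Draws plot locations on pixels with positive canopy cover and reports
#' per-plot deciduous and evergreen basal areas. Total basal area scales
#' with pixel canopy cover; the plot deciduous share is a noisy draw
#' centred on the pixel deciduous fraction (logit-space jitter), exactly
#' equal to it when `ba_noise = 0`.
#'
#' @param truth A `landscape_truth`.
#' @param year Inventory year.
#' @param n_plots Number of plots (>= 1).
#' @param ba_noise Dispersion of the deciduous share around the pixel value.
#' @param seed Integer seed.
#' @return Data frame with columns `plot_id`, `row`, `col`,
#'   `deciduous_ba`, `evergreen_ba` (m^2).
#' @export
sample_plots <- function(truth, year, n_plots = 2000L, ba_noise = 0.05,
                         seed = 1L) {
  if (n_plots < 1) stop_cfg("n_plots", "must be >= 1")
  comp <- evaluate_composition(truth, year)
  eligible <- which(comp$cover > 0)
  if (length(eligible) == 0) stop("no eligible pixels: canopy cover is zero everywhere", call. = FALSE)
  withr::with_seed(seed, {
    idx <- sample(eligible, n_plots, replace = n_plots > length(eligible))
    rc <- arrayInd(idx, truth$grid_shape)
    dec <- comp$dec[idx]
    cover <- comp$cover[idx]
    share <- dec
    if (ba_noise > 0) {
      share <- clamp01(dec + rnorm(n_plots, 0, ba_noise))
    }
    total_ba <- 40 * cover * exp(rnorm(n_plots, 0, if (ba_noise > 0) 0.2 else 0))
    data.frame(
      plot_id = sprintf("P%05d", seq_len(n_plots)),
      row = rc[, 1], col = rc[, 2],
      deciduous_ba = total_ba * share,
      evergreen_ba = total_ba * (1 - share)
    )
  })
}

#' Render a coarse seasonal albedo raster
#'
#' Evaluates the bilinear albedo forward model on the fine grid, adds
#' Gaussian noise, clips to \[0, 1\], block-averages by `coarse_factor`
#' (default 16, about 500 m from 30 m pixels) and attaches a seeded
#' validity mask standing in for solar-zenith screening.
#'
#' @param truth A `landscape_truth`.
#' @param year Evaluation year.
#' @param season Season id.
#' @param coarse_factor Integer aggregation factor; must divide both grid
#'   dimensions.
#' @param noise_sd Fine-scale albedo noise standard deviation.
#' @param invalid_fraction Fraction of coarse cells flagged invalid.
#' @param seed Integer seed.
#' @return List with coarse matrices `albedo` and logical `valid`, plus
#'   `season`, `year` and `coarse_factor`.
#' @export
render_albedo <- function(truth, year, season, coarse_factor = 16L,
                          noise_sd = 0.01, invalid_fraction = 0.05,
                          seed = 1L) {
  check_season(season)
  gs <- truth$grid_shape
  if (coarse_factor < 1 || gs[1] %% coarse_factor != 0 || gs[2] %% coarse_factor != 0)
    stop(sprintf("coarse_factor %d must divide grid %dx%d", coarse_factor, gs[1], gs[2]),
         call. = FALSE)
  comp <- evaluate_composition(truth, year)
  b <- truth$albedo_coeffs[[season]]
  alpha <- b$b0 + b$b_d * comp$dec + b$b_c * comp$cover + b$b_dc * comp$dec * comp$cover
  withr::with_seed(seed, {
    if (noise_sd > 0) alpha <- alpha + matrix(rnorm(length(alpha), 0, noise_sd), gs[1], gs[2])
    alpha <- clamp01(alpha)
    coarse <- block_mean(alpha, coarse_factor)
    valid <- matrix(TRUE, nrow(coarse), ncol(coarse))
    if (invalid_fraction > 0) {
      valid <- matrix(runif(length(coarse)) > invalid_fraction,
                      nrow(coarse), ncol(coarse))
    }
    list(albedo = coarse, valid = valid, season = season, year = year,
         coarse_factor = coarse_factor)
  })
}

#' Render a radiative-kernel field
#'
#' Produces a smooth, strictly negative kernel field in W m^-2 per unit
#' albedo increase at the coarse resolution. Default seasonal magnitudes
#' (spring -120, summer -150, fall -70) are synthetic, plausible values
#' chosen so that a 0.01 albedo increase yields a forcing of order
#' -1 W m^-2; they are not taken from any archived kernel product.
#'
#' @param truth A `landscape_truth`.
#' @param season Season id.
#' @param coarse_factor Integer aggregation factor dividing the grid.
#' @param mean_kernel Spatial mean (W m^-2 per unit albedo); defaults by
#'   season. Set `relative_sd = 0` for a constant field.
#' @param relative_sd Relative spatial variation (fraction of the mean).
#' @param seed Integer seed.
#' @return List with matrix `kernel`, `season` and `coarse_factor`.
#' @export
render_kernel <- function(truth, season, coarse_factor = 16L,
                          mean_kernel = NULL, relative_sd = 0.1, seed = 1L) {
  check_season(season)
  gs <- truth$grid_shape
  if (coarse_factor < 1 || gs[1] %% coarse_factor != 0 || gs[2] %% coarse_factor != 0)
    stop(sprintf("coarse_factor %d must divide grid %dx%d", coarse_factor, gs[1], gs[2]),
         call. = FALSE)
  defaults <- c(spring = -120, summer = -150, fall = -70)
  mu <- mean_kernel %||% defaults[[season]]
  if (mu >= 0) stop_cfg("mean_kernel", "must be negative (cooling per unit albedo increase)")
  cr <- gs[1] / coarse_factor; cc <- gs[2] / coarse_factor
  kernel <- withr::with_seed(seed, {
    if (relative_sd > 0) {
      f <- smooth_field(cr, cc, max(2, cr / 8))
      k <- mu * (1 + relative_sd * f)
      pmin(k, -1e-6)  # keep strictly negative even in field tails
    } else {
      matrix(mu, cr, cc)
    }
  })
  list(kernel = kernel, season = season, coarse_factor = coarse_factor)
}
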