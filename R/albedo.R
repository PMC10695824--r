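## Seasonal albedo compositing, the composition -> albedo model, and the
## kernel conversion of albedo change into shortwave radiative forcing.

#' Season month windows
#'
#' @return Named list: spring March-May, summer June-August, fall
#'   September-November.
#' @export
season_months <- function() {
  list(spring = 3:5, summer = 6:8, fall = 9:11)
}

#' Median seasonal albedo composite from daily rasters
#'
#' Per-pixel median over the valid days of the season (an even count takes
#' the mean of the two middle values); pixels with no valid day are
#' masked. Days carrying a `month` field are filtered to the season's
#' month window first.
#'
#' @param days List of daily layers, each a list with matrix `albedo`,
#'   logical `valid`, and optionally integer `month`.
#' @param season Season id (selects the month window and tags the output).
#' @return Object of class `seasonal_albedo`: `season`, matrix `albedo`
#'   (`NA` where masked), logical `valid_mask`.
#' @export
seasonal_albedo_composite <- function(days, season) {
  check_season(season)
  if (length(days) < 1) stop("need at least one day", call. = FALSE)
  window <- season_months()[[season]]
  keep <- vapply(days, function(d) is.null(d$month) || d$month %in% window, logical(1))
  days <- days[keep]
  if (length(days) < 1) stop("no day falls inside the season month window", call. = FALSE)
  ref <- days[[1]]$albedo
  for (d in days) {
    check_same_shape(d$albedo, ref)
    check_same_shape(d$valid, ref)
  }
  vals <- vapply(days, function(d) {
    a <- d$albedo
    a[!d$valid] <- NA_real_
    as.vector(a)
  }, numeric(length(ref)))
  vals <- matrix(vals, nrow = length(ref))
  med <- apply(vals, 1, median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  albedo <- matrix(med, nrow(ref), ncol(ref))
  structure(list(season = season, albedo = albedo, valid_mask = !is.na(albedo)),
            class = "seasonal_albedo")
}

cover_values <- function(x) {
  if (inherits(x, "cover_map")) x$estimate else x
}

#' Stratified albedo training sample
#'
#' Draws at most `n_per_bin` seeded samples per 0.1-wide albedo interval
#' from pixels where the albedo composite is valid and both cover maps
#' are scored, pairing `(deciduous_fraction, tree_canopy_cover, albedo)`.
#'
#' @param albedo A `seasonal_albedo` at the analysis resolution.
#' @param dec_map,cover_map Cover maps (`cover_map` objects or matrices).
#' @param bin_width Albedo bin width (default 0.1).
#' @param n_per_bin Cap per occupied bin.
#' @param seed Integer seed.
#' @return Data frame with columns `deciduous_fraction`,
#'   `tree_canopy_cover`, `albedo`.
#' @export
sample_albedo_training <- function(albedo, dec_map, cover_map, bin_width = 0.1,
                                   n_per_bin = 300L, seed = 1L) {
  d <- cover_values(dec_map); cv <- cover_values(cover_map)
  a <- albedo$albedo
  check_same_shape(a, d); check_same_shape(a, cv)
  ok <- which(albedo$valid_mask & !is.na(d) & !is.na(cv))
  if (length(ok) == 0) stop("no valid pixels to sample", call. = FALSE)
  nb <- ceiling(1 / bin_width)
  bins <- pmin(floor(a[ok] / bin_width), nb - 1) + 1L
  withr::with_seed(seed, {
    keep <- unlist(lapply(sort(unique(bins)), function(b) {
      idx <- ok[bins == b]
      if (length(idx) > n_per_bin) sample(idx, n_per_bin) else idx
    }), use.names = FALSE)
  })
  data.frame(deciduous_fraction = d[keep], tree_canopy_cover = cv[keep],
             albedo = a[keep])
}

#' Fit the composition-to-albedo model
#'
#' Ensemble regression of seasonal albedo on exactly two predictors,
#' deciduous fraction and tree canopy cover. Reports impurity-based
#' predictor importance shares and a 5-fold cross-validated r-squared.
#'
#' @param records Data frame from [sample_albedo_training()] (>= 50 rows).
#' @param hyperparams Optional hyperparameter overrides (see
#'   [model_spec()]).
#' @param folds CV folds for the reported r-squared.
#' @param seed Integer seed.
#' @return Object of class `albedo_model` with `fit`, `importance`
#'   (shares summing to 1), `cv_r2`, and the training albedo `range`.
#' @export
fit_albedo_model <- function(records, hyperparams = list(), folds = 5L, seed = 1L) {
  predictors <- c("deciduous_fraction", "tree_canopy_cover")
  if (nrow(records) < 50) stop("need at least 50 training records", call. = FALSE)
  for (p in predictors) {
    if (sd(records[[p]]) == 0)
      stop(sprintf("degenerate predictor '%s': constant in the training sample", p),
           call. = FALSE)
  }
  hp <- utils::modifyList(
    list(n_trees = 300L, max_features = "sqrt", min_samples_split = 5L,
         min_samples_leaf = 3L), hyperparams)
  dat <- records[, c("albedo", predictors)]
  fit <- ranger::ranger(
    dependent.variable.name = "albedo", data = dat,
    num.trees = hp$n_trees, mtry = resolve_mtry(hp$max_features, 2L),
    min.node.size = hp$min_samples_split, min.bucket = hp$min_samples_leaf,
    importance = "impurity", seed = seed, num.threads = 1L)
  imp <- fit$variable.importance
  imp <- imp / sum(imp)
  ids <- withr::with_seed(derive_seed(seed, 77), sample(rep_len(seq_len(folds), nrow(dat))))
  r2s <- vapply(seq_len(folds), function(k) {
    f <- ranger::ranger(dependent.variable.name = "albedo",
                        data = dat[ids != k, , drop = FALSE],
                        num.trees = hp$n_trees, mtry = resolve_mtry(hp$max_features, 2L),
                        min.node.size = hp$min_samples_split, min.bucket = hp$min_samples_leaf,
                        seed = derive_seed(seed, k), num.threads = 1L)
    pred <- predict(f, dat[ids == k, predictors, drop = FALSE], num.threads = 1L)$predictions
    r2_score(dat$albedo[ids == k], pred)
  }, numeric(1))
  structure(list(fit = fit, importance = imp, cv_r2 = mean(r2s, na.rm = TRUE),
                 range = range(records$albedo), hyperparams = hp),
            class = "albedo_model")
}

#' Predict seasonal albedo from cover maps
#'
#' @param model An `albedo_model`.
#' @param dec_map,cover_map Cover maps for one epoch (`cover_map` objects
#'   or matrices); pixels where either is nodata are masked.
#' @param season Season tag for the output.
#' @param epoch Epoch tag.
#' @return A `seasonal_albedo` on the cover-map grid.
#' @export
predict_albedo <- function(model, dec_map, cover_map, season, epoch = NA_integer_) {
  check_season(season)
  d <- cover_values(dec_map); cv <- cover_values(cover_map)
  check_same_shape(d, cv)
  ok <- which(!is.na(d) & !is.na(cv))
  albedo <- matrix(NA_real_, nrow(d), ncol(d))
  if (length(ok)) {
    newdata <- data.frame(deciduous_fraction = d[ok], tree_canopy_cover = cv[ok])
    albedo[ok] <- predict(model$fit, newdata, num.threads = 1L)$predictions
  }
  structure(list(season = season, epoch = epoch, albedo = albedo,
                 valid_mask = !is.na(albedo)),
            class = "seasonal_albedo")
}

#' Shortwave radiative forcing from albedo change
#'
#' Per-pixel forcing is the epoch albedo difference multiplied by the
#' radiative kernel: `forcing = (albedo_end - albedo_start) * kernel`
#' (W m^-2). With the negative kernel convention an albedo increase
#' yields negative forcing (cooling). Pixels where either albedo is
#' masked are masked.
#'
#' @param albedo_start,albedo_end `seasonal_albedo` objects of the same
#'   season.
#' @param kernel Kernel matrix (W m^-2 per unit albedo) on the same grid,
#'   or a list with a `kernel` element.
#' @return Object of class `forcing_map` with `season`, `period` and
#'   matrix `forcing`.
#' @export
radiative_forcing <- function(albedo_start, albedo_end, kernel) {
  if (!identical(albedo_start$season, albedo_end$season))
    stop(sprintf("season mismatch: '%s' vs '%s'",
                 albedo_start$season, albedo_end$season), call. = FALSE)
  k <- if (is.list(kernel)) kernel$kernel else kernel
  check_same_shape(albedo_start$albedo, albedo_end$albedo)
  check_same_shape(albedo_start$albedo, k)
  forcing <- (albedo_end$albedo - albedo_start$albedo) * k
  structure(list(season = albedo_start$season,
                 period = c(albedo_start$epoch %||% NA, albedo_end$epoch %||% NA),
                 forcing = forcing),
            class = "forcing_map")
}

#' Non-winter mean forcing
#'
#' Unweighted arithmetic mean of the spring, summer and fall forcing maps
#' on their common valid mask.
#'
#' @param forcings List of three `forcing_map` objects.
#' @return Matrix of mean forcing (`NA` off the common mask).
#' @export
nonwinter_mean_forcing <- function(forcings) {
  stopifnot(length(forcings) == 3)
  mats <- lapply(forcings, function(f) f$forcing)
  common <- !is.na(mats[[1]]) & !is.na(mats[[2]]) & !is.na(mats[[3]])
  out <- (mats[[1]] + mats[[2]] + mats[[3]]) / 3
  out[!common] <- NA_real_
  out
}
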