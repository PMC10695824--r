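## End-to-end orchestration: simulate -> composite -> train/predict cover
## -> albedo/forcing -> change report. Every stage seed derives from the
## run seed, so a rerun with the same configuration reproduces the report
## exactly.

#' Default pipeline configuration
#'
#' Defines the demo-scale study conditions: two epochs (2000 and 2015), a
#' 256 x 256 synthetic landscape, six acquisition dates per season with
#' 15% cloud cover and reflectance noise 0.01, 2,000 inventory plots,
#' five daily albedo layers per season at 16x coarsening, and the
#' chronosequence/reporting thresholds (0.25 tree-dominated cover, 0.95
#' correlation pruning, z = 1.96).
#'
#' @param grid_shape Landscape dimensions.
#' @param seed Run seed.
#' @return Named configuration list for [run_pipeline()].
#' @export
default_pipeline_config <- function(grid_shape = c(256L, 256L), seed = 1L) {
  list(
    seed = as.integer(seed),
    truth = list(grid_shape = as.integer(grid_shape)),
    epochs = c(2000L, 2015L),
    n_dates = 6L, cloud_fraction = 0.15, reflectance_noise = 0.01,
    n_plots = 2000L, ba_noise = 0.05,
    bin_width = 0.1, undersample_target = "median",
    train_fraction = 0.70, thin_distance = 1000,
    corr_threshold = 0.95, prune_sample_n = 800L,
    hyper_grid = expand.grid(n_trees = c(150L, 300L), max_features = "sqrt",
                             min_samples_split = 2L, min_samples_leaf = c(1L, 3L),
                             stringsAsFactors = FALSE),
    cv_folds = 5L, cv_repeats = 1L,
    canopy_n_per_stratum = 150L, canopy_reference_noise = 0.02,
    albedo_days = 5L, coarse_factor = 16L, albedo_noise = 0.01,
    albedo_invalid_fraction = 0.05, albedo_n_per_bin = 300L,
    tree_cover_threshold = 0.25, z = 1.96
  )
}

build_epoch_stack <- function(truth, epoch, cfg) {
  comps <- list()
  for (i in seq_along(SEASONS)) {
    s <- SEASONS[i]
    refl <- render_reflectance(
      truth, epoch, s, n_dates = cfg$n_dates,
      cloud_fraction = cfg$cloud_fraction, noise_sd = cfg$reflectance_noise,
      seed = derive_seed(cfg$seed, epoch %% 100 * 10 + i))
    comps[[s]] <- median_composite(refl)
  }
  terrain <- terrain_layers(truth$dem, truth$pixel_size)
  assemble_stack(comps$spring, comps$summer, comps$fall, terrain, epoch = epoch)
}

one_season_features <- function(features) {
  intersect(features, c(paste("summer", c(BANDS, INDICES), sep = "_"), TERRAIN))
}

train_cover_models <- function(records, features, cfg, response_col, response_tag,
                               seed_offset) {
  search <- function(feats, mode) {
    if (!is.null(cfg$hyper_grid) && nrow(cfg$hyper_grid) > 1) {
      grid_search(records[records$split == "train", ], feats, grid = cfg$hyper_grid,
                  folds = cfg$cv_folds, repeats = cfg$cv_repeats,
                  seed = derive_seed(cfg$seed, seed_offset), response_col = response_col,
                  mode = mode, response = response_tag)
    } else {
      hp <- if (!is.null(cfg$hyper_grid)) as.list(cfg$hyper_grid[1, ]) else list()
      model_spec(feats, hp, mode = mode, response = response_tag,
                 seed = derive_seed(cfg$seed, seed_offset))
    }
  }
  spec3 <- search(features, "three_season")
  spec1 <- search(one_season_features(features), "one_season")
  train <- records[records$split == "train", ]
  list(three = fit_cover_model(train, spec3, response_col = response_col),
       one = fit_cover_model(train, spec1, response_col = response_col),
       spec3 = spec3, spec1 = spec1)
}

drop_na_features <- function(records, features) {
  ok <- complete.cases(records[, features, drop = FALSE])
  if (!all(ok)) message(sprintf("dropping %d record(s) with masked features", sum(!ok)))
  records[ok, , drop = FALSE]
}

#' Run the full analysis pipeline on a synthetic landscape
#'
#' Executes every stage: landscape simulation, seasonal median composites
#' and the 36-layer stacks for both epochs, deciduous-fraction and canopy
#' cover model training (binned under-sampling, 70/30 split, optional
#' grid search) and map prediction with leaf-spread uncertainty, seasonal
#' albedo compositing/downscaling, the composition-to-albedo model,
#' kernel radiative forcing, and the stratified change report. When
#' `outdir` is given, rasters, the report (CSV + JSON), the fire
#' perimeters (GeoJSON), the configuration snapshot (YAML) and an md5
#' manifest are written there.
#'
#' @param config Configuration list; see [default_pipeline_config()].
#' @param outdir Optional artifact directory.
#' @return Object of class `borealbedo_run`: truth, stacks, models, cover
#'   maps, albedo composites/predictions, forcing maps, validation
#'   statistics and the `change_report`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  epochs <- cfg$epochs
  stopifnot(length(epochs) == 2, epochs[1] < epochs[2])

  ## --- simulate ---------------------------------------------------------
  truth <- generate_truth(cfg$truth, seed = cfg$seed)
  gs <- truth$grid_shape

  ## --- composite --------------------------------------------------------
  stacks <- lapply(setNames(epochs, epochs), function(e) build_epoch_stack(truth, e, cfg))
  stack1 <- stacks[[as.character(epochs[1])]]
  stack2 <- stacks[[as.character(epochs[2])]]

  ## --- deciduous-fraction models ---------------------------------------
  plots <- plot_response(sample_plots(truth, epochs[1], n_plots = cfg$n_plots,
                                      ba_noise = cfg$ba_noise,
                                      seed = derive_seed(cfg$seed, 11)))
  pix_sample <- sample_stack_pixels(stack1, cfg$prune_sample_n,
                                    seed = derive_seed(cfg$seed, 12))
  features <- prune_correlated(stack1, pix_sample, cfg$corr_threshold)
  plots <- cbind(plots, extract_features(stack1, plots$row, plots$col))
  plots <- drop_na_features(plots, features)
  counts <- table(response_bins(plots$dec_fraction, cfg$bin_width))
  target <- switch(as.character(cfg$undersample_target),
                   min = min(counts), median = ceiling(median(counts)),
                   as.integer(cfg$undersample_target))
  balanced <- binned_undersample(plots, bin_width = cfg$bin_width, target = target,
                                 seed = derive_seed(cfg$seed, 13))
  balanced <- split_train_validation(balanced, cfg$train_fraction,
                                     seed = derive_seed(cfg$seed, 14))
  dec_models <- train_cover_models(balanced, features, cfg, "dec_fraction",
                                   "deciduous_fraction", 15)
  dec_valid <- thin_for_validation(balanced[balanced$split == "validation", ],
                                   min_distance = cfg$thin_distance,
                                   pixel_size = truth$pixel_size,
                                   seed = derive_seed(cfg$seed, 16))
  comp1 <- evaluate_composition(truth, epochs[1])
  dec_validation <- validate_model(dec_models$three, dec_valid, "dec_fraction")
  truth_at <- comp1$dec[cbind(dec_valid$row, dec_valid$col)]
  dec_pred <- predict_cover(dec_models$three, dec_valid, uncertainty = FALSE)$estimate
  dec_validation_truth <- list(r2 = r2_score(truth_at, dec_pred),
                               rmse = rmse_score(truth_at, dec_pred),
                               n = length(truth_at))

  ## --- canopy cover models ---------------------------------------------
  reference <- withr::with_seed(derive_seed(cfg$seed, 21), {
    clamp01(comp1$cover + matrix(rnorm(prod(gs), 0, cfg$canopy_reference_noise),
                                 gs[1], gs[2]))
  })
  canopy_records <- train_canopy_reference(reference, cfg$canopy_n_per_stratum,
                                           seed = derive_seed(cfg$seed, 22))
  canopy_records <- cbind(canopy_records,
                          extract_features(stack1, canopy_records$row, canopy_records$col))
  canopy_records <- drop_na_features(canopy_records, features)
  canopy_records <- split_train_validation(canopy_records, cfg$train_fraction,
                                           seed = derive_seed(cfg$seed, 23))
  canopy_models <- train_cover_models(canopy_records, features, cfg, "cover",
                                      "tree_canopy_cover", 24)
  canopy_valid <- thin_for_validation(canopy_records[canopy_records$split == "validation", ],
                                      min_distance = cfg$thin_distance,
                                      pixel_size = truth$pixel_size,
                                      seed = derive_seed(cfg$seed, 25))
  canopy_validation <- validate_model(canopy_models$three, canopy_valid, "cover")
  truth_cov <- comp1$cover[cbind(canopy_valid$row, canopy_valid$col)]
  cov_pred <- predict_cover(canopy_models$three, canopy_valid, uncertainty = FALSE)$estimate
  canopy_validation_truth <- list(r2 = r2_score(truth_cov, cov_pred),
                                  rmse = rmse_score(truth_cov, cov_pred),
                                  n = length(truth_cov))

  ## --- predict cover maps ----------------------------------------------
  dec_maps <- lapply(stacks, function(st)
    predict_map(dec_models$three, dec_models$one, st))
  cover_maps <- lapply(stacks, function(st)
    predict_map(canopy_models$three, canopy_models$one, st))

  ## --- albedo and forcing -----------------------------------------------
  e1 <- as.character(epochs[1]); e2 <- as.character(epochs[2])
  albedo_models <- list(); albedo_pred <- list(); forcings <- list()
  albedo_obs <- list(); kernels <- list()
  for (i in seq_along(SEASONS)) {
    s <- SEASONS[i]
    window <- season_months()[[s]]
    days <- lapply(seq_len(cfg$albedo_days), function(k) {
      r <- render_albedo(truth, epochs[1], s, coarse_factor = cfg$coarse_factor,
                         noise_sd = cfg$albedo_noise,
                         invalid_fraction = cfg$albedo_invalid_fraction,
                         seed = derive_seed(cfg$seed, 30 + 7 * i + k))
      list(albedo = r$albedo, valid = r$valid,
           month = window[((k - 1) %% length(window)) + 1])
    })
    comp <- seasonal_albedo_composite(days, s)
    fine <- downscale(comp$albedo, cfg$coarse_factor, clip_range = c(0, 1))
    fine_valid <- downscale(matrix(as.numeric(comp$valid_mask), nrow(comp$albedo)),
                            cfg$coarse_factor) > 0.5
    fine[!fine_valid] <- NA_real_
    obs <- structure(list(season = s, epoch = epochs[1], albedo = fine,
                          valid_mask = !is.na(fine)), class = "seasonal_albedo")
    albedo_obs[[s]] <- obs
    records <- sample_albedo_training(obs, dec_maps[[e1]], cover_maps[[e1]],
                                      n_per_bin = cfg$albedo_n_per_bin,
                                      seed = derive_seed(cfg$seed, 60 + i))
    albedo_models[[s]] <- fit_albedo_model(records, seed = derive_seed(cfg$seed, 65 + i))
    albedo_pred[[s]] <- list(
      start = predict_albedo(albedo_models[[s]], dec_maps[[e1]], cover_maps[[e1]],
                             s, epoch = epochs[1]),
      end = predict_albedo(albedo_models[[s]], dec_maps[[e2]], cover_maps[[e2]],
                           s, epoch = epochs[2]))
    kern <- render_kernel(truth, s, coarse_factor = cfg$coarse_factor,
                          seed = derive_seed(cfg$seed, 70 + i))
    kernels[[s]] <- downscale(kern$kernel, cfg$coarse_factor)
    forcings[[s]] <- radiative_forcing(albedo_pred[[s]]$start, albedo_pred[[s]]$end,
                                       kernels[[s]])
  }

  ## --- change analysis ---------------------------------------------------
  fire_rast <- rasterize_fires(truth$fires, gs)
  burned <- burned_between(fire_rast$year, epochs[1], epochs[2])
  mask <- analysis_mask(cover_maps[[e1]], cover_maps[[e2]], burned,
                        threshold = cfg$tree_cover_threshold)
  deltas <- list(dec = dec_maps[[e2]]$estimate - dec_maps[[e1]]$estimate,
                 cover = cover_maps[[e2]]$estimate - cover_maps[[e1]]$estimate)
  sigs <- list(
    dec = significance(deltas$dec, dec_maps[[e1]]$uncertainty,
                       dec_maps[[e2]]$uncertainty, z = cfg$z),
    cover = significance(deltas$cover, cover_maps[[e1]]$uncertainty,
                         cover_maps[[e2]]$uncertainty, z = cfg$z))
  albedo_deltas <- lapply(setNames(SEASONS, SEASONS), function(s)
    albedo_pred[[s]]$end$albedo - albedo_pred[[s]]$start$albedo)
  report <- stratified_summary(deltas, sigs, albedo_deltas, forcings,
                               strata = fire_rast$class, mask = mask$mask,
                               pixel_size = truth$pixel_size)
  fires_strata <- matrix(ifelse(is.na(fire_rast$class), NA_character_, "fires_all"),
                         gs[1], gs[2])
  fires_row <- stratified_summary(deltas, sigs, albedo_deltas, forcings,
                                  strata = fires_strata, mask = mask$mask,
                                  pixel_size = truth$pixel_size)
  report <- rbind(report, fires_row[fires_row$stratum == "fires_all", ])
  rownames(report) <- NULL

  run <- structure(list(
    config = cfg, truth = truth, stacks = stacks,
    dec_models = dec_models, canopy_models = canopy_models,
    dec_maps = dec_maps, cover_maps = cover_maps,
    albedo_obs = albedo_obs, albedo_models = albedo_models,
    albedo_pred = albedo_pred, forcings = forcings, kernels = kernels,
    fire_rast = fire_rast, mask = mask, deltas = deltas, sigs = sigs,
    albedo_deltas = albedo_deltas,
    validation = list(
      dec = dec_validation, dec_vs_truth = dec_validation_truth,
      canopy = canopy_validation, canopy_vs_truth = canopy_validation_truth),
    report = report
  ), class = "borealbedo_run")

  if (!is.null(outdir)) write_run_artifacts(run, outdir)
  run
}

#' @export
print.borealbedo_run <- function(x, ...) {
  v <- x$validation
  cat(sprintf(paste0(
    "<borealbedo_run> %d x %d landscape, epochs %d-%d\n",
    "  deciduous fraction: validation r2 %.3f rmse %.3f (vs truth r2 %.3f rmse %.3f)\n",
    "  canopy cover:       validation r2 %.3f rmse %.3f (vs truth r2 %.3f rmse %.3f)\n",
    "  report: %d strata rows\n"),
    x$truth$grid_shape[1], x$truth$grid_shape[2],
    x$config$epochs[1], x$config$epochs[2],
    v$dec$r2, v$dec$rmse, v$dec_vs_truth$r2, v$dec_vs_truth$rmse,
    v$canopy$r2, v$canopy$rmse, v$canopy_vs_truth$r2, v$canopy_vs_truth$rmse,
    nrow(x$report)))
  invisible(x)
}

#' Write run artifacts to a directory
#'
#' Writes estimate/uncertainty rasters for both responses and epochs,
#' seasonal forcing rasters, the change report (CSV and JSON), fire
#' perimeters (GeoJSON), the configuration snapshot (YAML) and a manifest
#' with md5 hashes of every artifact.
#'
#' @param run A `borealbedo_run`.
#' @param outdir Directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_run_artifacts <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ps <- run$truth$pixel_size
  paths <- character(0)
  put <- function(x, name) {
    p <- file.path(outdir, name)
    write_raster(x, p, pixel_size = ps)
    paths <<- c(paths, p, hdr_path(p))
  }
  for (e in names(run$dec_maps)) {
    put(run$dec_maps[[e]]$estimate, sprintf("deciduous_fraction_%s.envi", e))
    put(run$dec_maps[[e]]$uncertainty, sprintf("deciduous_fraction_%s_sd.envi", e))
    put(run$cover_maps[[e]]$estimate, sprintf("tree_canopy_cover_%s.envi", e))
    put(run$cover_maps[[e]]$uncertainty, sprintf("tree_canopy_cover_%s_sd.envi", e))
  }
  for (s in names(run$forcings)) {
    put(run$forcings[[s]]$forcing, sprintf("forcing_%s.envi", s))
  }
  report_csv <- file.path(outdir, "change_report.csv")
  write.csv(run$report, report_csv, row.names = FALSE)
  report_json <- file.path(outdir, "change_report.json")
  jsonlite::write_json(run$report, report_json, dataframe = "rows", na = "null",
                       digits = NA)
  fires_path <- file.path(outdir, "fires.geojson")
  write_fires_geojson(run$truth$fires, fires_path)
  cfg_path <- file.path(outdir, "config.yaml")
  cfg <- run$config
  cfg$hyper_grid <- NULL  # data frame; re-supplied programmatically
  write_config(cfg, cfg_path)
  paths <- c(paths, report_csv, report_json, fires_path, cfg_path)
  manifest <- list(seed = run$config$seed,
                   package_version = as.character(utils::packageVersion("borealbedo")),
                   files = lapply(setNames(paths, basename(paths)),
                                  function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
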