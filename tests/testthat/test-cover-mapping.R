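# Grid search, ensemble fitting with leaf retention, uncertainty,
# map prediction, validation and stratified canopy sampling.

test_that("grid search picks the better arm and is deterministic", {
  recs <- linear_records(150, noise = 0.02, seed = 1)
  grid1 <- data.frame(n_trees = 50L, max_features = "sqrt",
                      min_samples_split = 2L, min_samples_leaf = 1L,
                      stringsAsFactors = FALSE)
  single <- grid_search(recs, c("x1", "x2"), grid1, repeats = 1, seed = 2,
                        response_col = "dec_fraction")
  expect_equal(single$hyperparams$n_trees, 50L)

  grid2 <- data.frame(n_trees = c(50L, 1L), max_features = "sqrt",
                      min_samples_split = 2L, min_samples_leaf = 1L,
                      stringsAsFactors = FALSE)
  best <- grid_search(recs, c("x1", "x2"), grid2, repeats = 1, seed = 3,
                      response_col = "dec_fraction")
  expect_equal(best$hyperparams$n_trees, 50L)
  expect_gt(best$cv_stats$mean_r2,
            best$grid_stats$mean_r2[best$grid_stats$n_trees == 1L])

  again <- grid_search(recs, c("x1", "x2"), grid2, repeats = 1, seed = 3,
                       response_col = "dec_fraction")
  expect_identical(best$cv_stats, again$cv_stats)
  expect_error(grid_search(recs[1:8, ], c("x1", "x2"), grid1, folds = 5, seed = 1,
                           response_col = "dec_fraction"), "fewer folds")
})

test_that("constant response collapses to a constant prediction with zero sd", {
  recs <- linear_records(80, seed = 4)
  recs$dec_fraction <- 0.4
  m <- fit_cover_model(recs, model_spec(c("x1", "x2"), list(n_trees = 30L), seed = 5))
  p <- predict_cover(m, recs[1:10, ])
  expect_equal(p$estimate, rep(0.4, 10), tolerance = 1e-12)
  expect_true(all(p$uncertainty == 0))
})

test_that("training r2 dominates CV r2 and predictions stay in [0, 1]", {
  recs <- linear_records(200, noise = 0.05, seed = 6)
  spec <- grid_search(recs, c("x1", "x2"),
                      data.frame(n_trees = 100L, max_features = "sqrt",
                                 min_samples_split = 2L, min_samples_leaf = 1L,
                                 stringsAsFactors = FALSE),
                      repeats = 1, seed = 7, response_col = "dec_fraction")
  m <- fit_cover_model(recs, spec)
  pred <- predict_cover(m, recs, uncertainty = FALSE)$estimate
  train_r2 <- 1 - sum((recs$dec_fraction - pred)^2) /
    sum((recs$dec_fraction - mean(recs$dec_fraction))^2)
  expect_gte(train_r2, spec$cv_stats$mean_r2)
  expect_true(all(pred >= 0 & pred <= 1))
  expect_error(fit_cover_model(recs, model_spec(c("x1", "zzz"))), "zzz")
})

test_that("leaf uncertainty equals the pooled-leaf sd computed by brute force", {
  ## hand case: a leaf pooling responses {0.2, 0.4} must report the n-1
  ## denominator sd, 0.1414
  expect_lt(abs(borealbedo:::pooled_sd(2, 0.2 + 0.4, 0.2^2 + 0.4^2) - 0.1414),
            1e-4)

  ## brute-force pooling oracle on a real fit
  train <- linear_records(120, noise = 0.05, seed = 8)
  m <- fit_cover_model(train, model_spec(c("x1", "x2"),
                                         list(n_trees = 25L, min_samples_leaf = 3L),
                                         seed = 9))
  new <- linear_records(15, seed = 10)
  got <- leaf_uncertainty(m, new)

  tn_train <- predict(m$fit, train[, c("x1", "x2")], type = "terminalNodes",
                      num.threads = 1)$predictions
  tn_new <- predict(m$fit, new[, c("x1", "x2")], type = "terminalNodes",
                    num.threads = 1)$predictions
  oracle <- vapply(seq_len(nrow(new)), function(i) {
    pooled <- c()
    for (t in seq_len(m$fit$num.trees)) {
      w <- m$fit$inbag.counts[[t]]
      rows <- which(tn_train[, t] == tn_new[i, t] & w > 0)
      pooled <- c(pooled, rep(train$dec_fraction[rows], times = w[rows]))
    }
    if (length(pooled) <= 1) 0 else sd(pooled)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(all(got >= 0))
})

test_that("prediction maps obey the three-season / one-season mask logic", {
  truth <- small_truth(seed = 17, n_fires = 2L)
  st <- clean_stack(truth)
  recs <- plot_response(sample_plots(truth, 2000, 400, ba_noise = 0, seed = 18))
  recs <- cbind(recs, extract_features(st, recs$row, recs$col))
  feats3 <- layer_registry()
  feats1 <- borealbedo:::one_season_features(feats3)
  m3 <- fit_cover_model(recs, model_spec(feats3, list(n_trees = 40L), seed = 19))
  m1 <- fit_cover_model(recs, model_spec(feats1, list(n_trees = 40L),
                                         mode = "one_season", seed = 19))

  ## all seasons valid everywhere: 100% three-season
  map_all <- suppressMessages(predict_map(m3, m1, st))
  expect_true(all(map_all$source_mode == 1L))
  expect_equal(map_all$three_season_share, 1)
  expect_true(all(map_all$estimate >= 0 & map_all$estimate <= 1))

  ## punch a spring hole over ~10% of pixels: those fall back to one-season
  hole <- matrix(FALSE, 48, 48); hole[1:10, 1:23] <- TRUE
  st2 <- st
  st2$complete_mask[hole] <- FALSE
  map_holed <- suppressMessages(predict_map(m3, m1, st2))
  expect_true(all(map_holed$source_mode[hole] == 2L))
  expect_true(all(map_holed$source_mode[!hole] == 1L))
  expect_equal(map_holed$three_season_share, 1 - sum(hole) / (48 * 48))
})

test_that("prediction is invariant to tiling the stack", {
  truth <- small_truth(seed = 20, n_fires = 0L)
  st <- clean_stack(truth)
  recs <- plot_response(sample_plots(truth, 2000, 300, ba_noise = 0, seed = 21))
  recs <- cbind(recs, extract_features(st, recs$row, recs$col))
  m3 <- fit_cover_model(recs, model_spec(layer_registry(), list(n_trees = 30L), seed = 22))
  m1 <- fit_cover_model(recs, model_spec(borealbedo:::one_season_features(layer_registry()),
                                         list(n_trees = 30L), mode = "one_season", seed = 22))
  whole <- suppressMessages(predict_map(m3, m1, st))
  tile <- function(rows) {
    sub <- st
    sub$layers <- lapply(st$layers, function(m) m[rows, , drop = FALSE])
    sub$complete_mask <- st$complete_mask[rows, , drop = FALSE]
    sub$summer_mask <- st$summer_mask[rows, , drop = FALSE]
    suppressMessages(predict_map(m3, m1, sub))$estimate
  }
  stitched <- rbind(tile(1:24), tile(25:48))
  expect_equal(stitched, whole$estimate, tolerance = 1e-12)
})

test_that("validation reports adjusted r2, rmse, and degenerate flags", {
  recs <- linear_records(120, noise = 0.03, seed = 23)
  recs$split <- "train"
  m <- fit_cover_model(recs, model_spec(c("x1", "x2"), list(n_trees = 60L), seed = 24))
  val <- linear_records(60, noise = 0.03, seed = 25)
  v <- validate_model(m, val)
  expect_true(v$adjusted)
  expect_true(v$r2 <= v$r2_plain)
  expect_gt(v$r2, 0.5)
  expect_lt(v$rmse, 0.15)

  ## perfect predictor limit: evaluating on the training responses with a
  ## deterministic constant-leaf model
  recs0 <- recs; recs0$dec_fraction <- 0.3
  m0 <- fit_cover_model(recs0, model_spec(c("x1", "x2"), list(n_trees = 10L), seed = 26))
  v0 <- validate_model(m0, recs0)
  expect_equal(v0$rmse, 0)

  ## mean-only predictor has r2 <= 0 out of sample
  vm <- validate_model(m0, val)
  expect_lte(vm$r2_plain, 0)

  ## n <= p + 1 falls back to plain r2 with flag
  v_small <- validate_model(m, val[1:3, ])
  expect_false(v_small$adjusted)
})

test_that("stratified canopy sampling matches the reference histogram", {
  withr::with_seed(27, {
    ref <- matrix(runif(2500), 50, 50)
  })
  recs <- train_canopy_reference(ref, n_per_stratum = 5, seed = 28)
  expect_equal(nrow(recs), 50)  # 10 occupied strata x 5
  expect_equal(recs$cover, ref[cbind(recs$row, recs$col)])

  ## stratum occupancy equals brute-force histogram
  big <- train_canopy_reference(ref, n_per_stratum = 10000, seed = 29)
  got <- table(cut(big$cover, seq(0, 1, 0.1), include.lowest = TRUE))
  want <- table(cut(as.vector(ref), seq(0, 1, 0.1), include.lowest = TRUE))
  expect_equal(as.vector(got), as.vector(want))

  ## constant reference occupies a single stratum (others logged skipped)
  const <- matrix(0.5, 20, 20)
  expect_message(one <- train_canopy_reference(const, n_per_stratum = 7, seed = 30),
                 "empty")
  expect_equal(nrow(one), 7)
  expect_true(all(one$cover == 0.5))
})

test_that("mean leaf uncertainty grows with reflectance noise", {
  truth <- small_truth(seed = 31, n_fires = 2L)
  noise_levels <- c(0.01, 0.02, 0.04)
  mean_sd <- vapply(noise_levels, function(ns) {
    comps <- lapply(setNames(c("spring", "summer", "fall"),
                             c("spring", "summer", "fall")), function(s)
      median_composite(render_reflectance(truth, 2000, s, n_dates = 3,
                                          cloud_fraction = 0, noise_sd = ns,
                                          seed = 32)))
    st <- assemble_stack(comps$spring, comps$summer, comps$fall,
                         terrain_layers(truth$dem, 30), epoch = 2000)
    recs <- plot_response(sample_plots(truth, 2000, 400, ba_noise = 0, seed = 33))
    recs <- cbind(recs, extract_features(st, recs$row, recs$col))
    recs <- recs[complete.cases(recs), ]
    m <- fit_cover_model(recs, model_spec(layer_registry(), list(n_trees = 50L), seed = 34))
    sample_px <- sample_stack_pixels(st, 300, seed = 35)
    mean(leaf_uncertainty(m, sample_px))
  }, numeric(1))
  expect_true(all(diff(mean_sd) > 0))
})
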