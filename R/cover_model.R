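## Ensemble regression for deciduous fraction and tree canopy cover.
##
## The backend is ranger; on top of it the fit retains, for every terminal
## leaf of every tree, the count / sum / sum-of-squares of the in-bag
## training responses routed there. Pixel uncertainty is the sample
## standard deviation (n - 1 denominator) of the pooled leaf responses,
## concatenated with multiplicity across all trees.

#' Default hyperparameter grid
#'
#' Desk-scale grid over ensemble size, features per split, minimum
#' records to split a node, and minimum records per leaf.
#'
#' @return Data frame of hyperparameter combinations.
#' @export
default_hyper_grid <- function() {
  expand.grid(
    n_trees = c(100L, 300L),
    max_features = c("sqrt", "third"),
    min_samples_split = c(2L, 5L),
    min_samples_leaf = c(1L, 3L),
    stringsAsFactors = FALSE
  )
}

resolve_mtry <- function(max_features, p) {
  switch(as.character(max_features),
         sqrt = max(1L, floor(sqrt(p))),
         third = max(1L, floor(p / 3)),
         {
           v <- suppressWarnings(as.integer(max_features))
           if (is.na(v) || v < 1) stop_cfg("max_features", "must be 'sqrt', 'third' or a positive integer")
           min(v, p)
         })
}

fit_ranger <- function(records, features, hyper, seed, response_col) {
  dat <- records[, c(response_col, features), drop = FALSE]
  names(dat)[1] <- "response"
  ranger::ranger(
    dependent.variable.name = "response", data = dat,
    num.trees = hyper$n_trees,
    mtry = resolve_mtry(hyper$max_features, length(features)),
    min.node.size = hyper$min_samples_split,
    min.bucket = hyper$min_samples_leaf,
    keep.inbag = TRUE, respect.unordered.factors = "order",
    seed = seed, num.threads = 1L
  )
}

r2_score <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

rmse_score <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' Cross-validated hyperparameter grid search
#'
#' Evaluates every hyperparameter combination with repeated k-fold
#' cross-validation (fold partitions are drawn once per repeat and shared
#' across combinations) and selects the combination with the highest mean
#' CV r-squared; ties broken by lower mean RMSE, then lower RMSE standard
#' deviation, then grid order.
#'
#' @param records Training records (response + feature columns).
#' @param features Character vector of feature column names.
#' @param grid Data frame of combinations ([default_hyper_grid()]).
#' @param folds Number of CV folds (default 5).
#' @param repeats Number of re-seeded CV repetitions (default 3).
#' @param seed Integer seed.
#' @param response_col Response column name.
#' @param mode Model mode tag (`"three_season"` or `"one_season"`).
#' @param response Response tag (`"deciduous_fraction"` or
#'   `"tree_canopy_cover"`).
#' @return Object of class `model_spec` with the winning `hyperparams` and
#'   `cv_stats` (`mean_r2`, `rmse`, `rmse_sd`).
#' @export
grid_search <- function(records, features, grid = default_hyper_grid(),
                        folds = 5L, repeats = 3L, seed = 1L,
                        response_col = "dec_fraction",
                        mode = "three_season", response = "deciduous_fraction") {
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  n <- nrow(records)
  if (floor(n / folds) < 2)
    stop(sprintf("a %d-fold split of %d records leaves folds with < 2 records; use fewer folds", folds, n),
         call. = FALSE)
  fold_ids <- withr::with_seed(seed, {
    lapply(seq_len(repeats), function(r) sample(rep_len(seq_len(folds), n)))
  })
  eval_combo <- function(hyper) {
    r2s <- c(); rmses <- c()
    for (r in seq_len(repeats)) {
      ids <- fold_ids[[r]]
      for (k in seq_len(folds)) {
        train <- records[ids != k, , drop = FALSE]
        test <- records[ids == k, , drop = FALSE]
        fit <- fit_ranger(train, features, hyper, seed = derive_seed(seed, r * 10 + k),
                          response_col = response_col)
        pred <- predict(fit, test[, features, drop = FALSE], num.threads = 1L)$predictions
        r2s <- c(r2s, r2_score(test[[response_col]], pred))
        rmses <- c(rmses, rmse_score(test[[response_col]], pred))
      }
    }
    c(mean_r2 = mean(r2s, na.rm = TRUE), rmse = mean(rmses), rmse_sd = sd(rmses))
  }
  stats <- t(vapply(seq_len(nrow(grid)), function(i) eval_combo(grid[i, , drop = FALSE]),
                    numeric(3)))
  best <- order(-stats[, "mean_r2"], stats[, "rmse"], stats[, "rmse_sd"],
                seq_len(nrow(grid)))[1]
  structure(list(
    response = response, mode = mode, features = features,
    hyperparams = as.list(grid[best, , drop = FALSE]),
    cv_stats = as.list(stats[best, ]),
    grid_stats = cbind(grid, stats),
    seed = as.integer(seed)
  ), class = "model_spec")
}

#' Construct a model spec without searching
#'
#' @param features Feature names.
#' @param hyperparams Named list (n_trees, max_features, min_samples_split,
#'   min_samples_leaf); missing entries get defaults 300/"sqrt"/2/1.
#' @param mode,response,seed Tags as in [grid_search()].
#' @return A `model_spec`.
#' @export
model_spec <- function(features, hyperparams = list(), mode = "three_season",
                       response = "deciduous_fraction", seed = 1L) {
  hp <- utils::modifyList(
    list(n_trees = 300L, max_features = "sqrt", min_samples_split = 2L,
         min_samples_leaf = 1L), hyperparams)
  structure(list(response = response, mode = mode, features = features,
                 hyperparams = hp, cv_stats = NULL, seed = as.integer(seed)),
            class = "model_spec")
}

## Per-tree leaf statistics of the in-bag training responses.
build_leaf_stats <- function(fit, records, features, response_col) {
  dat <- records[, features, drop = FALSE]
  tn <- predict(fit, dat, type = "terminalNodes", num.threads = 1L)$predictions
  y <- records[[response_col]]
  lapply(seq_len(fit$num.trees), function(t) {
    w <- fit$inbag.counts[[t]]
    use <- w > 0
    ids <- tn[use, t]
    ww <- w[use]; yy <- y[use]
    n <- rowsum(ww, ids)
    s <- rowsum(ww * yy, ids)
    q <- rowsum(ww * yy^2, ids)
    list(ids = as.integer(rownames(n)), n = as.vector(n),
         s = as.vector(s), q = as.vector(q))
  })
}

#' Fit a cover model with leaf-sample retention
#'
#' Fits the bagged tree ensemble described by a `model_spec` and stores
#' per-leaf response statistics so that per-pixel uncertainty (pooled leaf
#' standard deviation) can be computed at prediction time.
#'
#' @param records Training records (must contain the response and all
#'   spec features).
#' @param spec A `model_spec`.
#' @param response_col Response column name.
#' @return Object of class `cover_model`.
#' @export
fit_cover_model <- function(records, spec, response_col = "dec_fraction") {
  missing <- setdiff(spec$features, names(records))
  if (length(missing))
    stop(sprintf("features missing from records: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  fit <- fit_ranger(records, spec$features, spec$hyperparams, seed = spec$seed,
                    response_col = response_col)
  leaf_stats <- build_leaf_stats(fit, records, spec$features, response_col)
  structure(list(fit = fit, spec = spec, features = spec$features,
                 leaf_stats = leaf_stats, n_train = nrow(records)),
            class = "cover_model")
}

#' Predict estimates (and optionally uncertainty) for feature rows
#'
#' @param model A `cover_model`.
#' @param newdata Data frame of feature rows.
#' @param uncertainty Also compute pooled leaf standard deviations?
#' @return List with `estimate` and (optionally) `uncertainty` vectors.
#' @export
predict_cover <- function(model, newdata, uncertainty = TRUE) {
  est <- predict(model$fit, newdata[, model$features, drop = FALSE],
                 num.threads = 1L)$predictions
  out <- list(estimate = est)
  if (uncertainty) out$uncertainty <- leaf_uncertainty(model, newdata)
  out
}

#' Pooled-leaf uncertainty of predictions
#'
#' For each row, pools the in-bag training responses of the one leaf
#' reached in every tree (concatenated across trees, with multiplicity)
#' and returns the sample standard deviation (n - 1 denominator) of the
#' pooled responses; 0 when the pooled responses are all identical or the
#' pooled count is 1.
#'
#' @param model A `cover_model`.
#' @param newdata Data frame of feature rows.
#' @return Numeric vector of standard deviations (>= 0).
#' @export
leaf_uncertainty <- function(model, newdata) {
  tn <- predict(model$fit, newdata[, model$features, drop = FALSE],
                type = "terminalNodes", num.threads = 1L)$predictions
  m <- nrow(tn)
  N <- numeric(m); S <- numeric(m); Q <- numeric(m)
  for (t in seq_len(ncol(tn))) {
    st <- model$leaf_stats[[t]]
    j <- match(tn[, t], st$ids)
    N <- N + st$n[j]
    S <- S + st$s[j]
    Q <- Q + st$q[j]
  }
  pooled_sd(N, S, Q)
}

#' Predict a cover map from a feature stack
#'
#' Pixels with all three seasons valid are scored by the three-season
#' model; pixels valid in summer only fall back to the one-season model;
#' the remainder are nodata. The per-pixel model used is recorded in
#' `source_mode`, and the share of scored pixels handled by the
#' three-season model is reported.
#'
#' @param model_three Three-season `cover_model`.
#' @param model_one One-season `cover_model` (summer + terrain features).
#' @param stack A `feature_stack`.
#' @param uncertainty Compute the uncertainty layer?
#' @return Object of class `cover_map` with matrices `estimate`,
#'   `uncertainty`, integer `source_mode` (0 nodata, 1 three-season,
#'   2 one-season) and `three_season_share` (fraction of scored pixels).
#' @export
predict_map <- function(model_three, model_one, stack, uncertainty = TRUE) {
  gs <- dim(stack$complete_mask)
  idx3 <- which(stack$complete_mask)
  idx1 <- which(stack$summer_mask & !stack$complete_mask)
  if (length(idx3) + length(idx1) == 0)
    warning("no pixel is valid in any season: empty map")
  est <- matrix(NA_real_, gs[1], gs[2])
  unc <- matrix(NA_real_, gs[1], gs[2])
  src <- matrix(0L, gs[1], gs[2])
  score <- function(model, idx) {
    feats <- as.data.frame(lapply(stack$layers[model$features], function(m) m[idx]))
    predict_cover(model, feats, uncertainty = uncertainty)
  }
  if (length(idx3)) {
    p <- score(model_three, idx3)
    est[idx3] <- p$estimate
    if (uncertainty) unc[idx3] <- p$uncertainty
    src[idx3] <- 1L
  }
  if (length(idx1)) {
    p <- score(model_one, idx1)
    est[idx1] <- p$estimate
    if (uncertainty) unc[idx1] <- p$uncertainty
    src[idx1] <- 2L
  }
  share <- if (length(idx3) + length(idx1) > 0) {
    length(idx3) / (length(idx3) + length(idx1))
  } else NA_real_
  message(sprintf("three-season model used for %.1f%% of scored pixels", 100 * share))
  structure(list(
    response = model_three$spec$response, epoch = stack$epoch,
    estimate = est, uncertainty = unc, source_mode = src,
    three_season_share = share
  ), class = "cover_map")
}

#' @export
print.cover_map <- function(x, ...) {
  cat(sprintf("<cover_map> %s, epoch %s, %.1f%% scored (%.1f%% three-season)\n",
              x$response, x$epoch, 100 * mean(x$source_mode > 0),
              100 * (x$three_season_share %||% NA)))
  invisible(x)
}

#' Validate a model on held-out records
#'
#' Reports adjusted r-squared (adjusting for the number of retained
#' features) and RMSE on a validation set. When `n <= p + 1` the adjusted
#' value is undefined and the plain r-squared is returned with
#' `adjusted = FALSE`.
#'
#' @param model A `cover_model`.
#' @param records Validation records (disjoint from training; thin with
#'   [thin_for_validation()] first).
#' @param response_col Response column name.
#' @return List `r2` (adjusted where defined), `r2_plain`, `rmse`, `n`,
#'   `adjusted` flag.
#' @export
validate_model <- function(model, records, response_col = "dec_fraction") {
  pred <- predict_cover(model, records, uncertainty = FALSE)$estimate
  obs <- records[[response_col]]
  n <- length(obs)
  p <- length(model$features)
  r2 <- r2_score(obs, pred)
  if (n > p + 1) {
    list(r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1), r2_plain = r2,
         rmse = rmse_score(obs, pred), n = n, adjusted = TRUE)
  } else {
    list(r2 = r2, r2_plain = r2, rmse = rmse_score(obs, pred), n = n,
         adjusted = FALSE)
  }
}

#' Stratified sampling against a reference cover raster
#'
#' Draws a seeded stratified random sample of pixels, one stratum per
#' cover bin (10 equal-width bins by default), for training the canopy
#' cover model against a reference cover layer. Empty strata are skipped
#' with a message.
#'
#' @param reference Reference cover matrix in \[0, 1\].
#' @param n_per_stratum Samples per occupied stratum.
#' @param breaks Bin edges over \[0, 1\].
#' @param seed Integer seed.
#' @return Data frame with `row`, `col`, `cover`.
#' @export
train_canopy_reference <- function(reference, n_per_stratum = 200L,
                                   breaks = seq(0, 1, 0.1), seed = 1L) {
  v <- as.vector(reference)
  stratum <- cut(v, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(length(breaks) - 1L), function(b) {
      idx <- which(stratum == b & !is.na(v))
      if (length(idx) == 0) {
        message(sprintf("stratum %d (%.1f-%.1f) empty; skipped",
                        b, breaks[b], breaks[b + 1]))
        return(NULL)
      }
      take <- if (length(idx) > n_per_stratum) sample(idx, n_per_stratum) else idx
      rc <- arrayInd(take, dim(reference))
      data.frame(row = rc[, 1], col = rc[, 2], cover = v[take])
    })
  })
  do.call(rbind, rows)
}
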