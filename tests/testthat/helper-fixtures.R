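# Shared fixtures, built in code. Small grids keep unit tests fast; the
# acceptance tests use the default 256 x 256 study conditions via a
# memoised run shared across blocks.

small_truth <- function(seed = 7L, grid = c(48L, 48L), n_fires = 4L, ...) {
  generate_truth(utils::modifyList(list(grid_shape = grid, n_fires = n_fires),
                                   list(...)), seed = seed)
}

## A stack built from noiseless, cloud-free renders (exact mixtures).
clean_stack <- function(truth, year = 2000) {
  comps <- lapply(setNames(c("spring", "summer", "fall"),
                           c("spring", "summer", "fall")), function(s) {
    median_composite(render_reflectance(truth, year, s, n_dates = 3,
                                        cloud_fraction = 0, noise_sd = 0,
                                        seed = 1))
  })
  assemble_stack(comps$spring, comps$summer, comps$fall,
                 terrain_layers(truth$dem, truth$pixel_size), epoch = year)
}

## Training table with known linear response y = a*x1 + b*x2 (+ noise).
linear_records <- function(n = 200, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    x1 <- runif(n); x2 <- runif(n)
    data.frame(x1 = x1, x2 = x2,
               dec_fraction = clamp01_(0.6 * x1 + 0.3 * x2 + rnorm(n, 0, noise)))
  })
}

clamp01_ <- function(x) pmin(pmax(x, 0), 1)

## Memoised full-scale pipeline run shared by the acceptance tests.
acceptance_env <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (is.null(acceptance_env$run)) {
    cfg <- default_pipeline_config(grid_shape = c(256L, 256L), seed = 1L)
    acceptance_env$run <- suppressMessages(run_pipeline(cfg))
  }
  acceptance_env$run
}
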