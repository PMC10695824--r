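# Generator: determinism, succession dynamics, mixture rendering, plots,
# albedo and kernels.

test_that("truth generation is deterministic and respects parameter checks", {
  a <- small_truth(seed = 1)
  b <- small_truth(seed = 1)
  expect_identical(a$dec_base, b$dec_base)
  expect_identical(a$cover_base, b$cover_base)
  expect_identical(a$dem, b$dem)
  expect_identical(a$fires, b$fires)
  expect_true(all(a$dec_base >= 0 & a$dec_base <= 1))
  expect_true(all(a$cover_base >= 0 & a$cover_base <= 1))
  expect_error(generate_truth(list(succession_params = list(
    tau_c = 25, tau_d = 15, d_peak = 0.4, d_late = 0.6)), seed = 1),
    "succession_params")
  expect_error(generate_truth(list(grid_shape = c(0L, 5L)), seed = 1),
               "grid_shape")
})

test_that("zero fires means composition equals the base fields in every year", {
  truth <- small_truth(seed = 3, n_fires = 0L)
  for (year in c(1960, 2000, 2015)) {
    comp <- evaluate_composition(truth, year)
    expect_identical(comp$dec, truth$dec_base)
    expect_identical(comp$cover, truth$cover_base)
  }
})

test_that("burned-pixel fraction matches an independent winding-number scan", {
  truth <- generate_truth(list(grid_shape = c(64L, 64L), n_fires = 5L), seed = 7)
  fy <- last_fire_year(truth, 2018)
  pkg_fraction <- mean(!is.na(fy))

  ## independent oracle: winding-number point-in-polygon, scalar loop
  winding_inside <- function(px, py, ring) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- nrow(ring)
    if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
    wn <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (y[i] <= py) {
        if (y[j] > py &&
            (x[j] - x[i]) * (py - y[i]) - (px - x[i]) * (y[j] - y[i]) > 0) wn <- wn + 1
      } else {
        if (y[j] <= py &&
            (x[j] - x[i]) * (py - y[i]) - (px - x[i]) * (y[j] - y[i]) < 0) wn <- wn - 1
      }
    }
    wn != 0
  }
  count <- 0L
  for (r in seq_len(64)) {
    for (c in seq_len(64)) {
      inside <- FALSE
      for (f in truth$fires) {
        if (winding_inside(c - 0.5, r - 0.5, f$polygon[[1]])) { inside <- TRUE; break }
      }
      if (inside) count <- count + 1L
    }
  }
  ## fire polygons here are simple (no holes, no self-intersection), so the
  ## even-odd and winding rules must agree exactly
  expect_equal(pkg_fraction, count / 64^2)
})

test_that("succession curve hits its stated landmarks", {
  sp <- list(tau_c = 25, tau_d = 15, d_peak = 0.75, d_late = 0.10)
  truth <- small_truth(seed = 2, n_fires = 0L)
  truth$fires <- list(list(polygon = list(cbind(c(-1, 49, 49, -1), c(-1, -1, 49, 49))),
                           year = 1970L))
  truth$fire_masks <- list(matrix(TRUE, 48, 48))

  comp_peak <- evaluate_composition(truth, 1970 + sp$tau_d)
  expect_equal(unique(as.vector(comp_peak$dec)), sp$d_peak)

  comp_late <- evaluate_composition(truth, 1970)  # t = 0: fire this year
  expect_true(all(comp_late$cover == 0))

  ## large-t limit checked on the curve itself (years capped at 2018 on grid)
  expect_equal(borealbedo:::succession_dec(50 * sp$tau_d, sp), sp$d_late,
               tolerance = 1e-6)
})

test_that("reflectance is the exact endmember mixture in the noiseless limit", {
  truth <- small_truth(seed = 5, n_fires = 0L)
  e <- truth$endmembers
  cases <- list(c(d = 1, c = 1), c(d = 0.5, c = 0), c(d = 0.5, c = 0.5))
  for (case in cases) {
    truth$dec_base <- matrix(case[["d"]], 48, 48)
    truth$cover_base <- matrix(case[["c"]], 48, 48)
    refl <- render_reflectance(truth, 2000, "summer", n_dates = 2,
                               cloud_fraction = 0, noise_sd = 0, seed = 1)
    for (b in c("blue", "green", "red", "nir", "swir1", "swir2")) {
      expected <- case[["c"]] * (case[["d"]] * e["deciduous", "summer", b] +
                                   (1 - case[["d"]]) * e["evergreen", "summer", b]) +
        (1 - case[["c"]]) * e["background", "summer", b]
      for (dt in refl$dates) {
        expect_equal(unique(as.vector(dt$bands[[b]])), expected, tolerance = 1e-12)
      }
    }
  }
  expect_error(render_reflectance(truth, 2000, "winter", seed = 1), "season")
})

test_that("mixture is linear in d and c against a symbolic oracle", {
  truth <- small_truth(seed = 6, n_fires = 0L)
  e <- truth$endmembers
  withr::with_seed(11, {
    for (k in 1:10) {
      d <- runif(1); cv <- runif(1)
      truth$dec_base <- matrix(d, 48, 48)
      truth$cover_base <- matrix(cv, 48, 48)
      refl <- render_reflectance(truth, 2000, "spring", n_dates = 1,
                                 cloud_fraction = 0, noise_sd = 0, seed = 1)
      ## closed form: alpha_b = c*d*(E_dec - E_eve) + c*E_eve + (1 - c)*E_bg
      for (b in c("nir", "red")) {
        expected <- cv * d * (e["deciduous", "spring", b] - e["evergreen", "spring", b]) +
          cv * e["evergreen", "spring", b] + (1 - cv) * e["background", "spring", b]
        expect_equal(refl$dates[[1]]$bands[[b]][10, 10], expected, tolerance = 1e-12)
      }
    }
  })
})

test_that("plot tables are reproducible and noiseless shares equal pixel dec", {
  truth <- small_truth(seed = 8)
  p1 <- sample_plots(truth, 2000, 100, ba_noise = 0, seed = 4)
  p2 <- sample_plots(truth, 2000, 100, ba_noise = 0, seed = 4)
  expect_identical(p1, p2)
  comp <- evaluate_composition(truth, 2000)
  share <- p1$deciduous_ba / (p1$deciduous_ba + p1$evergreen_ba)
  expect_equal(share, comp$dec[cbind(p1$row, p1$col)], tolerance = 1e-12)
})

test_that("mean noiseless plot share matches mean pixel dec over many plots", {
  truth <- small_truth(seed = 9)
  p <- sample_plots(truth, 2000, 10000, ba_noise = 0, seed = 5)
  comp <- evaluate_composition(truth, 2000)
  share <- p$deciduous_ba / (p$deciduous_ba + p$evergreen_ba)
  expect_equal(mean(share), mean(comp$dec[cbind(p$row, p$col)]), tolerance = 1e-12)
})

test_that("albedo forward model matches its closed form and block means", {
  truth <- small_truth(seed = 10, n_fires = 0L)
  truth$dec_base <- matrix(0.4, 48, 48)
  truth$cover_base <- matrix(0.6, 48, 48)
  b <- truth$albedo_coeffs$spring
  expected <- b$b0 + b$b_d * 0.4 + b$b_c * 0.6 + b$b_dc * 0.4 * 0.6
  r <- render_albedo(truth, 2000, "spring", coarse_factor = 8, noise_sd = 0,
                     invalid_fraction = 0, seed = 1)
  expect_equal(unique(as.vector(r$albedo)), expected, tolerance = 1e-12)
  expect_error(render_albedo(truth, 2000, "spring", coarse_factor = 7, seed = 1),
               "divide")

  ## hand-computed 2x2 block mean
  expect_equal(borealbedo:::block_mean(matrix(c(0.3, 0.5, 0.4, 0.6), 2, 2), 2)[1, 1],
               0.45)
})

test_that("spring albedo strictly decreases with canopy cover at fixed dec", {
  truth <- small_truth(seed = 11, n_fires = 0L)
  b <- truth$albedo_coeffs$spring
  covers <- seq(0.1, 0.9, 0.2)
  alphas <- vapply(covers, function(cv) {
    truth$dec_base <- matrix(0.5, 48, 48)
    truth$cover_base <- matrix(cv, 48, 48)
    r <- render_albedo(truth, 2000, "spring", coarse_factor = 8, noise_sd = 0,
                       invalid_fraction = 0, seed = 1)
    r$albedo[1, 1]
  }, numeric(1))
  expect_true(all(diff(alphas) < 0))
  ## coefficient sign structure: b_d > 0 all seasons, spring b_c most negative
  cf <- default_albedo_coeffs()
  expect_true(all(vapply(cf, function(x) x$b_d > 0, logical(1))))
  expect_true(cf$spring$b_c < 0 && abs(cf$summer$b_c) < abs(cf$spring$b_c))
})

test_that("kernels are negative and hit their configured means", {
  truth <- small_truth(seed = 12)
  for (s in c("spring", "summer", "fall")) {
    k <- render_kernel(truth, s, coarse_factor = 8, seed = 2)
    expect_true(all(k$kernel < 0))
  }
  kc <- render_kernel(truth, "spring", coarse_factor = 8, relative_sd = 0, seed = 2)
  expect_true(all(kc$kernel == -120))
  ks <- render_kernel(truth, "summer", coarse_factor = 8, relative_sd = 0.1, seed = 3)
  expect_lt(abs(mean(ks$kernel) - (-150)) / 150, 0.05)
})

test_that("chronosequence: recent burns gain deciduous fraction, old burns lose it", {
  truth <- generate_truth(list(grid_shape = c(128L, 128L), n_fires = 30L), seed = 21)
  fy <- last_fire_year(truth, 2018)
  d2000 <- evaluate_composition(truth, 2000)$dec
  d2015 <- evaluate_composition(truth, 2015)$dec
  delta <- d2015 - d2000
  recent <- !is.na(fy) & fy >= 1999 & fy <= 2014
  old <- !is.na(fy) & fy <= 1978
  expect_gt(sum(recent), 0)
  expect_gt(sum(old), 0)
  expect_gt(mean(delta[recent]), 0)
  expect_lte(mean(delta[old]), 0)
})
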