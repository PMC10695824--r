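## Bicubic convolution resampling (Keys kernel, a = -0.5), used to bring
## coarse (~500 m) albedo and kernel rasters onto the fine (30 m) analysis
## grid. Separable implementation: per-axis 4-tap weight matrices applied
## as matrix products; edges use replication padding.

keys_kernel <- function(x, a = -0.5) {
  ax <- abs(x)
  ifelse(ax <= 1,
         (a + 2) * ax^3 - (a + 3) * ax^2 + 1,
         ifelse(ax < 2, a * ax^3 - 5 * a * ax^2 + 8 * a * ax - 4 * a, 0))
}

## Weight matrix mapping n_coarse cells to n_fine = n_coarse * factor cells,
## with fine-pixel centres sampled in coarse-cell-centre coordinates.
bicubic_axis_weights <- function(n_coarse, factor) {
  n_fine <- n_coarse * factor
  w <- matrix(0, n_fine, n_coarse)
  for (i in seq_len(n_fine)) {
    t <- (i - 0.5) / factor + 0.5  # position in coarse index space
    base <- floor(t)
    f <- t - base
    taps <- base + (-1L:2L)
    wts <- keys_kernel(f - (-1:2))
    taps <- clamp(taps, 1L, n_coarse)  # edge replication
    for (k in 1:4) w[i, taps[k]] <- w[i, taps[k]] + wts[k]
  }
  w
}

#' Bicubic downscaling of a coarse raster
#'
#' Interpolates a coarse raster onto a grid `factor` times finer in each
#' dimension using bicubic convolution (Keys kernel, a = -0.5). The
#' interpolant reproduces constants exactly and linear ramps away from the
#' replicated edges. Physical quantities such as albedo can be clipped to
#' their valid range; kernels are left unclipped.
#'
#' @param coarse Numeric matrix.
#' @param factor Integer upscale factor (>= 1; use [block_mean()] to
#'   aggregate instead).
#' @param clip_range Optional length-2 numeric range to clip the output to.
#' @return Matrix of dimensions `dim(coarse) * factor`.
#' @export
downscale <- function(coarse, factor, clip_range = NULL) {
  if (factor < 1) stop("scale factor < 1: use aggregation (block_mean), not interpolation", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) out <- coarse
  else {
    wr <- bicubic_axis_weights(nrow(coarse), factor)
    wc <- bicubic_axis_weights(ncol(coarse), factor)
    out <- wr %*% coarse %*% t(wc)
  }
  if (!is.null(clip_range)) out <- clamp(out, clip_range[1], clip_range[2])
  out
}
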