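#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd cor predict rnorm runif quantile setNames complete.cases
#' @importFrom utils head write.csv read.csv
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp01 <- function(x) clamp(x, 0, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: '%s' %s", field, msg), call. = FALSE)
}

check_same_shape <- function(a, b, what = "rasters") {
  da <- dim(a); db <- dim(b)
  if (!identical(da, db)) {
    stop(sprintf("%s have mismatched shapes: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

## Derive a stage-specific seed from a run seed, staying inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

## Separable Gaussian blur with replicated edges; kernel truncated at 3 sigma.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(x); nc <- ncol(x)
  ## rows pass
  out <- matrix(0, nr, nc)
  for (j in seq(-r, r)) {
    idx <- clamp(seq_len(nr) + j, 1L, nr)
    out <- out + k[j + r + 1L] * x[idx, , drop = FALSE]
  }
  ## cols pass
  res <- matrix(0, nr, nc)
  for (j in seq(-r, r)) {
    idx <- clamp(seq_len(nc) + j, 1L, nc)
    res <- res + k[j + r + 1L] * out[, idx, drop = FALSE]
  }
  res
}

## Smooth standardized random field (mean 0, sd 1) used for base fields,
## terrain, clouds and kernels. Caller controls RNG state.
smooth_field <- function(nrow, ncol, range_px = 12) {
  z <- matrix(rnorm(nrow * ncol), nrow, ncol)
  z <- gaussian_blur(z, range_px / 3)
  z <- z - mean(z)
  s <- sd(as.vector(z))
  if (s > 0) z <- z / s
  z
}

## Block mean aggregation by integer factor (coarse_factor must divide dims).
block_mean <- function(x, factor) {
  nr <- nrow(x); nc <- ncol(x)
  if (nr %% factor != 0 || nc %% factor != 0) {
    stop(sprintf("coarse_factor %d does not divide grid %dx%d", factor, nr, nc),
         call. = FALSE)
  }
  cr <- nr / factor; cc <- nc / factor
  ri <- rep(seq_len(cr), each = factor)
  ci <- rep(seq_len(cc), each = factor)
  rowsum_r <- rowsum(x, group = ri, reorder = TRUE)
  t(rowsum(t(rowsum_r), group = ci, reorder = TRUE)) / factor^2
}

## Sample standard deviation from pooled (n, sum, sum of squares). Guard
## against catastrophic cancellation when all pooled responses are equal:
## a variance below the round-off floor of q is exactly zero.
pooled_sd <- function(n, s, q) {
  v <- (q - s^2 / n) / (n - 1)
  v[v < 1e-12 * pmax(q, 1)] <- 0
  out <- sqrt(pmax(v, 0))
  out[n <= 1] <- 0
  out
}
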