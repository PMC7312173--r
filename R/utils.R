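# small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian blur with reflecting boundaries
#'
#' Separable Gaussian convolution, the standard pre-smoothing applied to the
#' DAPI channel before thresholding (default sigma = 1 px).
#'
#' @param img numeric matrix.
#' @param sigma standard deviation of the Gaussian kernel in pixels; 0 returns
#'   the input unchanged.
#' @return numeric matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma = 1) {
  stopifnot(is.matrix(img), sigma >= 0)
  if (sigma == 0) return(img)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  cpp_conv_sep(img, k)
}

# disk structuring-element offsets (dr, dc) of radius r (r >= 1)
disk_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# fill holes: background components of !bin not touching the border become fg
fill_holes <- function(bin) {
  lab <- cpp_label4(!bin)
  if (max(lab) == 0L) return(bin)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  holes <- lab > 0L & !(lab %in% border)
  bin | holes
}

# density mode (location of the highest kernel-density peak)
density_mode <- function(x, ...) {
  d <- density(x, ...)
  d$x[which.max(d$y)]
}

# local maxima of a density object, ordered by height (descending)
density_peaks <- function(x, ...) {
  d <- density(x, ...)
  y <- d$y
  i <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf))
  i <- i[order(y[i], decreasing = TRUE)]
  list(x = d$x[i], y = y[i])
}

# deterministic child seed derived from a master seed (keeps below 2^31)
child_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}

# bilinear interpolation of a coarse grid (values at centers xs, ys) onto
# query points; constant extrapolation beyond the outer centers
interp_grid <- function(ys, xs, z, yq, xq) {
  if (length(ys) == 1L && length(xs) == 1L) return(rep(z[1, 1], length(yq)))
  iy <- findInterval(yq, ys, all.inside = TRUE)
  ix <- findInterval(xq, xs, all.inside = TRUE)
  y0 <- ys[iy]; y1 <- ys[pmin(iy + 1L, length(ys))]
  x0 <- xs[ix]; x1 <- xs[pmin(ix + 1L, length(xs))]
  dy <- y1 - y0; dy[dy <= 0] <- 1
  dx <- x1 - x0; dx[dx <= 0] <- 1
  ty <- pmin(1, pmax(0, (yq - y0) / dy))
  tx <- pmin(1, pmax(0, (xq - x0) / dx))
  i1 <- pmin(iy + 1L, length(ys)); j1 <- pmin(ix + 1L, length(xs))
  z00 <- z[cbind(iy, ix)]; z01 <- z[cbind(iy, j1)]
  z10 <- z[cbind(i1, ix)]; z11 <- z[cbind(i1, j1)]
  (1 - ty) * ((1 - tx) * z00 + tx * z01) + ty * ((1 - tx) * z10 + tx * z11)
}

# full-raster bilinear interpolation of a coarse grid; factorized row/col
# weights, much faster than the scattered version for whole images
interp_grid_full <- function(ys, xs, z, nr, nc) {
  if (length(ys) == 1L && length(xs) == 1L) return(matrix(z[1, 1], nr, nc))
  yq <- seq_len(nr); xq <- seq_len(nc)
  iy <- findInterval(yq, ys, all.inside = TRUE)
  ix <- findInterval(xq, xs, all.inside = TRUE)
  i1 <- pmin(iy + 1L, length(ys)); j1 <- pmin(ix + 1L, length(xs))
  dy <- ys[i1] - ys[iy]; dy[dy <= 0] <- 1
  dx <- xs[j1] - xs[ix]; dx[dx <= 0] <- 1
  ty <- pmin(1, pmax(0, (yq - ys[iy]) / dy))
  tx <- pmin(1, pmax(0, (xq - xs[ix]) / dx))
  zy0 <- z[iy, , drop = FALSE] * (1 - ty) + z[i1, , drop = FALSE] * ty
  zy0[, ix, drop = FALSE] * rep(1 - tx, each = nr) +
    zy0[, j1, drop = FALSE] * rep(tx, each = nr)
}

# fill NA cells of a coarse grid from nearest non-NA neighbours (iterative)
fill_na_grid <- function(z) {
  if (!anyNA(z)) return(z)
  if (all(is.na(z))) stop("grid has no fitted cells to interpolate from")
  nr <- nrow(z); nc <- ncol(z)
  while (anyNA(z)) {
    zn <- z
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!is.na(z[i, j])) next
      nb <- c(
        if (i > 1) z[i - 1, j], if (i < nr) z[i + 1, j],
        if (j > 1) z[i, j - 1], if (j < nc) z[i, j + 1]
      )
      if (any(!is.na(nb))) zn[i, j] <- mean(nb, na.rm = TRUE)
    }
    z <- zn
  }
  z
}
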