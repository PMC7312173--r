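# nuclei_segmentation: adaptive log-weighted Otsu thresholding and
# watershed partitioning of overlapping nuclei.

#' Log-weighted Otsu threshold
#'
#' Otsu's between-class-variance criterion computed on the histogram of
#' \code{log(1 + intensity)} (256 bins); the maximizing bin boundary is
#' returned on the original intensity scale. The log weighting makes the
#' threshold robust to the heavy right tail of fluorescence foregrounds.
#'
#' @param pixels numeric vector of intensities (an image sample).
#' @param bins number of histogram bins.
#' @return scalar threshold (original intensity scale).
#' @export
log_weighted_otsu <- function(pixels, bins = 256L) {
  x <- pixels[is.finite(pixels)]
  if (length(unique(x[x > 0])) < 2L || diff(range(x)) == 0)
    stop("degenerate histogram: need at least two distinct positive intensities")
  lx <- log1p(x)
  edges <- seq(min(lx), max(lx), length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(lx, edges, rightmost.closed = TRUE), bins),
                     nbins = bins)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  k <- otsu_split(counts, mids)
  expm1(edges[k + 1L])
}

# index k of the best split (classes = bins 1..k vs k+1..n) maximizing
# between-class variance; exhaustive over all bin boundaries
otsu_split <- function(counts, mids) {
  counts <- as.numeric(counts)
  n <- sum(counts)
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * mids)
  mt <- m0[length(m0)]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m0 / w0
  mu1 <- (mt - m0) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  which.max(bcv)
}

#' Segment nuclei from the DAPI channel
#'
#' Gaussian blur (default sigma = 1 px) followed by an adaptive log-weighted
#' Otsu threshold: a threshold is computed per window and blended bilinearly
#' across window centres. Windows without detectable foreground (foreground /
#' background contrast below \code{contrast_sd} background standard
#' deviations) contribute no threshold; if no window has foreground the
#' result is an empty label map. Holes are filled, objects below
#' \code{min_area} are dropped, and 4-connected components are labelled.
#'
#' @param dapi DAPI \code{slide_image}.
#' @param sigma Gaussian blur standard deviation, pixels.
#' @param min_area minimum object area in square micrometres.
#' @param adaptive_window window side for the adaptive threshold, pixels.
#' @param contrast_sd minimum (foreground mean - background mean) in units of
#'   the background standard deviation for a window threshold to count.
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(dapi, sigma = 1, min_area = 30,
                           adaptive_window = 1024L, contrast_sd = 6) {
  stopifnot(inherits(dapi, "slide_image"))
  sm <- gaussian_blur(dapi$pixels, sigma)
  nr <- nrow(sm); nc <- ncol(sm)
  nwr <- max(1L, round(nr / adaptive_window))
  nwc <- max(1L, round(nc / adaptive_window))
  r_edges <- round(seq(0, nr, length.out = nwr + 1L))
  c_edges <- round(seq(0, nc, length.out = nwc + 1L))
  thr <- matrix(NA_real_, nwr, nwc)
  ctr_r <- (r_edges[-1] + r_edges[-(nwr + 1L)]) / 2
  ctr_c <- (c_edges[-1] + c_edges[-(nwc + 1L)]) / 2
  for (i in seq_len(nwr)) for (j in seq_len(nwc)) {
    w <- sm[(r_edges[i] + 1L):r_edges[i + 1L], (c_edges[j] + 1L):c_edges[j + 1L]]
    t_ij <- tryCatch(log_weighted_otsu(as.vector(w)), error = function(e) NA_real_)
    if (is.na(t_ij)) next
    lo <- w[w <= t_ij]; hi <- w[w > t_ij]
    if (length(hi) == 0 || length(lo) < 2) next
    if ((mean(hi) - mean(lo)) >= contrast_sd * max(sd(lo), 1e-12))
      thr[i, j] <- log1p(t_ij)
  }
  if (all(is.na(thr))) return(matrix(0L, nr, nc))
  thr <- fill_na_grid(thr)
  # bilinear blend of per-window thresholds (log domain), then threshold
  fg <- log1p(sm) > interp_grid_full(ctr_r, ctr_c, thr, nr, nc)
  fg <- fill_holes(fg)
  lab <- cpp_label4(fg)
  min_px <- min_area / dapi$pixel_size^2
  prune_small_labels(lab, min_px)
}

# drop labels below min_px pixels and relabel contiguously 1..N
prune_small_labels <- function(lab, min_px) {
  n <- max(lab)
  if (n == 0L) return(lab)
  st <- cpp_label_stats(lab, matrix(0, 0, 0), n)
  keep <- st$count >= min_px
  remap <- integer(n)
  remap[keep] <- seq_len(sum(keep))
  out <- lab
  pos <- lab > 0L
  out[pos] <- remap[lab[pos]]
  out
}

# solidity of one region given its pixel coordinates (convex hull area ratio)
region_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n < 4L) return(1)
  pts <- cbind(cols, rows)   # pixel coordinates are already distinct
  h <- chull(pts)
  hp <- pts[h, , drop = FALSE]
  # shoelace area of the hull through pixel centres, + n/2-ish boundary slack;
  # use hull area + 0.5*perimeter + 1 (Pick-style) so a convex region gives ~1
  x <- hp[, 1]; y <- hp[, 2]
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  hull_px <- a + per / 2 + 1
  min(1, n / hull_px)
}

# default nucleus-centre detector: regional maxima of the h-maxima transform
# of the smoothed distance transform of the clump mask; returns the seed
# label raster and the relief it was derived from
distance_centers <- function(dapi_patch, mask, h = 2, sigma = 2) {
  d <- cpp_edt(mask)
  d <- gaussian_blur(d, sigma)
  hm <- cpp_reconstruct_dilate(d - h, d)
  list(seeds = cpp_regional_maxima(hm, mask), dist = d)
}

#' Partition overlapping nuclei
#'
#' Objects whose area or solidity deviates from single-nucleus statistics
#' (area above \code{area_factor} times the modal single-nucleus area, or
#' solidity below \code{solidity_min}) are treated as clumps. A centre
#' detector proposes one seed per nucleus (default: regional maxima of the
#' h-maxima-transformed, smoothed distance transform), and clump pixels are
#' assigned to centres by a seeded watershed on the inverted smoothed DAPI
#' image. Splitting only relabels: the union of foreground pixels is
#' unchanged.
#'
#' @param labelmap integer label matrix from \code{\link{segment_nuclei}}.
#' @param dapi DAPI \code{slide_image} (used for the watershed relief).
#' @param method \code{"seeded_watershed"} (default) or \code{"salr_centers"};
#'   the latter requires a user-supplied \code{center_fun} implementing a
#'   short-range-attraction/long-range-repulsion centre finder and errors
#'   otherwise.
#' @param center_fun optional \code{function(dapi_patch, mask)} returning an
#'   integer seed matrix (one positive label per detected centre).
#' @param h h-maxima depth (pixels of distance) for the default detector.
#' @param sigma smoothing of the distance transform / DAPI relief.
#' @param area_factor,solidity_min clump-detection rule parameters.
#' @param mode_area modal single-nucleus area in pixels; estimated from the
#'   label map's area distribution when \code{NULL}.
#' @param relief_on watershed relief: \code{"distance"} (default; negated
#'   smoothed distance transform, a geometric nearest-centre partition) or
#'   \code{"intensity"} (inverted smoothed DAPI).
#' @return relabelled integer matrix with contiguous labels.
#' @export
partition_overlaps <- function(labelmap, dapi,
                               method = c("seeded_watershed", "salr_centers"),
                               center_fun = NULL, h = 2, sigma = 2,
                               area_factor = 1.6, solidity_min = 0.9,
                               mode_area = NULL,
                               relief_on = c("distance", "intensity")) {
  method <- match.arg(method)
  relief_on <- match.arg(relief_on)
  if (method == "salr_centers" && is.null(center_fun))
    stop("no SALR centre detector is installed; pass center_fun= or use ",
         "method = \"seeded_watershed\"")
  n <- max(labelmap)
  if (n == 0L) return(labelmap)
  st <- cpp_label_stats(labelmap, matrix(0, 0, 0), n)
  areas <- st$count
  mode_area <- mode_area %||%
    (if (n >= 5L) density_mode(areas) else median(areas))
  out <- labelmap
  next_label <- n
  sm_dapi <- NULL
  for (id in seq_len(n)) {
    # objects well below one modal nucleus cannot be clumps; skip the hull test
    if (areas[id] < 0.75 * mode_area) next
    r0 <- max(1L, st$rmin[id] - 2L); r1 <- min(nrow(out), st$rmax[id] + 2L)
    c0 <- max(1L, st$cmin[id] - 2L); c1 <- min(ncol(out), st$cmax[id] + 2L)
    patch_lab <- out[r0:r1, c0:c1]
    mask <- patch_lab == id
    idx <- which(mask, arr.ind = TRUE)
    is_clump <- areas[id] > area_factor * mode_area ||
      region_solidity(idx[, 1], idx[, 2]) < solidity_min
    if (!is_clump) next
    if (is.null(sm_dapi)) sm_dapi <- gaussian_blur(dapi$pixels, sigma)
    dp <- sm_dapi[r0:r1, c0:c1]
    if (!is.null(center_fun)) {
      seeds <- center_fun(dp, mask)
      dist <- gaussian_blur(cpp_edt(mask), sigma)
    } else {
      dc <- distance_centers(dp, mask, h = h, sigma = sigma)
      seeds <- dc$seeds
      dist <- dc$dist
    }
    nseeds <- max(seeds)
    if (nseeds <= 1L) next
    # geometric partition: each clump pixel goes to its nearest centre, via a
    # seeded watershed on the negated smoothed distance transform (the
    # "intensity" relief fails on additive overlaps, whose junction is bright)
    relief <- if (relief_on == "distance") -dist else -dp
    ws <- cpp_watershed(relief, seeds, mask)
    # unassigned pixels (disconnected slivers) keep the original label
    new_ids <- c(id, next_label + seq_len(nseeds - 1L))
    next_label <- next_label + nseeds - 1L
    patch_lab[mask] <- ifelse(ws[mask] > 0L, new_ids[ws[mask]], id)
    out[r0:r1, c0:c1] <- patch_lab
  }
  prune_small_labels(out, 1)
}
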