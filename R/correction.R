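# intensity_correction: background surface, fast-axis stripe factors, DAPI
# foreground band anchoring (G1 -> 1, G2 -> 2), gamma-H2AX baseline surface.
#
# The correction order is fixed: background surface -> stripes -> DAPI
# foreground -> gamma-H2AX foreground; the DAPI foreground must be corrected
# before any other channel's foreground.

# internal: wrap corrected pixels without the non-negativity check (noise
# excursions below zero are expected after background subtraction)
new_slide_image <- function(template, pixels) {
  out <- template
  out$pixels <- pixels
  out
}

#' Estimate the smooth additive background surface
#'
#' Robust local statistics (per-block medians of background pixels, smoothed
#' and interpolated bilinearly) of all pixels not covered by (dilated)
#' nucleus foreground. Subtracting the returned surface makes the background
#' median approximately zero everywhere.
#'
#' @param image \code{slide_image}.
#' @param background_mask logical matrix, \code{TRUE} on background pixels
#'   (typically the complement of the dilated segmentation foreground).
#' @param block block side in pixels for the local medians.
#' @param min_coverage minimum fraction of background pixels required.
#' @return object of class \code{background_surface}: coarse grid + centres;
#'   use \code{\link{eval_surface}} for the full-resolution field.
#' @export
estimate_background_surface <- function(image, background_mask, block = 256L,
                                        min_coverage = 0.05) {
  stopifnot(inherits(image, "slide_image"))
  px <- image$pixels
  stopifnot(identical(dim(background_mask), dim(px)))
  if (mean(background_mask) < min_coverage)
    stop("background covers ", sprintf("%.1f%%", 100 * mean(background_mask)),
         " of pixels (< ", 100 * min_coverage, "%); estimate the surface on ",
         "lower-confluence tiles")
  nr <- nrow(px); nc <- ncol(px)
  nbr <- max(1L, round(nr / block)); nbc <- max(1L, round(nc / block))
  r_edges <- round(seq(0, nr, length.out = nbr + 1L))
  c_edges <- round(seq(0, nc, length.out = nbc + 1L))
  grid <- matrix(NA_real_, nbr, nbc)
  for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
    rr <- (r_edges[i] + 1L):r_edges[i + 1L]
    cc <- (c_edges[j] + 1L):c_edges[j + 1L]
    v <- px[rr, cc][background_mask[rr, cc]]
    if (length(v) >= 30L) grid[i, j] <- median(v)
  }
  grid <- fill_na_grid(grid)
  # light smoothing of the block medians; skipped for coarse grids where the
  # reflecting boundary would visibly flatten gradients at the slide edges
  if (nbr >= 8L && nbc >= 8L) grid <- gaussian_blur(grid, 0.7)
  structure(list(grid = grid,
                 centers_r = (r_edges[-1] + r_edges[-(nbr + 1L)]) / 2,
                 centers_c = (c_edges[-1] + c_edges[-(nbc + 1L)]) / 2,
                 dim = c(nr, nc)),
            class = "background_surface")
}

#' Evaluate a background surface at full resolution (or at points)
#' @param surface \code{background_surface}.
#' @param rows,cols optional pixel coordinates; default: full raster.
#' @export
eval_surface <- function(surface, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    interp_grid_full(surface$centers_r, surface$centers_c, surface$grid,
                     surface$dim[1], surface$dim[2])
  } else {
    interp_grid(surface$centers_r, surface$centers_c, surface$grid, rows, cols)
  }
}

#' Subtract the background surface from a slide
#' @param image \code{slide_image}.
#' @param surface \code{background_surface}.
#' @return \code{slide_image} with flattened background (may contain small
#'   negative noise excursions).
#' @export
subtract_background <- function(image, surface) {
  new_slide_image(image, image$pixels - eval_surface(surface))
}

#' Estimate and remove fast-axis stripe artifacts
#'
#' Scan-line calibration errors multiply whole scan lines. Per line, the
#' robust background level is compared with the smooth background surface;
#' lines whose implied factor deviates from 1 by more than
#' \code{max(min_dev, nsig * mad)} are divided by their factor (the
#' un-flattened line is divided, then the surface re-subtracted, so the
#' correction is exactly multiplicative on the original counts). All other
#' lines are left untouched.
#'
#' @param image background-flattened \code{slide_image}.
#' @param background_mask logical background raster.
#' @param surface the \code{background_surface} that was subtracted.
#' @param nsig robust z-score needed to flag a line.
#' @param min_level minimum mean background-surface level (counts) on a line
#'   for its multiplicative factor to be identifiable.
#' @param min_dev minimum absolute factor deviation to flag a line.
#' @return list: \code{image} (corrected \code{slide_image}),
#'   \code{factors} (one per scan line, exactly 1 for unflagged lines).
#' @export
remove_stripes <- function(image, background_mask, surface, nsig = 6,
                           min_dev = 0.02, min_level = 5) {
  stopifnot(inherits(image, "slide_image"))
  if (is.null(image$fast_axis)) stop("fast_axis metadata missing on the slide")
  px <- image$pixels
  transposed <- image$fast_axis == "rows"   # scan lines are columns then
  if (transposed) {
    px <- t(px); background_mask <- t(background_mask)
  }
  surf <- eval_surface(surface)
  if (transposed) surf <- t(surf)
  nlines <- nrow(px)
  resid <- rep(NA_real_, nlines)
  slevel <- rep(NA_real_, nlines)
  for (l in seq_len(nlines)) {
    sel <- background_mask[l, ]
    if (sum(sel) < 20L) next
    resid[l] <- median(px[l, sel])
    slevel[l] <- mean(surf[l, sel])
  }
  factors <- rep(1, nlines)
  est <- 1 + resid / pmax(slevel, 1e-9)
  # a multiplicative line factor is only identifiable when the line has a
  # measurable background level
  est[is.na(est) | slevel < min_level] <- 1
  dev <- est - 1
  noise <- stats::mad(dev, center = 0)
  flag <- abs(dev) > max(min_dev, nsig * noise)
  factors[flag] <- est[flag]
  for (l in which(flag)) {
    px[l, ] <- (px[l, ] + surf[l, ]) / factors[l] - surf[l, ]
  }
  if (transposed) px <- t(px)
  list(image = new_slide_image(image, px), factors = factors)
}

# two Gaussians + uniform background, 1D EM with a fixed iteration count.
# The uniform component absorbs S-phase cells and mis-segmented debris that
# would otherwise bias the G1/G2 band centres inward. Every update is
# affine-equivariant (the uniform support is the data range), which keeps
# the band-anchoring correction a projection up to estimation noise.
em2_normal <- function(x, mu, iter = 150L) {
  u_dens <- 1 / max(diff(range(x)), .Machine$double.eps)
  s <- rep(diff(range(mu)) / 8, 2)
  w <- c(0.45, 0.45, 0.10)
  for (k in seq_len(iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
    d3 <- w[3] * u_dens
    tot <- d1 + d2 + d3
    tot[tot <= 0] <- .Machine$double.xmin
    r1 <- d1 / tot; r2 <- d2 / tot
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 <= 1 || n2 <= 1) break
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    s <- sqrt(pmax(c(sum(r1 * (x - mu[1])^2) / n1,
                     sum(r2 * (x - mu[2])^2) / n2),
                   (1e-6 * abs(diff(mu)))^2))
    w <- c(n1, n2, length(x) - n1 - n2) / length(x)
  }
  o <- order(mu[1:2])
  list(mu = mu[o], sigma = s[o], w = c(w[o], w[3]))
}

# kernel-density mode of x restricted to [center - hw, center + hw];
# falls back to the centre when the window holds too few points
local_mode <- function(x, center, hw) {
  xs <- x[x >= center - hw & x <= center + hw]
  if (length(xs) < 25L) return(center)
  density_mode(xs)
}

# find the (G1, G2) band-mode pair of an intensity sample: two density peaks
# with ratio in [1.5, 2.7], maximizing joint prominence; NULL if unimodal
find_band_pair <- function(x) {
  pk <- density_peaks(x)
  if (length(pk$x) < 2L) return(NULL)
  keep <- pk$y > 0.05 * max(pk$y)
  px <- pk$x[keep]; py <- pk$y[keep]
  best <- NULL; best_score <- -Inf
  for (i in seq_along(px)) for (j in seq_along(px)) {
    if (px[j] <= px[i]) next
    ratio <- px[j] / px[i]
    if (ratio < 1.5 || ratio > 2.7) next
    score <- py[i] * py[j]
    if (score > best_score) { best_score <- score; best <- c(px[i], px[j]) }
  }
  best
}

#' Anchor the G1 and G2 DAPI bands at 1 and 2
#'
#' Slow-axis windows (equal-count) each get a two-component Gaussian mixture
#' fit of the per-nucleus integrated DAPI intensity; the two band centres are
#' smoothed against slow-axis position with lowess, and every nucleus's
#' intensity is mapped affinely (per position) so the fitted G1 curve lands
#' at 1 and the G2 curve at 2.
#'
#' @param records nucleus table with columns \code{i_dapi} (integrated DAPI)
#'   and \code{slow_um} (slow-axis position of the centroid, micrometres).
#' @param span lowess span (fraction of the slow-axis extent).
#' @param n_windows number of slow-axis windows; default scales with the
#'   number of nuclei.
#' @param min_nuclei minimum number of records required.
#' @return list: \code{records} (with \code{i_dapi} replaced by the corrected
#'   value and the original kept as \code{i_dapi_raw}), \code{gain_curve}
#'   (window centres and raw/smoothed band centres).
#' @export
normalize_dapi_foreground <- function(records, span = 0.3, n_windows = NULL,
                                      min_nuclei = 500L) {
  stopifnot(all(c("i_dapi", "slow_um") %in% names(records)))
  x <- records$i_dapi
  if (length(x) < min_nuclei)
    stop("need at least ", min_nuclei, " nuclei to anchor the DAPI bands")
  if (is.null(find_band_pair(x)))
    stop("DAPI intensity distribution is unimodal; cannot anchor G1/G2 bands")
  n <- length(x)
  nw <- n_windows %||% max(4L, min(24L, floor(n / 300)))
  qs <- quantile(records$slow_um, probs = seq(0, 1, length.out = nw + 1L))
  win <- cut(records$slow_um, unique(qs), include.lowest = TRUE, labels = FALSE)
  nw <- max(win)
  ctr <- c1 <- c2 <- rep(NA_real_, nw)
  for (w in seq_len(nw)) {
    sel <- win == w
    ctr[w] <- median(records$slow_um[sel])
    pair <- find_band_pair(x[sel])
    if (is.null(pair)) next
    # trim to the plausible band range (equivariant: bounds derive from the
    # detected modes) so clump/debris tails do not enter the fit
    xs <- x[sel]
    xs <- xs[xs > 0.55 * pair[1] & xs < 1.45 * pair[2]]
    if (length(xs) < 50L) next
    fit <- em2_normal(xs, pair)
    # the band "position" is its ridge: refine each EM mean to the local KDE
    # mode within +-2.5 sigma (still affine-equivariant)
    c1[w] <- local_mode(xs, fit$mu[1], 2.5 * fit$sigma[1])
    c2[w] <- local_mode(xs, fit$mu[2], 2.5 * fit$sigma[2])
  }
  ok <- !is.na(c1)
  if (sum(ok) < 2L)
    stop("fewer than two slow-axis windows show both DAPI bands")
  sm1 <- lowess(ctr[ok], c1[ok], f = span)
  sm2 <- lowess(ctr[ok], c2[ok], f = span)
  C1 <- approx(sm1$x, sm1$y, xout = records$slow_um, rule = 2)$y
  C2 <- approx(sm2$x, sm2$y, xout = records$slow_um, rule = 2)$y
  if (any(C2 - C1 <= 0)) stop("fitted G2 band does not exceed the G1 band")
  out <- records
  if (is.null(out$i_dapi_raw)) out$i_dapi_raw <- out$i_dapi
  out$i_dapi <- 1 + (records$i_dapi - C1) / (C2 - C1)
  list(records = out,
       gain_curve = list(center_um = ctr[ok], g1 = c1[ok], g2 = c2[ok],
                         g1_smooth = sm1, g2_smooth = sm2, span = span))
}

#' Flatten the gamma-H2AX foreground using undamaged G1 cells
#'
#' G1 cells (corrected DAPI in [0.7, 1.3]) are binned into blocks of
#' \code{block_mm} millimetres; per block the baseline is the mean of the
#' gamma-H2AX intensities between the 2nd and 4th percentile of that block's
#' G1 cells (the undamaged subpopulation), guarded never to exceed the
#' block's G1 median. The block baselines are interpolated into a smooth
#' surface and subtracted from every nucleus's integrated gamma-H2AX
#' intensity; negative results are clipped to zero.
#'
#' @param records nucleus table with \code{i_gh2ax}, \code{i_dapi}
#'   (corrected), \code{x_um}, \code{y_um}.
#' @param block_mm block side, millimetres.
#' @param percentile_band percentile window (fractions) of G1 gamma-H2AX
#'   intensities regarded as undamaged.
#' @param min_g1 blocks with fewer G1 cells are interpolated from neighbours.
#' @param g1_range corrected-DAPI window selecting G1 cells.
#' @return list: \code{records} (corrected \code{i_gh2ax}, original kept as
#'   \code{i_gh2ax_raw}), \code{baseline} (block grid + centres).
#' @export
flatten_gh2ax_foreground <- function(records, block_mm = 1,
                                     percentile_band = c(0.02, 0.04),
                                     min_g1 = 20L, g1_range = c(0.7, 1.3)) {
  stopifnot(all(c("i_gh2ax", "i_dapi", "x_um", "y_um") %in% names(records)))
  bu <- block_mm * 1000
  xr <- range(records$x_um); yr <- range(records$y_um)
  nbx <- max(1L, round(diff(xr) / bu)); nby <- max(1L, round(diff(yr) / bu))
  ex <- seq(xr[1], xr[2], length.out = nbx + 1L)
  ey <- seq(yr[1], yr[2], length.out = nby + 1L)
  bx <- pmin(pmax(findInterval(records$x_um, ex, rightmost.closed = TRUE), 1L), nbx)
  by <- pmin(pmax(findInterval(records$y_um, ey, rightmost.closed = TRUE), 1L), nby)
  is_g1 <- records$i_dapi >= g1_range[1] & records$i_dapi <= g1_range[2]
  grid <- matrix(NA_real_, nby, nbx)
  for (i in seq_len(nby)) for (j in seq_len(nbx)) {
    g <- records$i_gh2ax[is_g1 & by == i & bx == j]
    if (length(g) < min_g1) next
    qs <- quantile(g, percentile_band)
    inside <- g[g >= qs[1] & g <= qs[2]]
    base <- if (length(inside) > 0) mean(inside) else mean(qs)
    # guard: the baseline must stay below the local G1 median, otherwise we
    # would be flattening real damage
    grid[i, j] <- min(base, median(g))
  }
  if (all(is.na(grid)))
    stop("no ", block_mm, " mm block contains >= ", min_g1,
         " G1 cells; cannot fit the gamma-H2AX baseline surface")
  grid <- fill_na_grid(grid)
  cy <- (ey[-1] + ey[-(nby + 1L)]) / 2
  cx <- (ex[-1] + ex[-(nbx + 1L)]) / 2
  at <- interp_grid(cy, cx, grid, records$y_um, records$x_um)
  out <- records
  if (is.null(out$i_gh2ax_raw)) out$i_gh2ax_raw <- out$i_gh2ax
  out$i_gh2ax <- pmax(0, records$i_gh2ax - at)
  list(records = out,
       baseline = list(grid = grid, centers_y = cy, centers_x = cx,
                       block_mm = block_mm, percentile_band = percentile_band))
}

#' Full intensity-correction chain for one two-channel slide
#'
#' Fixed order: background surface (each channel) -> stripe removal (each
#' channel) -> per-nucleus intensity measurement -> DAPI band anchoring ->
#' gamma-H2AX baseline flattening.
#'
#' @param dapi,gh2ax \code{slide_image}s (co-registered).
#' @param labels nucleus label matrix.
#' @param dilate_px background mask excludes foreground dilated by this many
#'   pixels.
#' @param span,block_mm,percentile_band see
#'   \code{\link{normalize_dapi_foreground}} and
#'   \code{\link{flatten_gh2ax_foreground}}.
#' @param flatten_gh2ax set \code{FALSE} when the slide has no gamma-H2AX
#'   channel of interest.
#' @param min_nuclei minimum records required for band anchoring.
#' @return list with \code{records} (corrected per-nucleus table),
#'   \code{model} (surfaces, stripe factors, gain curve, baseline) and the
#'   corrected channel images.
#' @export
correct_slide <- function(dapi, gh2ax, labels, dilate_px = 4L, span = 0.3,
                          block_mm = 1, percentile_band = c(0.02, 0.04),
                          flatten_gh2ax = TRUE, min_nuclei = 500L) {
  fg <- labels > 0L
  if (dilate_px > 0) {
    fgd <- cpp_dilate_gray(matrix(as.numeric(fg), nrow(fg)), disk_offsets(dilate_px))
    bg_mask <- fgd == 0
  } else bg_mask <- !fg
  surf_d <- estimate_background_surface(dapi, bg_mask)
  dapi_f <- subtract_background(dapi, surf_d)
  sd_out <- remove_stripes(dapi_f, bg_mask, surf_d)
  surf_g <- estimate_background_surface(gh2ax, bg_mask)
  gh_f <- subtract_background(gh2ax, surf_g)
  sg_out <- remove_stripes(gh_f, bg_mask, surf_g)
  records <- measure_nuclei(labels, sd_out$image, sg_out$image)
  nd <- normalize_dapi_foreground(records, span = span, min_nuclei = min_nuclei)
  records <- nd$records
  baseline <- NULL
  if (flatten_gh2ax) {
    fg_out <- flatten_gh2ax_foreground(records, block_mm = block_mm,
                                       percentile_band = percentile_band)
    records <- fg_out$records
    baseline <- fg_out$baseline
  }
  list(records = records,
       model = list(background_dapi = surf_d, background_gh2ax = surf_g,
                    stripe_factors_dapi = sd_out$factors,
                    stripe_factors_gh2ax = sg_out$factors,
                    gain_curve = nd$gain_curve, gh2ax_baseline = baseline),
       dapi = sd_out$image, gh2ax = sg_out$image)
}
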