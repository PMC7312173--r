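# nuclear_features: per-nucleus shape, Fourier-descriptor, intensity,
# radial-shell, Haralick-texture and granularity features.

#' Measure basic per-nucleus intensities and geometry
#'
#' Light-weight record table (id, centroid, area, integrated intensities,
#' slow-axis position) used by the correction chain; full features come from
#' \code{\link{extract_features}}.
#'
#' @param labels integer label matrix.
#' @param dapi,gh2ax corrected \code{slide_image}s (\code{gh2ax} may be
#'   \code{NULL}).
#' @return data frame, one row per label.
#' @export
measure_nuclei <- function(labels, dapi, gh2ax = NULL) {
  n <- max(labels)
  ps <- dapi$pixel_size
  if (n == 0L)
    return(data.frame(nucleus_id = integer(0), row = numeric(0), col = numeric(0),
                      x_um = numeric(0), y_um = numeric(0), slow_um = numeric(0),
                      area_um2 = numeric(0), i_dapi = numeric(0),
                      i_gh2ax = numeric(0)))
  st <- cpp_label_stats(labels, dapi$pixels, n)
  row <- st$rmean / st$count
  col <- st$cmean / st$count
  gh <- if (is.null(gh2ax)) rep(NA_real_, n)
        else cpp_label_stats(labels, gh2ax$pixels, n)$sum
  data.frame(
    nucleus_id = seq_len(n), row = row, col = col,
    x_um = col * ps, y_um = row * ps,
    slow_um = slow_axis_position(dapi, row, col),
    area_um2 = st$count * ps^2,
    i_dapi = st$sum, i_gh2ax = gh
  )
}

# Moore-neighbour boundary tracing (8-connected, clockwise); returns an
# n x 2 matrix of (row, col) boundary pixel coordinates
trace_boundary <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty region")
  nr <- nrow(mask)
  start <- idx[1]                      # first fg pixel in column-major scan
  if (length(idx) == 1L)
    return(matrix(c((start - 1L) %% nr + 1L, (start - 1L) %/% nr + 1L), 1))
  # neighbour order: clockwise starting E
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  at <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= ncol(mask) && mask[r, c]
  r0 <- (start - 1L) %% nr + 1L; c0 <- (start - 1L) %/% nr + 1L
  out_r <- integer(0); out_c <- integer(0)
  r <- r0; c <- c0
  # backtrack direction: we entered the start pixel from the W (scan order)
  b <- 5L
  repeat {
    out_r <- c(out_r, r); out_c <- c(out_c, c)
    found <- FALSE
    for (k in 0:7) {
      d <- (b + 1L + k) %% 8L + 1L     # start just after the backtrack dir
      rr <- r + dr[d]; cc <- c + dc[d]
      if (at(rr, cc)) {
        b <- (d + 3L) %% 8L            # new backtrack = direction we came from
        r <- rr; c <- cc
        found <- TRUE
        break
      }
    }
    if (!found) break                   # isolated pixel group
    if (r == r0 && c == c0 && length(out_r) > 2L) break
  }
  cbind(out_r, out_c, deparse.level = 0)
}

#' Shape features of one nucleus region
#'
#' Area (pixel count scaled), perimeter (8-connected boundary chain length),
#' eccentricity and orientation from central second moments, solidity from
#' the convex hull.
#'
#' @param mask logical matrix: the region (connected, non-empty).
#' @param pixel_size micrometres per pixel.
#' @return named list: \code{area_um2}, \code{perimeter_um},
#'   \code{eccentricity}, \code{solidity}, \code{orientation} (radians,
#'   angle of the major axis to the column/x axis).
#' @export
shape_features <- function(mask, pixel_size = 1) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stop("empty region")
  area <- n * pixel_size^2
  if (n == 1L)
    return(list(area_um2 = area, perimeter_um = 4 * pixel_size,
                eccentricity = 0, solidity = 1, orientation = 0))
  bnd <- trace_boundary(mask)
  per <- if (nrow(bnd) > 1L) {
    steps <- sqrt(diff(c(bnd[, 1], bnd[1, 1]))^2 + diff(c(bnd[, 2], bnd[1, 2]))^2)
    sum(steps) * pixel_size
  } else 4 * pixel_size
  r <- idx[, 1] - mean(idx[, 1]); c <- idx[, 2] - mean(idx[, 2])
  # +1/12: moment of a unit square pixel about its centre
  mu20 <- mean(c^2) + 1 / 12
  mu02 <- mean(r^2) + 1 / 12
  mu11 <- mean(r * c)
  tr <- mu20 + mu02
  dlt <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (tr + dlt) / 2; l2 <- (tr - dlt) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(pmax(0, 1 - l2 / l1))
  orient <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  list(area_um2 = area, perimeter_um = per, eccentricity = ecc,
       solidity = region_solidity(idx[, 1], idx[, 2]), orientation = orient)
}

#' Fourier descriptors of a closed boundary
#'
#' The boundary is resampled to \code{n_samples} points equally spaced in
#' arclength, taken as complex numbers, and Fourier-transformed. The DC term
#' is dropped (translation invariance), magnitudes are divided by the
#' dominant first-harmonic magnitude (rotation, scale and start-point
#' invariance), and the \code{K} largest-period remaining harmonics are
#' returned in the fixed order: opposite first harmonic, +2, -2, +3, -3, ...
#'
#' @param boundary n x 2 matrix of (row, col) (or (y, x)) boundary points, in
#'   traversal order; the contour is treated as closed. Self-intersecting
#'   contours are processed without any topology check.
#' @param K number of descriptor magnitudes.
#' @param n_samples resampling length.
#' @return numeric vector of \code{K} normalized magnitudes.
#' @export
fourier_descriptors <- function(boundary, K = 16L, n_samples = 256L) {
  stopifnot(is.matrix(boundary), ncol(boundary) == 2)
  if (nrow(boundary) < 2L * K)
    stop("contour too short: need at least 2*K = ", 2 * K, " points")
  z <- complex(real = boundary[, 2], imaginary = boundary[, 1])
  if (z[1] != z[length(z)]) z <- c(z, z[1])
  seg <- Mod(diff(z))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) stop("degenerate contour (zero length)")
  t_out <- seq(0, L, length.out = n_samples + 1L)[-(n_samples + 1L)]
  zr <- complex(real = approx(s, Re(z), xout = t_out)$y,
                imaginary = approx(s, Im(z), xout = t_out)$y)
  F <- fft(zr) / n_samples
  # frequency k lives at index k+1 (k >= 0) and n_samples+1+k (k < 0)
  fpos <- function(k) if (k >= 0) F[k + 1L] else F[n_samples + 1L + k]
  m1 <- max(Mod(fpos(1)), Mod(fpos(-1)))
  if (m1 <= 0) stop("degenerate contour (no first harmonic)")
  ks <- integer(0)
  k <- 1L
  while (length(ks) < K + 1L) {
    ks <- c(ks, k, -k)
    k <- k + 1L
  }
  mags <- vapply(ks, function(k) Mod(fpos(k)), numeric(1))
  # drop the dominant first harmonic itself; keep the other of +-1 first
  drop_i <- if (Mod(fpos(1)) >= Mod(fpos(-1))) 1L else 2L
  (mags[-drop_i] / m1)[seq_len(K)]
}

#' Radial shell mean intensities
#'
#' Region pixels are binned into \code{S} equal-width bins of normalized
#' distance-to-boundary (0 = boundary, 1 = innermost); shell 1 is the
#' outermost (boundary) shell, shell \code{S} the innermost core.
#'
#' @param mask logical region matrix.
#' @param img intensity matrix, same shape.
#' @param S number of shells (>= 2).
#' @return numeric vector of \code{S} shell means, outermost first.
#' @export
shell_intensities <- function(mask, img, S = 4L) {
  stopifnot(S >= 2L, identical(dim(mask), dim(img)))
  npx <- sum(mask)
  if (npx < S) stop("region smaller than the number of shells")
  d <- cpp_edt(mask)
  dn <- d[mask] / max(d[mask])
  shell <- pmin(S, floor(dn * S) + 1L)
  v <- img[mask]
  vapply(seq_len(S), function(s) {
    if (any(shell == s)) mean(v[shell == s]) else NA_real_
  }, numeric(1))
}

# 13 Haralick statistics of one normalized, symmetric GLCM
haralick_stats <- function(P) {
  N <- nrow(P)
  tot <- sum(P)
  if (tot <= 0) return(rep(0, 13))
  p <- P / tot
  i <- matrix(seq_len(N), N, N)
  j <- t(i)
  px <- rowSums(p)                      # == colSums by symmetry
  mu <- sum(seq_len(N) * px)
  sg <- sqrt(sum((seq_len(N) - mu)^2 * px))
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sg > 0) (sum(i * j * p) - mu^2) / sg^2 else 0
  variance <- sum((i - mu)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  # sum / difference distributions
  psum <- vapply(2:(2 * N), function(k) sum(p[i + j == k]), numeric(1))
  pdif <- vapply(0:(N - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ksum <- 2:(2 * N); kdif <- 0:(N - 1)
  sum_avg <- sum(ksum * psum)
  sum_var <- sum((ksum - sum_avg)^2 * psum)
  sum_ent <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(p))
  dif_avg <- sum(kdif * pdif)
  dif_var <- sum((kdif - dif_avg)^2 * pdif)
  dif_ent <- -sum(xlogx(pdif))
  hx <- -sum(xlogx(px))
  pxpy <- outer(px, px)
  hxy1 <- -sum(ifelse(pxpy > 0, p * log(pxpy), 0))
  hxy2 <- -sum(xlogx(pxpy))
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_avg = sum_avg, sum_var = sum_var,
    sum_ent = sum_ent, entropy = entropy, dif_var = dif_var,
    dif_ent = dif_ent, imc1 = imc1, imc2 = imc2)
}

#' Haralick texture features
#'
#' Intensities inside the region are quantized to \code{levels} gray levels
#' over the region's min-max range; gray-level co-occurrence matrices for the
#' four distance-1 offsets (0, 45, 90, 135 degrees) are symmetrized and
#' normalized, and the 13 Haralick statistics are averaged over offsets. A
#' constant region returns the defined limits (contrast 0, angular second
#' moment 1, correlation 0 by convention).
#'
#' @param mask logical region matrix (>= 4 px).
#' @param img intensity matrix.
#' @param levels number of gray levels (>= 2; 64 by default, 8+ recommended
#'   for real texture).
#' @param offsets integer matrix of (dr, dc) offsets; default the four
#'   standard distance-1 directions.
#' @param average return the offset average (default) or a 4 x 13 matrix.
#' @return named numeric vector of 13 statistics.
#' @export
haralick_features <- function(mask, img, levels = 64L,
                              offsets = rbind(c(0L, 1L), c(-1L, 1L),
                                              c(-1L, 0L), c(-1L, -1L)),
                              average = TRUE) {
  stopifnot(levels >= 2L, identical(dim(mask), dim(img)))
  if (sum(mask) < 4L) stop("region too small for texture (need >= 4 px)")
  v <- img[mask]
  rng <- range(v)
  q <- matrix(0L, nrow(img), ncol(img))
  if (diff(rng) == 0) {
    q[mask] <- 1L
  } else {
    q[mask] <- pmin(levels, floor((v - rng[1]) / diff(rng) * levels) + 1L)
  }
  res <- t(apply(offsets, 1, function(o) {
    haralick_stats(cpp_glcm(q, levels, o[1], o[2]))
  }))
  colnames(res) <- names(haralick_stats(matrix(1)))
  if (average) colMeans(res) else res
}

#' Granularity spectrum
#'
#' CellProfiler-style iterative erosion/reconstruction: at scale g the image
#' is eroded once more with a radius-1 disk, reconstructed under the original,
#' and element g is the percentage of the starting mean intensity removed at
#' that scale. The spectrum sums to at most 100 and is invariant to intensity
#' rescaling.
#'
#' @param mask logical region matrix (non-empty).
#' @param img intensity matrix.
#' @param G number of spectrum elements.
#' @return numeric vector of \code{G} percentages.
#' @export
granularity_spectrum <- function(mask, img, G = 16L) {
  stopifnot(G >= 1L, identical(dim(mask), dim(img)))
  if (!any(mask)) stop("empty region")
  orig <- img * mask
  start_mean <- mean(orig[mask])
  if (start_mean <= 0) return(rep(0, G))
  se <- disk_offsets(1)
  ero <- orig
  cur <- start_mean
  out <- numeric(G)
  for (g in seq_len(G)) {
    ero <- cpp_erode_gray(ero, se)
    ero[ero == Inf] <- 0
    rec <- cpp_reconstruct_dilate(ero, orig)
    nm <- mean(rec[mask])
    out[g] <- 100 * (cur - nm) / start_mean
    cur <- nm
  }
  out
}

#' Intensity features of one region
#'
#' @param mask logical region matrix.
#' @param img intensity matrix.
#' @return named list: integrated (sum), mean, std and the 5/25/50/75/95
#'   percent quantiles.
#' @export
intensity_features <- function(mask, img) {
  v <- img[mask]
  if (length(v) == 0L) stop("empty region")
  q <- quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  list(integrated = sum(v), mean = mean(v),
       std = if (length(v) > 1) sd(v) else 0,
       q05 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q95 = q[5])
}

#' Extract the full per-nucleus feature table
#'
#' One row per label: geometry, shape, Fourier descriptors, DAPI intensity,
#' radial shells, Haralick texture and granularity (all from the DAPI
#' channel), plus intensity-only features from the gamma-H2AX channel.
#' Nuclei whose centroid falls in a QC-masked tile are flagged
#' (\code{qc_pass = FALSE}) and their features set to \code{NA}.
#'
#' @param labels integer label matrix.
#' @param dapi DAPI \code{slide_image} (corrected).
#' @param gh2ax optional gamma-H2AX \code{slide_image} (corrected).
#' @param K,S,levels,G feature-set sizes: Fourier descriptors, shells, GLCM
#'   gray levels, granularity elements.
#' @param qc optional \code{\link{qc_mask}}.
#' @return data frame with a stable column order.
#' @export
extract_features <- function(labels, dapi, gh2ax = NULL, K = 16L, S = 4L,
                             levels = 64L, G = 16L, qc = NULL) {
  n <- max(labels)
  base <- measure_nuclei(labels, dapi, gh2ax)
  fd_cols <- sprintf("fd_%02d", seq_len(K))
  sh_cols <- sprintf("shell_%d", seq_len(S))
  har_cols <- paste0("har_", names(haralick_stats(matrix(1))))
  gr_cols <- sprintf("gran_%02d", seq_len(G))
  int_cols <- c("dapi_mean", "dapi_std", "dapi_q05", "dapi_q25", "dapi_q50",
                "dapi_q75", "dapi_q95")
  gh_cols <- c("gh2ax_mean", "gh2ax_std", "gh2ax_q05", "gh2ax_q25",
               "gh2ax_q50", "gh2ax_q75", "gh2ax_q95")
  shape_cols <- c("perimeter_um", "eccentricity", "solidity", "orientation")
  all_cols <- c(shape_cols, fd_cols, int_cols, sh_cols, har_cols, gr_cols, gh_cols)
  feat <- matrix(NA_real_, n, length(all_cols),
                 dimnames = list(NULL, all_cols))
  qc_pass <- rep(TRUE, n)
  if (n > 0) {
    st <- cpp_label_stats(labels, dapi$pixels, n)
    if (!is.null(qc)) qc_pass <- !qc_masked_at(qc, base$row, base$col)
    for (id in seq_len(n)) {
      if (!qc_pass[id]) next
      r0 <- max(1L, st$rmin[id] - 1L); r1 <- min(nrow(labels), st$rmax[id] + 1L)
      c0 <- max(1L, st$cmin[id] - 1L); c1 <- min(ncol(labels), st$cmax[id] + 1L)
      mask <- labels[r0:r1, c0:c1] == id
      dimg <- dapi$pixels[r0:r1, c0:c1]
      sh <- shape_features(mask, dapi$pixel_size)
      feat[id, shape_cols] <- c(sh$perimeter_um, sh$eccentricity,
                                sh$solidity, sh$orientation)
      bnd <- trace_boundary(mask)
      if (nrow(bnd) >= 2L * K)
        feat[id, fd_cols] <- fourier_descriptors(bnd, K)
      di <- intensity_features(mask, dimg)
      feat[id, int_cols] <- c(di$mean, di$std, di$q05, di$q25, di$q50,
                              di$q75, di$q95)
      if (sum(mask) >= S)
        feat[id, sh_cols] <- shell_intensities(mask, dimg, S)
      if (sum(mask) >= 4L)
        feat[id, har_cols] <- haralick_features(mask, dimg, levels)
      feat[id, gr_cols] <- granularity_spectrum(mask, dimg, G)
      if (!is.null(gh2ax)) {
        gi <- intensity_features(mask, gh2ax$pixels[r0:r1, c0:c1])
        feat[id, gh_cols] <- c(gi$mean, gi$std, gi$q05, gi$q25, gi$q50,
                               gi$q75, gi$q95)
      }
    }
  }
  cbind(base, qc_pass = qc_pass, as.data.frame(feat))
}
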