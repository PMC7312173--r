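# shape, Fourier descriptors, shells, Haralick, granularity, intensity

test_that("shape features match analytic values on disks and ellipses", {
  disk <- ellipse_mask(20, 20)
  sh <- shape_features(disk, pixel_size = 0.5)
  expect_within(sh$area_um2, pi * 10^2, 0.02 * pi * 100)
  expect_lt(sh$eccentricity, 0.1)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  s1 <- shape_features(single, pixel_size = 0.5)
  expect_equal(s1$area_um2, 0.25)
  expect_equal(s1$eccentricity, 0)

  ell <- ellipse_mask(40, 20)
  se <- shape_features(ell, pixel_size = 1)
  expect_within(se$eccentricity, sqrt(1 - (20 / 40)^2), 0.02)
  expect_gt(se$solidity, 0.95)
  expect_error(shape_features(matrix(FALSE, 3, 3)), "empty")
})

# analytic closed contours for the Fourier-descriptor tests
analytic_ellipse <- function(a, b, angle = 0, n = 400, scale = 1) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- scale * a * cos(t); y <- scale * b * sin(t)
  cbind(y * cos(angle) + x * sin(angle), x * cos(angle) - y * sin(angle))
}

test_that("Fourier descriptors: circle, invariance, and a direct-DFT oracle", {
  circ <- analytic_ellipse(10, 10)
  fd <- fourier_descriptors(circ, K = 16)
  expect_true(all(fd < 0.01))

  e1 <- fourier_descriptors(analytic_ellipse(20, 10, angle = 0.3), K = 16)
  e2 <- fourier_descriptors(analytic_ellipse(20, 10, angle = 1.9, scale = 2.7),
                            K = 16)
  expect_equal(e1, e2, tolerance = 1e-6)

  # oracle: direct DFT of the analytically parameterized resampled boundary.
  # For an axis-aligned ellipse sampled uniformly in arclength, compute the
  # same normalized magnitudes by explicit DFT sums.
  bnd <- analytic_ellipse(20, 10)
  z <- complex(real = bnd[, 2], imaginary = bnd[, 1])
  z <- c(z, z[1])
  s <- c(0, cumsum(Mod(diff(z))))
  M <- 256
  tq <- seq(0, s[length(s)], length.out = M + 1)[-(M + 1)]
  zr <- complex(real = approx(s, Re(z), tq)$y, imaginary = approx(s, Im(z), tq)$y)
  dft <- function(k) sum(zr * exp(-2i * pi * k * (0:(M - 1)) / M)) / M
  m1 <- max(Mod(dft(1)), Mod(dft(-1)))
  ks <- c(-1, 2, -2, 3, -3, 4, -4, 5, -5, 6, -6, 7, -7, 8, -8, 9)
  oracle <- abs(vapply(ks, function(k) Mod(dft(k)), numeric(1))) / m1
  expect_equal(fourier_descriptors(bnd, K = 16), oracle, tolerance = 1e-9)

  expect_error(fourier_descriptors(analytic_ellipse(5, 5, n = 10), K = 16),
               "contour too short")
})

test_that("shell intensities: uniform, ramp, bright rim + brute-force oracle", {
  disk <- ellipse_mask(18, 18)
  img <- matrix(7, nrow(disk), ncol(disk))
  sh <- shell_intensities(disk, img, S = 4)
  expect_true(all(abs(sh - 7) / 7 < 0.02))

  d <- slidedamage:::cpp_edt(disk)
  sh2 <- shell_intensities(disk, d, S = 4)   # intensity = distance to boundary
  expect_true(all(diff(sh2) > 0))            # increasing toward the core

  rim <- matrix(1, nrow(disk), ncol(disk))
  rim[d > 0 & d <= 3] <- 10
  sh3 <- shell_intensities(disk, rim, S = 4)
  expect_identical(which.max(sh3), 1L)
  # brute-force binning oracle on the same distance transform
  dn <- d[disk] / max(d[disk])
  bin <- pmin(4, floor(dn * 4) + 1)
  oracle <- vapply(1:4, function(s) mean(rim[disk][bin == s]), numeric(1))
  expect_equal(sh3, oracle, tolerance = 1e-12)
  expect_error(shell_intensities(matrix(c(TRUE, TRUE), 1), matrix(1, 1, 2), S = 4),
               "smaller")
})

test_that("Haralick: constant limits and hand-enumerated checkerboard GLCM", {
  m <- matrix(TRUE, 8, 8)
  h <- haralick_features(m, matrix(5, 8, 8), levels = 8)
  expect_equal(unname(h["contrast"]), 0)
  expect_equal(unname(h["asm"]), 1)
  expect_equal(unname(h["correlation"]), 0)

  chk <- matrix(rep(c(1, 2), 32), 8, 8)
  chk[, seq(2, 8, 2)] <- 3 - chk[, seq(2, 8, 2)]
  hh <- haralick_features(m, chk, levels = 2, average = FALSE)
  # hand enumeration, 0-degree offset on a 2-level checkerboard: every
  # horizontal neighbour pair is (1,2) or (2,1), so the symmetrized GLCM is
  # fully off-diagonal: contrast = 1, ASM = 2 * 0.5^2 = 0.5
  expect_equal(unname(hh[1, "contrast"]), 1)
  expect_equal(unname(hh[1, "asm"]), 0.5)
})

test_that("Haralick matches the frozen scikit-image reference to 1e-6", {
  patch <- as.matrix(read.csv(test_path("fixtures", "haralick_patch.csv"),
                              header = FALSE))
  h <- haralick_features(matrix(TRUE, 16, 16), patch, levels = 8,
                         average = FALSE)
  # reference: skimage.feature.graycomatrix/graycoprops (symmetric, normed,
  # levels = 8), computed once; offset order mapped to ours
  ref_asm <- c(0.018532986111, 0.018864197531, 0.019019097222, 0.019417283951)
  ref_contrast <- c(10.233333333333, 9.982222222222, 9.491666666667,
                    9.466666666667)
  ref_corr <- c(-0.021804175002, 0.006061774239, 0.053147860785,
                0.054640497090)
  expect_equal(unname(h[, "asm"]), ref_asm, tolerance = 1e-6)
  expect_equal(unname(h[, "contrast"]), ref_contrast, tolerance = 1e-6)
  expect_equal(unname(h[, "correlation"]), ref_corr, tolerance = 1e-6)
})

test_that("granularity: disk scale localization, zero image, scale invariance,
           and the brute-force oracle", {
  # cone-profiled spots of radius 5: all intensity is removed by opening
  # scales <= 5 (a flat disk would instead release everything at r + 1)
  img <- matrix(0, 40, 40)
  for (ctr in list(c(10, 10), c(10, 30), c(30, 10), c(30, 30))) {
    dd <- outer(seq_len(40) - ctr[1], seq_len(40) - ctr[2],
                function(y, x) sqrt(x^2 + y^2))
    img <- img + pmax(100 * (1 - dd / 5), 0)
  }
  mask <- matrix(TRUE, 40, 40)
  gs <- granularity_spectrum(mask, img, G = 8)
  expect_gt(sum(gs[1:5]), 95)        # all mass at scales <= the spot radius
  expect_lt(gs[7], 1)                # radius + 2: nothing left to remove
  expect_lte(sum(gs), 100 + 1e-9)

  expect_true(all(granularity_spectrum(mask, matrix(0, 40, 40), G = 4) == 0))
  expect_equal(granularity_spectrum(mask, img * 2, G = 8), gs,
               tolerance = 1e-12)

  set.seed(5)
  small <- matrix(runif(18 * 18, 0, 100), 18, 18)
  msk <- ellipse_mask(8, 7, n = 18)
  expect_equal(granularity_spectrum(msk, small, G = 5),
               brute_granularity(msk, small, G = 5), tolerance = 1e-10)
})

test_that("intensity features: exact small case and damage-proxy correlation", {
  m <- matrix(c(rep(TRUE, 10), rep(FALSE, 6)), 4, 4)
  f <- intensity_features(m, matrix(2, 4, 4))
  expect_equal(f$integrated, 20)
  expect_equal(f$mean, 2)
  expect_equal(f$std, 0)

  # generator oracle: integrated gH2AX / DAPI tracks true_damage_fraction
  art <- artifact_spec(background = list(enable = FALSE),
                       stripes = list(enable = FALSE),
                       gain_drift = list(enable = FALSE),
                       noise = list(shot = 0.2, read = 2),
                       damage = list(mode = "plain", amplitude = 0.9,
                                     decay_um = 400, bernoulli = FALSE))
  sim <- generate_slide(500, c(G1 = 0.5, S = 0.1, G2 = 0.4), artifacts = art,
                        confluence = 0.2, seed = 17)
  n <- nrow(sim$truth$nuclei)
  std <- slidedamage:::cpp_label_stats(sim$truth$labels, sim$dapi$pixels, n)
  stg <- slidedamage:::cpp_label_stats(sim$truth$labels, sim$gh2ax$pixels, n)
  ratio <- stg$sum / std$sum
  r <- cor(ratio, sim$truth$nuclei$true_damage_fraction, method = "spearman")
  expect_gt(r, 0.95)
})

test_that("feature extraction is deterministic, QC-aware, and equivariant", {
  sim <- clean_slide()
  crop <- function(m) m[1:300, 1:300]
  lab <- crop(sim$truth$labels)
  keep <- setdiff(unique(as.vector(lab)), 0L)
  # drop nuclei cut by the crop
  full <- table(factor(sim$truth$labels, levels = keep))
  inside <- table(factor(lab, levels = keep))
  lab[!lab %in% keep[inside == full]] <- 0L
  lab <- slidedamage:::prune_small_labels(lab, 1)
  dapi <- slide_image(crop(sim$dapi$pixels), "DAPI", 0.5)
  f1 <- extract_features(lab, dapi)
  f2 <- extract_features(lab, dapi)
  expect_identical(f1, f2)

  # intensity rescaling: shape/Fourier invariant, intensities equivariant
  dapi2 <- slide_image(crop(sim$dapi$pixels) * 3, "DAPI", 0.5)
  f3 <- extract_features(lab, dapi2)
  expect_equal(f3$i_dapi, 3 * f1$i_dapi, tolerance = 1e-12)
  expect_equal(f3$eccentricity, f1$eccentricity, tolerance = 1e-12)
  fd_cols <- grep("^fd_", names(f1), value = TRUE)
  expect_equal(f3[fd_cols], f1[fd_cols], tolerance = 1e-9)
  gr_cols <- grep("^gran_", names(f1), value = TRUE)
  expect_equal(f3[gr_cols], f1[gr_cols], tolerance = 1e-9)

  # QC-masked nucleus: flagged, features NaN
  qc <- structure(list(masked = matrix(TRUE, 1, 1), reason = matrix("blurry", 1, 1),
                       tile = 300L, pixel_size = 0.5, dim = c(300L, 300L)),
                  class = "qc_mask")
  f4 <- extract_features(lab, dapi, qc = qc)
  expect_true(all(!f4$qc_pass))
  expect_true(all(is.na(f4$eccentricity)))
})

test_that("tile-local extraction equals whole-slide extraction", {
  sim <- clean_slide()
  lab <- sim$truth$labels
  f_all <- extract_features(lab, sim$dapi)
  # pick a nucleus, extract from a tight tile around it
  id <- f_all$nucleus_id[which.max(f_all$qc_pass)]
  sel <- which(lab == id, arr.ind = TRUE)
  r0 <- max(1, min(sel[, 1]) - 8); r1 <- max(sel[, 1]) + 8
  c0 <- max(1, min(sel[, 2]) - 8); c1 <- max(sel[, 2]) + 8
  labt <- lab[r0:r1, c0:c1]
  labt[labt != id] <- 0L
  labt[labt == id] <- 1L
  ft <- extract_features(labt, slide_image(sim$dapi$pixels[r0:r1, c0:c1],
                                           "DAPI", 0.5))
  for (cn in c("area_um2", "perimeter_um", "eccentricity", "solidity",
               grep("^(fd_|shell_|har_|gran_)", names(ft), value = TRUE)))
    expect_equal(ft[[cn]], f_all[[cn]][f_all$nucleus_id == id],
                 tolerance = 1e-9, label = cn)
})
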