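# synthetic_slide: ground-truthed two-channel slide generator.
#
# The generator renders ellipse-like nuclei with per-phase DNA content
# (G2 = 2 x G1, S uniform in between, condensed mitotic morphologies per the
# five visual classes), gamma-H2AX proportional to true damage fraction x DNA
# content, and layers every slide artifact the pipeline must undo:
# foreground gain drift -> additive background surface -> fast-axis stripes ->
# local blur -> Poisson-Gaussian noise.

PHASES <- c("G1", "S", "G2", "M2", "M3", "M4", "M5")

#' Artifact specification for the synthetic slide generator
#'
#' Defaults are the generator's stated world: a smooth additive background
#' surface, a x1.2 stripe on every 64th scan line, a 0.3-amplitude sinusoidal
#' DAPI gain drift along the slow axis, Poisson-Gaussian noise, and no local
#' blur. Damage is off by default (\code{mode = "none"}).
#'
#' @param background additive background surface:
#'   \code{list(enable, dapi_level, gh2ax_level, rel_amplitude)}; the surface
#'   is \code{level * (1 + rel_amplitude * s(r, c))} with \code{s} a fixed
#'   smooth quadratic in [-1, 1].
#' @param stripes multiplicative scan-line calibration error:
#'   \code{list(enable, period, factor)} applied to every \code{period}-th
#'   scan line of both channels.
#' @param gain_drift multiplicative DAPI foreground drift along the slow axis:
#'   \code{list(enable, amplitude, cycles)} giving
#'   \code{1 + amplitude * sin(2 pi cycles t)} over the slow-axis extent.
#' @param gh2ax_offset additive per-pixel foreground offset on the gamma-H2AX
#'   channel (uneven staining): \code{list(enable, level)} counts modulated by
#'   a smooth field.
#' @param blur_regions list of \code{list(rows, cols, sigma)} rectangles
#'   blurred in place (emulates out-of-focus patches).
#' @param noise \code{list(shot, read)}: Gaussian noise with variance
#'   \code{shot * intensity + read^2}.
#' @param treatment_center_um physical (y, x) of the treatment location in
#'   micrometres, or \code{NULL} for the slide centre.
#' @param damage radial damage field parameters, see
#'   \code{\link{radial_damage_field}}: \code{list(mode, amplitude, decay_um,
#'   ring_radius_um, ring_width_um, bernoulli, min_magnitude, baseline)}.
#' @return list of class \code{artifact_spec}.
#' @export
artifact_spec <- function(background = list(),
                          stripes = list(),
                          gain_drift = list(),
                          gh2ax_offset = list(),
                          blur_regions = list(),
                          noise = list(),
                          treatment_center_um = NULL,
                          damage = list()) {
  spec <- list(
    background = modifyList(list(enable = TRUE, dapi_level = 120,
                                 gh2ax_level = 80, rel_amplitude = 0.5),
                            background),
    stripes = modifyList(list(enable = TRUE, period = 64L, factor = 1.2), stripes),
    gain_drift = modifyList(list(enable = TRUE, amplitude = 0.3, cycles = 1), gain_drift),
    gh2ax_offset = modifyList(list(enable = FALSE, level = 30), gh2ax_offset),
    blur_regions = blur_regions,
    noise = modifyList(list(shot = 0.5, read = 3), noise),
    treatment_center_um = treatment_center_um,
    damage = modifyList(list(mode = "none", amplitude = 0.7, decay_um = 1200,
                             ring_radius_um = 1000, ring_width_um = 300,
                             bernoulli = TRUE, min_magnitude = 0.25,
                             baseline = 0.02),
                        damage)
  )
  if (spec$stripes$factor <= 0) stop("stripe factor must be positive")
  if (spec$background$dapi_level < 0 || spec$background$gh2ax_level < 0)
    stop("background levels must be non-negative")
  class(spec) <- "artifact_spec"
  spec
}

#' Round-trip an artifact spec through YAML
#' @param spec \code{artifact_spec}.
#' @param path YAML file.
#' @export
write_artifact_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_artifact_spec
#' @export
read_artifact_spec <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(artifact_spec, x[setdiff(names(x), character(0))])
}

#' Radial true-damage field
#'
#' Plain mode decays monotonically from the treatment centre
#' (\code{amplitude * exp(-d / decay_um)}); ring mode is a Gaussian annulus
#' peaked at \code{ring_radius_um} (the jet-orifice radius).
#'
#' @param distance_um distance from the treatment centre, micrometres (>= 0).
#' @param params damage parameter list as in \code{\link{artifact_spec}}.
#' @return expected damage fraction in [0, 1].
#' @export
radial_damage_field <- function(distance_um, params = artifact_spec()$damage) {
  if (any(distance_um < 0)) stop("distance must be non-negative")
  p <- modifyList(artifact_spec()$damage, as.list(params))
  switch(p$mode,
    none = rep(0, length(distance_um)),
    plain = p$amplitude * exp(-distance_um / p$decay_um),
    ring = p$amplitude * exp(-(distance_um - p$ring_radius_um)^2 /
                               (2 * p$ring_width_um^2)),
    stop("unknown damage mode: ", p$mode)
  )
}

# per-phase morphology and DNA-content draws; one row per nucleus.
# Areas in um^2; dna in G1-population units (G1 mean = 1, G2 mean = 2;
# condensed mitotic figures measure ~2.3, post-anaphase halves ~1.1).
sample_morphology <- function(phases) {
  n <- length(phases)
  if (n == 0L)
    return(data.frame(phase = character(0), area_um2 = numeric(0),
                      aspect = numeric(0), dna = numeric(0),
                      speckle = numeric(0), irr_amp = numeric(0),
                      type = character(0), stringsAsFactors = FALSE))
  out <- data.frame(phase = phases, area_um2 = NA_real_, aspect = NA_real_,
                    dna = NA_real_, speckle = NA_real_, irr_amp = NA_real_,
                    type = "ellipse", stringsAsFactors = FALSE)
  for (ph in unique(phases)) {
    i <- which(phases == ph)
    m <- length(i)
    p <- switch(ph,
      G1 = list(a = rnorm(m, 170, 15), asp = runif(m, 1.0, 1.4),
                d = rnorm(m, 1.0, 0.05), sp = 0.12, irr = 0.03, ty = "ellipse"),
      S  = {
        t <- runif(m)
        list(a = (170 + 110 * t) * (1 + rnorm(m, 0, 0.08)),
             asp = runif(m, 1.0, 1.4),
             d = 1 + t + rnorm(m, 0, 0.02), sp = 0.12, irr = 0.03, ty = "ellipse")
      },
      G2 = list(a = rnorm(m, 280, 25), asp = runif(m, 1.0, 1.4),
                d = rnorm(m, 2.0, 0.10), sp = 0.12, irr = 0.03, ty = "ellipse"),
      M2 = list(a = rnorm(m, 250, 18), asp = runif(m, 1.0, 1.2),
                d = rnorm(m, 2.3, 0.10), sp = 0.40, irr = 0.14, ty = "ellipse"),
      M3 = list(a = rnorm(m, 250, 18), asp = runif(m, 2.7, 3.5),
                d = rnorm(m, 2.3, 0.10), sp = 0.32, irr = 0.08, ty = "ellipse"),
      M4 = list(a = rnorm(m, 240, 18), asp = runif(m, 1.0, 1.2),
                d = rnorm(m, 2.2, 0.10), sp = 0.32, irr = 0.10, ty = "dumbbell"),
      M5 = list(a = rnorm(m, 120, 10), asp = runif(m, 1.4, 1.9),
                d = rnorm(m, 1.1, 0.06), sp = 0.40, irr = 0.16, ty = "ellipse"),
      stop("unknown phase: ", ph))
    out$area_um2[i] <- pmax(p$a, 40)
    out$aspect[i] <- p$asp
    out$dna[i] <- pmax(p$d, 0.2)
    out$speckle[i] <- p$sp
    out$irr_amp[i] <- p$irr
    out$type[i] <- p$ty
  }
  out
}

# render one soft-edged, speckled, radius-modulated ellipse (or dumbbell)
# into a square patch; returns intensity patch (sum-normalized later), mask,
# and half-size. All lengths in pixels.
render_nucleus_patch <- function(area_px, aspect, orient, speckle_sd, irr_amp,
                                 type, edge_px = 1.2) {
  b <- sqrt(area_px / (pi * aspect))   # minor semi-axis
  a <- aspect * b                      # major semi-axis
  if (type == "dumbbell") {
    la <- sqrt(area_px / 2 / pi) * 1.05  # lobe radius (two round lobes)
    half <- ceiling(la * 2.6 + 3)
  } else {
    half <- ceiling(a * (1 + irr_amp) + edge_px + 2)
  }
  sz <- 2L * half + 1L
  dy <- matrix(rep(-half:half, sz), sz, sz)
  dx <- t(dy)
  one_lobe <- function(cy, cx, sa, sb, th, amp) {
    u <- cos(th) * (dx - cx) + sin(th) * (dy - cy)
    v <- -sin(th) * (dx - cx) + cos(th) * (dy - cy)
    q <- sqrt((u / sa)^2 + (v / sb)^2)
    if (amp > 0) {
      psi <- atan2(v / sb, u / sa)
      k <- sample(2:6, 2)
      phs <- runif(2, 0, 2 * pi)
      mod <- 1 + amp * (cos(k[1] * psi + phs[1]) + 0.6 * cos(k[2] * psi + phs[2])) / 1.6
      q <- q / mod
    }
    en <- edge_px / sqrt(sa * sb)
    s <- pmin(1, pmax(0, (1 - q) / en))
    # ground-truth extent at the half-maximum contour of the soft edge
    list(w = s * s * (3 - 2 * s), inside = q <= 1 - en / 2)
  }
  if (type == "dumbbell") {
    la <- sqrt(area_px / 2 / pi) * 1.05
    off <- 0.95 * la
    l1 <- one_lobe(-off * sin(orient), -off * cos(orient), la, la * 0.9, orient, irr_amp)
    l2 <- one_lobe(off * sin(orient), off * cos(orient), la, la * 0.9, orient, irr_amp)
    w <- pmax(l1$w, l2$w)
    inside <- l1$inside | l2$inside
  } else {
    l <- one_lobe(0, 0, a, b, orient, irr_amp)
    w <- l$w
    inside <- l$inside
  }
  if (speckle_sd > 0) {
    z <- gaussian_blur(matrix(rnorm(sz * sz), sz, sz), 1)
    z <- z / sd(z)
    w <- w * exp(speckle_sd * z - speckle_sd^2 / 2)
  }
  list(w = w, mask = inside, half = half, a = a, b = b)
}

# render a gamma-H2AX patch on the same mask: 20% diffuse + focal spots
render_gh2ax_patch <- function(mask, w, n_foci) {
  sz <- nrow(mask)
  g <- w * 0.2
  if (n_foci > 0) {
    idx <- which(mask)
    if (length(idx) > 0) {
      pick <- idx[sample.int(length(idx), n_foci, replace = TRUE)]
      spots <- matrix(0, sz, sz)
      for (p in pick) spots[p] <- spots[p] + 1
      spots <- gaussian_blur(spots, 1.5) * mask
      g <- g + spots
    }
  }
  g
}

#' Generate a ground-truthed synthetic two-channel slide
#'
#' Before artifacts, each nucleus's rendered DAPI intensity integrates exactly
#' to \code{dna_content * dapi_gain}, and its gamma-H2AX intensity to
#' \code{gh2ax_gain * dna_content * (baseline + true_damage_fraction)}.
#' Artifacts are then applied in the fixed order: DAPI foreground gain drift,
#' additive background surface, scan-line stripes, local blur, noise.
#'
#' @param n_nuclei number of nuclei to place (0 gives a blank slide).
#' @param phase_mix named probability vector over
#'   \code{c("G1","S","G2","M2","M3","M4","M5")}; must sum to 1.
#' @param artifacts an \code{\link{artifact_spec}}.
#' @param confluence fraction of slide area covered by nuclei, in (0, 1];
#'   used (with the sampled areas) to choose the slide size when \code{shape}
#'   is \code{NULL}.
#' @param pixel_size micrometres per pixel (default 0.5, a 20x scan).
#' @param shape optional c(rows, cols) in pixels; overrides \code{confluence}
#'   sizing.
#' @param seed integer seed; identical seeds reproduce bit-identical slides.
#' @param dapi_gain integrated DAPI counts per unit DNA content.
#' @param gh2ax_gain integrated gamma-H2AX counts per unit (DNA x damage).
#' @param sep_frac minimum centre separation as a fraction of the sum of
#'   effective radii (< 1 permits overlaps).
#' @param max_retries placement retries per nucleus before failing with the
#'   achieved confluence.
#' @return list with \code{dapi}, \code{gh2ax} (\code{slide_image}s) and
#'   \code{truth}: \code{nuclei} data frame (one row per nucleus: id, phase,
#'   centre, axes, orientation, dna_content, true_damage_fraction,
#'   distance_um, integrated pre-artifact intensities), \code{labels} integer
#'   raster, and the realized \code{artifacts}.
#' @export
generate_slide <- function(n_nuclei,
                           phase_mix = c(G1 = 0.55, S = 0.12, G2 = 0.27,
                                         M2 = 0.015, M3 = 0.015, M4 = 0.015,
                                         M5 = 0.015),
                           artifacts = artifact_spec(),
                           confluence = 0.25,
                           pixel_size = 0.5,
                           shape = NULL,
                           seed = 1,
                           dapi_gain = 4e5,
                           gh2ax_gain = 2e5,
                           sep_frac = 0.95,
                           max_retries = 1000L) {
  stopifnot(n_nuclei >= 0, confluence > 0, confluence <= 1)
  if (!all(names(phase_mix) %in% PHASES) || is.null(names(phase_mix)))
    stop("phase_mix must be named with phases among: ", paste(PHASES, collapse = ", "))
  if (abs(sum(phase_mix) - 1) > 1e-8) stop("phase_mix must sum to 1")
  set.seed(as.integer(seed))

  # phase draws and morphologies
  phases <- if (n_nuclei > 0)
    sample(names(phase_mix), n_nuclei, replace = TRUE, prob = phase_mix)
  else character(0)
  morph <- sample_morphology(phases)
  area_px <- morph$area_um2 / pixel_size^2
  eff_r <- sqrt(area_px / pi) * sqrt(morph$aspect)   # effective max radius

  if (is.null(shape)) {
    tot <- sum(area_px)
    side <- if (n_nuclei > 0) ceiling(sqrt(tot / confluence)) else 512
    shape <- c(side, side)
  }
  nr <- shape[1]; nc <- shape[2]
  margin <- if (n_nuclei > 0) ceiling(max(eff_r) + 4) else 8
  if (n_nuclei > 0 && (nr - 2 * margin < 2 || nc - 2 * margin < 2))
    stop("slide too small for the requested nuclei")

  # treatment centre and per-nucleus damage
  tc_um <- artifacts$treatment_center_um %||% (c(nr, nc) / 2 * pixel_size)

  # --- placement: dart throwing with a spatial hash ---------------------------
  centers <- matrix(NA_real_, n_nuclei, 2)
  if (n_nuclei > 0) {
    cell <- max(2 * max(eff_r), 8)
    grid_nr <- max(1L, ceiling(nr / cell)); grid_nc <- max(1L, ceiling(nc / cell))
    bucket <- vector("list", grid_nr * grid_nc)
    bkey <- function(y, x) {
      gi <- pmin(pmax(ceiling(y / cell), 1L), grid_nr)
      gj <- pmin(pmax(ceiling(x / cell), 1L), grid_nc)
      (gj - 1L) * grid_nr + gi
    }
    ok_at <- function(i, y, x, partner = 0L) {
      gi <- ceiling(y / cell); gj <- ceiling(x / cell)
      for (di in -1:1) for (dj in -1:1) {
        ii <- gi + di; jj <- gj + dj
        if (ii < 1 || ii > grid_nr || jj < 1 || jj > grid_nc) next
        for (j in bucket[[(jj - 1L) * grid_nr + ii]]) {
          if (j == partner) next
          d2 <- (y - centers[j, 1])^2 + (x - centers[j, 2])^2
          lim <- sep_frac * (eff_r[i] + eff_r[j])
          if (d2 < lim^2) return(FALSE)
        }
      }
      TRUE
    }
    # pair up M5 halves: consecutive M5 indices placed adjacently
    m5 <- which(phases == "M5")
    partner <- integer(n_nuclei)
    if (length(m5) >= 2) {
      np <- (length(m5) %/% 2) * 2
      for (k in seq(1, np, by = 2)) {
        partner[m5[k]] <- m5[k + 1]
        partner[m5[k + 1]] <- m5[k]
      }
    }
    placed <- 0L
    for (i in seq_len(n_nuclei)) {
      pa <- partner[i]
      done <- FALSE
      for (try in seq_len(max_retries)) {
        if (pa > 0L && pa < i && !is.na(centers[pa, 1])) {
          ang <- runif(1, 0, 2 * pi)
          dst <- 1.18 * (eff_r[i] + eff_r[pa])
          y <- centers[pa, 1] + dst * sin(ang)
          x <- centers[pa, 2] + dst * cos(ang)
          if (y < margin || y > nr - margin || x < margin || x > nc - margin) next
          if (!ok_at(i, y, x, partner = pa)) next
        } else {
          y <- runif(1, margin, nr - margin)
          x <- runif(1, margin, nc - margin)
          if (!ok_at(i, y, x)) next
        }
        centers[i, ] <- c(y, x)
        b <- bkey(y, x)
        bucket[[b]] <- c(bucket[[b]], i)
        placed <- placed + 1L
        done <- TRUE
        break
      }
      if (!done)
        stop(sprintf(paste0("placement failed for nucleus %d after %d retries; ",
                            "achieved confluence %.3f of requested %.3f -- ",
                            "lower confluence or n_nuclei"),
                     i, max_retries, sum(area_px[seq_len(placed)]) / (nr * nc),
                     confluence))
    }
  }

  # damage draws
  dist_um <- if (n_nuclei > 0)
    sqrt((centers[, 1] * pixel_size - tc_um[1])^2 +
         (centers[, 2] * pixel_size - tc_um[2])^2)
  else numeric(0)
  dmg <- artifacts$damage
  f_expect <- if (dmg$mode == "none") rep(0, n_nuclei) else
    radial_damage_field(dist_um, dmg)
  damage_frac <- if (dmg$mode == "none") rep(0, n_nuclei) else if (isTRUE(dmg$bernoulli)) {
    hit <- rbinom(n_nuclei, 1, pmin(1, f_expect))
    hit * runif(n_nuclei, dmg$min_magnitude, 1)
  } else {
    pmin(1, pmax(0, f_expect * (1 + rnorm(n_nuclei, 0, 0.15))))
  }

  # --- render -----------------------------------------------------------------
  dapi <- matrix(0, nr, nc)
  gh2ax <- matrix(0, nr, nc)
  labels <- matrix(0L, nr, nc)
  orient <- runif(max(n_nuclei, 1), 0, pi)
  rendered_area <- numeric(n_nuclei)
  maj <- numeric(n_nuclei); mnr <- numeric(n_nuclei)
  for (i in seq_len(n_nuclei)) {
    p <- render_nucleus_patch(area_px[i], morph$aspect[i], orient[i],
                              morph$speckle[i], morph$irr_amp[i], morph$type[i])
    tot_w <- sum(p$w)
    if (tot_w <= 0) next
    w <- p$w * (morph$dna[i] * dapi_gain / tot_w)
    i_gh <- gh2ax_gain * morph$dna[i] * (dmg$baseline + damage_frac[i])
    n_foci <- if (damage_frac[i] > 0) max(1L, round(30 * damage_frac[i])) else 0L
    g <- render_gh2ax_patch(p$mask, p$w, n_foci)
    sg <- sum(g)
    g <- if (sg > 0) g * (i_gh / sg) else g
    r0 <- round(centers[i, 1]) - p$half; c0 <- round(centers[i, 2]) - p$half
    rr <- r0:(r0 + 2 * p$half); cc <- c0:(c0 + 2 * p$half)
    sel_r <- rr >= 1 & rr <= nr; sel_c <- cc >= 1 & cc <= nc
    dapi[rr[sel_r], cc[sel_c]] <- dapi[rr[sel_r], cc[sel_c]] + w[sel_r, sel_c]
    gh2ax[rr[sel_r], cc[sel_c]] <- gh2ax[rr[sel_r], cc[sel_c]] + g[sel_r, sel_c]
    lab_patch <- labels[rr[sel_r], cc[sel_c]]
    msk <- p$mask[sel_r, sel_c]
    lab_patch[msk] <- i
    labels[rr[sel_r], cc[sel_c]] <- lab_patch
    rendered_area[i] <- sum(p$mask)
    maj[i] <- p$a; mnr[i] <- p$b
  }

  # --- artifacts ----------------------------------------------------------------
  # slow-axis coordinate (t in [0,1]) per scan line; fast_axis = "cols" so scan
  # lines are rows
  slow_t <- (seq_len(nr) - 0.5) / nr
  gd <- artifacts$gain_drift
  if (isTRUE(gd$enable) && gd$amplitude != 0) {
    gcurve <- 1 + gd$amplitude * sin(2 * pi * gd$cycles * slow_t)
    dapi <- dapi * gcurve   # row-wise multiply (foreground only: bg added later)
  }
  go <- artifacts$gh2ax_offset
  if (isTRUE(go$enable) && go$level != 0) {
    field <- smooth_field(nr, nc, 1)
    gh2ax <- gh2ax + (labels > 0L) * go$level * (1 + field) / 2
  }
  bg <- artifacts$background
  bg_dapi <- bg_gh <- matrix(0, nr, nc)
  if (isTRUE(bg$enable)) {
    s <- smooth_field(nr, nc, 2)
    bg_dapi <- bg$dapi_level * (1 + bg$rel_amplitude * s)
    bg_gh <- bg$gh2ax_level * (1 + bg$rel_amplitude * s)
    dapi <- dapi + bg_dapi
    gh2ax <- gh2ax + bg_gh
  }
  st <- artifacts$stripes
  stripe_lines <- integer(0)
  if (isTRUE(st$enable) && st$factor != 1) {
    stripe_lines <- seq.int(st$period, nr, by = st$period)
    dapi[stripe_lines, ] <- dapi[stripe_lines, ] * st$factor
    gh2ax[stripe_lines, ] <- gh2ax[stripe_lines, ] * st$factor
  }
  for (br in artifacts$blur_regions) {
    rr <- max(1, br$rows[1]):min(nr, br$rows[2])
    cc <- max(1, br$cols[1]):min(nc, br$cols[2])
    dapi[rr, cc] <- gaussian_blur(dapi[rr, cc], br$sigma)
    gh2ax[rr, cc] <- gaussian_blur(gh2ax[rr, cc], br$sigma)
  }
  nz <- artifacts$noise
  if (nz$shot > 0 || nz$read > 0) {
    dapi <- pmax(dapi + rnorm(nr * nc, 0, sqrt(pmax(nz$shot * dapi, 0) + nz$read^2)), 0)
    gh2ax <- pmax(gh2ax + rnorm(nr * nc, 0, sqrt(pmax(nz$shot * gh2ax, 0) + nz$read^2)), 0)
  }

  nuc <- data.frame(
    nucleus_id = seq_len(n_nuclei),
    phase = phases,
    center_row = if (n_nuclei) centers[, 1] else numeric(0),
    center_col = if (n_nuclei) centers[, 2] else numeric(0),
    major_px = maj, minor_px = mnr,
    orientation = orient[seq_len(n_nuclei)],
    area_px = rendered_area,
    dna_content = morph$dna,
    true_damage_fraction = damage_frac,
    distance_um = dist_um,
    i_dapi_true = morph$dna * dapi_gain,
    i_gh2ax_true = gh2ax_gain * morph$dna * (dmg$baseline + damage_frac),
    stringsAsFactors = FALSE
  )
  list(
    dapi = slide_image(dapi, "DAPI", pixel_size),
    gh2ax = slide_image(gh2ax, "gH2AX", pixel_size),
    truth = list(nuclei = nuc, labels = labels, artifacts = artifacts,
                 treatment_center_um = tc_um,
                 params = list(seed = seed, dapi_gain = dapi_gain,
                               gh2ax_gain = gh2ax_gain, pixel_size = pixel_size,
                               stripe_lines = stripe_lines, shape = c(nr, nc)))
  )
}

# deterministic smooth field in [-1, 1] over the raster (fixed low-order
# polynomial; `flavour` switches the coefficients so DAPI and gH2AX offsets
# differ)
smooth_field <- function(nr, nc, flavour = 1) {
  y <- (seq_len(nr) - 0.5) / nr * 2 - 1
  x <- (seq_len(nc) - 0.5) / nc * 2 - 1
  if (flavour == 1) {
    f <- outer(y, x, function(u, v) 0.7 * u + 0.5 * v - 0.6 * u * v)
  } else {
    f <- outer(y, x, function(u, v) 0.6 * u^2 - 0.5 * v + 0.4 * u * v - 0.3 * v^2)
  }
  f / max(abs(f))
}

#' Write the ground truth of a synthetic slide
#'
#' Label map as 32-bit TIFF plus a CSV table, one row per nucleus.
#' @param truth \code{truth} element of \code{\link{generate_slide}} output.
#' @param dir output directory.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_map(truth$labels, file.path(dir, "labels.tif"))
  write_nucleus_table(truth$nuclei, file.path(dir, "nuclei.csv"))
  invisible(dir)
}
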