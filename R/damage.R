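# damage_quantification: per-nucleus damage on the 0-150 scale, control
# baseline subtraction, damage ratios, and spatially binned maps centered on
# the treatment location.

#' Calibrate the damage scale
#'
#' The raw damage statistic is the ratio of corrected integrated intensities
#' I_gH2AX / I_DAPI. The printed scale runs 0-150; the calibration maps the
#' treated cohort's 99.9th ratio percentile to 150, so the damage-ratio
#' threshold of 75 reads as "half of maximal damage". Persist the returned
#' scale to compare slides.
#'
#' @param i_gh2ax,i_dapi corrected integrated intensities of the treated
#'   cohort.
#' @param probs calibration percentile.
#' @return scalar scale factor.
#' @export
calibrate_damage_scale <- function(i_gh2ax, i_dapi, probs = 0.999) {
  ok <- is.finite(i_gh2ax) & is.finite(i_dapi) & i_dapi > 0
  if (!any(ok)) stop("no valid records to calibrate the damage scale")
  q <- quantile(i_gh2ax[ok] / i_dapi[ok], probs, names = FALSE)
  if (q <= 0) stop("calibration percentile of the damage ratio is not positive")
  150 / q
}

#' Per-nucleus damage value
#'
#' \code{damage = clamp(scale * I_gH2AX / I_DAPI, 0, 150)}. Records with
#' non-positive I_DAPI are invalid (NA) and excluded from maps.
#'
#' @param i_gh2ax,i_dapi corrected integrated intensities (gamma-H2AX already
#'   baseline-flattened and clipped at 0).
#' @param scale calibration factor, see \code{\link{calibrate_damage_scale}}.
#' @return numeric vector in [0, 150]; NA for invalid records.
#' @export
damage_value <- function(i_gh2ax, i_dapi, scale) {
  out <- rep(NA_real_, length(i_gh2ax))
  ok <- is.finite(i_gh2ax) & is.finite(i_dapi) & i_dapi > 0
  out[ok] <- pmin(150, pmax(0, scale * i_gh2ax[ok] / i_dapi[ok]))
  out
}

#' Subtract the flow-control median damage
#'
#' @param treated damage values of the treated cohort.
#' @param control damage values of the flow-control cohort (gas flow, no
#'   plasma).
#' @return adjusted damage, floored at 0.
#' @export
subtract_control_baseline <- function(treated, control) {
  control <- control[is.finite(control)]
  if (length(control) == 0L) stop("control cohort is empty")
  pmax(0, treated - median(control))
}

#' Damage ratio
#'
#' Fraction of cells whose damage value strictly exceeds the threshold
#' (ties count as undamaged).
#'
#' @param damage damage values (0-150 scale).
#' @param threshold damage threshold; default 75.
#' @return scalar in [0, 1].
#' @export
damage_ratio <- function(damage, threshold = 75) {
  damage <- damage[is.finite(damage)]
  if (length(damage) == 0L) stop("damage ratio of an empty cohort is undefined")
  mean(damage > threshold)
}

#' Build a spatial damage map
#'
#' Square grid of \code{bin_mm} bins covering a disk of \code{diameter_mm}
#' centered on the treatment location; each QC-passing cell is assigned to
#' the bin containing its centroid and the per-bin statistic is the mean (or
#' median) damage or the damage ratio. Bins outside the disk, with no cells,
#' or QC-masked are missing (rendered white).
#'
#' @param records table with \code{x_um}, \code{y_um}, \code{damage},
#'   \code{phase} (and optionally \code{qc_pass}).
#' @param treatment_center_um physical (x, y) of the treatment location,
#'   micrometres.
#' @param diameter_mm map diameter (paper layout: 18 mm disks).
#' @param bin_mm bin side.
#' @param statistic \code{"mean_damage"}, \code{"median_damage"} or
#'   \code{"DR"}.
#' @param phase_filter \code{"all"} or one of \code{"G1"}, \code{"S"},
#'   \code{"G2"}, \code{"M"}.
#' @param threshold DR threshold (damage units, default 75).
#' @param qc optional \code{\link{qc_mask}} whose masked tiles knock out bins
#'   (bin centres are tested); requires records in the same pixel frame.
#' @return object of class \code{damage_map}: \code{value} and \code{count}
#'   matrices, \code{reason} matrix (\code{ok}, \code{outside},
#'   \code{no_cells}, \code{qc}), bin centres (micrometres, slide frame), and
#'   the build parameters.
#' @export
build_damage_map <- function(records, treatment_center_um, diameter_mm = 18,
                             bin_mm = 0.25,
                             statistic = c("DR", "mean_damage", "median_damage"),
                             phase_filter = "all", threshold = 75, qc = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("x_um", "y_um", "damage") %in% names(records)))
  rad_um <- diameter_mm * 1000 / 2
  bin_um <- bin_mm * 1000
  nb <- ceiling(diameter_mm / bin_mm)
  cx <- treatment_center_um[1]; cy <- treatment_center_um[2]
  edge_x <- cx - nb * bin_um / 2 + (0:nb) * bin_um
  edge_y <- cy - nb * bin_um / 2 + (0:nb) * bin_um
  ctr_x <- (edge_x[-1] + edge_x[-(nb + 1)]) / 2
  ctr_y <- (edge_y[-1] + edge_y[-(nb + 1)]) / 2
  sel <- is.finite(records$damage)
  if (!is.null(records$qc_pass)) sel <- sel & records$qc_pass
  if (phase_filter != "all") {
    if (is.null(records$phase)) stop("records carry no phase column")
    sel <- sel & !is.na(records$phase) & records$phase == phase_filter
    if (!any(sel)) warning("phase_filter = ", phase_filter,
                           " matches no cells; map is all-missing")
  }
  rec <- records[sel, , drop = FALSE]
  bx <- findInterval(rec$x_um, edge_x, rightmost.closed = TRUE)
  by <- findInterval(rec$y_um, edge_y, rightmost.closed = TRUE)
  inside <- bx >= 1 & bx <= nb & by >= 1 & by <= nb
  value <- matrix(NA_real_, nb, nb)
  count <- matrix(0L, nb, nb)
  reason <- matrix("no_cells", nb, nb)
  disk <- outer(ctr_y, ctr_x, function(y, x) sqrt((x - cx)^2 + (y - cy)^2)) <= rad_um
  reason[!disk] <- "outside"
  if (any(inside)) {
    key <- (bx[inside] - 1L) * nb + by[inside]
    dmg <- rec$damage[inside]
    for (k in unique(key)) {
      i <- ((k - 1L) %% nb) + 1L
      j <- ((k - 1L) %/% nb) + 1L
      if (!disk[i, j]) next
      v <- dmg[key == k]
      count[i, j] <- length(v)
      value[i, j] <- switch(statistic,
                            DR = mean(v > threshold),
                            mean_damage = mean(v),
                            median_damage = median(v))
      reason[i, j] <- "ok"
    }
  }
  if (!is.null(qc)) {
    ps <- qc$pixel_size
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      if (!disk[i, j]) next
      if (qc_masked_at(qc, ctr_y[i] / ps, ctr_x[j] / ps)) {
        value[i, j] <- NA_real_
        reason[i, j] <- "qc"
      }
    }
  }
  structure(list(value = value, count = count, reason = reason,
                 centers_x_um = ctr_x, centers_y_um = ctr_y,
                 treatment_center_um = c(cx, cy), diameter_mm = diameter_mm,
                 bin_mm = bin_mm, statistic = statistic,
                 phase_filter = phase_filter, threshold = threshold),
            class = "damage_map")
}

#' @export
print.damage_map <- function(x, ...) {
  cat(sprintf("damage_map: %s (%s phase), %d x %d bins of %.2f mm, %d cells binned\n",
              x$statistic, x$phase_filter, nrow(x$value), ncol(x$value),
              x$bin_mm, sum(x$count)))
  invisible(x)
}

#' Azimuthally averaged radial profile of a damage map
#'
#' @param map \code{damage_map}.
#' @param n_rings number of radial rings.
#' @return data frame: ring centre radius (micrometres), mean statistic over
#'   non-missing bins, bin count.
#' @export
map_radial_profile <- function(map, n_rings = NULL) {
  r <- outer(map$centers_y_um - map$treatment_center_um[2],
             map$centers_x_um - map$treatment_center_um[1],
             function(y, x) sqrt(x^2 + y^2))
  rmax <- map$diameter_mm * 1000 / 2
  n_rings <- n_rings %||% max(4L, floor(rmax / (map$bin_mm * 1000)))
  edges <- seq(0, rmax, length.out = n_rings + 1L)
  ring <- findInterval(r, edges, rightmost.closed = TRUE)
  ok <- !is.na(map$value)
  data.frame(
    r_um = (edges[-1] + edges[-(n_rings + 1L)]) / 2,
    value = vapply(seq_len(n_rings), function(k) {
      v <- map$value[ok & ring == k]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    n_bins = vapply(seq_len(n_rings), function(k) sum(ok & ring == k), numeric(1))
  )
}

#' Export a damage map as CSV grid and PNG image
#'
#' Missing bins are empty in the CSV and white in the PNG.
#'
#' @param map \code{damage_map}.
#' @param path_csv,path_png output paths (either may be \code{NULL}).
#' @param zmax colour scale maximum; default the statistic's natural range.
#' @export
export_damage_map <- function(map, path_csv = NULL, path_png = NULL, zmax = NULL) {
  if (!is.null(path_csv)) {
    m <- map$value
    dimnames(m) <- list(sprintf("y_%g", map$centers_y_um),
                        sprintf("x_%g", map$centers_x_um))
    write.csv(m, path_csv, na = "")
  }
  if (!is.null(path_png)) {
    zmax <- zmax %||% if (map$statistic == "DR") 1 else 150
    v <- map$value / zmax
    v[v > 1] <- 1
    img <- array(1, dim = c(nrow(v), ncol(v), 3))   # white background
    ok <- !is.na(v)
    # blue -> red colour ramp on valid bins
    img[, , 1][ok] <- v[ok]
    img[, , 2][ok] <- 0.2
    img[, , 3][ok] <- 1 - v[ok]
    png::writePNG(img, path_png)
  }
  invisible(map)
}
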