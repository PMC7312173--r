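# slide_io: slide containers, TIFF round-trips, tiling, quality-control masks

#' Construct a slide image
#'
#' A channel-tagged 2D intensity raster with physical metadata. Intensities
#' must be finite and non-negative (fluorescence counts).
#'
#' @param pixels numeric matrix \code{[row, col]}.
#' @param channel \code{"DAPI"} or \code{"gH2AX"}.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param fast_axis \code{"cols"} (default; each row is one scan line) or
#'   \code{"rows"}; see the package help page for the convention.
#' @param origin physical (y, x) offset of pixel (1,1) in micrometres.
#' @return object of class \code{slide_image}.
#' @export
slide_image <- function(pixels, channel = c("DAPI", "gH2AX"),
                        pixel_size, fast_axis = c("cols", "rows"),
                        origin = c(0, 0)) {
  channel <- match.arg(channel)
  fast_axis <- match.arg(fast_axis)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (micrometres/pixel)")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("slide intensities must be finite and non-negative")
  structure(
    list(pixels = pixels, channel = channel, pixel_size = pixel_size,
         fast_axis = fast_axis, origin = as.numeric(origin)),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("slide_image: %s channel, %d x %d px (%.2f x %.2f mm), %.3g um/px, fast axis = %s\n",
              x$channel, nrow(x$pixels), ncol(x$pixels),
              nrow(x$pixels) * x$pixel_size / 1000,
              ncol(x$pixels) * x$pixel_size / 1000,
              x$pixel_size, x$fast_axis))
  invisible(x)
}

# slow-axis physical position (um) of given row/col centroids
slow_axis_position <- function(image, row, col) {
  if (image$fast_axis == "cols") row * image$pixel_size else col * image$pixel_size
}

#' Read a whole-slide channel from TIFF
#'
#' 8- and 16-bit data are promoted to double without any rescaling (an 8-bit
#' value of 200 stays 200).
#'
#' @param path grayscale TIFF file.
#' @inheritParams slide_image
#' @return \code{slide_image}.
#' @export
read_slide <- function(path, channel = c("DAPI", "gH2AX"), pixel_size = NULL,
                       fast_axis = c("cols", "rows"), origin = c(0, 0)) {
  channel <- match.arg(channel)
  fast_axis <- match.arg(fast_axis)
  if (is.null(pixel_size))
    stop("pixel size metadata is not stored in plain TIFF; pass pixel_size= ",
         "(micrometres per pixel, e.g. pixel_size = 0.5)")
  px <- read_tiff(path)
  slide_image(px, channel, pixel_size, fast_axis, origin)
}

#' Write a slide channel to TIFF
#'
#' @param image \code{slide_image}.
#' @param path output file.
#' @param format storage format; \code{"uint16"} (default) rounds and clamps,
#'   \code{"float32"} stores corrected intensities losslessly to float precision.
#' @export
write_slide <- function(image, path, format = c("uint16", "uint8", "float32")) {
  stopifnot(inherits(image, "slide_image"))
  write_tiff(image$pixels, path, match.arg(format))
}

#' Read / write a nucleus label map (32-bit integer TIFF)
#' @param path TIFF file.
#' @return integer matrix; 0 = background, k > 0 = nucleus k.
#' @export
read_label_map <- function(path) {
  m <- read_tiff(path)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_label_map
#' @param labels integer matrix.
#' @export
write_label_map <- function(labels, path) {
  write_tiff(labels, path, "int32")
}

#' Tile a large raster
#'
#' Covers the full raster with tiles of side \code{tile} whose starts advance
#' by \code{tile - overlap}; the final tile in each direction is shortened to
#' the image edge. Offsets map tile-local to slide coordinates exactly.
#'
#' @param image \code{slide_image} or a matrix.
#' @param tile tile side in pixels; a tile larger than the image yields a
#'   single tile.
#' @param overlap overlap in pixels; must satisfy \code{tile > 2 * overlap}.
#' @return list of tiles, each \code{list(rows = c(r0, r1), cols = c(c0, c1),
#'   offset = c(row0 - 1, col0 - 1))} in 1-based pixel indices.
#' @export
tile_iterator <- function(image, tile = 2048L, overlap = 128L) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  if (tile <= 2 * overlap) stop("tile must exceed 2 * overlap")
  nr <- nrow(px); nc <- ncol(px)
  starts <- function(n) {
    if (tile >= n) return(1L)
    s <- seq.int(1L, n, by = tile - overlap)
    s[s + tile - 1L <= n | s == s[1]] -> s
    if (tail(s, 1) + tile - 1L < n) s <- c(s, n - tile + 1L)
    unique(s)
  }
  rs <- starts(nr); cs <- starts(nc)
  out <- vector("list", length(rs) * length(cs))
  k <- 0L
  for (r0 in rs) for (c0 in cs) {
    k <- k + 1L
    r1 <- min(r0 + tile - 1L, nr); c1 <- min(c0 + tile - 1L, nc)
    out[[k]] <- list(rows = c(r0, r1), cols = c(c0, c1), offset = c(r0 - 1L, c0 - 1L))
  }
  out
}

#' Stitch tile matrices back into a full raster
#'
#' Each pixel is taken from the tile whose non-overlapping core owns it, so
#' tiling followed by stitching reproduces the input exactly.
#'
#' @param tiles output of \code{\link{tile_iterator}} where each element has
#'   gained a \code{data} matrix of the tile's pixels.
#' @param dim full raster dimensions \code{c(nrow, ncol)}.
#' @export
stitch_tiles <- function(tiles, dim) {
  out <- matrix(NA_real_, dim[1], dim[2])
  for (t in tiles) {
    stopifnot(!is.null(t$data))
    out[t$rows[1]:t$rows[2], t$cols[1]:t$cols[2]] <- t$data
  }
  if (anyNA(out)) stop("tiles do not cover the raster")
  out
}

# discrete Laplacian (4-neighbour), interior pixels only
laplacian <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) return(matrix(0, 0, 0))
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  4 * img[i, j] - img[i - 1, j] - img[i + 1, j] - img[i, j - 1] - img[i, j + 1]
}

# normalized variance-of-Laplacian focus metric (invariant to intensity scale)
focus_metric <- function(img) {
  lp <- laplacian(img)
  m <- mean(img)
  if (length(lp) == 0 || m <= 0) return(0)
  stats::var(as.vector(lp)) / m^2
}

#' Quality-control mask for unusable slide regions
#'
#' Flags tiles that contain too few nuclei (\code{no_cells}) or whose
#' variance-of-Laplacian focus metric falls below a threshold (\code{blurry});
#' both kinds of tile are discarded from damage maps.
#'
#' @param image DAPI \code{slide_image}.
#' @param labels nucleus label map (integer matrix) used for the density test;
#'   \code{NULL} skips the density test.
#' @param tile tile side in pixels.
#' @param density_threshold minimum nuclei per square millimetre.
#' @param focus_threshold minimum normalized focus metric; tiles below are
#'   \code{blurry}. \code{NULL} skips the focus test.
#' @return object of class \code{qc_mask}: logical \code{masked} matrix over
#'   the tile grid, a parallel \code{reason} matrix (\code{"ok"},
#'   \code{"no_cells"}, \code{"blurry"}), tile size and pixel size.
#' @export
qc_mask <- function(image, labels = NULL, tile = 512L,
                    density_threshold = 10, focus_threshold = NULL) {
  stopifnot(inherits(image, "slide_image"))
  px <- image$pixels
  nrt <- ceiling(nrow(px) / tile); nct <- ceiling(ncol(px) / tile)
  masked <- matrix(FALSE, nrt, nct)
  reason <- matrix("ok", nrt, nct)
  cent <- NULL
  if (!is.null(labels) && max(labels) > 0L) {
    st <- cpp_label_stats(labels, matrix(0, 0, 0), max(labels))
    keep <- st$count > 0
    cent <- cbind(st$rmean[keep] / st$count[keep], st$cmean[keep] / st$count[keep])
  }
  mm2_per_tile_full <- (tile * image$pixel_size / 1000)^2
  for (i in seq_len(nrt)) for (j in seq_len(nct)) {
    r0 <- (i - 1L) * tile + 1L; r1 <- min(i * tile, nrow(px))
    c0 <- (j - 1L) * tile + 1L; c1 <- min(j * tile, ncol(px))
    area_mm2 <- ((r1 - r0 + 1) * (c1 - c0 + 1)) * (image$pixel_size / 1000)^2
    if (!is.null(labels)) {
      n <- if (is.null(cent)) 0L else
        sum(cent[, 1] >= r0 & cent[, 1] <= r1 & cent[, 2] >= c0 & cent[, 2] <= c1)
      if (n / area_mm2 < density_threshold) {
        masked[i, j] <- TRUE; reason[i, j] <- "no_cells"
        next
      }
    }
    if (!is.null(focus_threshold)) {
      if (focus_metric(px[r0:r1, c0:c1]) < focus_threshold) {
        masked[i, j] <- TRUE; reason[i, j] <- "blurry"
      }
    }
  }
  structure(list(masked = masked, reason = reason, tile = as.integer(tile),
                 pixel_size = image$pixel_size, dim = dim(px)),
            class = "qc_mask")
}

# is a pixel position (row, col) inside a masked QC tile?
qc_masked_at <- function(qc, row, col) {
  if (is.null(qc)) return(rep(FALSE, length(row)))
  i <- pmin(pmax(ceiling(row / qc$tile), 1L), nrow(qc$masked))
  j <- pmin(pmax(ceiling(col / qc$tile), 1L), ncol(qc$masked))
  qc$masked[cbind(i, j)]
}

#' Write / read a per-nucleus table as CSV
#'
#' Column order is stable and documented in the vignette.
#' @param records data frame of nucleus records.
#' @param path CSV path.
#' @export
write_nucleus_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nucleus_table
#' @export
read_nucleus_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
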