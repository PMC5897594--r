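#' Read a labelled segmentation image
#'
#' Reads an integer cell-ID raster (0 = background) from TIFF or PNG. TIFF
#' files are read with `as.is = TRUE` so stored integer labels survive; PNG
#' intensities in \[0, 1\] are rescaled back to integers from the file bit
#' depth. A numeric matrix can also be passed straight through.
#'
#' @param path Path to a TIFF or PNG label image, or an integer matrix.
#' @param pixel_size Physical side length of one pixel (default 1).
#' @return An integer matrix of class `label_image` with attribute
#'   `pixel_size`.
#' @export
read_label_image <- function(path, pixel_size = 1) {
  if (is.matrix(path)) {
    m <- path
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- tiff::readTIFF(path, as.is = TRUE)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    if (max(m) <= 1) m <- m * 65535
  } else {
    abort(paste0("unsupported image format: ", path))
  }
  if (length(dim(m)) == 3) m <- m[, , 1]
  label_image(round(m), pixel_size = pixel_size)
}

#' @rdname read_label_image
#' @param m Integer matrix of cell IDs.
#' @export
label_image <- function(m, pixel_size = 1) {
  m <- matrix(as.integer(round(m)), nrow(m), ncol(m))
  if (any(m < 0)) abort("label image IDs must be non-negative")
  class(m) <- c("label_image", class(m))
  attr(m, "pixel_size") <- pixel_size
  m
}

#' Write a label image as 16-bit TIFF
#'
#' @param image A `label_image` or integer matrix.
#' @param path Output TIFF path.
#' @export
write_label_image <- function(image, path) {
  m <- unclass(image)
  attr(m, "pixel_size") <- NULL
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

# pixel-centre coordinates: x = column index, y = nrow - row + 1 (y up)
label_matrix_to_xy <- function(m) {
  list(x = seq_len(ncol(m)), y = seq_len(nrow(m)))
}

#' Extract one closed contour per connected cell region
#'
#' Traces the boundary of every connected region of every nonzero ID with a
#' marching-squares iso-contour at level 0.5 of the region's indicator, so
#' vertices sit at sub-pixel positions on pixel-edge midpoints
#' (pixel-centre convention, x right / y up). Contours are returned
#' counter-clockwise. Regions touching the image border are returned but
#' flagged; regions that trace to fewer than 3 vertices are skipped with a
#' warning.
#'
#' @param image A `label_image` (or integer matrix of IDs, 0 = background).
#' @param pixel_size Physical length per pixel; defaults to the image
#'   attribute or 1.
#' @param min_pixels Regions smaller than this many pixels are skipped with a
#'   warning (default 1, i.e. keep everything traceable).
#' @return A tibble with one row per region: `cell_id`, `component`,
#'   `area_px` (pixel count), `border` (logical), and a list-column `contour`
#'   of contour tibbles in physical units.
#' @export
extract_contours <- function(image, pixel_size = NULL, min_pixels = 1) {
  m <- unclass(image)
  if (is.null(pixel_size)) {
    pixel_size <- attr(image, "pixel_size")
    if (is.null(pixel_size)) pixel_size <- 1
  }
  ids <- sort(unique(as.vector(m)))
  ids <- ids[ids != 0]
  if (!length(ids)) abort("no cells: label image contains no nonzero IDs")
  nr <- nrow(m)
  nc <- ncol(m)
  rows <- list()
  for (id in ids) {
    mask <- m == id
    lab <- EBImage::bwlabel(matrix(as.numeric(mask), nr, nc))
    ncomp <- max(lab)
    for (k in seq_len(ncomp)) {
      comp <- lab == k
      npx <- sum(comp)
      if (npx < min_pixels) {
        warn(sprintf("cell %d component %d: only %d pixel(s); skipped",
                     id, k, npx))
        next
      }
      border <- any(comp[1, ]) || any(comp[nr, ]) ||
        any(comp[, 1]) || any(comp[, nc])
      ct <- trace_component(comp)
      if (is.null(ct)) {
        warn(sprintf("cell %d component %d: fewer than 3 boundary vertices; skipped",
                     id, k))
        next
      }
      out <- contour_xy(ct$x * pixel_size, ct$y * pixel_size, cell_id = id)
      rows[[length(rows) + 1]] <- tibble::tibble(
        cell_id = id, component = k, area_px = npx,
        border = border, contour = list(out)
      )
    }
  }
  if (!length(rows)) abort("no cells: no traceable regions found")
  dplyr::bind_rows(rows)
}

# marching squares on one connected-component mask; returns the outer
# boundary loop (largest area), CCW, in pixel-centre coordinates
trace_component <- function(comp) {
  nr <- nrow(comp)
  nc <- ncol(comp)
  # pad with background so boundary loops close; z[i, j] is the value at
  # x = xs[i], y = ys[j] with y up
  z <- matrix(0, nc + 2, nr + 2)
  z[2:(nc + 1), 2:(nr + 1)] <- t(comp[nr:1, , drop = FALSE]) * 1
  xs <- 0:(nc + 1)
  ys <- 0:(nr + 1)
  cl <- grDevices::contourLines(xs, ys, z, levels = 0.5)
  if (!length(cl)) return(NULL)
  loops <- lapply(cl, function(l) {
    x <- l$x
    y <- l$y
    if (length(x) > 1 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
      x <- x[-length(x)]
      y <- y[-length(y)]
    }
    list(x = x, y = y) # z was built y-up, so coordinates come out y-up
  })
  areas <- vapply(loops, function(l) {
    if (length(l$x) < 3) return(0)
    xn <- c(l$x[-1], l$x[1]); yn <- c(l$y[-1], l$y[1])
    sum(l$x * yn - xn * l$y) / 2
  }, numeric(1))
  best <- which.max(abs(areas))
  if (abs(areas[best]) == 0 || length(loops[[best]]$x) < 3) return(NULL)
  l <- loops[[best]]
  if (areas[best] < 0) l <- list(x = rev(l$x), y = rev(l$y))
  l
}
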