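#' Analyse every cell of a labelled image
#'
#' Runs the full pipeline per cell: boundary extraction, arc-length
#' resampling, area canonicalisation, elliptic Fourier decomposition, rotor
#' reassignment to lobe modes, and the derived complexity metrics (XOR
#' profile on the source grid, marginal/cumulative difference, entropy,
#' natural cut-off). Border-touching cells are excluded from metrics by
#' default (their outlines are clipped) but stay listed with an exclusion
#' reason. The analysis path contains no randomness: identical input and
#' configuration give identical tables.
#'
#' @param image Path to a TIFF/PNG label image, or an integer ID matrix.
#' @param n_modes Number of lobe modes reported (default 50).
#' @param grid `"source"` (default): XOR computed on the image's own pixel
#'   grid, the natural choice for segmented microscopy data; `"synthetic"`:
#'   a `grid_size`^2 grid with the shape spanning ~60% of the field.
#' @param grid_size Synthetic grid side length (default 512).
#' @param include_border If `TRUE`, analyse border-touching cells too.
#' @param n_points Contour resampling density (default 1000).
#' @param pixel_size Physical length per pixel.
#' @param min_pixels Minimum region size analysed.
#' @return A tibble with one row per cell region: identifiers
#'   (`cell_id`, `component`), `area_px`, `border`, `excluded`, `reason`,
#'   spectrum columns `L1..L<n_modes>`, `dominant_mode`, `argmax_md_mode`,
#'   `cd`, `entropy`, `cutoff`.
#' @export
analyze_image <- function(image, n_modes = 50, grid = c("source", "synthetic"),
                          grid_size = 512, include_border = FALSE,
                          n_points = 1000, pixel_size = 1, min_pixels = 16) {
  grid <- match.arg(grid)
  img <- read_label_image(image, pixel_size = pixel_size)
  cells <- extract_contours(img, min_pixels = min_pixels)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    info <- cells[i, ]
    if (info$border && !include_border) {
      out[[i]] <- dplyr::bind_cols(
        info[c("cell_id", "component", "area_px", "border")],
        tibble::tibble(excluded = TRUE, reason = "touches image border")
      )
      next
    }
    rec <- analyze_contour(info$contour[[1]], n_modes = n_modes,
                           grid = grid, grid_size = grid_size,
                           n_points = n_points, pixel_size = pixel_size)
    out[[i]] <- dplyr::bind_cols(
      info[c("cell_id", "component", "area_px", "border")],
      tibble::tibble(excluded = FALSE, reason = NA_character_),
      rec
    )
  }
  dplyr::bind_rows(out)
}

#' Analyse a single contour
#'
#' @param contour A contour tibble (physical units).
#' @inheritParams analyze_image
#' @return A one-row tibble of spectrum columns and metrics (see
#'   [analyze_image()]).
#' @export
analyze_contour <- function(contour, n_modes = 50,
                            grid = c("synthetic", "source"), grid_size = 512,
                            n_points = 1000, pixel_size = 1) {
  grid <- match.arg(grid)
  fit <- loco_efa(contour, n_modes = n_modes, n_points = n_points)
  if (grid == "source") {
    # pixel-centre grid of the source image, cropped to the cell + margin
    g <- list(
      x = seq(floor(min(contour$x) / pixel_size) - 2,
              ceiling(max(contour$x) / pixel_size) + 2) * pixel_size,
      y = seq(floor(min(contour$y) / pixel_size) - 2,
              ceiling(max(contour$y) / pixel_size) + 2) * pixel_size
    )
    original <- rasterise_contour(contour, g)
    prof <- xor_profile(fit, n_max = n_modes, grid = g, original = original,
                        to_grid = function(ct) {
                          contour_xy(ct$x / fit$scale, ct$y / fit$scale)
                        })
  } else {
    prof <- xor_profile(fit, n_max = n_modes,
                        grid = make_raster_grid(fit$contour, n = grid_size))
  }
  sp <- fit$spectrum
  wide <- tibble::as_tibble(as.list(stats::setNames(sp$L, paste0("L", sp$l))))
  dplyr::bind_cols(
    wide,
    tibble::tibble(
      dominant_mode = dominant_mode(fit),
      argmax_md_mode = argmax_marginal(prof),
      cd = attr(prof, "cd"),
      entropy = shape_entropy(fit, l_max = n_modes),
      cutoff = attr(prof, "cutoff")
    )
  )
}

#' @rdname analyze_contour
#' @param path Path to a contour CSV (header `x,y`).
#' @export
analyze_contour_file <- function(path, ...) {
  analyze_contour(read_contour_csv(path), ...)
}

#' Long-format lobe spectra from a record table
#'
#' @param records A record tibble from [analyze_image()].
#' @return A tibble `(cell_id, component, l, L)`.
#' @export
spectra_long <- function(records) {
  lcols <- grep("^L[0-9]+$", names(records), value = TRUE)
  out <- tidyr::pivot_longer(
    records[c("cell_id", "component", lcols)],
    dplyr::all_of(lcols), names_to = "l", values_to = "L"
  )
  out$l <- as.integer(sub("^L", "", out$l))
  dplyr::arrange(out, .data$cell_id, .data$component, .data$l)
}

parse_map_metric <- function(metric, records) {
  valid <- c("L:<mode>", "cd", "entropy", "argmax_md", "dominant_mode",
             "cutoff", "area_px")
  if (grepl("^L:[0-9]+$", metric)) {
    l <- sub("^L:", "L", metric)
    if (!l %in% names(records)) {
      abort(sprintf("mode %s not present in records", metric))
    }
    list(col = l, label = sub(":", "", metric), categorical = FALSE)
  } else if (metric %in% c("cd", "entropy", "area_px", "cutoff")) {
    list(col = metric, label = metric, categorical = FALSE)
  } else if (metric %in% c("argmax_md", "argmax_md_mode")) {
    list(col = "argmax_md_mode", label = "mode of max marginal difference",
         categorical = TRUE)
  } else if (metric == "dominant_mode") {
    list(col = "dominant_mode", label = "dominant lobe mode",
         categorical = TRUE)
  } else {
    abort(paste0("unknown metric '", metric, "'; valid metrics: ",
                 paste(valid, collapse = ", ")))
  }
}

#' Colour-coded per-cell tissue maps
#'
#' Fills every cell of a label image with a colour scale of a chosen
#' per-cell quantity (an `L` mode via `"L:6"`, `cd`, `entropy`, or the
#' categorical mode of maximum marginal difference via `"argmax_md"`).
#'
#' @param image Label image (path or matrix) matching `records`.
#' @param records Record tibble from [analyze_image()].
#' @param metric Metric name; unknown names error with the list of valid
#'   options.
#' @param out_path Optional PNG output path; a JSON sidecar with the colour
#'   scale range is written next to it.
#' @return A ggplot object (invisibly when `out_path` is given).
#' @export
render_mode_map <- function(image, records, metric = "L:6",
                            out_path = NULL) {
  img <- read_label_image(image)
  spec <- parse_map_metric(metric, records)
  vals <- records[[spec$col]]
  ids <- records$cell_id
  m <- unclass(img)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$id <- as.vector(t(m)) # expand_grid varies col fastest
  df$value <- vals[match(df$id, ids)]
  df$value[df$id == 0] <- NA
  df$y <- nrow(m) - df$row + 1
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = spec$label) +
    ggplot2::theme_void()
  if (spec$categorical) {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::scale_fill_viridis_d(na.value = "grey20")
  } else {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(na.value = "grey20")
  }
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, p, width = 6, height = 6, dpi = 150)
    rng <- range(vals[match(unique(df$id[df$id != 0]), ids)], na.rm = TRUE)
    sidecar <- sub("\\.[a-zA-Z]+$", ".json", out_path)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        list(metric = metric, scale_min = rng[1], scale_max = rng[2],
             categorical = spec$categorical),
        sidecar, auto_unbox = TRUE
      )
    }
    return(invisible(p))
  }
  p
}
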