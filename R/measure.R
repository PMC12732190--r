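#' Extract and threshold the ROIs of one plate row
#'
#' For each well of the requested row, pixels inside the circular ROI are
#' thresholded on the 8-bit grayscale value: a pixel belongs to the
#' agglutination mask when its gray level is at most `threshold_max`
#' (inclusive; the default keeps gray 0--235 and discards 236--255).
#' Everything outside an ROI is treated as white background and never enters
#' a mask, mirroring extraction of the well bottoms onto a white canvas
#' before particle analysis.
#'
#' @param image A [plate_image()] (8-bit grayscale).
#' @param grid A [build_roi_grid()] result.
#' @param row 1-based plate row to extract.
#' @param threshold_max Inclusive upper gray level of the mask (default 235).
#' @return An object of class `roi_masks`: a list with one element per well
#'   (ordered by column), each holding `row`, `col`, the bounding-box origin
#'   `x0`, `y0`, the logical `mask` matrix, the ROI `center` and `radius`.
#' @export
extract_and_threshold <- function(image, grid, row, threshold_max = 235) {
  stopifnot(inherits(image, "plate_image"), inherits(grid, "roi_grid"))
  if (!is.numeric(threshold_max) || threshold_max < 0 || threshold_max > 255)
    stop("`threshold_max` must be a gray level in [0, 255]", call. = FALSE)
  px <- image$pixels
  ny <- nrow(px); nx <- ncol(px)
  g <- roi_grid_row(grid, row)
  masks <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    cx <- g$center_x_px[i]; cy <- g$center_y_px[i]; r <- g$radius_px[i]
    x0 <- floor(cx - r); x1 <- ceiling(cx + r)
    y0 <- floor(cy - r); y1 <- ceiling(cy + r)
    if (x0 < 1 || y0 < 1 || x1 > nx || y1 > ny)
      stop(sprintf("ROI out of image bounds at row %d col %d", row, g$col[i]),
           call. = FALSE)
    sub <- px[y0:y1, x0:x1, drop = FALSE]
    xs <- x0:x1; ys <- y0:y1
    in_roi <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
    masks[[i]] <- list(row = g$row[i], col = g$col[i], x0 = x0, y0 = y0,
                       mask = in_roi & (sub <= threshold_max),
                       center = c(cx, cy), radius = r)
  }
  structure(masks, class = "roi_masks", threshold_max = threshold_max)
}

#' Measure area and centroid of each well mask
#'
#' The particle-analysis step: per well, the mask pixel count is converted to
#' mm^2 through the squared pixel scale, the centroid is the mean pixel
#' position of the mask, and the number of connected components (8-neighbor)
#' is recorded as a diagnostic -- a fragmented edge-effect mat shows several
#' components where a contiguous mat shows one. Components within a well are
#' summed into a single area so fragmented and contiguous mats are
#' comparable. Results are sorted by ascending centroid x, reproducing the
#' left-to-right well order of the row.
#'
#' @param masks An [extract_and_threshold()] result.
#' @param grid The [build_roi_grid()] the masks came from.
#' @param scale A [pixel_scale()].
#' @param row 1-based plate row (recorded in the output).
#' @return A data frame with one row per well: `row`, `col`, `area_mm2`,
#'   `centroid_x_px`, `centroid_y_px`, `n_components`, `n_pixels`. An empty
#'   mask yields area 0 with the centroid at the ROI center and 0 components.
#' @export
measure_wells <- function(masks, grid, scale, row) {
  stopifnot(inherits(masks, "roi_masks"), inherits(scale, "pixel_scale"))
  mm2_per_px <- scale$mm_per_px^2
  out <- lapply(masks, function(m) {
    npx <- sum(m$mask)
    if (npx == 0L) {
      cx <- m$center[1]; cy <- m$center[2]; ncomp <- 0L
    } else {
      idx <- which(m$mask, arr.ind = TRUE)
      cy <- mean(idx[, 1]) + m$y0 - 1
      cx <- mean(idx[, 2]) + m$x0 - 1
      ncomp <- as.integer(max(EBImage::bwlabel(m$mask)))
    }
    data.frame(row = m$row, col = m$col,
               area_mm2 = npx * mm2_per_px,
               centroid_x_px = cx, centroid_y_px = cy,
               n_components = ncomp, n_pixels = npx)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$centroid_x_px), , drop = FALSE]
  rownames(res) <- NULL
  res$row <- row
  res
}

#' Measure every requested row of a plate image
#'
#' Convenience wrapper running [extract_and_threshold()] and
#' [measure_wells()] over a set of plate rows.
#'
#' @inheritParams extract_and_threshold
#' @param rows Rows to measure (default: all rows of the grid).
#' @param scale Pixel scale; defaults to the scale attached to the grid.
#' @return A data frame of per-well measurements, rows stacked.
#' @export
measure_plate <- function(image, grid, rows = NULL, threshold_max = 235,
                          scale = attr(grid, "scale")) {
  if (is.null(rows)) rows <- sort(unique(grid$row))
  res <- lapply(rows, function(r) {
    m <- extract_and_threshold(image, grid, r, threshold_max)
    measure_wells(m, grid, scale, r)
  })
  do.call(rbind, res)
}

#' Write or read a per-well measurement table
#'
#' The interchange CSV has columns `plate_id, row, col, area_mm2,
#' centroid_x, centroid_y, n_components`.
#'
#' @param measurements Data frame from [measure_wells()]/[measure_plate()].
#' @param path CSV path.
#' @param plate_id Identifier recorded in the `plate_id` column; scalar, or
#'   one value per measurement row when a run spans several plates.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_measurements_csv <- function(measurements, path, plate_id = "plate1") {
  df <- data.frame(plate_id = plate_id,
                   row = measurements$row, col = measurements$col,
                   area_mm2 = measurements$area_mm2,
                   centroid_x = measurements$centroid_x_px,
                   centroid_y = measurements$centroid_y_px,
                   n_components = measurements$n_components)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "row", "col", "area_mm2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("measurement CSV is missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}
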