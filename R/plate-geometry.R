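#' Physical description of a round-bottom microplate
#'
#' Captures the plate properties the imaging pipeline needs: the grid
#' dimensions, the manufacturer's well-bottom diameter (the calibration
#' reference), the center-to-center well pitch, and the fraction of the well
#' bottom each circular region of interest (ROI) covers. The ROI is drawn
#' slightly smaller than the well bottom so that the well wall never enters
#' the measurement.
#'
#' @param n_rows Number of plate rows (default 8, a standard 96-well plate).
#' @param n_cols Number of wells per row; each column is one serial-dilution
#'   step (default 12).
#' @param well_bottom_diameter_mm Well-bottom diameter in mm as stated by the
#'   plate manufacturer. No universal default exists; it must be supplied for
#'   the plate in use.
#' @param well_pitch_mm Center-to-center well spacing in mm (default 9, the
#'   ANSI/SLAS 96-well standard).
#' @param roi_fraction Fraction of the well-bottom diameter covered by each
#'   ROI (default 0.95).
#'
#' @return An object of class `plate_geometry`.
#' @examples
#' plate_geometry(well_bottom_diameter_mm = 6.4)
#' @export
plate_geometry <- function(n_rows = 8L, n_cols = 12L,
                           well_bottom_diameter_mm,
                           well_pitch_mm = 9,
                           roi_fraction = 0.95) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L)
    stop("`n_rows` must be a positive integer", call. = FALSE)
  if (is.na(n_cols) || n_cols < 2L)
    stop("`n_cols` must be an integer >= 2 (a dilution series needs at least two wells)",
         call. = FALSE)
  if (!is.numeric(well_bottom_diameter_mm) || well_bottom_diameter_mm <= 0)
    stop("`well_bottom_diameter_mm` must be > 0", call. = FALSE)
  if (!is.numeric(roi_fraction) || roi_fraction <= 0 || roi_fraction > 1)
    stop("`roi_fraction` must be in (0, 1]", call. = FALSE)
  if (!is.numeric(well_pitch_mm) || well_pitch_mm < well_bottom_diameter_mm)
    stop("`well_pitch_mm` must be >= `well_bottom_diameter_mm`", call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         well_bottom_diameter_mm = well_bottom_diameter_mm,
         well_pitch_mm = well_pitch_mm,
         roi_fraction = roi_fraction),
    class = "plate_geometry")
}

#' @export
print.plate_geometry <- function(x, ...) {
  cat(sprintf("plate_geometry: %d x %d wells, bottom %.3g mm, pitch %.3g mm, ROI fraction %.2f\n",
              x$n_rows, x$n_cols, x$well_bottom_diameter_mm,
              x$well_pitch_mm, x$roi_fraction))
  invisible(x)
}

#' Construct a pixel scale directly
#'
#' @param mm_per_px Isotropic image scale in mm per pixel, > 0.
#' @return An object of class `pixel_scale`.
#' @seealso [calibrate_scale()] to derive the scale from an in-image well
#'   measurement.
#' @export
pixel_scale <- function(mm_per_px) {
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L ||
      !is.finite(mm_per_px) || mm_per_px <= 0)
    stop("invalid calibration: `mm_per_px` must be a single positive number",
         call. = FALSE)
  structure(list(mm_per_px = mm_per_px), class = "pixel_scale")
}

#' @export
print.pixel_scale <- function(x, ...) {
  cat(sprintf("pixel_scale: %.6g mm/px\n", x$mm_per_px))
  invisible(x)
}

#' Calibrate the image scale from one well
#'
#' The scale is set the same way it is done at the bench: measure the
#' edge-to-edge pixel distance across one well bottom in the image and divide
#' the manufacturer's known well-bottom diameter by it.
#'
#' @param well_edge_to_edge_px Measured well-bottom diameter in pixels, > 0.
#' @param well_bottom_diameter_mm Manufacturer's well-bottom diameter in mm,
#'   > 0.
#' @return A [pixel_scale()] with `mm_per_px = well_bottom_diameter_mm /
#'   well_edge_to_edge_px`.
#' @examples
#' calibrate_scale(100, 6.4) # 0.064 mm/px
#' @export
calibrate_scale <- function(well_edge_to_edge_px, well_bottom_diameter_mm) {
  if (!is.numeric(well_edge_to_edge_px) || length(well_edge_to_edge_px) != 1L ||
      !is.finite(well_edge_to_edge_px) || well_edge_to_edge_px <= 0)
    stop("invalid calibration: `well_edge_to_edge_px` must be > 0", call. = FALSE)
  if (!is.numeric(well_bottom_diameter_mm) || length(well_bottom_diameter_mm) != 1L ||
      !is.finite(well_bottom_diameter_mm) || well_bottom_diameter_mm <= 0)
    stop("invalid calibration: `well_bottom_diameter_mm` must be > 0", call. = FALSE)
  pixel_scale(well_bottom_diameter_mm / well_edge_to_edge_px)
}

#' Lay out the circular ROI grid over the wells
#'
#' Starting from the pixel coordinates of the first (top-left) well center,
#' ROI centers are placed row-major at the well pitch converted to pixels;
#' every ROI shares the same radius, `roi_fraction` times the well-bottom
#' radius. This replaces the manual duplicate-and-drag placement of an
#' interactive ROI manager with a deterministic computation, so the same
#' anchor always yields the same grid. Image coordinates follow the raster
#' convention: origin at the top-left pixel (1, 1), x rightward, y downward.
#'
#' @param geometry A [plate_geometry()].
#' @param scale A [pixel_scale()].
#' @param first_well_center_px Numeric length-2, `(x, y)` pixel coordinates of
#'   the center of well A1 (row 1, column 1).
#' @return A data frame of class `roi_grid` with one row per well and columns
#'   `row`, `col` (1-based), `center_x_px`, `center_y_px`, `radius_px`, in
#'   row-major order. The geometry and scale are attached as attributes.
#' @examples
#' g <- plate_geometry(n_rows = 1, n_cols = 2, well_bottom_diameter_mm = 6.4)
#' build_roi_grid(g, pixel_scale(0.1), c(50, 50))
#' @export
build_roi_grid <- function(geometry, scale, first_well_center_px) {
  stopifnot(inherits(geometry, "plate_geometry"), inherits(scale, "pixel_scale"))
  if (!is.numeric(first_well_center_px) || length(first_well_center_px) != 2L ||
      any(!is.finite(first_well_center_px)))
    stop("`first_well_center_px` must be finite (x, y) pixel coordinates",
         call. = FALSE)
  pitch_px <- geometry$well_pitch_mm / scale$mm_per_px
  radius_px <- geometry$roi_fraction * geometry$well_bottom_diameter_mm /
    (2 * scale$mm_per_px)
  idx <- expand.grid(col = seq_len(geometry$n_cols),
                     row = seq_len(geometry$n_rows))
  grid <- data.frame(
    row = idx$row,
    col = idx$col,
    center_x_px = first_well_center_px[1] + (idx$col - 1L) * pitch_px,
    center_y_px = first_well_center_px[2] + (idx$row - 1L) * pitch_px,
    radius_px = radius_px)
  structure(grid, class = c("roi_grid", "data.frame"),
            geometry = geometry, scale = scale)
}

# ROIs of one plate row, ordered by column
roi_grid_row <- function(grid, row) {
  g <- grid[grid$row == row, , drop = FALSE]
  if (nrow(g) == 0L)
    stop(sprintf("row %d is not part of the ROI grid", row), call. = FALSE)
  g[order(g$col), , drop = FALSE]
}
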