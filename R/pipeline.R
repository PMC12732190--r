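#' Analyze one run: plate image(s) to endpoint calls
#'
#' The full imaging workflow for one assay run: build the ROI grid from the
#' anchor and plate geometry, threshold and measure every well of every
#' plate image, concatenate multi-plate series by well index, derive the
#' positivity threshold from the run's own negative-control row, and call
#' the endpoint of each sample and positive-control row. A negative-control
#' row is mandatory -- the threshold is never reused across runs because
#' pellet areas drift with red-blood-cell age.
#'
#' @param images List of [plate_image()]s (or 8-bit matrices), one per
#'   physical plate, sharing geometry and anchor. Row i of every image
#'   belongs to the same dilution series, continued left-to-right across
#'   plates.
#' @param geometry A [plate_geometry()] (its `n_rows` is overridden by the
#'   number of roles supplied).
#' @param scale A [pixel_scale()].
#' @param anchor_px `(x, y)` pixel center of well (1, 1).
#' @param roles Character vector, one of `"sample"`, `"positive_control"`,
#'   `"negative_control"` per analyzed plate row; exactly one negative
#'   control is required.
#' @param sample_ids Identifiers per row (default `row1`, `row2`, ...).
#' @param series_lengths Optional integer per row: number of wells actually
#'   in the series (trailing wells are dropped before endpoint calling).
#' @param threshold_max Inclusive gray-level threshold (default 235).
#' @param n_sd Negative-control SD multiplier (default 3).
#' @param dilution_factor Per-step dilution factor (default 2).
#' @return An object of class `plate_run`: `measurements` (per-well data
#'   frame with `plate` and `well_index` columns), `neg_stats`, and
#'   `calls` (named list of [call_endpoint()] results for every
#'   non-negative row).
#' @export
analyze_plate_run <- function(images, geometry, scale, anchor_px, roles,
                              sample_ids = paste0("row", seq_along(roles)),
                              series_lengths = NULL,
                              threshold_max = 235, n_sd = 3,
                              dilution_factor = 2) {
  roles <- match.arg(roles, c("sample", "positive_control",
                              "negative_control"), several.ok = TRUE)
  if (sum(roles == "negative_control") != 1L)
    stop("exactly one negative-control row is required per run", call. = FALSE)
  if (length(sample_ids) != length(roles))
    stop("`sample_ids` and `roles` lengths differ", call. = FALSE)
  n_rows_used <- length(roles)
  geom <- plate_geometry(n_rows = n_rows_used, n_cols = geometry$n_cols,
                         well_bottom_diameter_mm = geometry$well_bottom_diameter_mm,
                         well_pitch_mm = geometry$well_pitch_mm,
                         roi_fraction = geometry$roi_fraction)
  grid <- build_roi_grid(geom, scale, anchor_px)
  meas <- list()
  for (p in seq_along(images)) {
    im <- images[[p]]
    if (!inherits(im, "plate_image")) im <- plate_image(im, scale)
    m <- measure_plate(im, grid, threshold_max = threshold_max, scale = scale)
    m$plate <- p
    m$well_index <- (p - 1L) * geom$n_cols + m$col
    meas[[p]] <- m
  }
  meas <- do.call(rbind, meas)

  neg_row <- which(roles == "negative_control")
  neg_areas <- meas$area_mm2[meas$row == neg_row]
  stats <- negative_stats(neg_areas, n_sd = n_sd)

  calls <- list()
  for (ri in seq_len(n_rows_used)) {
    if (ri == neg_row) next
    a <- meas[meas$row == ri, , drop = FALSE]
    a <- a[order(a$well_index), , drop = FALSE]
    areas <- a$area_mm2
    if (!is.null(series_lengths) && !is.na(series_lengths[ri]))
      areas <- areas[seq_len(min(series_lengths[ri], length(areas)))]
    calls[[sample_ids[ri]]] <- call_endpoint(areas, stats, dilution_factor)
  }
  structure(list(measurements = meas, neg_stats = stats, calls = calls,
                 roles = roles, sample_ids = sample_ids,
                 threshold_max = threshold_max),
            class = "plate_run")
}

#' @export
print.plate_run <- function(x, ...) {
  print(x$neg_stats)
  for (id in names(x$calls)) {
    cat(id, ": ", sep = "")
    print(x$calls[[id]])
  }
  invisible(x)
}

#' Run the analyzer on a rendered synthetic plate
#'
#' Applies [analyze_plate_run()] to a [render_plate()] result using the
#' renderer's own geometry, scale and anchor -- the end-to-end round trip
#' used to validate the pipeline against ground truth.
#'
#' @param sp A [render_plate()] result.
#' @param ... Passed on to [analyze_plate_run()] (e.g. `threshold_max`,
#'   `n_sd`).
#' @return A `plate_run` object.
#' @export
analyze_synthetic_plate <- function(sp, ...) {
  stopifnot(inherits(sp, "synthetic_plate"))
  roles <- vapply(sp$layout, `[[`, "", "role")
  ids <- vapply(sp$layout, `[[`, "", "sample_id")
  lens <- vapply(sp$layout, function(r)
    if (is.null(r$series)) NA_integer_ else r$series$n_wells, 1L)
  analyze_plate_run(sp$images, sp$geometry, sp$scale, sp$anchor_px,
                    roles = roles, sample_ids = ids,
                    series_lengths = lens, ...)
}

#' Endpoint summary table of a run
#'
#' @param run A [analyze_plate_run()] result.
#' @return Data frame with one row per called series: `sample_id`,
#'   `last_positive`, `first_negative`, `hau` (the censored all-negative
#'   case prints as `"<1"`), `artifact_wells` (semicolon-separated),
#'   `threshold_area_mm2`.
#' @export
endpoint_table <- function(run) {
  stopifnot(inherits(run, "plate_run"))
  rows <- lapply(names(run$calls), function(id) {
    cl <- run$calls[[id]]
    data.frame(sample_id = id,
               last_positive = cl$last_positive,
               first_negative = cl$first_negative,
               hau = if (cl$censored) "<1" else format(cl$hau, scientific = FALSE, trim = TRUE),
               artifact_wells = paste(cl$artifact_wells, collapse = ";"),
               threshold_area_mm2 = cl$threshold_area_mm2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot per-well area against well number
#'
#' The diagnostic graph of the assay: thresholded area (mm^2) per well,
#' one line per series, with the negative-control mean and the
#' mean + 3 SD positivity threshold drawn as horizontal references.
#'
#' @param run A [analyze_plate_run()] result.
#' @return A ggplot object.
#' @export
plot_row_areas <- function(run) {
  stopifnot(inherits(run, "plate_run"))
  m <- run$measurements
  m$series <- run$sample_ids[m$row]
  ggplot2::ggplot(m, ggplot2::aes(x = well_index, y = area_mm2,
                                  colour = series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = run$neg_stats$mean_area_mm2,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = run$neg_stats$threshold_area_mm2,
                        linetype = "dotted") +
    ggplot2::labs(x = "well number", y = expression(area ~ (mm^2)),
                  colour = NULL,
                  subtitle = "dashed: negative-control mean; dotted: mean + 3 SD threshold") +
    ggplot2::theme_minimal()
}
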