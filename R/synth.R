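#' Parameters of the synthetic plate renderer
#'
#' The renderer emulates overnight photographs of round-bottom wells on a
#' backlit lightbox: a white background, red-toned agglutination shapes that
#' convert to mid-gray under luminance weighting (well below the 235
#' threshold), a mild left-to-right illumination gradient, and Gaussian
#' sensor noise. Well phenotype follows the assay's morphology sequence:
#' far above the detection threshold a broad mat covers most of the well; at
#' very high analyte amounts the mat can roll up into small polygons (the
#' low-dilution edge effect, whose thresholded area is deceptively small);
#' near the threshold mats become fuzzy, oblong, or develop a central donut
#' hole; below it, cells settle into a compact dark pellet.
#'
#' Positivity is sampled from a logistic in log2(amount / theta) with width
#' `logistic_width`; `logistic_width = 0` gives the hard rule
#' `amount >= theta_ng`.
#'
#' @param theta_ng Detection threshold of the simulated assay in ng
#'   (default 200).
#' @param logistic_width Width of the amount-to-positivity transition in
#'   log2 units (default 0.05; 0 = hard threshold). The default confines
#'   the stochastic transition to roughly a quarter dilution step around
#'   theta -- a well half a step above threshold essentially never flips,
#'   while wells landing very close to theta remain ambiguous -- matching
#'   how sharply the real assay turns over between adjacent wells.
#' @param edge_effect_amount_ng Analyte amount above which a positive well
#'   renders as edge-effect polygons (default 150000 ng, i.e. roughly the
#'   first five wells of a strong powder extract).
#' @param edge_effect_prob Probability that a well above
#'   `edge_effect_amount_ng` shows the edge effect (default 1).
#' @param noise_sd Gaussian pixel noise, gray levels (default 2).
#' @param illumination_gradient Maximum relative brightness drop across the
#'   image width (default 0.03).
#' @param pellet_area_fraction,pellet_area_jitter Mean pellet area as a
#'   fraction of the ROI area (default 0.055) and the relative half-width of
#'   its bounded uniform jitter (default 0.2, i.e. +/- 20%). Sedimented
#'   red-cell dots are stereotyped in size, so their variation is modeled
#'   with hard bounds rather than Gaussian tails; this keeps the largest
#'   possible pellet safely inside the mean + 3 SD negative band.
#' @param pellet_drift Additive offset on the pellet area fraction,
#'   emulating red-blood-cell aging between runs (default 0).
#' @param mat_area_fraction,mat_area_sd Full-mat area fraction (defaults
#'   0.80, 0.03); all normal area draws are clamped at 2 SD.
#' @param fuzzy_area_fraction,fuzzy_area_sd Near-threshold fuzzy-mat area
#'   fraction (defaults 0.45, 0.05).
#' @param donut_outer_fraction Outer-disk fraction of a donut mat (default
#'   0.55); the hole radius is `donut_hole_fraction` of the outer radius
#'   (default 0.35).
#' @param donut_hole_fraction See `donut_outer_fraction`.
#' @param edge_polygon_area_fraction,edge_polygon_area_sd Total polygon area
#'   fraction of an edge-effect well (defaults 0.03, 0.005) -- below the
#'   pellet reference so the artifact classifies negative, as observed.
#' @param mat_gray,pellet_gray,polygon_gray,background_gray 8-bit gray
#'   levels of the rendered classes (defaults 175, 90, 140, 255). Shape
#'   grays sit below the 235 threshold, the background above it.
#' @param seed Optional integer seed; seeded renders are bit-reproducible.
#' @return An object of class `render_params`.
#' @export
render_params <- function(theta_ng = 200,
                          logistic_width = 0.05,
                          edge_effect_amount_ng = 150000,
                          edge_effect_prob = 1,
                          noise_sd = 2,
                          illumination_gradient = 0.03,
                          pellet_area_fraction = 0.055,
                          pellet_area_jitter = 0.2,
                          pellet_drift = 0,
                          mat_area_fraction = 0.80,
                          mat_area_sd = 0.03,
                          fuzzy_area_fraction = 0.45,
                          fuzzy_area_sd = 0.05,
                          donut_outer_fraction = 0.55,
                          donut_hole_fraction = 0.35,
                          edge_polygon_area_fraction = 0.03,
                          edge_polygon_area_sd = 0.005,
                          mat_gray = 175, pellet_gray = 90,
                          polygon_gray = 140, background_gray = 255,
                          seed = NULL) {
  if (theta_ng <= 0) stop("`theta_ng` must be > 0", call. = FALSE)
  if (logistic_width < 0) stop("`logistic_width` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  p <- as.list(environment())
  structure(p, class = "render_params")
}

#' Sample the phenotype of one simulated well
#'
#' Positivity is Bernoulli with probability
#' `plogis(log2(amount / theta) / logistic_width)` (hard threshold at width
#' 0). Positive wells far above threshold render as a full mat; within two
#' dilution steps of threshold as a fuzzy mat or donut; above
#' `edge_effect_amount_ng` (with probability `edge_effect_prob`) as
#' edge-effect polygons. Negative wells render as a pellet. Uses the
#' current RNG stream; seed upstream for reproducibility.
#'
#' @param amount_ng Analyte amount in the well, ng (>= 0).
#' @param params A [render_params()].
#' @return A list of class `well_phenotype`: `state` (one of `"mat"`,
#'   `"edge_polygon"`, `"fuzzy_mat"`, `"donut"`, `"pellet"`),
#'   `area_fraction` (target thresholded area as a fraction of the ROI
#'   area), `ground_truth_positive`.
#' @export
simulate_phenotype <- function(amount_ng, params = render_params()) {
  stopifnot(inherits(params, "render_params"))
  if (amount_ng < 0) stop("`amount_ng` must be >= 0", call. = FALSE)
  positive <- if (amount_ng == 0) {
    FALSE
  } else if (params$logistic_width == 0) {
    amount_ng >= params$theta_ng
  } else {
    p <- stats::plogis(log2(amount_ng / params$theta_ng) /
                         params$logistic_width)
    stats::runif(1) < p
  }
  # normal draws clamped at 2 SD: phenotype sizes are stereotyped, not
  # heavy-tailed
  rtrunc <- function(mean, sd, lo = 0.01)
    max(lo, mean + sd * max(-2, min(2, stats::rnorm(1))))
  if (!positive) {
    state <- "pellet"
    m <- params$pellet_area_fraction + params$pellet_drift
    af <- max(0.01, m * (1 + stats::runif(1, -params$pellet_area_jitter,
                                          params$pellet_area_jitter)))
  } else if (amount_ng >= params$edge_effect_amount_ng &&
             stats::runif(1) < params$edge_effect_prob) {
    state <- "edge_polygon"
    af <- rtrunc(params$edge_polygon_area_fraction,
                 params$edge_polygon_area_sd, lo = 0.005)
  } else if (amount_ng >= 4 * params$theta_ng) {
    state <- "mat"
    af <- min(0.95, rtrunc(params$mat_area_fraction, params$mat_area_sd))
  } else {
    state <- if (stats::runif(1) < 0.5) "fuzzy_mat" else "donut"
    af <- if (state == "fuzzy_mat") {
      min(0.95, rtrunc(params$fuzzy_area_fraction, params$fuzzy_area_sd))
    } else {
      params$donut_outer_fraction * (1 - params$donut_hole_fraction^2)
    }
  }
  structure(list(state = state, area_fraction = af,
                 ground_truth_positive = positive),
            class = "well_phenotype")
}

# --- shape rasterization (pixel-center rule) --------------------------------

draw_disk <- function(img, cx, cy, r, gray) {
  if (r <= 0) return(img)
  ys <- max(1, floor(cy - r)):min(nrow(img), ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  m <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
  sub <- img[ys, xs, drop = FALSE]
  sub[m] <- gray
  img[ys, xs] <- sub
  img
}

draw_ellipse <- function(img, cx, cy, a, b, angle, gray) {
  r <- max(a, b)
  ys <- max(1, floor(cy - r)):min(nrow(img), ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  dx <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  dy <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
  u <- (dx * cos(angle) + dy * sin(angle)) / a
  v <- (-dx * sin(angle) + dy * cos(angle)) / b
  m <- u^2 + v^2 <= 1
  sub <- img[ys, xs, drop = FALSE]
  sub[m] <- gray
  img[ys, xs] <- sub
  img
}

# even-odd point-in-polygon over a pixel bounding box
draw_polygon <- function(img, vx, vy, gray) {
  ys <- max(1, floor(min(vy))):min(nrow(img), ceiling(max(vy)))
  xs <- max(1, floor(min(vx))):min(ncol(img), ceiling(max(vx)))
  px <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  py <- matrix(ys, nrow = length(ys), ncol = length(xs))
  n <- length(vx)
  inside <- matrix(FALSE, length(ys), length(xs))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  sub <- img[ys, xs, drop = FALSE]
  sub[inside] <- gray
  img[ys, xs] <- sub
  img
}

shoelace_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1))
  abs(sum(vx[j] * vy - vx * vy[j])) / 2
}

# render one well phenotype centered at (cx, cy) with ROI radius r_roi
render_well <- function(img, cx, cy, r_roi, phen, params) {
  a_roi <- pi * r_roi^2
  target <- phen$area_fraction * a_roi
  switch(phen$state,
    pellet = draw_disk(img, cx, cy, sqrt(target / pi), params$pellet_gray),
    mat = draw_disk(img, cx, cy, sqrt(target / pi), params$mat_gray),
    fuzzy_mat = {
      q <- stats::runif(1, 1.15, 1.45)
      a <- sqrt(target * q / pi); b <- a / q
      draw_ellipse(img, cx, cy, a, b, stats::runif(1, 0, pi),
                   params$mat_gray)
    },
    donut = {
      r_out <- sqrt(params$donut_outer_fraction) * r_roi
      img <- draw_disk(img, cx, cy, r_out, params$mat_gray)
      draw_disk(img, cx, cy, params$donut_hole_fraction * r_out,
                params$background_gray)
    },
    edge_polygon = {
      n_poly <- sample(1:2, 1)
      for (k in seq_len(n_poly)) {
        ang <- stats::runif(1, 0, 2 * pi)
        pcx <- cx + 0.45 * r_roi * cos(ang)
        pcy <- cy + 0.45 * r_roi * sin(ang)
        nv <- sample(5:7, 1)
        th <- sort(stats::runif(nv, 0, 2 * pi))
        rad <- stats::runif(nv, 0.5, 1)
        s <- sqrt((target / n_poly) / shoelace_area(rad * cos(th),
                                                    rad * sin(th)))
        s <- min(s, 0.35 * r_roi)  # keep polygons inside the ROI
        img <- draw_polygon(img, pcx + s * rad * cos(th),
                            pcy + s * rad * sin(th), params$polygon_gray)
      }
      img
    },
    stop(sprintf("unknown phenotype state '%s'", phen$state), call. = FALSE))
}

#' Describe one plate row of a synthetic layout
#'
#' @param sample_id Identifier for the row.
#' @param role One of `"sample"`, `"positive_control"`,
#'   `"negative_control"`.
#' @param series A [dilution_series()]; required except for the negative
#'   control. For a powder extract the series tracks powder mass and
#'   `analyte_fraction` gives the active-lectin mass fraction of the powder.
#' @param analyte_fraction Active analyte per unit powder mass (default 1,
#'   i.e. the series concentration is the analyte itself).
#' @return A list of class `layout_row`.
#' @export
layout_row <- function(sample_id, role = c("sample", "positive_control",
                                           "negative_control"),
                       series = NULL, analyte_fraction = 1) {
  role <- match.arg(role)
  if (role != "negative_control") {
    if (!inherits(series, "dilution_series"))
      stop(sprintf("row '%s' (%s) needs a dilution_series", sample_id, role),
           call. = FALSE)
  }
  if (analyte_fraction < 0 || analyte_fraction > 1)
    stop("`analyte_fraction` must be in [0, 1]", call. = FALSE)
  structure(list(sample_id = sample_id, role = role, series = series,
                 analyte_fraction = analyte_fraction),
            class = "layout_row")
}

#' Render a synthetic plate photograph (or plate pair) with ground truth
#'
#' Each layout row is rendered as one plate row; a series longer than the
#' plate width spills onto a second (or further) plate image, exactly as a
#' 24-well series occupies the same row of two physical plates. Control
#' rows span every plate. Wells beyond a row's series length are rendered
#' as plain pellets and marked `in_series = FALSE` in the truth table.
#'
#' @param layout List of [layout_row()]s, at most `geometry$n_rows` long.
#' @param geometry A [plate_geometry()].
#' @param scale A [pixel_scale()] (default 0.1 mm/px).
#' @param params A [render_params()]; `params$seed`, when set, makes the
#'   render bit-reproducible.
#' @param anchor_px `(x, y)` pixel center of well 1 of the first row
#'   (default: one pitch from the top-left corner).
#' @return An object of class `synthetic_plate`: `images` (list of 8-bit
#'   integer matrices, one per plate), `truth` (data frame with per-well
#'   `plate`, `plate_row`, `plate_col`, `well_index`, `sample_id`, `role`,
#'   `amount_ng`, `powder_ng`, `state`, `area_fraction`, `positive`,
#'   `in_series`), plus the `geometry`, `scale`, `params`, `anchor_px` and
#'   `layout` used.
#' @export
render_plate <- function(layout, geometry, scale = pixel_scale(0.1),
                         params = render_params(), anchor_px = NULL) {
  stopifnot(inherits(geometry, "plate_geometry"),
            inherits(scale, "pixel_scale"),
            inherits(params, "render_params"))
  if (!length(layout) || !all(vapply(layout, inherits, TRUE, "layout_row")))
    stop("`layout` must be a non-empty list of layout_row objects",
         call. = FALSE)
  if (length(layout) > geometry$n_rows)
    stop(sprintf("layout has %d rows but the plate has %d",
                 length(layout), geometry$n_rows), call. = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)

  n_cols <- geometry$n_cols
  series_len <- vapply(layout, function(r)
    if (is.null(r$series)) n_cols else r$series$n_wells, 1L)
  n_plates <- max(1L, ceiling(max(series_len) / n_cols))
  pitch_px <- geometry$well_pitch_mm / scale$mm_per_px
  r_roi <- geometry$roi_fraction * geometry$well_bottom_diameter_mm /
    (2 * scale$mm_per_px)
  if (is.null(anchor_px)) anchor_px <- c(pitch_px, pitch_px)
  n_rows_used <- length(layout)
  w <- ceiling(anchor_px[1] * 2 + (n_cols - 1) * pitch_px)
  h <- ceiling(anchor_px[2] * 2 + (n_rows_used - 1) * pitch_px)

  truth <- list()
  images <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    img <- matrix(as.numeric(params$background_gray), nrow = h, ncol = w)
    for (ri in seq_len(n_rows_used)) {
      lr <- layout[[ri]]
      cy <- anchor_px[2] + (ri - 1) * pitch_px
      for (cc in seq_len(n_cols)) {
        cx <- anchor_px[1] + (cc - 1) * pitch_px
        wi <- (p - 1L) * n_cols + cc
        in_series <- !is.null(lr$series) && wi <= lr$series$n_wells
        if (lr$role == "negative_control" || !in_series) {
          powder <- NA_real_
          amount <- 0
        } else {
          powder <- amount_in_well(lr$series, wi)
          amount <- powder * lr$analyte_fraction
        }
        phen <- simulate_phenotype(amount, params)
        img <- render_well(img, cx, cy, r_roi, phen, params)
        truth[[length(truth) + 1L]] <- data.frame(
          plate = p, plate_row = ri, plate_col = cc, well_index = wi,
          sample_id = lr$sample_id, role = lr$role,
          amount_ng = amount, powder_ng = powder,
          state = phen$state, area_fraction = phen$area_fraction,
          positive = phen$ground_truth_positive,
          in_series = lr$role == "negative_control" | in_series,
          stringsAsFactors = FALSE)
      }
    }
    if (params$illumination_gradient > 0) {
      fac <- 1 - params$illumination_gradient *
        (seq_len(w) - 1) / max(1, w - 1)
      img <- sweep(img, 2, fac, "*")
    }
    if (params$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, params$noise_sd)
    images[[p]] <- matrix(as.integer(pmin(pmax(round(img), 0), 255)),
                          nrow = h, ncol = w)
  }
  structure(
    list(images = images, truth = do.call(rbind, truth),
         geometry = geometry, scale = scale, params = params,
         anchor_px = anchor_px, layout = layout),
    class = "synthetic_plate")
}

#' @export
print.synthetic_plate <- function(x, ...) {
  cat(sprintf("synthetic_plate: %d plate image(s) %d x %d px, %d layout rows, %d wells in truth table\n",
              length(x$images), ncol(x$images[[1]]), nrow(x$images[[1]]),
              length(x$layout), nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic plate set to disk
#'
#' Writes `<prefix>_NNN.png` per plate, `<prefix>.truth.csv`, and
#' `<prefix>.params.yaml` (full render provenance including the seed).
#'
#' @param sp A [render_plate()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"plate"`).
#' @return Character vector of the files written, invisibly.
#' @export
write_synthetic_plate <- function(sp, dir, prefix = "plate") {
  stopifnot(inherits(sp, "synthetic_plate"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (p in seq_along(sp$images)) {
    f <- file.path(dir, sprintf("%s_%03d.png", prefix, p))
    write_plate_png(sp$images[[p]], f)
    files <- c(files, f)
  }
  ft <- file.path(dir, paste0(prefix, ".truth.csv"))
  utils::write.csv(sp$truth, ft, row.names = FALSE)
  fp <- file.path(dir, paste0(prefix, ".params.yaml"))
  prov <- list(
    geometry = unclass(sp$geometry),
    scale = unclass(sp$scale),
    anchor_px = sp$anchor_px,
    params = Filter(Negate(is.null), unclass(sp$params)))
  yaml::write_yaml(prov, fp)
  invisible(c(files, ft, fp))
}
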