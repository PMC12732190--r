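# shared fixture builders and independent oracles

std_geometry <- function(n_rows = 8L, n_cols = 12L)
  plate_geometry(n_rows = n_rows, n_cols = n_cols,
                 well_bottom_diameter_mm = 6.4, well_pitch_mm = 9)

# deterministic renderer: no noise, no gradient, hard positivity threshold
quiet_params <- function(seed = 1L, ...)
  render_params(noise_sd = 0, illumination_gradient = 0,
                logistic_width = 0, seed = seed, ...)

# brute-force oracle: count pixels whose centers fall inside the disk,
# by explicit loop over the bounding box (independent of the mask path)
disk_pixel_count <- function(cx, cy, r) {
  n <- 0L
  for (y in floor(cy - r):ceiling(cy + r))
    for (x in floor(cx - r):ceiling(cx + r))
      if ((x - cx)^2 + (y - cy)^2 <= r^2) n <- n + 1L
  n
}

# brute-force oracle: thresholded pixel count inside one circular ROI
roi_threshold_count <- function(px, cx, cy, r, thr = 235) {
  n <- 0L
  for (y in floor(cy - r):ceiling(cy + r))
    for (x in floor(cx - r):ceiling(cx + r))
      if ((x - cx)^2 + (y - cy)^2 <= r^2 && px[y, x] <= thr) n <- n + 1L
  n
}

# one-sample-plus-negative layout for round-trip tests; start amount is in
# analyte ng for a 100 uL first well
single_sample_layout <- function(first_well_ng, n_wells = 12L,
                                 analyte_fraction = 1) {
  list(
    layout_row("S", "sample",
               dilution_series(first_well_ng / 100, n_wells = n_wells),
               analyte_fraction = analyte_fraction),
    layout_row("NEG", "negative_control"))
}
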