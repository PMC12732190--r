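test_that("phenotype simulation follows the morphology sequence", {
  p <- quiet_params()
  expect_identical(simulate_phenotype(0, p)$state, "pellet")
  expect_false(simulate_phenotype(0, p)$ground_truth_positive)

  # deep in the positive regime with the edge effect disabled: a full mat
  p_noedge <- quiet_params(edge_effect_amount_ng = Inf)
  set.seed(1)
  ph <- simulate_phenotype(16 * 200, p_noedge)
  expect_identical(ph$state, "mat")
  expect_true(ph$ground_truth_positive)

  # the dose-response sweep from 600 ng down to 50 ng at a hard threshold:
  # positive at and above 200 ng, negative below
  set.seed(2)
  for (amt in c(600, 500, 400, 300, 200, 100, 50)) {
    ph <- simulate_phenotype(amt, p_noedge)
    expect_identical(ph$ground_truth_positive, amt >= 200)
    if (amt < 200) expect_identical(ph$state, "pellet")
  }

  # pellets are always smaller than mats
  set.seed(3)
  pel <- simulate_phenotype(0, p)
  mat <- simulate_phenotype(6400, p_noedge)
  expect_lt(pel$area_fraction, mat$area_fraction)
})

test_that("an all-PBS plate renders pellets matching the negative stats", {
  lay <- list(layout_row("NEG", "negative_control"),
              layout_row("NEG2", "negative_control"))
  # two PBS rows: treat the second as a 'sample' to call against the first
  lay[[2]] <- layout_row("PBS", "sample", dilution_series(1e-6, n_wells = 12))
  sp <- render_plate(lay, std_geometry(n_rows = 2), pixel_scale(0.1),
                     quiet_params(seed = 5))
  expect_true(all(sp$truth$state == "pellet"))
  run <- analyze_synthetic_plate(sp)
  cl <- run$calls[["PBS"]]
  expect_true(cl$censored)
  # pellet areas hover near the negative-control mean
  pbs_areas <- run$measurements$area_mm2[run$measurements$row == 2]
  expect_lt(abs(mean(pbs_areas) - run$neg_stats$mean_area_mm2),
            3 * run$neg_stats$sd_area_mm2 + 0.2)
})

test_that("seeded renders are bit-reproducible", {
  lay <- single_sample_layout(104000)
  p <- render_params(seed = 123)
  sp1 <- render_plate(lay, std_geometry(n_rows = 2), pixel_scale(0.1), p)
  sp2 <- render_plate(lay, std_geometry(n_rows = 2), pixel_scale(0.1), p)
  expect_identical(sp1$images, sp2$images)
  expect_identical(sp1$truth, sp2$truth)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  write_plate_png(sp1$images[[1]], f1)
  write_plate_png(sp2$images[[1]], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("rendered pellets measure within 5% of their analytic area", {
  # fine scale so pixelation of the small pellet disk stays well below 5%
  lay <- list(layout_row("NEG", "negative_control"))
  sp <- render_plate(lay, std_geometry(n_rows = 1), pixel_scale(0.05),
                     quiet_params(seed = 9))
  run <- analyze_synthetic_plate(sp)
  grid <- build_roi_grid(std_geometry(n_rows = 1), sp$scale, sp$anchor_px)
  a_roi <- pi * (grid$radius_px[1] * 0.05)^2
  m <- run$measurements
  tr <- sp$truth
  for (i in seq_len(nrow(tr))) {
    analytic <- tr$area_fraction[i] * a_roi
    measured <- m$area_mm2[m$row == tr$plate_row[i] & m$col == tr$plate_col[i]]
    expect_lt(abs(measured - analytic) / analytic, 0.05)
  }
})

test_that("a 10% w/v extract at 32.7% analyte crosses 200 ng after well 14", {
  # powder amounts bracket theta/0.327 between wells 14 and 15, so the
  # ground-truth endpoint lands on well 14 under a hard threshold
  lay <- list(
    layout_row("DRK", "sample", dilution_series(100000, n_wells = 24),
               analyte_fraction = 0.327),
    layout_row("NEG", "negative_control"))
  sp <- render_plate(lay, std_geometry(n_rows = 2), pixel_scale(0.1),
                     quiet_params(seed = 21))
  tr <- sp$truth[sp$truth$sample_id == "DRK" & sp$truth$in_series, ]
  expect_equal(max(tr$well_index[tr$positive]), 14L)
  run <- analyze_synthetic_plate(sp)
  expect_equal(run$calls[["DRK"]]$last_positive, 14L)
  expect_equal(run$calls[["DRK"]]$hau, 8192)
})

test_that("edge-effect injection flags artifacts but never moves the endpoint", {
  mk <- function(edge_amount) {
    lay <- list(
      layout_row("S", "sample", dilution_series(100000, n_wells = 24),
                 analyte_fraction = 0.327),
      layout_row("NEG", "negative_control"))
    sp <- render_plate(lay, std_geometry(n_rows = 2), pixel_scale(0.1),
                       quiet_params(seed = 31,
                                    edge_effect_amount_ng = edge_amount))
    analyze_synthetic_plate(sp)$calls[["S"]]
  }
  with_edge <- mk(150000)
  without_edge <- mk(Inf)
  expect_equal(with_edge$last_positive, without_edge$last_positive)
  expect_gt(length(with_edge$artifact_wells), 0)
  expect_equal(length(without_edge$artifact_wells), 0)
  expect_true(all(with_edge$artifact_wells < with_edge$last_positive))
})

test_that("doubling the starting concentration shifts the endpoint by one well", {
  # margin placed mid-step (sqrt(2) above a well boundary) so the logistic
  # sampling almost never flips the crossing well
  hits <- 0L
  for (i in 1:100) {
    lp <- integer(2)
    for (k in 1:2) {
      start_ng <- 200 * 2^(5 - 1) * sqrt(2) * 2^(k - 1)
      lay <- single_sample_layout(start_ng)
      # coarse raster: the ground-truth endpoint is raster-independent
      sp <- render_plate(lay, std_geometry(n_rows = 2), pixel_scale(0.25),
                         render_params(seed = 1000 + 2 * i + k))
      tr <- sp$truth[sp$truth$sample_id == "S" & sp$truth$in_series, ]
      lp[k] <- max(c(0L, tr$well_index[tr$positive]))
    }
    if (lp[2] == lp[1] + 1L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("synthetic plate sets write images, truth and provenance", {
  dir <- tempfile("synth")
  lay <- single_sample_layout(104000)
  sp <- render_plate(lay, std_geometry(n_rows = 2), pixel_scale(0.1),
                     render_params(seed = 77))
  files <- write_synthetic_plate(sp, dir)
  expect_true(all(file.exists(files)))
  truth <- read.csv(file.path(dir, "plate.truth.csv"))
  expect_equal(nrow(truth), nrow(sp$truth))
  prov <- yaml::read_yaml(file.path(dir, "plate.params.yaml"))
  expect_equal(prov$params$seed, 77)
  # PNG round trip preserves the 8-bit pixels exactly
  back <- to_grayscale_8bit(read_plate_image(file.path(dir, "plate_001.png")))
  expect_identical(back$pixels, sp$images[[1]])
})
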