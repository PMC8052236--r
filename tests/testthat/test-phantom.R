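# Small, fast phantom configurations are used here; the full-scale corpora
# live in the acceptance tests.

test_that("phantom_spec validates its inputs", {
  expect_s3_class(phantom_spec(), "phantom_spec")
  expect_error(phantom_spec(electrode_spacing = 3, electrode_diameter = 4),
               "exceed")
  expect_error(phantom_spec(head_radius = -1))
  expect_error(phantom_spec(spacing = c(1, 1)), "3 positive")
  expect_error(phantom_spec(n_wires = -2))
})

test_that("one 4-electrode strip: 4 clusters, centroids within 1 mm of truth", {
  spec <- phantom_spec(head_radius = 30, strips = c(4), grids = list(),
                       n_wires = 0, n_stitches = 0, n_screws = 0,
                       spacing = c(0.7, 0.7, 0.625), seed = 3)
  ph <- generate_phantom(spec)
  expect_equal(nrow(ph$truth), 4)
  expect_true(all(ph$truth$class == "ECOG"))
  iso <- resample_isotropic(ph$volume, 0.5)
  lab <- label_clusters(threshold_metal(iso, 2500))
  expect_equal(lab$n_clusters, 4)
  tab <- compute_feature_table(lab)
  for (i in seq_len(4)) {
    d <- sqrt((tab$centroid_x_mm - ph$truth$x_mm[i])^2 +
              (tab$centroid_y_mm - ph$truth$y_mm[i])^2 +
              (tab$centroid_z_mm - ph$truth$z_mm[i])^2)
    expect_lt(min(d), 1.0)
  }
})

test_that("same spec and seed produce bit-identical phantoms", {
  spec <- phantom_spec(head_radius = 30, strips = c(4), grids = list(),
                       n_wires = 2, n_stitches = 3, n_screws = 1,
                       spacing = c(0.8, 0.8, 0.625), seed = 11)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$truth, b$truth)
})

test_that("overlapping electrode pair fuses into a single cluster", {
  spec <- phantom_spec(head_radius = 30, strips = c(4), grids = list(),
                       n_wires = 0, n_stitches = 0, n_screws = 0,
                       spacing = c(0.7, 0.7, 0.625),
                       overlap_electrode_pairs = 1, seed = 5)
  ph <- generate_phantom(spec)
  expect_equal(sum(ph$truth$class == "ECOG"), 5)  # 4 strip + 1 overlapped
  iso <- resample_isotropic(ph$volume, 0.5)
  lab <- label_clusters(threshold_metal(iso, 2500))
  expect_equal(lab$n_clusters, nrow(ph$truth) - 1)
})

test_that("partial volume inflates electrode volumes beyond 2x nominal", {
  ph <- t2_phantoms()[[1]]
  ec <- subset(ph$features, true_class == "ECOG")
  nominal <- pi * 2^2 * 0.5 / 0.5^3       # 50.27 voxels at 0.5 mm
  expect_true(all(ec$volume > 2 * nominal))
  # disc-likeness: median circularity and cylinder similarity within 30%
  # of the ideal-disc values (1 and (5/4)sqrt(5/3) in moment mode)
  expect_lt(abs(stats::median(ec$circularity) - 1), 0.3)
  expect_lt(abs(stats::median(ec$cylinder_similarity) -
                (5 / 4) * sqrt(5 / 3)), 0.3 * (5 / 4) * sqrt(5 / 3))
})

test_that("wire clusters are elongated (median circularity > 2)", {
  spec <- phantom_spec(head_radius = 35, strips = c(4), grids = list(),
                       n_wires = 8, n_stitches = 0, n_screws = 0,
                       spacing = c(0.7, 0.7, 0.625), seed = 21)
  pp <- phantom_pipeline(spec)
  wires <- subset(pp$features, true_class == "NON_ELECTRODE")
  expect_gte(nrow(wires), 6)
  expect_gt(stats::median(wires$circularity), 2)
})

test_that("class counts in labeled tables match the spec counts", {
  pps <- t2_phantoms()
  for (pp in pps[1:2]) {
    # default spec: strips 8 + 12, one 6x8 grid, 10 wires, 15 stitches,
    # 2 screws, no deliberate overlaps
    expect_equal(sum(pp$truth$class == "ECOG"), 8 + 12 + 48)
    expect_equal(sum(pp$truth$class == "NON_ELECTRODE"), 27)
    tab_counts <- table(pp$features$true_class)
    expect_equal(unname(tab_counts["ECOG"]), 68)
  }
})

test_that("depth arrays render contacts; fused shaft merges them", {
  spec <- phantom_spec(head_radius = 30, strips = c(4), grids = list(),
                       n_wires = 0, n_stitches = 0, n_screws = 0,
                       spacing = c(0.7, 0.7, 0.625),
                       depth_arrays = list(c(4, 2.0, 1.3, 5)), seed = 8)
  pp <- phantom_pipeline(spec)
  expect_equal(sum(pp$truth$class == "DEPTH"), 4)
  expect_equal(sum(pp$features$true_class == "DEPTH"), 4)

  fus <- phantom_spec(head_radius = 30, strips = c(4), grids = list(),
                      n_wires = 0, n_stitches = 0, n_screws = 0,
                      spacing = c(0.7, 0.7, 0.625), depth_fused = TRUE,
                      depth_arrays = list(c(4, 2.0, 1.3, 5)), seed = 8)
  ppf <- phantom_pipeline(fus)
  expect_lt(ppf$n_clusters, pp$n_clusters)
})

test_that("impossible scenes raise geometry errors naming the object", {
  expect_error(generate_phantom(
    phantom_spec(head_radius = 60, grid_shape = c(40, 40, 40),
                 spacing = c(1, 1, 1), seed = 1)), "does not fit")
  expect_error(generate_phantom(
    phantom_spec(head_radius = 30, strips = c(4), grids = list(),
                 spacing = c(0.7, 0.7, 0.625), n_wires = 0, n_stitches = 0,
                 n_screws = 0, depth_arrays = list(c(12, 2, 1.3, 5)),
                 seed = 1)), "depth")
})

test_that("match_detections: exact hit, far miss, empty detections", {
  truth <- data.frame(object_id = 1:2, class = c("ECOG", "ECOG"),
                      x_mm = c(0, 10), y_mm = 0, z_mm = 0,
                      geometry = "disc", stringsAsFactors = FALSE)
  det <- data.frame(predicted_class = c("ECOG", "ECOG"),
                    centroid_x_mm = c(0, 25), centroid_y_mm = 0,
                    centroid_z_mm = 0)
  res <- match_detections(det, truth, tolerance_mm = 2)
  pc <- res$per_class[res$per_class$class == "ECOG", ]
  expect_equal(pc$tp, 1)   # exact hit
  expect_equal(pc$fp, 1)   # detection 15 mm from anything
  expect_equal(pc$fn, 1)   # truth at x=10 unmatched
  expect_equal(pc$sensitivity, 50)

  none <- match_detections(det[0, ], truth, 2)
  pcn <- none$per_class[none$per_class$class == "ECOG", ]
  expect_equal(pcn$sensitivity, 0)
  expect_equal(pcn$fn, 2)
  expect_error(match_detections(det, truth, tolerance_mm = 0), "> 0")
})
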