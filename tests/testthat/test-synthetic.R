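small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_tumors = 2, rois_per_compartment = 1,
                   tumor_cells_per_roi = c(299, 864), ...)
}

test_that("generators are bitwise-deterministic under a fixed seed", {
  cfg <- small_config(seed = 11)
  c1 <- generate_cohort(cfg); c2 <- generate_cohort(cfg)
  expect_identical(c1$cells, c2$cells)
  expect_identical(c1$truth, c2$truth)
  b1 <- generate_barcode_counts(cfg); b2 <- generate_barcode_counts(cfg)
  expect_identical(b1$counts, b2$counts)
  cfg2 <- small_config(seed = 12)
  expect_false(identical(generate_cohort(cfg2)$cells$x_um, c1$cells$x_um))
})

test_that("cohorts respect the configured ROI size range and class constraints", {
  cfg <- small_config(seed = 21)
  co <- generate_cohort(cfg)
  counts <- table(co$cells$roi_id[co$cells$tissue_class == "tumor"])
  expect_true(all(counts >= 299 & counts <= 864))
  stromal <- co$cells[co$cells$compartment == "stroma", ]
  expect_false(any(stromal$tissue_class %in% c("acinar", "adm", "islet")))
  lob_classes <- unique(co$cells$tissue_class[co$cells$compartment == "lobule"])
  expect_true(all(c("acinar", "adm", "duct", "islet", "fibrosis") %in% lob_classes))
  # every cell lies inside its ROI polygon; every lobular ROI has a front
  polys <- list(); for (a in co$regions)
    if (identical(a$role, "roi_boundary")) polys[[a$roi_id]] <- a$geometry
  for (roi in names(polys)) {
    sub <- co$cells[co$cells$roi_id == roi, ]
    expect_true(all(distance_to_annotation(
      as.matrix(sub[, c("x_um", "y_um")]), polys[[roi]]) == 0))
  }
  lob_rois <- unique(co$cells$roi_id[co$cells$compartment == "lobule"])
  expect_setequal(names(co$fronts), lob_rois)
})

test_that("invalid configs fail naming the offending field", {
  expect_error(small_config(tumor_cells_per_roi = c(10, 5)), "tumor_cells_per_roi")
  expect_error(small_config(class_mixture = list(lobule = c(acinar = 0.5))),
               "class_mixture")
  bad_mix <- list(lobule = c(acinar = 1), stroma = c(adm = 0.5, fibrosis = 0.5))
  expect_error(small_config(class_mixture = bad_mix), "acinar/adm/islet")
  cl <- synthetic_config()$clonality
  cl$hop_rate <- 1.5
  expect_error(small_config(clonality = cl), "hop_rate")
  ac <- synthetic_config()$atrophy_composition
  ac$mild <- c(amy_only = 0.9, double = 0.5, krt19_only = 0.2)
  expect_error(small_config(atrophy_composition = ac), "atrophy_composition")
})

test_that("planted compartment marker means are recovered at scale", {
  ## Monte-Carlo check against the planted Beta means: many ROIs, one marker
  cfg <- synthetic_config(
    seed = 5, n_tumors = 40, rois_per_compartment = 2,
    tumor_cells_per_roi = c(299, 864),
    marker_effects = list(M = c(lobule = 0.45, stroma = 0.15, sd = 0.05)),
    nontumor_ratio = 0.1)
  co <- generate_cohort(cfg)
  tum <- co$cells[co$cells$tissue_class == "tumor", ]
  frac <- tapply(tum$positive_M, tum$roi_id, mean)
  comp <- tapply(tum$compartment, tum$roi_id, function(x) x[1])
  mean_lob <- mean(frac[comp == "lobule"]); mean_str <- mean(frac[comp == "stroma"])
  expect_lt(abs(mean_lob - 0.45), 0.02)   # 80 ROIs/compartment, sd 0.05
  expect_lt(abs(mean_str - 0.15), 0.02)
})

test_that("ADM density is enriched toward the invasion front", {
  cfg <- synthetic_config(seed = 31, n_tumors = 3, rois_per_compartment = 2,
                          tumor_cells_per_roi = c(299, 400), nontumor_ratio = 2)
  co <- generate_cohort(cfg)
  lob <- co$cells[co$cells$compartment == "lobule" &
                    co$cells$tissue_class %in% c("adm", "acinar"), ]
  d <- unlist(lapply(split(lob, lob$roi_id), function(sub) {
    distance_to_annotation(as.matrix(sub[, c("x_um", "y_um")]),
                           co$fronts[[sub$roi_id[1]]])
  }))
  cls <- unlist(lapply(split(lob, lob$roi_id), function(sub) sub$tissue_class))
  near <- d < 50
  frac_near <- mean(cls[near] == "adm"); frac_far <- mean(cls[!near] == "adm")
  expect_gt(frac_near, frac_far)   # exp(-d/50) weighting must show up
})

test_that("intensity fields encode the planted gradient exactly without noise", {
  cfg <- synthetic_config(seed = 2, front_gradient = c(100, 1, 0))
  front <- mn_polyline(rbind(c(0, -500), c(0, 500)))
  f <- generate_intensity_field(cfg, front, extent = c(0, 0, 60, 30),
                                pixel_size_um = 1)
  expect_equal(dim(f$grid), c(30, 60))
  ## pixel centered at x = 30.5 um from the front has value 100 - 30.5
  expect_equal(f$grid[10, 31], 100 - 30.5)
  cfg0 <- synthetic_config(seed = 2, front_gradient = c(42, 0, 0))
  f0 <- generate_intensity_field(cfg0, front, c(0, 0, 20, 20), 1)
  expect_true(all(f0$grid == 42))
  expect_error(generate_intensity_field(
    cfg, mn_polyline(rbind(c(1, 1), c(1, 1))), c(0, 0, 10, 10), 1),
    "degenerate front")
})

test_that("planted gradient slope is recovered by regression on a noisy field", {
  cfg <- synthetic_config(seed = 13, front_gradient = c(baseline = 300,
                                                        decay_per_um = 1,
                                                        noise_sd = 5))
  front <- mn_polyline(rbind(c(0, -300), c(0, 300)))
  set.seed(99)
  f <- generate_intensity_field(cfg, front, extent = c(0, -150, 250, 150),
                                pixel_size_um = 2)
  xs <- runif(400, 10, 240); ys <- runif(400, -140, 140)
  d <- xs                                  # distance to the vertical front
  v <- vapply(seq_along(xs), function(i) {
    j <- ceiling(xs[i] / 2); i2 <- ceiling((ys[i] + 150) / 2)
    f$grid[i2, j]
  }, numeric(1))
  slope <- coef(lm(v ~ d))[["d"]]
  expect_lt(abs(slope - (-1)) / 1, 0.05)   # within 5% of the planted decay
})

test_that("barcode generator plants exact clonal structure when hopping is off", {
  cfg <- small_config(seed = 4, clonality = list(
    n_barcodes = 10, clone_freqs = list(S1 = 1.0), depth = 10000, hop_rate = 0))
  bc <- generate_barcode_counts(cfg)
  expect_equal(sum(bc$counts), 10000)
  expect_equal(unname(bc$counts["bc00001", "S1"]), 10000)
})

test_that("top-clone frequency is unbiased over replicates (binomial oracle)", {
  ## planted 99/1 two-clone sample: mean top-clone fraction ~ 0.99 +- 0.002
  tops <- vapply(1:200, function(r) {
    cfg <- small_config(seed = 1000 + r, clonality = list(
      n_barcodes = 5, clone_freqs = list(S1 = c(0.99, 0.01)),
      depth = 1e5, hop_rate = 0))
    bc <- generate_barcode_counts(cfg)
    max(bc$counts[, "S1"]) / sum(bc$counts[, "S1"])
  }, numeric(1))
  expect_lt(abs(mean(tops) - 0.99), 0.002)
})

test_that("cohort truth manifest round-trips through the writer", {
  cfg <- small_config(seed = 8)
  co <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  truth <- read_cohort_truth(d)
  roi <- names(co$truth$rois)[1]
  expect_equal(truth$rois[[roi]]$n_tumor_cells, co$truth$rois[[roi]]$n_tumor_cells)
  expect_equal(truth$rois[[roi]]$marker_p$MUC5AC,
               co$truth$rois[[roi]]$marker_p$MUC5AC)
  cells <- read_cell_table(file.path(d, "cells.csv"))
  expect_equal(nrow(cells), nrow(co$cells))
})
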