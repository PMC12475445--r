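# hand-built micro-ROI: one tumor cell with an ADM cell at 12 um, a duct
# cell at 30 um, and a fibrosis region containing a second tumor cell
micro_roi <- function() {
  cells <- data.frame(
    cell_id = c("t1", "t2", "a1", "d1"),
    x_um = c(0, 105, 12, 30), y_um = c(0, 105, 0, 0),
    tissue_class = c("tumor", "tumor", "adm", "duct"),
    roi_id = "r1", compartment = "lobule", tumor_id = "T01",
    stringsAsFactors = FALSE)
  fib <- mn_polygon(rbind(c(100, 100), c(110, 100), c(110, 110), c(100, 110)))
  regions <- structure(list(
    list(region_id = "fib1", roi_id = "r1", role = "class-region",
         tissue_class = "fibrosis", geometry = fib, attributes = list()),
    list(region_id = "fr1", roi_id = "r1", role = "front",
         tissue_class = NA_character_,
         geometry = mn_polyline(rbind(c(-20, -50), c(-20, 150))),
         attributes = list())), class = "mn_annotations")
  list(cells = cells, regions = regions)
}

test_that("call_contacts applies the strict 20 um rule to cells and regions", {
  fx <- micro_roi()
  ct <- call_contacts(fx$cells, fx$regions, radius_um = 20)
  expect_equal(nrow(ct), 2)
  t1 <- ct[ct$cell_id == "t1", ]
  expect_equal(t1$nearest_adm, 12)
  expect_equal(t1$nearest_duct, 30)              # recorded but not a contact
  expect_equal(t1$distance_to_front, 20)
  t2 <- ct[ct$cell_id == "t2", ]
  expect_equal(t2$nearest_fibrosis, 0)           # inside the region
  m <- microniche:::contact_matrix(ct)
  expect_true(m[ct$cell_id == "t1", "adm"])
  expect_false(m[ct$cell_id == "t1", "duct"])    # 30 >= 20
  expect_true(m[ct$cell_id == "t2", "fibrosis"])
  expect_warning(ct0 <- call_contacts(fx$cells[fx$cells$tissue_class != "tumor", ],
                                      fx$regions), "no tumor cells")
  expect_equal(nrow(ct0), 0)
})

test_that("contact table equals brute-force recomputation on a synthetic ROI", {
  cfg <- synthetic_config(seed = 17, n_tumors = 1, rois_per_compartment = 1,
                          tumor_cells_per_roi = c(299, 320))
  co <- generate_cohort(cfg)
  roi <- unique(co$cells$roi_id)[1]
  sub <- co$cells[co$cells$roi_id == roi, ]
  ct <- call_contacts(sub, co$regions, radius_um = 20)
  tum <- sub[sub$tissue_class == "tumor", ]
  for (i in sample(nrow(tum), 25)) {             # spot-check cells
    for (cl in c("adm", "fibrosis", "acinar")) {
      targ <- sub[sub$tissue_class == cl, ]
      if (!nrow(targ)) next
      d <- min(sqrt((targ$x_um - tum$x_um[i])^2 + (targ$y_um - tum$y_um[i])^2))
      expect_equal(ct[[paste0("nearest_", cl)]][ct$cell_id == tum$cell_id[i]],
                   d, tolerance = 1e-9)
    }
  }
})

test_that("contact fractions and shares follow the hand-count definitions", {
  # 2 cells: one touches {fibrosis}, one {fibrosis, adm}
  ct <- data.frame(cell_id = c("a", "b"), roi_id = "r", compartment = "lobule",
                   distance_to_front = NA_real_,
                   nearest_fibrosis = c(5, 10), nearest_adm = c(NA, 15))
  attr(ct, "radius_um") <- 20
  cf <- contact_fractions(ct)
  expect_equal(cf$fraction[cf$tissue_class == "fibrosis"], 1.0)
  expect_equal(cf$fraction[cf$tissue_class == "adm"], 0.5)
  expect_equal(cf$share[cf$tissue_class == "fibrosis"], 2 / 3)
  expect_equal(cf$share[cf$tissue_class == "adm"], 1 / 3)
  expect_equal(sum(cf$share, na.rm = TRUE), 1)
  expect_error(contact_fractions(ct, group_by = "nope"), "unknown group key")
})

test_that("front-distance profiles bin half-open, keep NA policy, and aggregate", {
  ct <- data.frame(cell_id = sprintf("c%d", 1:5), roi_id = "r",
                   compartment = "lobule",
                   distance_to_front = c(5, 5, 25, NA, 5),
                   nearest_adm = c(1, NA, 1, 1, NA),
                   nearest_fibrosis = c(3, 3, NA, 3, 3))
  attr(ct, "radius_um") <- 20
  prof <- composition_by_front_distance(ct, bin_width_um = 10)
  expect_equal(attr(prof, "n_excluded"), 1)
  b0 <- prof[prof$bin_start == 0, ]
  expect_equal(b0$n, rep(3, nrow(b0)))
  expect_equal(b0$fraction[b0$tissue_class == "adm"], 1 / 3)
  b1 <- prof[prof$bin_start == 10, ]                 # empty bin
  expect_true(all(is.na(b1$fraction)) && all(b1$n == 0))
  # aggregation over bins equals contact_fractions on the same cells
  cf <- contact_fractions(ct[!is.na(ct$distance_to_front), ])
  for (cl in c("adm", "fibrosis")) {
    sub <- prof[prof$tissue_class == cl & prof$n > 0, ]
    expect_equal(sum(sub$fraction * sub$n) / sum(sub$n),
                 cf$fraction[cf$tissue_class == cl])
  }
})

test_that("compartment area fractions sum to 1 and reject overlaps", {
  sq <- function(x0, w) mn_polygon(rbind(c(x0, 0), c(x0 + w, 0),
                                         c(x0 + w, w), c(x0, w)))
  ann <- function(id, geom, comp)
    list(region_id = id, roi_id = id, role = "tumor_area",
         tissue_class = NA_character_, geometry = geom,
         attributes = list(compartment = comp))
  # areas 100 / 400 / 25 with distinct footprints
  anns <- structure(list(
    ann("a", sq(0, 10), "lobule"),
    ann("b", sq(20, 20), "stroma"),
    ann("c", sq(50, 5), "other")), class = "mn_annotations")
  fr <- compartment_area_fractions(anns)
  expect_equal(unname(fr), c(100, 400, 25) / 525)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  single <- structure(list(ann("a", sq(0, 10), "stroma")),
                      class = "mn_annotations")
  expect_equal(unname(compartment_area_fractions(single)["stroma"]), 1.0)
  bad <- structure(list(ann("a", sq(0, 10), "lobule"),
                        ann("b", sq(5, 10), "stroma")),
                   class = "mn_annotations")
  expect_error(compartment_area_fractions(bad), "a/b")
})

test_that("area fractions agree with an independent shoelace computation", {
  set.seed(23)
  mk <- function(cx, comp, id) {
    ang <- sort(runif(7, 0, 2 * pi)); r <- runif(7, 5, 12)
    list(region_id = id, roi_id = id, role = "tumor_area",
         tissue_class = NA_character_,
         geometry = mn_polygon(cbind(cx + r * cos(ang), r * sin(ang))),
         attributes = list(compartment = comp))
  }
  anns <- structure(list(mk(0, "lobule", "p1"), mk(40, "stroma", "p2"),
                         mk(80, "stroma", "p3")), class = "mn_annotations")
  shoelace <- function(m) {
    n <- nrow(m); s <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      s <- s + m[i, 1] * m[j, 2] - m[j, 1] * m[i, 2]
    }
    abs(s) / 2
  }
  areas <- vapply(anns, function(a) shoelace(a$geometry$outer), numeric(1))
  fr <- compartment_area_fractions(anns)
  expect_equal(unname(fr["lobule"]), areas[1] / sum(areas), tolerance = 1e-12)
  expect_equal(unname(fr["stroma"]), sum(areas[2:3]) / sum(areas),
               tolerance = 1e-12)
})

test_that("exocrine composition counts AMY/KRT19 phenotypes per lobule", {
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:11),
    x_um = 1:11, y_um = 1,
    tissue_class = c(rep("acinar", 4), rep("adm", 3), rep("duct", 2),
                     "immune", "tumor"),
    roi_id = "lob1", compartment = "lobule", tumor_id = "T01",
    positive_AMY = c(rep(TRUE, 4), rep(TRUE, 3), rep(FALSE, 2), FALSE, FALSE),
    positive_KRT19 = c(rep(FALSE, 4), rep(TRUE, 3), rep(TRUE, 2), FALSE, TRUE),
    stringsAsFactors = FALSE)
  lob <- structure(list(list(region_id = "lob1", roi_id = "lob1",
                             role = "lobule", tissue_class = NA_character_,
                             geometry = unit_square(50),
                             attributes = list(atrophy_stage = "mild"))),
                   class = "mn_annotations")
  ec <- exocrine_composition(cells, lob)
  # tumor cell excluded: denominator 10; 4 AMY+only, 3 double, 2 KRT19+only
  expect_equal(ec$n_cells, 10)
  expect_equal(ec$frac_amy_only, 0.4)
  expect_equal(ec$frac_double, 0.3)
  expect_equal(ec$frac_krt19_only, 0.2)
  expect_identical(ec$atrophy_stage, "mild")
  # empty lobule -> NA fractions
  lob2 <- lob; lob2[[1]]$roi_id <- "lobX"; lob2[[1]]$region_id <- "lobX"
  ec2 <- exocrine_composition(cells, structure(lob2, class = "mn_annotations"))
  expect_true(is.na(ec2$frac_amy_only) && ec2$n_cells == 0)
})

test_that("stage-dependent composition reproduces the planted pattern", {
  cfg <- synthetic_config(seed = 77, n_tumors = 5, rois_per_compartment = 2,
                          tumor_cells_per_roi = c(299, 400), nontumor_ratio = 2)
  co <- generate_cohort(cfg)
  lobs <- Filter(function(a) identical(a$role, "roi_boundary") &&
                   !is.null(a$attributes$atrophy_stage), co$regions)
  ec <- exocrine_composition(co$cells, structure(lobs, class = "mn_annotations"))
  means <- aggregate(cbind(frac_amy_only, frac_double) ~ atrophy_stage,
                     data = ec, FUN = mean)
  amy <- setNames(means$frac_amy_only, means$atrophy_stage)
  dbl <- setNames(means$frac_double, means$atrophy_stage)
  expect_gt(amy[["minimal"]], amy[["end-stage"]])          # acinar loss
  expect_gt(max(dbl[c("mild", "moderate")]), dbl[["end-stage"]])  # ADM peak
})

test_that("proximity grouping is strict and the comparison flags planted shifts", {
  # strict boundary: 19 um -> within, 20 um -> above
  cells <- data.frame(
    cell_id = c("t1", "t2", "r1"),
    x_um = c(19, 20, 0), y_um = 0,
    tissue_class = c("tumor", "tumor", "acinar"),
    roi_id = "r", compartment = "lobule", tumor_id = "T01",
    counterstain_intensity = 1, intensity_M = c(2, 1, 0),
    stringsAsFactors = FALSE)
  res <- proximity_intensity_compare(cells, "acinar", "M")
  expect_identical(res$cells$group, c("within", "above"))
  # identical normalized values everywhere -> NA p by convention
  cells$intensity_M <- cells$counterstain_intensity
  res2 <- proximity_intensity_compare(cells, "acinar", "M")
  expect_true(all(res2$cells[, "norm_M"] == 1))
  expect_true(is.na(res2$tests$p))
  # planted 1.5x shift, lognormal noise: detected with small p
  set.seed(41)
  n <- 400
  sim <- data.frame(
    cell_id = sprintf("c%d", 1:(2 * n + 1)),
    x_um = c(runif(n, 0, 10), runif(n, 100, 200), 0), y_um = 0,
    tissue_class = c(rep("tumor", 2 * n), "acinar"),
    roi_id = "r", compartment = "lobule", tumor_id = "T01",
    counterstain_intensity = exp(rnorm(2 * n + 1, 0, 0.1)),
    stringsAsFactors = FALSE)
  sim$intensity_M <- exp(rnorm(2 * n + 1, 0, 0.3)) *
    c(rep(1.5, n), rep(1, n), 1) * sim$counterstain_intensity
  res3 <- proximity_intensity_compare(sim, "acinar", "M")
  expect_lt(res3$tests$p_adj, 0.05)
  expect_gt(res3$tests$median_within, res3$tests$median_above)
})
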