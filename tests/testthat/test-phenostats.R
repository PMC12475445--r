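test_that("fraction matrix computes positives over tumor cells with NA policy", {
  cells <- rbind(
    transform(tiny_cells(), roi_id = "r1"),
    transform(tiny_cells(), roi_id = "r2", cell_id = c("c4", "c5", "c6"),
              positive_MUC5AC = c(FALSE, FALSE, FALSE)))
  fm <- build_fraction_matrix(cells, markers = "MUC5AC")
  # one tumor cell per ROI; positive in r1, negative in r2
  expect_equal(unname(fm$matrix["MUC5AC", c("r1", "r2")]), c(1, 0))
  # 300 tumor cells, 75 positive -> 0.25
  big <- data.frame(cell_id = sprintf("c%d", 1:300), x_um = 1, y_um = 1,
                    tissue_class = "tumor", roi_id = "R", compartment = "stroma",
                    tumor_id = "T01",
                    positive_X = c(rep(TRUE, 75), rep(FALSE, 225)))
  expect_equal(unname(build_fraction_matrix(big, "X")$matrix["X", "R"]), 0.25)
  # marker not measured -> NA, not 0; declared all-negative -> 0
  big$positive_Y <- NA
  fm2 <- build_fraction_matrix(big, c("X", "Y"),
                               all_negative = list(Y = "other_roi"))
  expect_true(is.na(fm2$matrix["Y", "R"]))
  fm3 <- build_fraction_matrix(big, c("X", "Y"), all_negative = list(Y = "R"))
  expect_equal(unname(fm3$matrix["Y", "R"]), 0)
  # threshold required when only intensities exist
  big$positive_Y <- NULL; big$intensity_Y <- 1
  expect_error(build_fraction_matrix(big, "Y"), "threshold missing")
})

test_that("paired compartment test handles degenerate and planted cases", {
  # all pairs identical -> NA p, flagged
  sim <- simulate_fraction_cohort(c(M = 0.3), n_tumors = 6, seed = 2)
  sim$matrix[1, ] <- 0.5
  res <- paired_compartment_test(sim)
  expect_true(is.na(res$p))
  expect_identical(res$note, "all_differences_zero")
  # fewer than 2 complete pairs -> NA with warning
  sim2 <- simulate_fraction_cohort(c(M = 0.3), n_tumors = 2, seed = 3)
  sim2$matrix[1, sim2$meta$tumor_id == "T01"] <- NA
  sim2$matrix[1, sim2$meta$tumor_id == "T02" &
                sim2$meta$compartment == "lobule"] <- NA
  expect_warning(res2 <- paired_compartment_test(sim2), "fewer than 2")
  expect_true(is.na(res2$p))
  # planted shift is detected and direction is right
  sim3 <- simulate_fraction_cohort(c(UP = 0.3, NULL1 = 0), n_tumors = 30,
                                   seed = 4)
  res3 <- paired_compartment_test(sim3)
  expect_lt(res3$p_adj[res3$marker == "UP"], 0.001)
  expect_gt(res3$mean_lobule[res3$marker == "UP"],
            res3$mean_stroma[res3$marker == "UP"])
})

test_that("BH adjustment follows the step-up rule and its invariants", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))   # frozen hand application
  set.seed(6)
  praw <- runif(25)
  padj <- p.adjust(praw, "BH")
  expect_true(all(padj >= praw))
  expect_true(all(diff(padj[order(praw)]) >= -1e-15))   # monotone in raw p
})

test_that("kruskal_dunn reproduces hand-computed statistics", {
  # H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2, no ties:
  # groups A: ranks 1,2,3 ; B: ranks 4,5,6 -> H = 27/7 = 3.857
  kd <- kruskal_dunn(c(1, 2, 3, 4, 5, 6), c("A", "A", "A", "B", "B", "B"))
  expect_equal(kd$statistic, 27 / 7, tolerance = 1e-6)
  # identical values -> statistic 0, p 1
  kd0 <- kruskal_dunn(rep(5, 8), rep(c("A", "B"), each = 4))
  expect_equal(kd0$statistic, 0)
  expect_equal(kd0$p_value, 1)
  expect_error(kruskal_dunn(1:3, rep("A", 3)), "at least 2")
})

test_that("Dunn flags only pairs involving the shifted group", {
  hits_shift <- 0; hits_null <- 0; n_rep <- 200
  set.seed(8)
  for (r in 1:n_rep) {
    vals <- c(rnorm(5, 0), rnorm(5, 0), rnorm(5, 3))
    kd <- kruskal_dunn(vals, rep(c("g1", "g2", "g3"), each = 5))
    pw <- kd$pairwise
    with3 <- pw$group1 == "g3" | pw$group2 == "g3"
    # "flags only pairs involving g3": some g3 pair significant, null pair not
    if (any(pw$p_adj[with3] < 0.05)) hits_shift <- hits_shift + 1
    if (any(pw$p_adj[!with3] < 0.05)) hits_null <- hits_null + 1
  }
  expect_gte(hits_shift / n_rep, 0.90)
  expect_lt(hits_null / n_rep, 0.15)
})

test_that("simpson_diversity matches enumeration and hits the extremes", {
  expect_equal(simpson_diversity(c(0.51, 0.52, 0.55)), 0)     # one decile
  expect_equal(simpson_diversity(c(0.05, 0.45, 0.95)), 1)     # all distinct
  # counts (2,1): 3 pairs, 1 same-bin pair -> 2/3
  expect_equal(simpson_diversity(c(0.11, 0.12, 0.31)), 2 / 3)
  expect_true(is.na(simpson_diversity(c(0.5))))
  expect_true(is.na(simpson_diversity(c(0.5, NA))))
  # invariant to ROI order; bounded in [0, 1]
  set.seed(9)
  for (i in 1:20) {
    fr <- runif(sample(2:12, 1))
    s <- simpson_diversity(fr)
    expect_equal(simpson_diversity(sample(fr)), s)
    expect_gte(s, 0); expect_lte(s, 1)
  }
  # raw-fraction variant treats distinct values as categories
  expect_equal(simpson_diversity(c(0.11, 0.12, 0.11), binned = FALSE), 2 / 3)
})

test_that("cluster_rois separates duplicated blocks and is order-invariant", {
  block <- function(val, ids) {
    m <- matrix(val, nrow = 3, ncol = length(ids),
                dimnames = list(c("m1", "m2", "m3"), ids))
    m + matrix(rnorm(length(m), 0, 0.01), nrow = 3)
  }
  set.seed(10)
  mat <- cbind(block(0.2, sprintf("A%d", 1:4)), block(0.8, sprintf("B%d", 1:4)))
  meta <- data.frame(roi_id = colnames(mat),
                     tumor_id = "T01",
                     compartment = rep(c("lobule", "stroma"), each = 4))
  fm <- list(matrix = mat, meta = meta)
  cl <- cluster_rois(fm, k = 2)
  expect_equal(adjusted_rand_index(cl$labels, rep(1:2, each = 4)), 1)
  # permuting input columns leaves the result identical
  perm <- sample(ncol(mat))
  cl2 <- cluster_rois(list(matrix = mat[, perm], meta = meta[perm, ]), k = 2)
  expect_identical(cl$order, cl2$order)
  expect_identical(cl$labels, cl2$labels)
  # all-NA marker rows are dropped with a warning
  mat2 <- rbind(mat, bad = NA)
  expect_warning(cluster_rois(list(matrix = mat2, meta = meta), 2), "all-NA")
})

test_that("subtype_contingency applies the tie margin and frozen test values", {
  # frozen: table [[2,0],[0,2]] -> Fisher p = 1/3, chi-squared = 4 uncorrected
  res <- subtype_contingency(basal = c(0.9, 0.8, 0.1, 0.2),
                             classical = c(0.1, 0.2, 0.9, 0.8),
                             compartment = c("stroma", "stroma", "lobule", "lobule"))
  expect_equal(unname(res$table["basal", "stroma"]), 2)
  expect_equal(res$fisher_p, 1 / 3, tolerance = 1e-9)
  expect_equal(res$chisq_statistic, 4)
  # 0.50 vs 0.48 with delta 0.05 -> indeterminate, excluded
  res2 <- subtype_contingency(c(0.50, 0.9, 0.1), c(0.48, 0.1, 0.9),
                              c("lobule", "stroma", "lobule"))
  expect_identical(res2$labels[1], "indeterminate")
  expect_equal(sum(res2$table), 2)
  # zero margin: chi-squared NA, Fisher still computed
  res3 <- subtype_contingency(c(0.9, 0.8), c(0.1, 0.1), c("lobule", "stroma"))
  expect_true(is.na(res3$chisq_statistic))
  expect_false(is.na(res3$fisher_p))
})
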