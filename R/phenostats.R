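## -- compartment phenotype statistics -----------------------------------------

#' Build a marker x ROI positive-fraction matrix
#'
#' Per ROI and marker, the fraction of tumor cells positive for the marker.
#' Positivity comes from `positive_<marker>` columns or, when absent, from
#' `intensity_<marker> >= thresholds[marker]`; a measured marker without
#' either is an error. ROIs declared completely negative for a marker are
#' set to fraction 0 (the only imputation performed); a marker not measured
#' in an ROI stays `NA`, never 0.
#'
#' @param cells data.frame of cells with `tumor_id` per ROI.
#' @param markers marker names; default: all `positive_`/`intensity_`
#'   columns found.
#' @param thresholds optional named numeric per-marker thresholds (used when
#'   a positivity column is absent).
#' @param all_negative optional named list: marker -> character vector of
#'   ROI ids declared completely negative (set to 0).
#' @return An `mn_fraction_matrix`: list with `matrix` (markers x ROIs,
#'   values in `[0,1]` or `NA`) and `meta` (data.frame `roi_id`, `tumor_id`,
#'   `compartment`).
#' @export
build_fraction_matrix <- function(cells, markers = NULL, thresholds = NULL,
                                  all_negative = NULL) {
  if (is.null(markers)) {
    markers <- unique(c(sub("^positive_", "", grep("^positive_", names(cells), value = TRUE)),
                        sub("^intensity_", "", grep("^intensity_", names(cells), value = TRUE))))
    markers <- setdiff(markers, c("AMY", "KRT19"))
  }
  if (!length(markers)) stopf("no markers found")
  if (!"tumor_id" %in% names(cells)) stopf("cells need a 'tumor_id' column")
  tum <- cells[cells$tissue_class == "tumor", , drop = FALSE]
  rois <- unique(tum$roi_id)
  meta <- unique(tum[, c("roi_id", "tumor_id", "compartment")])
  if (anyDuplicated(meta$roi_id))
    stopf("ROI(s) with inconsistent tumor_id/compartment metadata")
  meta <- meta[match(rois, meta$roi_id), , drop = FALSE]
  rownames(meta) <- NULL
  mat <- matrix(NA_real_, nrow = length(markers), ncol = length(rois),
                dimnames = list(markers, rois))
  for (m in markers) {
    pos_col <- paste0("positive_", m); int_col <- paste0("intensity_", m)
    if (pos_col %in% names(tum)) {
      pos <- tum[[pos_col]]
    } else if (int_col %in% names(tum)) {
      if (is.null(thresholds) || !m %in% names(thresholds))
        stopf("threshold missing for measured marker '%s'", m)
      pos <- tum[[int_col]] >= thresholds[[m]]
    } else stopf("marker '%s' has neither positivity nor intensity column", m)
    ok <- !is.na(pos)
    for (roi in rois) {
      idx <- tum$roi_id == roi & ok
      n <- sum(idx)
      if (n > 0) mat[m, roi] <- sum(pos[idx]) / n
    }
    neg <- all_negative[[m]]
    if (!is.null(neg)) mat[m, intersect(neg, rois)] <- 0
  }
  structure(list(matrix = mat, meta = meta), class = "mn_fraction_matrix")
}

as_fraction_matrix <- function(x) {
  if (inherits(x, "mn_fraction_matrix")) return(x)
  if (is.list(x) && !is.null(x$matrix) && !is.null(x$meta))
    return(structure(x[c("matrix", "meta")], class = "mn_fraction_matrix"))
  stopf("expected an mn_fraction_matrix (or list with $matrix and $meta)")
}

#' Paired compartment test per marker
#'
#' For each marker: compute each tumor's mean positive fraction per
#' compartment (over that tumor's ROIs), then run a two-tailed paired
#' Wilcoxon signed-rank test on the tumor-level lobule/stroma pairs, with
#' Benjamini-Hochberg correction across the marker family. Tumors missing a
#' compartment for a marker are dropped (count reported); zero differences
#' are dropped per the signed-rank convention, and an all-zero marker gets
#' `NA` p with a flag rather than p = 1.
#'
#' @param fm an `mn_fraction_matrix` from [build_fraction_matrix()] or
#'   [simulate_fraction_cohort()].
#' @return data.frame per marker: `n_pairs`, `n_dropped`, `mean_lobule`,
#'   `mean_stroma`, `statistic` (V), `p`, `p_adj`, `note`.
#' @export
paired_compartment_test <- function(fm) {
  fm <- as_fraction_matrix(fm)
  mat <- fm$matrix; meta <- fm$meta
  tumors <- unique(meta$tumor_id)
  out <- list()
  for (m in rownames(mat)) {
    lob <- str <- rep(NA_real_, length(tumors))
    for (i in seq_along(tumors)) {
      cols_l <- meta$tumor_id == tumors[i] & meta$compartment == "lobule"
      cols_s <- meta$tumor_id == tumors[i] & meta$compartment == "stroma"
      vl <- mat[m, cols_l]; vs <- mat[m, cols_s]
      if (any(!is.na(vl))) lob[i] <- mean(vl, na.rm = TRUE)
      if (any(!is.na(vs))) str[i] <- mean(vs, na.rm = TRUE)
    }
    complete <- !is.na(lob) & !is.na(str)
    n_dropped <- sum(!complete)
    lobc <- lob[complete]; strc <- str[complete]
    note <- ""
    if (sum(complete) < 2L) {
      warnf("marker %s: fewer than 2 complete tumor pairs; p set to NA", m)
      stat <- NA_real_; p <- NA_real_; note <- "insufficient_pairs"
    } else if (all(lobc == strc)) {
      stat <- NA_real_; p <- NA_real_; note <- "all_differences_zero"
    } else {
      wt <- suppressWarnings(wilcox.test(lobc, strc, paired = TRUE,
                                         alternative = "two.sided"))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    out[[m]] <- data.frame(
      marker = m, n_pairs = sum(complete), n_dropped = n_dropped,
      mean_lobule = mean(lobc), mean_stroma = mean(strc),
      statistic = stat, p = p, note = note, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$p_adj <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res[, c("marker", "n_pairs", "n_dropped", "mean_lobule", "mean_stroma",
          "statistic", "p", "p_adj", "note")]
}

#' Kruskal-Wallis test with BH-corrected Dunn post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis rank-sum test across groups, followed by
#' Dunn's pairwise z tests on mean ranks with Benjamini-Hochberg correction
#' across the pairwise family.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @return List: `statistic`, `df`, `p_value`, `pairwise` (data.frame
#'   `group1`, `group2`, `z`, `p`, `p_adj`).
#' @export
kruskal_dunn <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  tab <- table(groups)
  empty <- names(tab)[tab == 0]
  if (length(empty)) warnf("dropping empty group(s): %s", paste(empty, collapse = ", "))
  g <- factor(groups)
  if (nlevels(g) < 2L) stopf("need at least 2 non-empty groups")
  if (length(unique(values)) == 1L) {
    # fully tied data carry no rank information: H = 0, p = 1
    pairs <- utils::combn(levels(g), 2L)
    return(list(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                pairwise = data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                                      z = 0, p = 1, p_adj = 1,
                                      stringsAsFactors = FALSE)))
  }
  kw <- kruskal.test(values, g)
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sig2 <- N * (N + 1) / 12 - tie_term
  levs <- levels(g)
  mean_rank <- tapply(rk, g, mean)
  n_g <- tapply(rk, g, length)
  pairs <- utils::combn(levs, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt(sig2 * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[k] <- if (se > 0) (mean_rank[[a]] - mean_rank[[b]]) / se else 0
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         z = z, p = p, p_adj = p.adjust(p, method = "BH"),
                         stringsAsFactors = FALSE)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, pairwise = pairwise)
}

#' Simpson diversity of per-ROI marker fractions
#'
#' The probability that two ROIs drawn without replacement differ in their
#' (binned) positive fraction: fractions are placed into `n_bins` equal-width
#' bins on `[0, 1]` and the Gini-Simpson index
#' `1 - sum(n_i * (n_i - 1)) / (N * (N - 1))` is computed over the bin
#' counts. 0 when all ROIs share a bin, 1 when all differ. With
#' `binned = FALSE` the raw fractions are treated as categories instead
#' (continuous fractions almost never tie, so the binned variant is the
#' default and the bin count is explicit).
#'
#' @param fractions numeric vector of per-ROI fractions in `[0, 1]`; `NA`s
#'   are dropped.
#' @param n_bins number of equal-width bins (default 10 = deciles).
#' @param binned use binning (default) or raw distinct values.
#' @return Index in `[0, 1]`, or `NA` for fewer than 2 ROIs.
#' @export
simpson_diversity <- function(fractions, n_bins = 10L, binned = TRUE) {
  fr <- fractions[!is.na(fractions)]
  if (length(fr) < 2L) return(NA_real_)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]")
  cat <- if (binned) pmin(floor(fr * n_bins) + 1L, n_bins) else match(fr, unique(fr))
  n_i <- table(cat)
  N <- length(fr)
  1 - sum(n_i * (n_i - 1)) / (N * (N - 1))
}

#' Hierarchically cluster ROIs on their marker-fraction profiles
#'
#' Columns (ROIs) are clustered with Euclidean distance and Ward linkage
#' after imputing missing values with the marker's median; all-NA marker
#' rows are dropped with a warning. Columns are pre-sorted by id before
#' clustering so the result is invariant to input column order (the
#' documented tie-break).
#'
#' @param fm an `mn_fraction_matrix`.
#' @param k number of clusters to cut (default 2).
#' @return List: `order` (ROI ids in dendrogram leaf order), `labels`
#'   (named cluster ids), `hclust` (the tree).
#' @export
cluster_rois <- function(fm, k = 2L) {
  fm <- as_fraction_matrix(fm)
  mat <- fm$matrix
  if (ncol(mat) < 2L) stopf("need at least 2 ROI columns")
  all_na <- apply(mat, 1L, function(r) all(is.na(r)))
  if (any(all_na)) {
    warnf("dropping all-NA marker row(s): %s",
          paste(rownames(mat)[all_na], collapse = ", "))
    mat <- mat[!all_na, , drop = FALSE]
  }
  for (i in seq_len(nrow(mat))) {
    miss <- is.na(mat[i, ])
    if (any(miss)) mat[i, miss] <- median(mat[i, ], na.rm = TRUE)
  }
  mat <- mat[, order(colnames(mat)), drop = FALSE]   # determinism tie-break
  hc <- hclust(dist(t(mat)), method = "ward.D2")
  labels <- cutree(hc, k = k)
  list(order = colnames(mat)[hc$order], labels = labels, hclust = hc)
}

#' Predominant-subtype classification with contingency tests
#'
#' Labels each ROI `basal` when the basal fraction exceeds the classical
#' fraction by more than `delta`, `classical` for the reverse, and
#' `indeterminate` (excluded) otherwise; then tests the 2x2 subtype x
#' compartment table with a two-sided Pearson chi-squared test (uncorrected)
#' and a two-sided Fisher exact test. A zero table margin makes the
#' chi-squared statistic undefined (`NA`); Fisher is still computed.
#'
#' @param basal,classical per-ROI positive fractions for the basal and
#'   classical marker.
#' @param compartment per-ROI compartment labels (`lobule`/`stroma`).
#' @param delta indeterminate margin (default 0.05).
#' @return List: `labels`, `table`, `chisq_statistic`, `chisq_p`,
#'   `fisher_p`.
#' @export
subtype_contingency <- function(basal, classical, compartment, delta = 0.05) {
  if (length(basal) != length(classical) || length(basal) != length(compartment))
    stopf("inputs must have equal length")
  if (any(is.na(basal)) || any(is.na(classical)))
    stopf("both marker fractions must be present for every ROI")
  diff <- basal - classical
  labels <- ifelse(diff > delta, "basal",
                   ifelse(diff < -delta, "classical", "indeterminate"))
  keep <- labels != "indeterminate"
  tab <- table(subtype = factor(labels[keep], levels = c("basal", "classical")),
               compartment = factor(compartment[keep],
                                    levels = c("lobule", "stroma")))
  chisq_stat <- chisq_p <- NA_real_
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    chisq_stat <- unname(ct$statistic); chisq_p <- ct$p.value
  }
  fisher_p <- fisher.test(tab, alternative = "two.sided")$p.value
  list(labels = labels, table = tab, chisq_statistic = chisq_stat,
       chisq_p = chisq_p, fisher_p = fisher_p)
}
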