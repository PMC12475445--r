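## -- stromal marker profiles around tumor regions -----------------------------

#' Per-layer positive-cell fractions with enrichment tests
#'
#' Assigns cells to the concentric stromal layers of `layers` by the
#' half-open distance rule (a cell at exactly 15 um with 15 um rings falls
#' in the middle layer), optionally pre-filtering cells with high nuclear
#' circularity (non-stromal morphology) and cells positive for a tumor
#' marker, then reports per-layer positive fractions and a Kruskal-Wallis /
#' Dunn test across layers per marker.
#'
#' @param cells data.frame with `x_um`, `y_um` and `positive_<marker>`
#'   columns.
#' @param layers an `mn_layers` from [build_annuli()].
#' @param markers marker names to profile.
#' @param circularity_max optional cut: drop cells with
#'   `nuclear_circularity > circularity_max` (the upstream filter enriching
#'   for stromal content; 0.85 is a sensible cut when enabled).
#' @param exclude_marker optional tumor marker (e.g. `"p53"`): cells
#'   positive for it are dropped.
#' @return List: `fractions` (data.frame marker/layer/n/fraction, `NA` for
#'   empty layers), `tests` (per marker, [kruskal_dunn()] output), `layer`
#'   (the per-cell layer assignment).
#' @export
layer_fractions <- function(cells, layers, markers,
                            circularity_max = NULL, exclude_marker = NULL) {
  stopifnot(inherits(layers, "mn_layers"))
  if (!is.null(circularity_max) && "nuclear_circularity" %in% names(cells))
    cells <- cells[is.na(cells$nuclear_circularity) |
                     cells$nuclear_circularity <= circularity_max, , drop = FALSE]
  if (!is.null(exclude_marker)) {
    col <- paste0("positive_", exclude_marker)
    if (col %in% names(cells))
      cells <- cells[!isTRUE_vec(cells[[col]]), , drop = FALSE]
  }
  idx <- layer_index(cells, layers)
  frac <- list(); tests <- list()
  for (m in markers) {
    col <- paste0("positive_", m)
    if (!col %in% names(cells)) stopf("missing column '%s'", col)
    pos <- as.logical(cells[[col]])
    for (k in seq_len(layers$n_rings)) {
      in_k <- !is.na(idx) & idx == k
      n <- sum(in_k)
      frac[[length(frac) + 1L]] <- data.frame(
        marker = m, layer = k, n = n,
        fraction = if (n > 0) mean(pos[in_k]) else NA_real_,
        stringsAsFactors = FALSE)
    }
    keep <- !is.na(idx)
    tests[[m]] <- if (length(unique(idx[keep])) >= 2L)
      kruskal_dunn(as.numeric(pos[keep]), idx[keep]) else NULL
  }
  fractions <- do.call(rbind, frac)
  rownames(fractions) <- NULL
  list(fractions = fractions, tests = tests, layer = idx)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Coexpression overlap within a marker-positive population
#'
#' Among cells positive for `base_marker`, the fraction also positive for
#' each other marker, plus the full 2^k intersection-pattern counts for
#' Venn-style reporting (patterns partition the base-positive population,
#' so their counts sum to it exactly).
#'
#' @param cells data.frame with `positive_<marker>` columns.
#' @param base_marker the anchoring marker (e.g. `"NGFR"`).
#' @param other_markers markers to intersect with (e.g. ASMA, PDGFRA, CD74).
#' @return List: `n_base`, `fractions` (named), `patterns` (data.frame
#'   `pattern`, `count`, `fraction`); `NA` fractions with a warning when no
#'   base-positive cells exist.
#' @export
coexpression_overlap <- function(cells, base_marker, other_markers) {
  for (m in c(base_marker, other_markers))
    if (!paste0("positive_", m) %in% names(cells))
      stopf("missing positivity column for marker '%s'", m)
  base <- isTRUE_vec(cells[[paste0("positive_", base_marker)]])
  n_base <- sum(base)
  if (n_base == 0L) {
    warnf("no %s-positive cells; fractions are NA", base_marker)
    return(list(n_base = 0L,
                fractions = setNames(rep(NA_real_, length(other_markers)),
                                     other_markers),
                patterns = data.frame(pattern = character(0), count = integer(0),
                                      fraction = numeric(0))))
  }
  sub <- cells[base, , drop = FALSE]
  flags <- vapply(other_markers,
                  function(m) isTRUE_vec(sub[[paste0("positive_", m)]]),
                  logical(n_base))
  flags <- matrix(flags, nrow = n_base,
                  dimnames = list(NULL, other_markers))
  fractions <- colSums(flags) / n_base
  pat <- apply(flags, 1L, function(r)
    paste(paste0(other_markers, ifelse(r, "+", "-")), collapse = "/"))
  tab <- table(pat)
  patterns <- data.frame(pattern = names(tab), count = as.integer(tab),
                         fraction = as.integer(tab) / n_base,
                         stringsAsFactors = FALSE)
  patterns <- patterns[order(-patterns$count, patterns$pattern), , drop = FALSE]
  rownames(patterns) <- NULL
  list(n_base = n_base, fractions = fractions, patterns = patterns)
}

#' Stromal intensity gradient versus invasion-front distance
#'
#' For tumor cells in direct contact with fibrosis (nearest fibrosis
#' distance strictly below `contact_radius_um` in the supplied contact
#' table), measures the mean disk intensity (radius `disk_radius_um`,
#' negatives clamped to zero) around each cell and profiles a rolling
#' mean +/- sample SD of these intensities over distance to the invasion
#' front. Windows with fewer than `min_cells` cells report `NA`. Reference
#' populations (e.g. acinar and ADM cells) get the same disk measurement
#' without front conditioning.
#'
#' @param tumor_cells data.frame of tumor cells (`cell_id`, `x_um`,
#'   `y_um`).
#' @param field an [intensity_field()] covering all included disks.
#' @param front an `mn_polyline` invasion front.
#' @param contacts contact table from [call_contacts()] (supplies
#'   `nearest_fibrosis`).
#' @param disk_radius_um disk radius (default 25: a 50 um diameter disk;
#'   the upstream protocol is ambiguous between 25 and 50, so this is
#'   always explicit).
#' @param window_um full width of the rolling window (default 25).
#' @param min_cells minimum cells per window (default 20).
#' @param contact_radius_um fibrosis-contact inclusion radius (default 20).
#' @param reference_cells optional data.frame of non-tumor cells with a
#'   `tissue_class` column; per-class mean disk intensities are returned.
#' @return List of class `mn_gradient`: `cells` (per included tumor cell:
#'   `distance_to_front`, `disk_mean`), `profile` (distance-ordered rolling
#'   `mean`, `sd`, `n`), `references` (named means), `n_excluded`.
#' @export
ngfr_gradient <- function(tumor_cells, field, front, contacts,
                          disk_radius_um = 25, window_um = 25,
                          min_cells = 20L, contact_radius_um = 20,
                          reference_cells = NULL) {
  stopifnot(inherits(field, "mn_field"), inherits(front, "mn_polyline"))
  nf <- contacts$nearest_fibrosis[match(tumor_cells$cell_id, contacts$cell_id)]
  include <- !is.na(nf) & nf < contact_radius_um
  n_excluded <- sum(!include)
  sub <- tumor_cells[include, , drop = FALSE]
  if (nrow(sub) == 0L)
    stopf("no tumor cells with fibrosis contact within %g um", contact_radius_um)
  xy <- as.matrix(sub[, c("x_um", "y_um")])
  dmean <- vapply(seq_len(nrow(sub)), function(i)
    disk_mean_intensity(field, xy[i, ], disk_radius_um), numeric(1))
  dfront <- distance_to_annotation(xy, front)
  ord <- order(dfront)
  cells <- data.frame(cell_id = sub$cell_id[ord],
                      distance_to_front = dfront[ord],
                      disk_mean = dmean[ord], stringsAsFactors = FALSE)
  half <- window_um / 2
  prof_mean <- prof_sd <- rep(NA_real_, nrow(cells))
  prof_n <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    w <- abs(cells$distance_to_front - cells$distance_to_front[i]) <= half
    prof_n[i] <- sum(w)
    if (prof_n[i] >= min_cells) {
      prof_mean[i] <- mean(cells$disk_mean[w])
      prof_sd[i] <- sd(cells$disk_mean[w])
    }
  }
  profile <- data.frame(distance = cells$distance_to_front,
                        mean = prof_mean, sd = prof_sd, n = prof_n)
  references <- NULL
  if (!is.null(reference_cells) && nrow(reference_cells)) {
    references <- vapply(split(reference_cells,
                               reference_cells$tissue_class), function(rc) {
      rxy <- as.matrix(rc[, c("x_um", "y_um")])
      mean(vapply(seq_len(nrow(rc)), function(i)
        disk_mean_intensity(field, rxy[i, ], disk_radius_um), numeric(1)))
    }, numeric(1))
  }
  structure(list(cells = cells, profile = profile, references = references,
                 n_excluded = n_excluded, disk_radius_um = disk_radius_um,
                 window_um = window_um),
            class = "mn_gradient")
}

#' Thresholded positive-area fraction of a region
#'
#' Fraction of the region's pixels (assigned by pixel-center containment)
#' whose clamped intensity strictly exceeds `threshold`. Thresholds are
#' per-section configuration, mirroring the upstream per-slide visual
#' cut-offs; no automatic thresholding is attempted.
#'
#' @param field an [intensity_field()].
#' @param region an `mn_polygon`.
#' @param threshold intensity cut-off.
#' @return Fraction in `[0, 1]`, or `NA` when the region contains no pixel
#'   centers.
#' @export
positive_area_fraction <- function(field, region, threshold) {
  stopifnot(inherits(field, "mn_field"), inherits(region, "mn_polygon"))
  assert_scalar_num(threshold, "threshold")
  px <- field$pixel_size_um
  bb <- apply(region$outer, 2L, range)
  nr <- nrow(field$grid); nc <- ncol(field$grid)
  j0 <- max(1L, floor((bb[1, 1] - field$origin_um[1]) / px) + 1L)
  j1 <- min(nc, ceiling((bb[2, 1] - field$origin_um[1]) / px))
  i0 <- max(1L, floor((bb[1, 2] - field$origin_um[2]) / px) + 1L)
  i1 <- min(nr, ceiling((bb[2, 2] - field$origin_um[2]) / px))
  if (j0 > j1 || i0 > i1) return(NA_real_)
  jj <- j0:j1; ii <- i0:i1
  cx <- field$origin_um[1] + (jj - 0.5) * px
  cy <- field$origin_um[2] + (ii - 0.5) * px
  pts <- cbind(rep(cx, each = length(ii)), rep(cy, times = length(jj)))
  inside <- points_in_polygon(pts, region)
  if (!any(inside)) return(NA_real_)
  vals <- pmax(field$grid[ii, jj, drop = FALSE][inside], 0)
  mean(vals > threshold)
}
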