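## -- niche composition: what tumor cells touch --------------------------------

#' Call tumor-cell contacts within a fixed radius
#'
#' For every tumor cell, finds the tissue classes with at least one target
#' (class-labeled cell or class region annotation) at distance strictly less
#' than `radius_um` (default 20 um, the upstream contact rule), and the
#' nearest distance per class. Distances to the ROI's invasion front are
#' filled where a front annotation exists. Region classes outside the closed
#' vocabulary map to `"other"` rather than erroring.
#'
#' @param cells data.frame of cells (canonical columns; non-tumor cells are
#'   contact targets).
#' @param regions optional `mn_annotations`; polygons with a `tissue_class`
#'   act as targets, polylines with role `"front"` supply front distances.
#' @param radius_um contact radius in micrometres (strict `<`).
#' @return A contact table: one row per tumor cell with `nearest_<class>`
#'   distance columns (`NA` when the class is absent in the ROI),
#'   `distance_to_front`, `roi_id`, `compartment`. The radius is stored in
#'   `attr(, "radius_um")`.
#' @export
call_contacts <- function(cells, regions = NULL, radius_um = 20) {
  assert_scalar_num(radius_um, "radius_um", positive = TRUE)
  tum <- cells[cells$tissue_class == "tumor", , drop = FALSE]
  classes <- setdiff(TISSUE_CLASSES, "tumor")
  if (nrow(tum) == 0L) {
    warnf("no tumor cells in input; returning empty contact table")
    out <- data.frame(cell_id = character(0), roi_id = character(0),
                      compartment = character(0),
                      distance_to_front = numeric(0))
    for (cl in classes) out[[paste0("nearest_", cl)]] <- numeric(0)
    attr(out, "radius_um") <- radius_um
    return(out)
  }
  fronts <- list(); class_regions <- list()
  if (!is.null(regions)) {
    for (ann in regions) {
      if (identical(ann$role, "front")) {
        fronts[[ann$roi_id]] <- ann$geometry
      } else if (!is.na(ann$tissue_class) && inherits(ann$geometry, "mn_polygon")) {
        cl <- if (ann$tissue_class %in% TISSUE_CLASSES) ann$tissue_class else "other"
        if (cl != "tumor")
          class_regions[[length(class_regions) + 1L]] <-
            list(roi_id = ann$roi_id, class = cl, geometry = ann$geometry)
      }
    }
  }
  rois <- unique(tum$roi_id)
  rows <- vector("list", length(rois))
  for (ri in seq_along(rois)) {
    roi <- rois[[ri]]
    q <- tum[tum$roi_id == roi, , drop = FALSE]
    qxy <- as.matrix(q[, c("x_um", "y_um")])
    targ <- cells[cells$roi_id == roi & cells$tissue_class != "tumor", , drop = FALSE]
    nearest <- matrix(NA_real_, nrow = nrow(q), ncol = length(classes),
                      dimnames = list(NULL, classes))
    for (cl in classes) {
      tc <- targ[targ$tissue_class == cl, , drop = FALSE]
      d <- rep(Inf, nrow(q))
      if (nrow(tc)) {
        txy <- as.matrix(tc[, c("x_um", "y_um")])
        for (s in seq(1L, nrow(q), by = 512L)) {
          e <- min(s + 511L, nrow(q))
          dx <- outer(qxy[s:e, 1L], txy[, 1L], "-")
          dy <- outer(qxy[s:e, 2L], txy[, 2L], "-")
          d[s:e] <- pmin(d[s:e], sqrt(apply(dx * dx + dy * dy, 1L, min)))
        }
      }
      for (cr in class_regions)
        if (identical(cr$roi_id, roi) && cr$class == cl)
          d <- pmin(d, distance_to_annotation(qxy, cr$geometry))
      nearest[, cl] <- ifelse(is.finite(d), d, NA_real_)
    }
    dfront <- if (!is.null(fronts[[roi]]))
      distance_to_annotation(qxy, fronts[[roi]]) else rep(NA_real_, nrow(q))
    df <- data.frame(cell_id = q$cell_id, roi_id = q$roi_id,
                     compartment = if ("compartment" %in% names(q))
                       q$compartment else NA_character_,
                     distance_to_front = dfront, stringsAsFactors = FALSE)
    colnames(nearest) <- paste0("nearest_", classes)
    rows[[ri]] <- cbind(df, as.data.frame(nearest))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "radius_um") <- radius_um
  out
}

contact_matrix <- function(contacts) {
  radius <- attr(contacts, "radius_um") %||% stopf("not a contact table")
  cols <- grep("^nearest_", names(contacts), value = TRUE)
  m <- as.matrix(contacts[, cols, drop = FALSE]) < radius
  m[is.na(m)] <- FALSE
  colnames(m) <- sub("^nearest_", "", cols)
  m
}

#' Per-class contact fractions and normalized contact shares
#'
#' Two complementary statistics per group: (a) the fraction of tumor cells
#' with at least one contact of each class (a cell can count toward several
#' classes, so fractions may sum to more than 1); (b) normalized shares,
#' class-contact counts divided by total contacts (sums to 1 when any
#' contact exists).
#'
#' @param contacts a contact table from [call_contacts()].
#' @param group_by optional column name of `contacts` to group by (e.g.
#'   `"compartment"`).
#' @return Tidy data.frame: group, `tissue_class`, `n_cells`, `fraction`,
#'   `share`.
#' @export
contact_fractions <- function(contacts, group_by = NULL) {
  if (nrow(contacts) == 0L) stopf("empty contact table")
  m <- contact_matrix(contacts)
  if (!is.null(group_by)) {
    if (!group_by %in% names(contacts))
      stopf("unknown group key '%s'", group_by)
    groups <- as.character(contacts[[group_by]])
  } else groups <- rep("all", nrow(contacts))
  out <- list()
  for (g in unique(groups)) {
    sub <- m[groups == g, , drop = FALSE]
    tot <- sum(sub)
    out[[g]] <- data.frame(
      group = g, tissue_class = colnames(sub), n_cells = nrow(sub),
      fraction = colMeans(sub),
      share = if (tot > 0) colSums(sub) / tot else NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Contact composition stratified by distance to the invasion front
#'
#' Bins tumor cells by their distance to the lobular invasion front into
#' half-open intervals `[0, w), [w, 2w), ...` and reports the per-class
#' contact fraction and cell count per bin. Cells without a front distance
#' are excluded and counted in `attr(, "n_excluded")`. Empty bins report
#' `NA` fractions (not 0).
#'
#' @param contacts a contact table from [call_contacts()].
#' @param bin_width_um bin width in micrometres (default 10).
#' @return Tidy data.frame: `bin_start`, `bin_end`, `n`, `tissue_class`,
#'   `fraction`.
#' @export
composition_by_front_distance <- function(contacts, bin_width_um = 10) {
  assert_scalar_num(bin_width_um, "bin_width_um", positive = TRUE)
  has_d <- !is.na(contacts$distance_to_front)
  n_excl <- sum(!has_d)
  sub <- contacts[has_d, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("no cells with a front distance")
  m <- contact_matrix(sub)
  bin <- floor(sub$distance_to_front / bin_width_um)
  bins <- seq(0L, max(bin))
  out <- list()
  for (b in bins) {
    idx <- bin == b
    n <- sum(idx)
    frac <- if (n > 0) colMeans(m[idx, , drop = FALSE]) else
      rep(NA_real_, ncol(m))
    out[[length(out) + 1L]] <- data.frame(
      bin_start = b * bin_width_um, bin_end = (b + 1) * bin_width_um,
      n = n, tissue_class = colnames(m), fraction = frac,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excl
  res
}

#' Compartment area fractions of annotated tumor area
#'
#' Shoelace areas of tumor-area polygons classed `lobule`, `stroma` or
#' `other`, as fractions of the total annotated area. Overlapping polygons
#' of different classes would double-count area and are an error.
#'
#' @param annotations `mn_annotations`; each polygon's compartment is read
#'   from `attributes$compartment`.
#' @return Named numeric vector of fractions (sums to 1).
#' @export
compartment_area_fractions <- function(annotations) {
  polys <- Filter(function(a) inherits(a$geometry, "mn_polygon"), annotations)
  if (!length(polys)) stopf("no polygon annotations supplied")
  comp <- vapply(polys, function(a)
    as.character(a$attributes$compartment %||% NA_character_), character(1))
  if (any(is.na(comp)) || !all(comp %in% c("lobule", "stroma", "other")))
    stopf("every tumor-area polygon needs attributes$compartment in {lobule, stroma, other}")
  bad <- character(0)
  for (i in seq_along(polys)) for (j in seq_len(i - 1L)) {
    if (comp[i] != comp[j] &&
        rings_overlap(polys[[i]]$geometry$outer, polys[[j]]$geometry$outer))
      bad <- c(bad, sprintf("%s/%s", polys[[j]]$region_id, polys[[i]]$region_id))
  }
  if (length(bad))
    stopf("overlapping annotations of different classes (double counting): %s",
          paste(bad, collapse = ", "))
  areas <- vapply(polys, function(a) polygon_area(a$geometry), numeric(1))
  tot <- tapply(areas, factor(comp, levels = c("lobule", "stroma", "other")),
                sum, default = 0)
  as.vector(tot / sum(areas)) -> fr
  setNames(fr, c("lobule", "stroma", "other"))
}

#' Exocrine composition of lobules by AMY/KRT19 phenotype
#'
#' Per lobule: fractions of `AMY+/KRT19-` (acinar), `AMY+/KRT19+`
#' (double-positive, early/intermediate ADM) and `AMY-/KRT19+` (ductally
#' committed) cells out of the total non-tumor cell count in the lobule
#' (tumor cells are excluded from the denominator; other cell types occupy
#' the remainder, so the three fractions sum to at most 1).
#'
#' @param cells data.frame with `positive_AMY`, `positive_KRT19`,
#'   `tissue_class` and `roi_id`.
#' @param lobules `mn_annotations` of lobule polygons carrying
#'   `attributes$atrophy_stage`; cells are matched by `roi_id`.
#' @return Tidy data.frame: `lobule_id`, `atrophy_stage`, `n_cells`,
#'   `frac_amy_only`, `frac_double`, `frac_krt19_only` (`NA` fractions for
#'   empty lobules).
#' @export
exocrine_composition <- function(cells, lobules) {
  if (!all(c("positive_AMY", "positive_KRT19") %in% names(cells)))
    stopf("cells need positive_AMY and positive_KRT19 columns")
  out <- list()
  for (ann in lobules) {
    if (!inherits(ann$geometry, "mn_polygon")) next
    stage <- ann$attributes$atrophy_stage %||% NA_character_
    sub <- cells[cells$roi_id == ann$roi_id & cells$tissue_class != "tumor", ,
                 drop = FALSE]
    n <- nrow(sub)
    if (n == 0L) {
      fr <- c(NA_real_, NA_real_, NA_real_)
    } else {
      amy <- sub$positive_AMY; krt <- sub$positive_KRT19
      fr <- c(sum(amy & !krt), sum(amy & krt), sum(!amy & krt)) / n
    }
    out[[length(out) + 1L]] <- data.frame(
      lobule_id = ann$region_id, atrophy_stage = stage, n_cells = n,
      frac_amy_only = fr[1], frac_double = fr[2], frac_krt19_only = fr[3],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare counterstain-normalized marker intensity by proximity
#'
#' Splits tumor cells into a "within" group (nearest reference-class cell at
#' distance strictly less than `radius_um`) and an "above" group, normalizes
#' each marker's nuclear intensity to the nuclear counterstain, and tests
#' the groups with a two-tailed unpaired Wilcoxon rank-sum test, BH-corrected
#' across markers. Cells with non-positive counterstain are excluded (count
#' reported via message).
#'
#' @param cells data.frame of cells; tumor cells are the queries,
#'   `reference_class` cells the targets.
#' @param reference_class tissue class of the reference population (e.g.
#'   `"acinar"`).
#' @param markers character vector of marker names (needs
#'   `intensity_<marker>` columns).
#' @param radius_um proximity radius (default 20, strict `<`).
#' @return List: `cells` (per-cell group and normalized intensities),
#'   `tests` (per marker: group sizes, medians, `p`, `p_adj`).
#' @export
proximity_intensity_compare <- function(cells, reference_class, markers,
                                        radius_um = 20) {
  tum <- cells[cells$tissue_class == "tumor", , drop = FALSE]
  ref <- cells[cells$tissue_class == reference_class, , drop = FALSE]
  if (!nrow(tum) || !nrow(ref)) stopf("need tumor and %s cells", reference_class)
  bad <- !(tum$counterstain_intensity > 0) | is.na(tum$counterstain_intensity)
  if (any(bad)) message(sum(bad), " cell(s) excluded for non-positive counterstain")
  tum <- tum[!bad, , drop = FALSE]
  qxy <- as.matrix(tum[, c("x_um", "y_um")])
  rxy <- as.matrix(ref[, c("x_um", "y_um")])
  d <- rep(Inf, nrow(tum))
  for (s in seq(1L, nrow(tum), by = 512L)) {
    e <- min(s + 511L, nrow(tum))
    dx <- outer(qxy[s:e, 1L], rxy[, 1L], "-")
    dy <- outer(qxy[s:e, 2L], rxy[, 2L], "-")
    d[s:e] <- sqrt(apply(dx * dx + dy * dy, 1L, min))
  }
  grp <- ifelse(d < radius_um, "within", "above")
  res <- data.frame(cell_id = tum$cell_id, nearest_reference = d,
                    group = grp, stringsAsFactors = FALSE)
  tests <- list()
  for (m in markers) {
    col <- paste0("intensity_", m)
    if (!col %in% names(tum)) stopf("missing column '%s'", col)
    norm <- tum[[col]] / tum$counterstain_intensity
    res[[paste0("norm_", m)]] <- norm
    w <- norm[grp == "within"]; a <- norm[grp == "above"]
    p <- if (!length(w) || !length(a)) NA_real_
         else if (all(c(w, a) == c(w, a)[1])) NA_real_  # identical everywhere
         else suppressWarnings(wilcox.test(w, a, alternative = "two.sided")$p.value)
    tests[[m]] <- data.frame(
      marker = m, n_within = length(w), n_above = length(a),
      median_within = if (length(w)) median(w) else NA_real_,
      median_above = if (length(a)) median(a) else NA_real_,
      p = p, stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, tests)
  tests$p_adj <- p.adjust(tests$p, method = "BH")
  rownames(tests) <- NULL
  list(cells = res, tests = tests)
}
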