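## -- synthetic tissue generator ----------------------------------------------
## Ground-truthed stand-in for the restricted clinical WSI exports. The
## generator plants the statistical structure the analysis assumes (paired
## lobular/stromal ROIs, compartment-dependent marker fractions, ADM
## enrichment at the invasion front, an NGFR intensity decay, stage-dependent
## exocrine composition, near-clonal barcode tables with index hopping) and
## records every planted parameter in a truth manifest.

DEFAULT_MARKER_EFFECTS <- list(
  ## classical markers: enriched in lobular invasion
  MUC5AC = c(lobule = 0.45, stroma = 0.15, sd = 0.05),
  CDX2   = c(lobule = 0.45, stroma = 0.15, sd = 0.05),
  ## basal markers: enriched in desmoplastic stroma
  KRT5   = c(lobule = 0.15, stroma = 0.45, sd = 0.05),
  KRT17  = c(lobule = 0.15, stroma = 0.45, sd = 0.05),
  HMGA2  = c(lobule = 0.15, stroma = 0.45, sd = 0.05),
  CA125  = c(lobule = 0.15, stroma = 0.45, sd = 0.05))

DEFAULT_CLASS_MIXTURE <- list(
  lobule = c(acinar = 0.35, adm = 0.25, duct = 0.10, islet = 0.05,
             fibrosis = 0.20, immune = 0.05),
  stroma = c(fibrosis = 0.70, immune = 0.15, nerve = 0.07, vessel = 0.08))

DEFAULT_LAYER_EFFECT <- list(
  ## myCAF marker enriched in the inner 15 um layer; iCAF marker flat
  ASMA   = c(0.60, 0.20, 0.20),
  PDGFRA = c(0.40, 0.40, 0.40),
  CD74   = c(0.30, 0.25, 0.20),
  NGFR   = c(0.50, 0.45, 0.40))

## expected {AMY+/KRT19-, double+, AMY-/KRT19+} fractions by atrophy stage;
## the remainder are other lobular cell types. Double positives (ADM in
## transition) peak at mild/moderate atrophy.
DEFAULT_ATROPHY_COMPOSITION <- list(
  "minimal"   = c(amy_only = 0.70, double = 0.10, krt19_only = 0.05),
  "mild"      = c(amy_only = 0.50, double = 0.28, krt19_only = 0.10),
  "moderate"  = c(amy_only = 0.35, double = 0.30, krt19_only = 0.18),
  "severe"    = c(amy_only = 0.15, double = 0.15, krt19_only = 0.45),
  "end-stage" = c(amy_only = 0.04, double = 0.06, krt19_only = 0.60))

DEFAULT_CLONALITY <- list(
  n_barcodes = 1000L,
  ## four samples emulating the injection experiment: two monoclonal
  ## (>= 99% one clone), one two-clone dominant, one five-clone
  clone_freqs = list(
    M1 = c(0.995, 0.005),
    M2 = c(0.992, 0.008),
    M3 = c(0.70, 0.25, 0.05),
    M4 = c(0.35, 0.25, 0.15, 0.10, 0.08, 0.07)),
  depth = 1e5,
  hop_rate = 0.002)

#' Configuration for the synthetic tissue generator
#'
#' Defaults encode the stated world the tests assume: 299-864 tumor cells per
#' ROI, compartment-dependent marker-positive fractions (classical markers up
#' in lobules, basal markers up in stroma), ADM enrichment within ~50 um of
#' the invasion front, an NGFR intensity decay of 1 intensity unit per um
#' from a baseline of 100 with noise sd 5, inner-layer myCAF enrichment
#' (0.6/0.2/0.2), a stage-dependent exocrine composition, and near-clonal
#' barcode tables with Poisson index-hopping bleed-through.
#'
#' @param seed integer RNG seed; all generators are bitwise-deterministic
#'   given the seed.
#' @param n_tumors number of tumors.
#' @param rois_per_compartment ROIs per tumor and compartment.
#' @param tumor_cells_per_roi integer range; each ROI's tumor-cell count is
#'   drawn uniformly from it.
#' @param class_mixture per-compartment probability vectors over non-tumor
#'   tissue classes; the stromal mixture may not contain acinar, ADM or
#'   islet cells.
#' @param marker_effects named list, marker -> c(lobule, stroma, sd): mean
#'   positive fraction per compartment and between-ROI dispersion.
#' @param front_gradient c(baseline, decay_per_um, noise_sd) for the NGFR
#'   intensity field.
#' @param intensity_floor lower clamp for generated intensities.
#' @param lambda_front_um decay length (um) of ADM enrichment toward the
#'   invasion front.
#' @param layer_effect named list, marker -> per-layer positive-fraction
#'   means (inner to outer).
#' @param atrophy_composition named list, stage -> expected fractions of
#'   c(amy_only, double, krt19_only); each sums to <= 1.
#' @param clonality list(n_barcodes, clone_freqs (list of per-sample
#'   frequency vectors, each summing to 1), depth, hop_rate in [0, 1)).
#' @param nontumor_ratio non-tumor cells generated per tumor cell.
#' @param roi_radius_um nominal ROI polygon radius.
#' @param make_fields generate an NGFR intensity field per lobular ROI.
#' @param field_pixel_um pixel size of generated fields (default 0.92).
#' @return A validated `mn_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_tumors = 5L,
                             rois_per_compartment = 3L,
                             tumor_cells_per_roi = c(299L, 864L),
                             class_mixture = DEFAULT_CLASS_MIXTURE,
                             marker_effects = DEFAULT_MARKER_EFFECTS,
                             front_gradient = c(baseline = 100, decay_per_um = 1,
                                                noise_sd = 5),
                             intensity_floor = 0,
                             lambda_front_um = 50,
                             layer_effect = DEFAULT_LAYER_EFFECT,
                             atrophy_composition = DEFAULT_ATROPHY_COMPOSITION,
                             clonality = DEFAULT_CLONALITY,
                             nontumor_ratio = 1.5,
                             roi_radius_um = 220,
                             make_fields = FALSE,
                             field_pixel_um = 0.92) {
  cfg <- list(seed = seed, n_tumors = n_tumors,
              rois_per_compartment = rois_per_compartment,
              tumor_cells_per_roi = tumor_cells_per_roi,
              class_mixture = class_mixture, marker_effects = marker_effects,
              front_gradient = front_gradient,
              intensity_floor = intensity_floor,
              lambda_front_um = lambda_front_um, layer_effect = layer_effect,
              atrophy_composition = atrophy_composition,
              clonality = clonality, nontumor_ratio = nontumor_ratio,
              roi_radius_um = roi_radius_um, make_fields = make_fields,
              field_pixel_um = field_pixel_um)
  validate_config(cfg)
  structure(cfg, class = "mn_config")
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stopf("invalid config field 'seed': must be a single integer")
  for (f in c("n_tumors", "rois_per_compartment"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1)
      stopf("invalid config field '%s': must be a positive integer", f)
  r <- cfg$tumor_cells_per_roi
  if (length(r) != 2L || r[1] > r[2] || r[1] < 1)
    stopf("invalid config field 'tumor_cells_per_roi': nonempty range required")
  for (comp in names(cfg$class_mixture)) {
    p <- cfg$class_mixture[[comp]]
    if (abs(sum(p) - 1) > 1e-9)
      stopf("invalid config field 'class_mixture': %s probabilities sum to %g, not 1",
            comp, sum(p))
    if (any(p < 0) || !all(names(p) %in% TISSUE_CLASSES))
      stopf("invalid config field 'class_mixture': %s has negative or unknown classes", comp)
  }
  if (any(c("acinar", "adm", "islet") %in%
          names(cfg$class_mixture$stroma[cfg$class_mixture$stroma > 0])))
    stopf("invalid config field 'class_mixture': stromal ROIs may not contain acinar/adm/islet cells")
  for (m in names(cfg$marker_effects)) {
    e <- cfg$marker_effects[[m]]
    if (length(e) != 3L || any(e[1:2] < 0) || any(e[1:2] > 1) || e[3] < 0)
      stopf("invalid config field 'marker_effects': %s needs c(lobule, stroma, sd) with fractions in [0,1]", m)
  }
  if (length(cfg$front_gradient) != 3L || cfg$front_gradient[[3]] < 0)
    stopf("invalid config field 'front_gradient': need c(baseline, decay_per_um, noise_sd)")
  if (cfg$lambda_front_um <= 0)
    stopf("invalid config field 'lambda_front_um': must be > 0")
  for (m in names(cfg$layer_effect)) {
    v <- cfg$layer_effect[[m]]
    if (any(v < 0) || any(v > 1))
      stopf("invalid config field 'layer_effect': %s fractions must be in [0,1]", m)
  }
  if (!setequal(names(cfg$atrophy_composition), ATROPHY_STAGES))
    stopf("invalid config field 'atrophy_composition': stages must be {%s}",
          paste(ATROPHY_STAGES, collapse = ", "))
  for (st in names(cfg$atrophy_composition)) {
    v <- cfg$atrophy_composition[[st]]
    if (any(v < 0) || sum(v) > 1 + 1e-9)
      stopf("invalid config field 'atrophy_composition': %s fractions must be >= 0 and sum to <= 1", st)
  }
  cl <- cfg$clonality
  if (cl$n_barcodes < 1) stopf("invalid config field 'clonality': n_barcodes must be positive")
  if (any(unlist(cl$depth) <= 0)) stopf("invalid config field 'clonality': depths must be positive")
  for (s in names(cl$clone_freqs))
    if (abs(sum(cl$clone_freqs[[s]]) - 1) > 1e-9)
      stopf("invalid config field 'clonality': clone frequencies for sample %s sum to %g, not 1",
            s, sum(cl$clone_freqs[[s]]))
  if (cl$hop_rate < 0 || cl$hop_rate >= 1)
    stopf("invalid config field 'clonality': hop_rate must be in [0, 1)")
  invisible(cfg)
}

## Beta draw parameterized by mean and sd (method of moments); degenerate sd
## returns the mean
rbeta_ms <- function(n, mean, sd) {
  mean <- min(max(mean, 1e-6), 1 - 1e-6)
  if (sd <= 0) return(rep(mean, n))
  v <- min(sd^2, mean * (1 - mean) * 0.99)
  k <- mean * (1 - mean) / v - 1
  rbeta(n, mean * k, (1 - mean) * k)
}

## gently star-shaped ROI polygon (bounded radial modulation keeps the
## boundary curvature compatible with outward offsetting)
roi_polygon <- function(center, radius, n_vertices = 16L, wobble = 0.12) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  phase <- runif(1, 0, 2 * pi)
  r <- radius * (1 + wobble * sin(2 * ang + phase))
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

## uniform points in a polygon by rejection from its bounding box, with an
## optional acceptance-weight function of the point coordinates
sample_in_polygon <- function(n, poly, weight_fn = NULL, max_iter = 5000L) {
  bb <- apply(poly$outer, 2L, range)
  out <- matrix(numeric(0), ncol = 2L)
  it <- 0L
  while (nrow(out) < n && it < max_iter) {
    it <- it + 1L
    m <- max(2L * (n - nrow(out)), 32L)
    cand <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]))
    keep <- points_in_polygon(cand, poly)
    cand <- cand[keep, , drop = FALSE]
    if (!is.null(weight_fn) && nrow(cand)) {
      w <- weight_fn(cand)
      cand <- cand[runif(nrow(cand)) < w, , drop = FALSE]
    }
    out <- rbind(out, cand)
  }
  if (nrow(out) < n) stopf("rejection sampling failed to place %d points", n)
  out[seq_len(n), , drop = FALSE]
}

#' Generate a ground-truthed synthetic cohort
#'
#' Builds `n_tumors` tumors with paired lobular and stromal ROIs. Each ROI is
#' a gently star-shaped polygon holding a uniformly drawn number of tumor
#' cells (default 299-864) plus non-tumor cells from the compartment's class
#' mixture. Lobular ROIs carry an invasion-front polyline; tumor cells lie on
#' the invaded side, exocrine cells on the other, with ADM density decaying
#' as `exp(-d_front / lambda)` away from the front. Marker positivity is
#' Bernoulli per cell with an ROI-level mean drawn from a Beta distribution
#' around the compartment mean. Lobular ROIs are assigned an atrophy stage
#' and their epithelial cells an AMY/KRT19 phenotype from the stage's
#' composition. All planted parameters are recorded in `$truth`.
#'
#' @param config an [synthetic_config()].
#' @return An `mn_cohort` list: `cells` (data.frame), `regions`
#'   (`mn_annotations`), `fronts` (named list of `mn_polyline` by roi_id),
#'   `fields` (named list of `mn_field`, if `make_fields`), `truth`.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  markers <- names(config$marker_effects)
  cells_list <- list(); regions <- list(); fronts <- list(); fields <- list()
  truth_rois <- list()
  stage_pool <- rep(ATROPHY_STAGES, length.out = config$n_tumors *
                      config$rois_per_compartment)
  roi_index <- 0L
  spacing <- 2 * config$roi_radius_um * 1.3 + 400
  for (t in seq_len(config$n_tumors)) {
    tumor_id <- sprintf("T%02d", t)
    for (comp in c("lobule", "stroma")) {
      for (r in seq_len(config$rois_per_compartment)) {
        roi_index <- roi_index + 1L
        set.seed(derive_seed(config$seed, roi_index))
        roi_id <- sprintf("%s_%s_%d", tumor_id, comp, r)
        center <- c(roi_index * spacing, ifelse(comp == "lobule", 0, spacing * 50))
        poly <- mn_polygon(roi_polygon(center, config$roi_radius_um), id = roi_id)
        n_tum <- sample(seq(config$tumor_cells_per_roi[1],
                            config$tumor_cells_per_roi[2]), 1L)
        mix <- config$class_mixture[[comp]]
        n_non <- round(n_tum * config$nontumor_ratio)
        class_counts <- as.vector(rmultinom(1L, n_non, mix))
        names(class_counts) <- names(mix)

        front <- NULL; stage <- NA_character_
        if (comp == "lobule") {
          ## invasion front: a vertical, lightly bent polyline through the
          ## ROI center; tumor on the left (invaded) side, exocrine right
          fy <- seq(center[2] - config$roi_radius_um * 1.4,
                    center[2] + config$roi_radius_um * 1.4, length.out = 5L)
          fx <- center[1] + runif(5L, -15, 15)
          front <- mn_polyline(cbind(fx, fy), id = paste0(roi_id, "_front"))
          stage <- stage_pool[[((t - 1L) * config$rois_per_compartment + r - 1L) %%
                                 length(stage_pool) + 1L]]
        }
        side <- function(xy) xy[, 1L] - center[1]   # <0: invaded side

        place <- function(n, cls) {
          if (n == 0L) return(NULL)
          wf <- NULL
          if (comp == "lobule") {
            lambda <- config$lambda_front_um
            wf <- switch(cls,
              tumor = function(xy) as.numeric(side(xy) < 0),
              acinar = , duct = , islet = function(xy) as.numeric(side(xy) > 0),
              adm = function(xy) ifelse(side(xy) > 0,
                exp(-distance_to_annotation(xy, front) / lambda), 0),
              NULL)
          }
          sample_in_polygon(n, poly, weight_fn = wf)
        }

        xy_t <- place(n_tum, "tumor")
        all_xy <- list(tumor = xy_t)
        for (cls in names(class_counts))
          all_xy[[cls]] <- place(class_counts[[cls]], cls)

        ## ROI-level marker positivity means (Beta around compartment mean)
        p_roi <- vapply(markers, function(m) {
          e <- config$marker_effects[[m]]
          rbeta_ms(1L, unname(e[comp]), unname(e["sd"]))
        }, numeric(1))

        dfs <- lapply(names(all_xy), function(cls) {
          xy <- all_xy[[cls]]
          if (is.null(xy)) return(NULL)
          n <- nrow(xy)
          df <- data.frame(
            cell_id = sprintf("%s_%s_%04d", roi_id, cls, seq_len(n)),
            x_um = xy[, 1L], y_um = xy[, 2L], tissue_class = cls,
            roi_id = roi_id, compartment = comp, tumor_id = tumor_id,
            nuclear_circularity = runif(n, 0.3, 0.95),
            counterstain_intensity = runif(n, 0.8, 1.2),
            stringsAsFactors = FALSE)
          for (m in markers) {
            pos <- if (cls == "tumor") runif(n) < p_roi[[m]] else rep(FALSE, n)
            df[[paste0("positive_", m)]] <- pos
            df[[paste0("intensity_", m)]] <-
              pmax(config$intensity_floor,
                   rnorm(n, mean = ifelse(pos, 2, 0.5), sd = 0.3))
          }
          if (comp == "lobule" && cls %in% c("acinar", "adm", "duct")) {
            compn <- config$atrophy_composition[[stage]]
            catp <- c(compn, other = 1 - sum(compn))
            cat <- sample(names(catp), n, replace = TRUE, prob = catp)
            df$positive_AMY <- cat %in% c("amy_only", "double")
            df$positive_KRT19 <- cat %in% c("krt19_only", "double")
          } else {
            df$positive_AMY <- FALSE
            df$positive_KRT19 <- FALSE
          }
          df
        })
        cells_list[[roi_id]] <- do.call(rbind, dfs)

        regions[[length(regions) + 1L]] <- list(
          region_id = roi_id, roi_id = roi_id, role = "roi_boundary",
          tissue_class = NA_character_, geometry = poly,
          attributes = list(compartment = comp, tumor_id = tumor_id,
                            atrophy_stage = if (is.na(stage)) NULL else stage))
        if (!is.null(front)) {
          regions[[length(regions) + 1L]] <- list(
            region_id = paste0(roi_id, "_front"), roi_id = roi_id,
            role = "front", tissue_class = NA_character_, geometry = front,
            attributes = list())
          fronts[[roi_id]] <- front
          if (isTRUE(config$make_fields)) {
            set.seed(derive_seed(config$seed, roi_index + 100000L))
            bb <- apply(poly$outer, 2L, range)
            fields[[roi_id]] <- generate_intensity_field(
              config, front,
              extent = c(bb[1, 1] - 30, bb[1, 2] - 30, bb[2, 1] + 30, bb[2, 2] + 30),
              pixel_size_um = config$field_pixel_um)
          }
        }
        truth_rois[[roi_id]] <- list(
          roi_id = roi_id, tumor_id = tumor_id, compartment = comp,
          n_tumor_cells = n_tum, class_counts = as.list(class_counts),
          marker_p = as.list(p_roi), atrophy_stage = stage,
          atrophy_composition = if (comp == "lobule")
            as.list(config$atrophy_composition[[stage]]) else NULL)
      }
    }
  }
  cells <- do.call(rbind, cells_list)
  rownames(cells) <- NULL
  truth <- list(config = unclass(config), rois = truth_rois,
                front_gradient = as.list(config$front_gradient),
                lambda_front_um = config$lambda_front_um)
  structure(list(cells = cells,
                 regions = structure(regions, class = "mn_annotations"),
                 fronts = fronts, fields = fields, truth = truth),
            class = "mn_cohort")
}

#' Generate a synthetic stain-intensity field with a planted front gradient
#'
#' Pixel value = `baseline - decay_per_um * dist(pixel center, front) +
#' N(0, noise_sd)`, floored at `config$intensity_floor`. The planted decay is
#' the recoverable ground truth for gradient analyses.
#'
#' @param config an [synthetic_config()] (uses `front_gradient` and
#'   `intensity_floor`).
#' @param front an `mn_polyline`; a degenerate front (all vertices equal) is
#'   an error.
#' @param extent c(xmin, ymin, xmax, ymax) in micrometres; must be nonempty.
#' @param pixel_size_um pixel size (default 0.92).
#' @return An [intensity_field()] whose origin is `(xmin, ymin)`.
#' @export
generate_intensity_field <- function(config, front, extent,
                                     pixel_size_um = 0.92) {
  stopifnot(inherits(front, "mn_polyline"))
  assert_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (extent[3] <= extent[1] || extent[4] <= extent[2])
    stopf("extent is empty")
  if (all(abs(front$coords[, 1] - front$coords[1, 1]) < 1e-12) &&
      all(abs(front$coords[, 2] - front$coords[1, 2]) < 1e-12))
    stopf("degenerate front: all vertices coincide")
  g <- config$front_gradient
  baseline <- unname(g[[1]]); decay <- unname(g[[2]]); noise_sd <- unname(g[[3]])
  nc <- ceiling((extent[3] - extent[1]) / pixel_size_um)
  nr <- ceiling((extent[4] - extent[2]) / pixel_size_um)
  cx <- extent[1] + (seq_len(nc) - 0.5) * pixel_size_um
  cy <- extent[2] + (seq_len(nr) - 0.5) * pixel_size_um
  pts <- cbind(rep(cx, each = nr), rep(cy, times = nc))
  d <- distance_to_annotation(pts, front)
  vals <- baseline - decay * d
  if (noise_sd > 0) vals <- vals + rnorm(length(vals), 0, noise_sd)
  grid <- matrix(pmax(vals, config$intensity_floor), nrow = nr, ncol = nc)
  intensity_field(grid, pixel_size_um = pixel_size_um,
                  origin_um = c(extent[1], extent[2]))
}

#' Generate a synthetic barcode count table with index hopping
#'
#' Per sample, counts are multinomial over that sample's clones at the
#' configured depth; index hopping then adds to every other sample a Poisson
#' count with mean `hop_rate * source count` per barcode, emulating
#' bleed-through of dominant clones on patterned flow cells.
#'
#' @param config an [synthetic_config()] (uses `clonality`).
#' @return List with `counts` (barcode x sample integer matrix) and `truth`
#'   (planted per-sample clone frequencies, barcode ownership, and the pure
#'   pre-hop counts).
#' @export
generate_barcode_counts <- function(config) {
  validate_config(config)
  cl <- config$clonality
  set.seed(derive_seed(config$seed, 999983L))
  samples <- names(cl$clone_freqs)
  n_clones <- vapply(cl$clone_freqs, length, integer(1))
  if (sum(n_clones) > cl$n_barcodes)
    stopf("clonality: n_barcodes (%d) smaller than total clones (%d)",
          cl$n_barcodes, sum(n_clones))
  barcodes <- sprintf("bc%05d", seq_len(cl$n_barcodes))
  counts <- matrix(0, nrow = cl$n_barcodes, ncol = length(samples),
                   dimnames = list(barcodes, samples))
  owner <- setNames(rep(NA_character_, cl$n_barcodes), barcodes)
  depth <- if (length(cl$depth) == 1L)
    setNames(rep(cl$depth, length(samples)), samples) else cl$depth
  offset <- 0L
  for (s in samples) {
    freqs <- cl$clone_freqs[[s]]
    idx <- offset + seq_along(freqs)
    offset <- offset + length(freqs)
    counts[idx, s] <- as.vector(rmultinom(1L, depth[[s]], freqs))
    owner[idx] <- s
  }
  pure <- counts
  if (cl$hop_rate > 0) {
    for (s in samples) {
      src <- pure[, s]
      nz <- which(src > 0)
      for (s2 in setdiff(samples, s))
        counts[nz, s2] <- counts[nz, s2] + rpois(length(nz), cl$hop_rate * src[nz])
    }
  }
  storage.mode(counts) <- "integer"
  list(counts = counts,
       truth = list(clone_freqs = cl$clone_freqs, owner = owner,
                    hop_rate = cl$hop_rate, depth = as.list(depth),
                    pure_counts = pure))
}

#' Simulate a marker-fraction cohort directly at the ROI level
#'
#' Fast generator for power/type-I studies of the paired compartment test
#' and ROI clustering: it plants the same compartment-shift model as
#' [generate_cohort()] but skips spatial cell placement. For each tumor and
#' marker with planted shift `delta`, the stromal mean is
#' `base_mean + N(0, tumor_sd)` and the lobular mean adds `N(delta,
#' shift_sd)`; each ROI draws its positive count binomially at a cell count
#' uniform in `cells_per_roi`.
#'
#' @param markers named numeric vector of planted lobule-minus-stroma shifts
#'   (0 = null marker).
#' @param n_tumors,rois_per_compartment cohort dimensions.
#' @param base_mean stromal mean positive fraction.
#' @param tumor_sd between-tumor sd of the stromal mean.
#' @param shift_sd between-tumor sd of the planted shift.
#' @param roi_sd between-ROI sd of the per-ROI positivity probability.
#' @param cells_per_roi integer range of tumor cells per ROI.
#' @param seed RNG seed.
#' @return List: `matrix` (markers x ROIs fraction matrix), `meta`
#'   (data.frame roi_id/tumor_id/compartment), `truth` (per-tumor planted
#'   means).
#' @export
simulate_fraction_cohort <- function(markers, n_tumors = 30L,
                                     rois_per_compartment = 3L,
                                     base_mean = 0.3, tumor_sd = 0.05,
                                     shift_sd = 0.1, roi_sd = 0.05,
                                     cells_per_roi = c(299L, 864L),
                                     seed = 1L) {
  if (is.null(names(markers))) stopf("'markers' must be a named shift vector")
  set.seed(as.integer(seed) %% 2147483647L)
  roi_id <- character(0); tumor_id <- character(0); compartment <- character(0)
  for (t in seq_len(n_tumors)) for (comp in c("lobule", "stroma"))
    for (r in seq_len(rois_per_compartment)) {
      roi_id <- c(roi_id, sprintf("T%02d_%s_%d", t, comp, r))
      tumor_id <- c(tumor_id, sprintf("T%02d", t))
      compartment <- c(compartment, comp)
    }
  meta <- data.frame(roi_id = roi_id, tumor_id = tumor_id,
                     compartment = compartment, stringsAsFactors = FALSE)
  mat <- matrix(NA_real_, nrow = length(markers), ncol = nrow(meta),
                dimnames = list(names(markers), meta$roi_id))
  truth <- list()
  for (m in names(markers)) {
    mu_str <- pmin(pmax(base_mean + rnorm(n_tumors, 0, tumor_sd), 0.01), 0.99)
    delta <- if (markers[[m]] == 0) rep(0, n_tumors)
             else rnorm(n_tumors, markers[[m]], shift_sd)
    mu_lob <- pmin(pmax(mu_str + delta, 0.01), 0.99)
    truth[[m]] <- list(mu_stroma = mu_str, mu_lobule = mu_lob)
    for (i in seq_len(nrow(meta))) {
      t <- match(meta$tumor_id[i], sprintf("T%02d", seq_len(n_tumors)))
      mu <- if (meta$compartment[i] == "lobule") mu_lob[t] else mu_str[t]
      p <- min(max(mu + rnorm(1, 0, roi_sd), 0.005), 0.995)
      n <- sample(seq(cells_per_roi[1], cells_per_roi[2]), 1L)
      mat[m, i] <- rbinom(1L, n, p) / n
    }
  }
  list(matrix = mat, meta = meta, truth = truth)
}

#' Generate stromal cells inside concentric layers with planted positivity
#'
#' Places `n_per_layer` cells uniformly inside each annulus of `layers` and
#' assigns marker positivity Bernoulli with the per-layer means from
#' `config$layer_effect`. Used to validate layer assignment and the
#' inner-layer enrichment statistics.
#'
#' @param config an [synthetic_config()].
#' @param layers an `mn_layers` from [build_annuli()].
#' @param n_per_layer cells per layer.
#' @return data.frame of cells with `x_um`, `y_um`, `true_layer`,
#'   `nuclear_circularity` and `positive_<marker>` columns.
#' @export
generate_layer_cells <- function(config, layers, n_per_layer = 200L) {
  stopifnot(inherits(layers, "mn_layers"))
  set.seed(derive_seed(config$seed, 424243L))
  out <- list()
  for (k in seq_len(layers$n_rings)) {
    pts <- matrix(numeric(0), ncol = 2L)
    ring1 <- layers$rings[[k]][[1L]]
    bb <- apply(ring1$outer, 2L, range)
    while (nrow(pts) < n_per_layer) {
      cand <- cbind(runif(4L * n_per_layer, bb[1, 1], bb[2, 1]),
                    runif(4L * n_per_layer, bb[1, 2], bb[2, 2]))
      li <- layer_index(cand, layers)
      pts <- rbind(pts, cand[!is.na(li) & li == k, , drop = FALSE])
    }
    pts <- pts[seq_len(n_per_layer), , drop = FALSE]
    df <- data.frame(
      cell_id = sprintf("L%d_%04d", k, seq_len(n_per_layer)),
      x_um = pts[, 1L], y_um = pts[, 2L], true_layer = k,
      nuclear_circularity = runif(n_per_layer, 0.3, 0.8),
      stringsAsFactors = FALSE)
    for (m in names(config$layer_effect)) {
      p <- config$layer_effect[[m]]
      p <- p[min(k, length(p))]
      df[[paste0("positive_", m)]] <- runif(n_per_layer) < p
    }
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a synthetic cohort to disk
#'
#' Cells to CSV, regions and fronts to GeoJSON, intensity fields to text
#' grids with JSON sidecars, and the truth manifest to JSON. The manifest
#' round-trips losslessly through [read_cohort_truth()].
#'
#' @param cohort an `mn_cohort` from [generate_cohort()].
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cell_table(cohort$cells, file.path(dir, "cells.csv"))
  write_annotations(cohort$regions, file.path(dir, "regions.geojson"))
  for (roi in names(cohort$fields))
    write_intensity_field(cohort$fields[[roi]],
                          file.path(dir, sprintf("field_%s.txt", roi)))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @param dir cohort directory written by [write_cohort()].
#' @export
read_cohort_truth <- function(dir) {
  jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
}
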