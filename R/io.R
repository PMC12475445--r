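## -- file formats -------------------------------------------------------------
## Cell tables are CSV (one row per detected cell), annotations are GeoJSON
## FeatureCollections, intensity grids are plain-text matrices with a JSON
## sidecar, barcode counts are CSV matrices. All coordinates are micrometres
## in image convention (origin top-left, y down).

CELL_REQUIRED <- c("cell_id", "x_um", "y_um", "tissue_class", "roi_id")

#' Construct an intensity field
#'
#' A dense rasterized stain-intensity grid. Row 1 is the top of the image;
#' pixel (i, j) has its center at
#' `origin_um + pixel_size_um * (j - 0.5, i - 0.5)`.
#'
#' @param grid numeric matrix (row-major image rows).
#' @param pixel_size_um pixel edge length in micrometres (default 0.92, the
#'   resolution of the high-resolution pixel thresholder used upstream).
#' @param origin_um length-2 numeric, top-left pixel corner in micrometres.
#' @return An object of class `mn_field`.
#' @export
intensity_field <- function(grid, pixel_size_um = 0.92, origin_um = c(0, 0)) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  assert_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (length(origin_um) != 2L || any(!is.finite(origin_um)))
    stopf("'origin_um' must be two finite numbers")
  if (any(!is.finite(grid))) stopf("intensity grid contains non-finite values")
  structure(list(grid = grid, pixel_size_um = pixel_size_um,
                 origin_um = as.numeric(origin_um)),
            class = "mn_field")
}

#' Read a cell table
#'
#' Reads a CSV export of detected cells into the canonical cell table. A
#' `dialect` mapping translates exporter-specific column names (e.g. a QuPath
#' "Centroid X µm" header) to the canonical ones. Marker intensity
#' columns are named `intensity_<marker>`, positivity columns
#' `positive_<marker>`; when a positivity column is absent but a threshold is
#' supplied, positivity is computed on load as `intensity >= threshold`.
#'
#' @param path CSV file path.
#' @param dialect named character vector mapping canonical column names to
#'   physical ones, e.g. `c(x_um = "Centroid X µm")`.
#' @param thresholds optional named numeric vector of per-marker positivity
#'   thresholds (the upstream study set these per slide by visual
#'   assessment; here they are explicit).
#' @return A data.frame of cells (one row per cell), canonical columns first,
#'   unknown columns preserved.
#' @export
read_cell_table <- function(path, dialect = NULL, thresholds = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      phys <- dialect[[canon]]
      if (!phys %in% names(df))
        stopf("dialect column '%s' (for '%s') not found in %s", phys, canon, path)
      names(df)[names(df) == phys] <- canon
    }
  }
  missing <- setdiff(CELL_REQUIRED, names(df))
  if (length(missing))
    stopf("cell table %s is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  for (col in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stopf("non-numeric %s at data row %d of %s", col, bad[1L], path)
    df[[col]] <- v
  }
  df$cell_id <- as.character(df$cell_id)
  df$roi_id <- as.character(df$roi_id)
  df$tissue_class <- as.character(df$tissue_class)
  unknown <- setdiff(unique(df$tissue_class), TISSUE_CLASSES)
  if (length(unknown))
    stopf("unknown tissue_class value(s) %s; accepted classes: %s",
          paste(sQuote(unknown), collapse = ", "),
          paste(TISSUE_CLASSES, collapse = ", "))
  if ("compartment" %in% names(df)) {
    df$compartment <- as.character(df$compartment)
    bad <- setdiff(unique(df$compartment), COMPARTMENTS)
    if (length(bad))
      stopf("unknown compartment value(s) %s; accepted: %s",
            paste(sQuote(bad), collapse = ", "),
            paste(COMPARTMENTS, collapse = ", "))
  }
  pos_cols <- grep("^positive_", names(df), value = TRUE)
  for (col in pos_cols) df[[col]] <- as.logical(df[[col]])
  if (!is.null(thresholds)) {
    for (m in names(thresholds)) {
      int_col <- paste0("intensity_", m); pos_col <- paste0("positive_", m)
      if (int_col %in% names(df) && !pos_col %in% names(df))
        df[[pos_col]] <- df[[int_col]] >= thresholds[[m]]
    }
  }
  df
}

#' Write a cell table
#'
#' Canonical CSV writer: UTF-8, '.' decimal separator, missing values as
#' empty cells, deterministic column order (canonical columns first). A
#' canonical file round-trips byte-identically through
#' `read_cell_table()` / `write_cell_table()`.
#'
#' @param cells data.frame of cells.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  lead <- intersect(c(CELL_REQUIRED, "compartment"), names(cells))
  cells <- cells[, c(lead, setdiff(names(cells), lead)), drop = FALSE]
  write.csv(cells, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read region annotations from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon/MultiPolygon/LineString geometries;
#' coordinates are micrometres in image convention. Feature properties must
#' carry `region_id`, `roi_id` and a `role` (one of `tumor_nest`, `lobule`,
#' `front`, `class-region`, `roi_boundary`); `tissue_class` and free-form
#' attributes (e.g. `atrophy_stage`, `invasion_category`) are preserved.
#' MultiPolygons are split into one annotation per part, suffixing
#' `region_id` with `_p1`, `_p2`, ...
#'
#' @param path GeoJSON file path.
#' @return List of region annotations (class `mn_annotations`); each element
#'   has `region_id`, `roi_id`, `role`, `tissue_class`, `geometry`
#'   (`mn_polygon`/`mn_polyline`), `attributes`.
#' @export
read_annotations <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stopf("%s is not a GeoJSON FeatureCollection", path)
  out <- list()
  for (feat in gj$features) {
    props <- feat$properties %||% list()
    rid <- props$region_id %||% stopf("feature without region_id in %s", path)
    ann_base <- list(
      region_id = rid,
      roi_id = props$roi_id %||% NA_character_,
      role = props$role %||% "class-region",
      tissue_class = props$tissue_class %||% NA_character_,
      attributes = props[setdiff(names(props),
                                 c("region_id", "roi_id", "role", "tissue_class"))])
    if (!is.na(ann_base$tissue_class) &&
        !ann_base$tissue_class %in% TISSUE_CLASSES)
      ann_base$tissue_class <- "other"
    st <- ann_base$attributes$atrophy_stage
    if (!is.null(st) && !st %in% ATROPHY_STAGES)
      stopf("region '%s': atrophy_stage '%s' not in {%s}", rid, st,
            paste(ATROPHY_STAGES, collapse = ", "))
    geom <- feat$geometry
    coords_of <- function(ring) {
      m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      as_coord_matrix(m, rid)
    }
    mk_poly <- function(rings, id) {
      outer <- coords_of(rings[[1L]])
      holes <- lapply(rings[-1L], coords_of)
      tryCatch(mn_polygon(outer, holes, id = id),
               error = function(e) stopf("region '%s': %s", id, conditionMessage(e)))
    }
    if (identical(geom$type, "Polygon")) {
      ann <- ann_base
      ann$geometry <- mk_poly(geom$coordinates, rid)
      out[[length(out) + 1L]] <- ann
    } else if (identical(geom$type, "MultiPolygon")) {
      for (k in seq_along(geom$coordinates)) {
        ann <- ann_base
        ann$region_id <- sprintf("%s_p%d", rid, k)
        ann$geometry <- mk_poly(geom$coordinates[[k]], ann$region_id)
        out[[length(out) + 1L]] <- ann
      }
    } else if (identical(geom$type, "LineString")) {
      m <- coords_of(geom$coordinates)
      if (nrow(m) < 2L) stopf("front '%s' has fewer than 2 vertices", rid)
      ann <- ann_base
      ann$geometry <- mn_polyline(m, id = rid)
      out[[length(out) + 1L]] <- ann
    } else {
      stopf("region '%s': unsupported geometry type '%s'", rid, geom$type)
    }
  }
  structure(out, class = "mn_annotations")
}

#' Write region annotations to GeoJSON
#'
#' Inverse of [read_annotations()] up to MultiPolygon normalization (parts
#' are written back as individual Polygons).
#'
#' @param annotations an `mn_annotations` list.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  feats <- lapply(annotations, function(ann) {
    props <- c(list(region_id = ann$region_id, roi_id = ann$roi_id,
                    role = ann$role, tissue_class = ann$tissue_class),
               ann$attributes)
    props <- props[!vapply(props, function(x) is.null(x) ||
                             (length(x) == 1L && is.na(x)), logical(1))]
    g <- ann$geometry
    geometry <- if (inherits(g, "mn_polygon")) {
      close_ring <- function(r) {
        r <- rbind(r, r[1L, ])
        lapply(seq_len(nrow(r)), function(i) as.list(unname(r[i, ])))
      }
      list(type = "Polygon",
           coordinates = c(list(close_ring(g$outer)), lapply(g$holes, close_ring)))
    } else {
      list(type = "LineString",
           coordinates = lapply(seq_len(nrow(g$coords)),
                                function(i) as.list(unname(g$coords[i, ]))))
    }
    list(type = "Feature", properties = props, geometry = geometry)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read/write an intensity field
#'
#' The grid is stored as a whitespace-separated text matrix; a JSON sidecar
#' (`<path>.json`) records `pixel_size_um`, `origin_um` and dimensions.
#'
#' @param field an [intensity_field()].
#' @param path grid file path (sidecar written alongside).
#' @return `read_intensity_field()` returns an `mn_field`;
#'   `write_intensity_field()` returns `path` invisibly.
#' @export
write_intensity_field <- function(field, path) {
  stopifnot(inherits(field, "mn_field"))
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- apply(field$grid, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, con)
  jsonlite::write_json(
    list(pixel_size_um = field$pixel_size_um,
         origin_um = field$origin_um,
         nrow = nrow(field$grid), ncol = ncol(field$grid)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_intensity_field
#' @export
read_intensity_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- scan(path, what = double(), quiet = TRUE)
  grid <- matrix(vals, nrow = meta$nrow, ncol = meta$ncol, byrow = TRUE)
  intensity_field(grid, pixel_size_um = meta$pixel_size_um,
                  origin_um = meta$origin_um)
}

#' Read/write a barcode count table
#'
#' CSV with one row per barcode (first column `barcode`) and one integer
#' column per sample. Counts must be nonnegative integers; ids unique.
#'
#' @param path CSV file path.
#' @param counts integer matrix, barcodes x samples, with dimnames.
#' @return `read_barcode_counts()` returns the validated matrix;
#'   `write_barcode_counts()` returns `path` invisibly.
#' @export
read_barcode_counts <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "barcode") stopf("first column of %s must be 'barcode'", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$barcode
  validate_counts(m)
  m
}

#' @rdname read_barcode_counts
#' @export
write_barcode_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(barcode = rownames(counts), counts, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_counts <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stopf("counts must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("counts must have barcode rownames and sample colnames")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stopf("barcode and sample ids must be unique")
  if (any(m < 0) || any(m != round(m)))
    stopf("counts must be nonnegative integers")
  invisible(m)
}

#' Write tidy result tables with a manifest
#'
#' Writes one CSV per named table (UTF-8, '.' decimal separator, `NA` as
#' empty cells) with a deterministic row order (stable sort on `keys` when
#' given), plus `manifest.json` listing file names, row counts and a hash of
#' `config`. Two runs on identical inputs produce byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param dest destination directory (created if needed).
#' @param keys optional named list: for each table, the column names to sort
#'   by.
#' @param config optional configuration object to hash into the manifest.
#' @return The manifest, invisibly.
#' @export
write_results <- function(tables, dest, keys = NULL, config = NULL) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stopf("'tables' must be a fully named list")
  ok <- dir.exists(dest) || dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stopf("cannot create destination directory '%s'", dest)
  entries <- list()
  for (nm in names(tables)) {
    tb <- as.data.frame(tables[[nm]])
    if (anyDuplicated(names(tb))) stopf("table '%s' has duplicate column names", nm)
    k <- keys[[nm]]
    if (!is.null(k) && nrow(tb) > 1L)
      tb <- tb[do.call(order, c(unname(tb[k]), list(method = "radix"))), , drop = FALSE]
    fn <- paste0(nm, ".csv")
    write.csv(tb, file.path(dest, fn), row.names = FALSE, na = "",
              quote = FALSE, fileEncoding = "UTF-8")
    entries[[nm]] <- list(file = fn, rows = nrow(tb))
  }
  manifest <- list(
    tables = entries,
    config_hash = rlang::hash(jsonlite::toJSON(config, auto_unbox = TRUE,
                                               digits = NA, null = "null")))
  jsonlite::write_json(manifest, file.path(dest, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
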