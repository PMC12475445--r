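## -- 2D geometry primitives ---------------------------------------------------
## All coordinates are micrometres in image convention (origin top-left,
## y increasing downward). The math below is convention-agnostic: distances
## and areas do not depend on the handedness of the axes.

#' Construct a simple polygon
#'
#' A polygon is a closed, non-self-intersecting outer ring with optional
#' holes. Vertices are given in micrometres; a duplicated closing vertex is
#' tolerated and removed.
#'
#' @param outer numeric matrix (n x 2) of outer-ring vertices, n >= 3.
#' @param holes list of hole rings, each an (n x 2) matrix.
#' @param id optional identifier used in error messages.
#' @return An object of class `mn_polygon`.
#' @export
mn_polygon <- function(outer, holes = list(), id = NULL) {
  outer <- ring_clean(outer, id)
  holes <- lapply(holes, ring_clean, id = id)
  if (!is_simple_ring(outer))
    stopf("polygon%s outer ring is self-intersecting",
          if (is.null(id)) "" else sprintf(" '%s'", id))
  for (h in holes)
    if (!is_simple_ring(h))
      stopf("polygon%s has a self-intersecting hole",
            if (is.null(id)) "" else sprintf(" '%s'", id))
  if (abs(signed_area(outer)) <= 0)
    stopf("polygon%s has zero area", if (is.null(id)) "" else sprintf(" '%s'", id))
  structure(list(outer = outer, holes = holes, id = id), class = "mn_polygon")
}

#' Construct a polyline (e.g., an invasion front)
#'
#' @param coords numeric matrix (n x 2), n >= 2, vertices in micrometres.
#' @param id optional identifier used in error messages.
#' @return An object of class `mn_polyline`.
#' @export
mn_polyline <- function(coords, id = NULL) {
  coords <- as_coord_matrix(coords, id)
  if (nrow(coords) < 2L)
    stopf("polyline%s needs at least 2 vertices",
          if (is.null(id)) "" else sprintf(" '%s'", id))
  structure(list(coords = coords, id = id), class = "mn_polyline")
}

as_coord_matrix <- function(x, id = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 2L || any(!is.finite(x)))
    stopf("coordinates%s must be a finite (n x 2) matrix",
          if (is.null(id)) "" else sprintf(" for '%s'", id))
  dimnames(x) <- NULL
  x
}

ring_clean <- function(ring, id = NULL) {
  ring <- as_coord_matrix(ring, id)
  n <- nrow(ring)
  if (n >= 2L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3L)
    stopf("ring%s needs at least 3 distinct vertices",
          if (is.null(id)) "" else sprintf(" for '%s'", id))
  ring
}

signed_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (shoelace, holes subtracted)
#'
#' @param poly an `mn_polygon`.
#' @return Area in square micrometres.
#' @export
polygon_area <- function(poly) {
  stopifnot(inherits(poly, "mn_polygon"))
  a <- abs(signed_area(poly$outer))
  for (h in poly$holes) a <- a - abs(signed_area(h))
  a
}

## segment crossing test including collinear overlap (used for simplicity
## checks and polygon-overlap detection)
segments_cross <- function(p1, p2, p3, p4, touch_ok = FALSE) {
  d1 <- orient2d(p3, p4, p1); d2 <- orient2d(p3, p4, p2)
  d3 <- orient2d(p1, p2, p3); d4 <- orient2d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  if (touch_ok) return(FALSE)
  on_seg <- function(a, b, c)
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
  (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

orient2d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])

is_simple_ring <- function(ring) {
  n <- nrow(ring)
  seg <- function(i) list(ring[i, ], ring[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 1L)) {
    si <- seg(i)
    for (j in seq(i + 1L, n)) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      sj <- seg(j)
      if (segments_cross(si[[1]], si[[2]], sj[[1]], sj[[2]])) return(FALSE)
    }
  }
  TRUE
}

## min distance from many points to one polyline path (closed = ring)
dist_to_path <- function(pts, path, closed = FALSE) {
  px <- pts[, 1L]; py <- pts[, 2L]
  n <- nrow(path)
  idx <- if (closed) cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
         else cbind(seq_len(n - 1L), seq(2L, n))
  dmin <- rep(Inf, length(px))
  for (k in seq_len(nrow(idx))) {
    a <- path[idx[k, 1L], ]; b <- path[idx[k, 2L], ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    len2 <- abx * abx + aby * aby
    if (len2 == 0) {
      d2 <- (px - a[1])^2 + (py - a[2])^2
    } else {
      t <- pmin(1, pmax(0, ((px - a[1]) * abx + (py - a[2]) * aby) / len2))
      dx <- px - (a[1] + t * abx); dy <- py - (a[2] + t * aby)
      d2 <- dx * dx + dy * dy
    }
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

## point-in-polygon with holes; boundary points count as inside
points_in_polygon <- function(pts, poly) {
  inside <- sp::point.in.polygon(pts[, 1L], pts[, 2L],
                                 poly$outer[, 1L], poly$outer[, 2L]) > 0
  for (h in poly$holes) {
    in_hole <- sp::point.in.polygon(pts[, 1L], pts[, 2L],
                                    h[, 1L], h[, 2L]) == 1L
    inside <- inside & !in_hole
  }
  inside
}

#' Distance from points to an annotation geometry
#'
#' Euclidean distance (micrometres) from each query point to the nearest
#' point of the geometry. For polygons the distance is 0 for points inside or
#' on the boundary; points inside a hole get their positive distance to the
#' surrounding ring. For polylines the distance is the minimum over segments.
#'
#' @param points numeric (m x 2) matrix or a length-2 vector.
#' @param geometry an `mn_polygon` or `mn_polyline`.
#' @return Numeric vector of distances, one per query point.
#' @export
distance_to_annotation <- function(points, geometry) {
  if (is.null(geometry)) stopf("empty geometry")
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as_coord_matrix(points)
  if (inherits(geometry, "mn_polyline"))
    return(dist_to_path(points, geometry$coords, closed = FALSE))
  if (!inherits(geometry, "mn_polygon")) stopf("unsupported geometry type")
  d <- dist_to_path(points, geometry$outer, closed = TRUE)
  for (h in geometry$holes) d <- pmin(d, dist_to_path(points, h, closed = TRUE))
  d[points_in_polygon(points, geometry)] <- 0
  d
}

#' Fixed-radius neighbor query
#'
#' For each query point, the identifiers of all targets whose distance is
#' strictly less than `radius_um` ("within 20 um" contacts use the strict
#' inequality). Targets may be points (matrix/data.frame with ids) or a named
#' list of geometries; a query inside a target polygon is at distance 0 and is
#' always included.
#'
#' @param queries (m x 2) matrix or data.frame with columns `x_um`, `y_um`.
#' @param targets (n x 2) matrix with rownames, a data.frame with `x_um`,
#'   `y_um` and ids in `cell_id`/rownames, or a named list of
#'   `mn_polygon`/`mn_polyline` objects.
#' @param radius_um positive radius in micrometres.
#' @return List (length m) of character vectors of target ids.
#' @export
neighbors_within <- function(queries, targets, radius_um) {
  assert_scalar_num(radius_um, "radius_um", positive = TRUE)
  q <- coerce_points(queries)
  m <- nrow(q$xy)
  if (m == 0L) return(list())
  if (is.list(targets) && !is.data.frame(targets)) {
    ids <- names(targets) %||% as.character(seq_along(targets))
    dmat <- vapply(targets, function(g) distance_to_annotation(q$xy, g),
                   numeric(m))
    dmat <- matrix(dmat, nrow = m)
    return(lapply(seq_len(m), function(i) ids[dmat[i, ] < radius_um]))
  }
  t <- coerce_points(targets)
  out <- vector("list", m)
  chunk <- 512L
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    dx <- outer(q$xy[s:e, 1L], t$xy[, 1L], "-")
    dy <- outer(q$xy[s:e, 2L], t$xy[, 2L], "-")
    d2 <- dx * dx + dy * dy
    hit <- d2 < radius_um^2
    for (i in seq_len(e - s + 1L)) out[[s + i - 1L]] <- t$ids[hit[i, ]]
  }
  out
}

coerce_points <- function(x) {
  if (is.data.frame(x)) {
    ids <- if ("cell_id" %in% names(x)) as.character(x$cell_id) else rownames(x)
    xy <- as.matrix(x[, c("x_um", "y_um")])
    dimnames(xy) <- NULL
  } else {
    xy <- as_coord_matrix(x)
    ids <- rownames(x) %||% as.character(seq_len(nrow(xy)))
  }
  list(xy = xy, ids = ids %||% as.character(seq_len(nrow(xy))))
}

## ---- polygon offsetting -----------------------------------------------------

## Outward offset of a simple ring by distance d, with round joins at convex
## vertices (arc sagitta <= arc_tol) and miter joins at reflex vertices.
## Exact for convex rings; errors if the result self-intersects (base too
## non-convex for the requested width).
offset_ring <- function(ring, d, arc_tol = 0.1) {
  if (d <= 0) stopf("offset distance must be > 0")
  if (signed_area(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  n <- nrow(ring)
  nx <- numeric(n); ny <- numeric(n)           # outward edge normals
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- ring[j, 1L] - ring[i, 1L]; ey <- ring[j, 2L] - ring[i, 2L]
    len <- sqrt(ex * ex + ey * ey)
    if (len == 0) stopf("degenerate edge in ring")
    nx[i] <- ey / len; ny[i] <- -ex / len      # right normal of CCW ring
  }
  step <- if (arc_tol >= d) pi / 4 else 2 * acos(1 - arc_tol / d)
  pts <- list()
  for (i in seq_len(n)) {
    prev <- if (i == 1L) n else i - 1L
    v <- ring[i, ]
    a0 <- atan2(ny[prev], nx[prev]); a1 <- atan2(ny[i], nx[i])
    sweep <- (a1 - a0) %% (2 * pi)
    if (sweep < 1e-12 || abs(sweep - 2 * pi) < 1e-12) {
      pts[[length(pts) + 1L]] <- v + d * c(nx[i], ny[i])
    } else if (sweep <= pi) {                  # convex: round join
      k <- max(1L, ceiling(sweep / step))
      ang <- a0 + sweep * (0:k) / k
      pts[[length(pts) + 1L]] <- cbind(v[1] + d * cos(ang), v[2] + d * sin(ang))
    } else {                                   # reflex: miter join
      a <- v + d * c(nx[prev], ny[prev]); dir_a <- ring[i, ] - ring[prev, ]
      b <- v + d * c(nx[i], ny[i])
      j <- if (i == n) 1L else i + 1L
      dir_b <- ring[j, ] - ring[i, ]
      den <- dir_a[1] * dir_b[2] - dir_a[2] * dir_b[1]
      p <- if (abs(den) < 1e-12) (a + b) / 2 else {
        t <- ((b[1] - a[1]) * dir_b[2] - (b[2] - a[2]) * dir_b[1]) / den
        a + t * dir_a
      }
      pts[[length(pts) + 1L]] <- p
    }
  }
  out <- do.call(rbind, lapply(pts, function(p) matrix(p, ncol = 2L)))
  keep <- c(TRUE, rowSums((out[-1L, , drop = FALSE] -
                           out[-nrow(out), , drop = FALSE])^2) > 1e-18)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) >= 2L && all(abs(out[1L, ] - out[nrow(out), ]) < 1e-12))
    out <- out[-nrow(out), , drop = FALSE]
  if (!is_simple_ring(out))
    stopf("outward offset at %g um self-intersects; base polygon is too non-convex for this width", d)
  out
}

## do the outer rings of two polygons intersect or nest?
rings_overlap <- function(r1, r2) {
  n1 <- nrow(r1); n2 <- nrow(r2)
  for (i in seq_len(n1)) {
    a1 <- r1[i, ]; b1 <- r1[if (i == n1) 1L else i + 1L, ]
    for (j in seq_len(n2)) {
      a2 <- r2[j, ]; b2 <- r2[if (j == n2) 1L else j + 1L, ]
      if (segments_cross(a1, b1, a2, b2)) return(TRUE)
    }
  }
  sp::point.in.polygon(r1[1L, 1L], r1[1L, 2L], r2[, 1L], r2[, 2L]) > 0 ||
    sp::point.in.polygon(r2[1L, 1L], r2[1L, 2L], r1[, 1L], r1[, 2L]) > 0
}

#' Build concentric outward annuli ("stromal layers") around a base region
#'
#' Constructs `n_rings` annuli of width `width_um` outward from the boundary
#' of the base polygon(s) by successive outward offsetting with round joins
#' (arc tolerance `arc_tol_um`). Ring i covers distances
#' `[(i-1)*w, i*w)` from the base boundary; rings exclude the base interior
#' and are pairwise disjoint. The default 15 um width approximates the
#' diameter of a single stromal cell.
#'
#' @param base an `mn_polygon` or list of `mn_polygon`s (must be far enough
#'   apart that their outermost offsets do not overlap).
#' @param width_um ring width in micrometres (default 15).
#' @param n_rings number of rings (default 3: inner/middle/outer).
#' @param arc_tol_um arc sagitta tolerance for round joins (default 0.1).
#' @return An object of class `mn_layers` with elements `base`, `rings` (list
#'   of lists of `mn_polygon` ring parts), `areas` (ring areas, um^2),
#'   `width_um`, `n_rings`.
#' @export
build_annuli <- function(base, width_um = 15, n_rings = 3L, arc_tol_um = 0.1) {
  assert_scalar_num(width_um, "width_um", positive = TRUE)
  if (!is.numeric(n_rings) || n_rings < 1) stopf("'n_rings' must be >= 1")
  n_rings <- as.integer(n_rings)
  bases <- if (inherits(base, "mn_polygon")) list(base) else base
  if (!length(bases) || !all(vapply(bases, inherits, TRUE, "mn_polygon")))
    stopf("'base' must be an mn_polygon or a list of them")
  offs <- lapply(bases, function(b) {
    rings <- vector("list", n_rings + 1L)
    rings[[1L]] <- b$outer
    for (k in seq_len(n_rings))
      rings[[k + 1L]] <- offset_ring(b$outer, k * width_um, arc_tol_um)
    rings
  })
  if (length(bases) > 1L) {
    for (i in seq_len(length(bases) - 1L))
      for (j in seq(i + 1L, length(bases)))
        if (rings_overlap(offs[[i]][[n_rings + 1L]], offs[[j]][[n_rings + 1L]]))
          stopf("base polygons %d and %d are closer than %g um; their layers would overlap",
                i, j, n_rings * width_um)
  }
  rings <- lapply(seq_len(n_rings), function(k) {
    lapply(offs, function(o)
      structure(list(outer = o[[k + 1L]], holes = list(o[[k]]), id = NULL),
                class = "mn_polygon"))
  })
  areas <- vapply(seq_len(n_rings), function(k) {
    sum(vapply(offs, function(o)
      abs(signed_area(o[[k + 1L]])) - abs(signed_area(o[[k]])), numeric(1)))
  }, numeric(1))
  structure(list(base = bases, rings = rings, areas = areas,
                 width_um = width_um, n_rings = n_rings,
                 arc_tol_um = arc_tol_um),
            class = "mn_layers")
}

#' Assign points to stromal layers by distance from the base boundary
#'
#' Points strictly inside the base region get `NA` (they are tumor, not
#' stroma); otherwise ring index `i` covers distances `[(i-1)*w, i*w)`
#' (half-open, so a point exactly at 15 um with w = 15 falls in ring 2).
#' Points beyond the outermost ring get `NA`.
#'
#' @param points (m x 2) matrix or data.frame with `x_um`, `y_um`.
#' @param layers an `mn_layers` object from [build_annuli()].
#' @return Integer vector of ring indices (1 = inner), `NA` outside.
#' @export
layer_index <- function(points, layers) {
  stopifnot(inherits(layers, "mn_layers"))
  xy <- coerce_points(points)$xy
  if (nrow(xy) == 0L) return(integer(0))
  d <- rep(Inf, nrow(xy))
  inside <- rep(FALSE, nrow(xy))
  for (b in layers$base) {
    d <- pmin(d, distance_to_annotation(xy, b))
    inside <- inside | points_in_polygon(xy, b)
  }
  idx <- as.integer(floor(d / layers$width_um)) + 1L
  idx[inside & d == 0] <- NA_integer_   # base interior/boundary is not stroma
  idx[idx > layers$n_rings] <- NA_integer_
  idx
}

#' Mean intensity inside a disk
#'
#' Mean over all pixels whose centers lie within `radius_um` of `center`,
#' after clamping negative pixel values (a known upstream artefact) to zero.
#'
#' @param field an [intensity_field()].
#' @param center length-2 numeric, disk center in micrometres.
#' @param radius_um disk radius in micrometres. The upstream protocol is
#'   ambiguous between a 50 um diameter and a 50 um radius; the default here
#'   is 25 (diameter 50 um) and the radius is always explicit.
#' @return Mean clamped intensity (>= 0).
#' @export
disk_mean_intensity <- function(field, center, radius_um = 25) {
  stopifnot(inherits(field, "mn_field"))
  assert_scalar_num(radius_um, "radius_um", positive = TRUE)
  px <- field$pixel_size_um
  nr <- nrow(field$grid); nc <- ncol(field$grid)
  cx <- (center[1] - field$origin_um[1]) / px   # in pixel units
  cy <- (center[2] - field$origin_um[2]) / px
  r <- radius_um / px
  if (cx + r <= 0 || cy + r <= 0 || cx - r >= nc || cy - r >= nr)
    stopf("disk at (%g, %g) lies entirely outside the intensity field",
          center[1], center[2])
  j0 <- max(1L, floor(cx - r) + 1L); j1 <- min(nc, ceiling(cx + r))
  i0 <- max(1L, floor(cy - r) + 1L); i1 <- min(nr, ceiling(cy + r))
  jj <- j0:j1; ii <- i0:i1
  dx <- (jj - 0.5) - cx; dy <- (ii - 0.5) - cy
  mask <- outer(dy * dy, dx * dx, "+") <= r * r
  if (!any(mask)) stopf("disk contains no pixel centers")
  vals <- field$grid[ii, jj, drop = FALSE][mask]
  mean(pmax(vals, 0))
}
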