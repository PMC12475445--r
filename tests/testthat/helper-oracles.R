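# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use scalar loops and their own containment test so they share
# no code path with the package internals they check.

# distance from one point to one segment, closed form, scalar
oracle_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- sum((p - a) * ab) / len2
  t <- min(1, max(0, t))
  sqrt(sum((p - (a + t * ab))^2))
}

# crossing-number point-in-ring test (no sp)
oracle_in_ring <- function(p, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > p[2]) != (yj > p[2]) &&
        p[1] < (xj - xi) * (p[2] - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# exhaustive per-segment minimum distance to an mn_polygon / mn_polyline
oracle_distance <- function(p, geom) {
  if (inherits(geom, "mn_polyline")) {
    cs <- geom$coords
    d <- Inf
    for (i in seq_len(nrow(cs) - 1L))
      d <- min(d, oracle_point_segment(p, cs[i, ], cs[i + 1L, ]))
    return(d)
  }
  rings <- c(list(geom$outer), geom$holes)
  inside <- oracle_in_ring(p, geom$outer)
  for (h in geom$holes) if (oracle_in_ring(p, h)) inside <- FALSE
  d <- Inf
  for (r in rings) {
    n <- nrow(r)
    for (i in seq_len(n))
      d <- min(d, oracle_point_segment(p, r[i, ], r[if (i == n) 1L else i + 1L, ]))
  }
  if (inside || d < 1e-12) 0 else d   # boundary counts as inside
}

# O(n*m) neighbor sets for point targets
oracle_neighbors <- function(q, t, ids, radius) {
  lapply(seq_len(nrow(q)), function(i) {
    d <- sqrt((t[, 1] - q[i, 1])^2 + (t[, 2] - q[i, 2])^2)
    ids[d < radius]
  })
}

unit_square <- function(side = 100) {
  mn_polygon(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))
}

# minimal canonical cell table
tiny_cells <- function() {
  data.frame(
    cell_id = c("c1", "c2", "c3"),
    x_um = c(1.5, 20, 35.25), y_um = c(2, 5, 7.5),
    tissue_class = c("tumor", "adm", "fibrosis"),
    roi_id = "roi1", compartment = "lobule", tumor_id = "T01",
    positive_MUC5AC = c(TRUE, FALSE, FALSE),
    intensity_MUC5AC = c(2.5, 0.5, 0.25),
    stringsAsFactors = FALSE)
}

tiny_counts <- function() {
  m <- matrix(c(100000L, 50L, 10L, 99000L, 0L, 800L), nrow = 3, byrow = TRUE,
              dimnames = list(c("bcA", "bcB", "bcC"), c("S1", "S2")))
  m
}
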