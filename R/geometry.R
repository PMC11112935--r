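# Plain planar geometry on micrometre coordinates (image convention:
# origin top-left, y increasing downward). Polygons are n x 2 matrices of
# vertices without a repeated closing vertex.

#' Polygon area by the shoelace formula
#'
#' @param poly numeric matrix with columns x, y (um), vertices in order,
#'   no repeated closing vertex.
#' @return area in um^2 (non-negative, orientation-independent).
#' @keywords internal
polygon_area_um2 <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Even-odd ray casting with an explicit boundary pass: points on a polygon
# edge (within `tol` um) count as inside, matching the closed-polygon rule
# used when restricting cells to the tumor mask.
points_in_polygon <- function(px, py, poly, tol = 1e-9) {
  stopifnot(length(px) == length(py))
  n <- nrow(poly)
  x1 <- poly[, 1]
  y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1])
  y2 <- c(y1[-1], y1[1])
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  for (e in seq_len(n)) {
    dx <- x2[e] - x1[e]
    dy <- y2[e] - y1[e]
    # boundary test: zero cross product and within the segment's bbox
    cross <- dx * (py - y1[e]) - (px - x1[e]) * dy
    on <- abs(cross) <= tol * (abs(dx) + abs(dy) + 1) &
      px >= pmin(x1[e], x2[e]) - tol & px <= pmax(x1[e], x2[e]) + tol &
      py >= pmin(y1[e], y2[e]) - tol & py <= pmax(y1[e], y2[e]) + tol
    on_edge <- on_edge | on
    # even-odd crossing of the horizontal ray towards +x
    straddles <- (y1[e] > py) != (y2[e] > py)
    if (any(straddles)) {
      xi <- x1[e] + dx * (py - y1[e]) / dy
      crossed <- straddles & (px < xi)
      inside <- xor(inside, crossed)
    }
  }
  inside | on_edge
}

# O(n^2) check that no two non-adjacent edges intersect (self-intersection
# guard for mask polygons; masks have few vertices so this is cheap).
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)] # skip edges adjacent to edge i
    for (j in js) {
      if (segments_intersect(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(s1, s2) {
  d1 <- orient(s2[1:2], s2[3:4], s1[1:2])
  d2 <- orient(s2[1:2], s2[3:4], s1[3:4])
  d3 <- orient(s1[1:2], s1[3:4], s2[1:2])
  d4 <- orient(s1[1:2], s1[3:4], s2[3:4])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

orient <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

bbox_of <- function(polys) {
  xs <- unlist(lapply(polys, function(p) range(p[, 1])))
  ys <- unlist(lapply(polys, function(p) range(p[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}
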