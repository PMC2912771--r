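#' Construct a simple polygon
#'
#' Builds the plain two-column coordinate matrix used throughout the package
#' to represent a cell outline. Vertices are stored counterclockwise; input
#' given clockwise is re-oriented. The polygon must be simple (tested lazily
#' by the operations that require it) and non-degenerate.
#'
#' @param x Numeric vector of x coordinates, or a two-column matrix /
#'   data frame of coordinates.
#' @param y Numeric vector of y coordinates if `x` is a vector.
#' @return A numeric matrix with columns `x`, `y` and class `"polygon2d"`,
#'   oriented counterclockwise.
#' @examples
#' sq <- polygon2d(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygon_area(sq)
#' @export
polygon2d <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- as.matrix(x)
  } else {
    m <- cbind(x, y)
  }
  if (ncol(m) != 2L) stop("polygon coordinates must have two columns", call. = FALSE)
  storage.mode(m) <- "double"
  if (nrow(m) < 3L) stop("a polygon needs at least 3 vertices", call. = FALSE)
  if (!all(is.finite(m))) stop("polygon coordinates must be finite", call. = FALSE)
  a <- signed_area(m)
  if (abs(a) < 1e-14) stop("degenerate polygon: zero area", call. = FALSE)
  if (a < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  dimnames(m) <- list(NULL, c("x", "y"))
  class(m) <- c("polygon2d", class(m))
  m
}

as_poly_matrix <- function(p) {
  m <- unclass(p)
  if (!is.matrix(m)) m <- as.matrix(m)
  m
}

# shoelace signed area; positive for CCW
signed_area <- function(m) {
  x <- m[, 1L]; y <- m[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

#' Polygon area, centroid and internal angles
#'
#' `polygon_area()` is the shoelace area; `polygon_centroid()` is the
#' area-weighted centroid of the uniform lamina (the division "center of
#' mass", not the vertex mean); `internal_vertex_angles()` returns one
#' interior angle per vertex. For any simple n-gon the angles sum to
#' \eqn{(n-2)\pi}, and for a regular polygon each angle is
#' \eqn{(n-2)\pi/n} — the 120-degree hexagon angle cells relax towards
#' when division is suppressed.
#'
#' @param p A polygon as returned by [polygon2d()] (any two-column
#'   coordinate matrix is accepted).
#' @return `polygon_area()`: a positive scalar. `polygon_centroid()`: a
#'   length-2 named numeric `c(x, y)`. `internal_vertex_angles()`: a
#'   numeric vector of angles in radians, each in \eqn{(0, 2\pi)} (reflex
#'   vertices of non-convex polygons exceed \eqn{\pi}).
#' @examples
#' hexagon <- regular_polygon(6, circumradius = 1)
#' polygon_area(hexagon)            # 3*sqrt(3)/2
#' internal_vertex_angles(hexagon)  # six angles of 2*pi/3
#' @export
polygon_area <- function(p) {
  m <- as_poly_matrix(p)
  if (nrow(m) < 3L) stop("degenerate polygon: fewer than 3 vertices", call. = FALSE)
  a <- abs(signed_area(m))
  if (a < 1e-14) stop("degenerate polygon: zero area", call. = FALSE)
  a
}

#' @rdname polygon_area
#' @export
polygon_centroid <- function(p) {
  m <- as_poly_matrix(p)
  x <- m[, 1L]; y <- m[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- 0.5 * sum(cross)
  if (abs(a) < 1e-14) stop("zero-area polygon has no centroid", call. = FALSE)
  c(x = sum((x + xn) * cross) / (6 * a), y = sum((y + yn) * cross) / (6 * a))
}

#' @rdname polygon_area
#' @export
internal_vertex_angles <- function(p) {
  m <- as_poly_matrix(p)
  n <- nrow(m)
  if (n < 3L) stop("degenerate polygon", call. = FALSE)
  if (signed_area(m) < 0) m <- m[rev(seq_len(n)), , drop = FALSE]
  ip <- c(n, seq_len(n - 1L))
  im <- c(seq_len(n)[-1L], 1L)
  e1x <- m[, 1L] - m[ip, 1L]; e1y <- m[, 2L] - m[ip, 2L]   # incoming edge
  e2x <- m[im, 1L] - m[, 1L]; e2y <- m[im, 2L] - m[, 2L]   # outgoing edge
  turn <- atan2(e1x * e2y - e1y * e2x, e1x * e2x + e1y * e2y)
  ang <- pi - turn
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 2 * pi)) {
    stop("degenerate polygon: ill-defined vertex angle", call. = FALSE)
  }
  ang
}

#' Regular polygon constructor
#'
#' @param n Number of vertices (at least 3).
#' @param circumradius Distance from center to each vertex.
#' @param center Length-2 numeric center.
#' @param phase Angular offset of the first vertex, radians.
#' @return A [polygon2d()] matrix.
#' @export
regular_polygon <- function(n, circumradius = 1, center = c(0, 0), phase = pi / 2) {
  stopifnot(n >= 3, circumradius > 0)
  th <- phase + 2 * pi * (seq_len(n) - 1L) / n
  polygon2d(center[1L] + circumradius * cos(th), center[2L] + circumradius * sin(th))
}

#' Point-in-polygon test
#'
#' Winding/crossing test. Points within `tol` of an edge are classified
#' `"boundary"`.
#'
#' @param p Polygon.
#' @param pt Length-2 numeric point.
#' @param tol Distance below which a point counts as on the boundary.
#' @return One of `"inside"`, `"outside"`, `"boundary"`.
#' @export
point_in_polygon <- function(p, pt, tol = 1e-12) {
  m <- as_poly_matrix(p)
  x <- m[, 1L]; y <- m[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  ex <- xn - x; ey <- yn - y
  len2 <- ex^2 + ey^2
  tt <- pmin(1, pmax(0, ((pt[1L] - x) * ex + (pt[2L] - y) * ey) / len2))
  d2 <- (x + tt * ex - pt[1L])^2 + (y + tt * ey - pt[2L])^2
  if (min(d2) <= tol^2) return("boundary")
  crosses <- ((y > pt[2L]) != (yn > pt[2L])) &
    (pt[1L] < x + (pt[2L] - y) * ex / ey)
  if (sum(crosses) %% 2L == 1L) "inside" else "outside"
}

# Intersections of the infinite line (c + t*dir) with polygon edges.
# Returns data.frame(t, s, edge) for edges hit with s in [0,1).
line_polygon_hits <- function(m, cpt, dir) {
  x <- m[, 1L]; y <- m[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  ex <- xn - x; ey <- yn - y
  ax <- x - cpt[1L]; ay <- y - cpt[2L]
  den <- dir[1L] * ey - dir[2L] * ex       # cross(dir, e)
  tt <- (ax * ey - ay * ex) / den          # cross(a - c, e)/cross(dir, e)
  ss <- (ax * dir[2L] - ay * dir[1L]) / den
  keep <- is.finite(tt) & is.finite(ss) & ss >= 0 & ss < 1
  data.frame(t = tt[keep], s = ss[keep], edge = which(keep))
}

#' Chord of a polygon through an interior point
#'
#' Intersects the infinite line through `center` with direction `dir` with
#' the polygon boundary and returns the maximal segment through `center`
#' that stays inside the polygon (for convex polygons, simply the chord).
#' This is the geometric core of cell division: the chord is the candidate
#' new wall. If the line passes within `vertex_tol` of a polygon vertex the
#' direction is rotated by `perturb` radians and retried, because the
#' division construction requires the new wall to cut two existing walls,
#' not a junction.
#'
#' @param p Polygon.
#' @param center Interior point the chord must pass through.
#' @param dir Length-2 direction vector (normalized internally).
#' @param vertex_tol Distance to a vertex below which the hit is treated as
#'   degenerate and the direction perturbed.
#' @param perturb Rotation applied per retry, radians.
#' @param max_retries Bounded number of perturbation retries.
#' @return A list with `p1`, `p2` (endpoints, `p1` on the negative side of
#'   `dir`), `edge1`, `edge2` (indices of the edges cut, edge i joining
#'   vertex i to i+1), and `dir` (the possibly perturbed unit direction).
#' @export
chord_through_point <- function(p, center, dir, vertex_tol = 1e-9,
                                perturb = 1e-7, max_retries = 40L) {
  m <- as_poly_matrix(p)
  if (signed_area(m) < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  side <- point_in_polygon(m, center)
  if (side == "boundary") stop("chord center lies on the polygon boundary", call. = FALSE)
  if (side == "outside") stop("chord center lies outside the polygon", call. = FALSE)
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-300) stop("zero direction vector", call. = FALSE)
  d0 <- dir / nd
  ang0 <- atan2(d0[2L], d0[1L])
  for (k in 0:max_retries) {
    # alternate +/- growing perturbations around the requested direction
    da <- if (k == 0L) 0 else (ceiling(k / 2) * perturb) * if (k %% 2L == 1L) 1 else -1
    d <- c(cos(ang0 + da), sin(ang0 + da))
    hits <- line_polygon_hits(m, center, d)
    if (nrow(hits) < 2L) next
    # degenerate if any hit is (numerically) at an edge endpoint
    x <- m[, 1L]; y <- m[, 2L]
    elen <- sqrt((c(x[-1L], x[1L]) - x)^2 + (c(y[-1L], y[1L]) - y)^2)[hits$edge]
    near_vertex <- pmin(hits$s, 1 - hits$s) * elen < vertex_tol
    if (any(near_vertex)) next
    tpos <- hits$t[hits$t > 0]
    tneg <- hits$t[hits$t < 0]
    if (!length(tpos) || !length(tneg)) next
    t2 <- min(tpos); t1 <- max(tneg)
    e2 <- hits$edge[hits$t == t2][1L]
    e1 <- hits$edge[hits$t == t1][1L]
    if (e1 == e2) next
    return(list(
      p1 = c(x = center[1L] + t1 * d[1L], y = center[2L] + t1 * d[2L]),
      p2 = c(x = center[1L] + t2 * d[1L], y = center[2L] + t2 * d[2L]),
      edge1 = e1, edge2 = e2, dir = d
    ))
  }
  stop("no valid chord found after perturbation retries", call. = FALSE)
}

# Chord lengths through `cpt` for a vector of axial directions `angles`.
# Vectorized over angles x edges; used by the shortest-path direction search.
chord_lengths <- function(m, cpt, angles) {
  x <- m[, 1L]; y <- m[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  ex <- xn - x; ey <- yn - y
  ax <- x - cpt[1L]; ay <- y - cpt[2L]
  dx <- cos(angles); dy <- sin(angles)
  # den[e, a] = cross(dir_a, edge_e)
  den <- outer(ey, dx) - outer(ex, dy)
  tt <- (ax * ey - ay * ex) / den
  ss <- (outer(ax, dy) - outer(ay, dx)) / den
  ok <- is.finite(tt) & ss >= 0 & ss < 1
  tp <- tt; tp[!ok | tt <= 0] <- Inf
  tn <- tt; tn[!ok | tt >= 0] <- -Inf
  tpos <- do.call(pmin, c(asplit(tp, 1L), list(na.rm = TRUE)))
  tneg <- do.call(pmax, c(asplit(tn, 1L), list(na.rm = TRUE)))
  out <- as.numeric(tpos - tneg)
  out[!is.finite(out)] <- NA_real_
  out
}

# Fan/ear-clipping triangulation of a simple polygon (vertex index triples).
triangulate_polygon <- function(m) {
  n <- nrow(m)
  if (signed_area(m) < 0) stop("triangulate_polygon expects CCW input", call. = FALSE)
  idx <- seq_len(n)
  tris <- matrix(integer(), ncol = 3L)
  guard <- 0L
  while (length(idx) > 3L) {
    nn <- length(idx)
    clipped <- FALSE
    for (j in seq_len(nn)) {
      i0 <- idx[if (j == 1L) nn else j - 1L]
      i1 <- idx[j]
      i2 <- idx[if (j == nn) 1L else j + 1L]
      a <- m[i0, ]; b <- m[i1, ]; cc <- m[i2, ]
      cr <- (b[1L] - a[1L]) * (cc[2L] - a[2L]) - (b[2L] - a[2L]) * (cc[1L] - a[1L])
      if (cr <= 1e-14) next   # reflex or collinear: not an ear
      others <- setdiff(idx, c(i0, i1, i2))
      if (length(others)) {
        px <- m[others, 1L]; py <- m[others, 2L]
        inside <- point_in_triangle(px, py, a, b, cc)
        if (any(inside)) next
      }
      tris <- rbind(tris, c(i0, i1, i2))
      idx <- idx[-j]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      guard <- guard + 1L
      if (guard > 2L) stop("ear clipping failed: polygon may be self-intersecting", call. = FALSE)
    }
  }
  rbind(tris, idx)
}

point_in_triangle <- function(px, py, a, b, cc) {
  s1 <- (b[1L] - a[1L]) * (py - a[2L]) - (b[2L] - a[2L]) * (px - a[1L])
  s2 <- (cc[1L] - b[1L]) * (py - b[2L]) - (cc[2L] - b[2L]) * (px - b[1L])
  s3 <- (a[1L] - cc[1L]) * (py - cc[2L]) - (a[2L] - cc[2L]) * (px - cc[1L])
  (s1 >= -1e-14) & (s2 >= -1e-14) & (s3 >= -1e-14)
}

#' Uniform random points inside a polygon
#'
#' Samples uniformly over the polygon interior by ear-clipping
#' triangulation, choosing a triangle with probability proportional to its
#' area, then sampling uniformly within the triangle. This realizes the
#' "random point within the mother cell drawn from a uniform distribution"
#' division-center mechanism.
#'
#' @param p Polygon.
#' @param n Number of points to draw.
#' @return An `n` x 2 matrix of points (a length-2 vector if `n = 1`).
#' @export
random_point_in_polygon <- function(p, n = 1L) {
  m <- as_poly_matrix(p)
  if (signed_area(m) < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  tris <- triangulate_polygon(m)
  areas <- apply(tris, 1L, function(ix) abs(signed_area(m[ix, , drop = FALSE])))
  pick <- sample.int(nrow(tris), n, replace = TRUE, prob = areas)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  a <- m[tris[pick, 1L], , drop = FALSE]
  b <- m[tris[pick, 2L], , drop = FALSE]
  cc <- m[tris[pick, 3L], , drop = FALSE]
  pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
  colnames(pts) <- c("x", "y")
  if (n == 1L) pts[1L, ] else pts
}
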