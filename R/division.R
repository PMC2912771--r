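#' Division plane
#'
#' A division plane is the straight path through a division center along an
#' axial division direction; it fully determines the new wall.
#'
#' @param center Length-2 numeric, strictly inside the mother cell.
#' @param direction Length-2 direction vector or a single angle in radians;
#'   canonicalized to a unit vector with angle in \eqn{[0, \pi)}.
#' @return A list of class `"division_plane"` with `center`, `dir` (unit
#'   vector) and `angle`.
#' @export
division_plane <- function(center, direction) {
  if (length(direction) == 1L) {
    ang <- direction %% pi
  } else {
    nd <- sqrt(sum(direction^2))
    if (nd < 1e-300) stop("zero division direction", call. = FALSE)
    ang <- atan2(direction[2L], direction[1L]) %% pi
  }
  structure(list(center = as.numeric(center)[1:2],
                 dir = c(cos(ang), sin(ang)), angle = ang),
            class = "division_plane")
}

#' Division rules
#'
#' A division rule combines a mechanism for the division center with a
#' mechanism for the division direction:
#'
#' * centers: `COM` (area center of mass of the mother cell) or `Random`
#'   (uniform random point within the mother cell);
#' * directions: `ShortestPath` (the direction minimizing the chord length
#'   through the center; Errera's rule when combined with COM),
#'   `RandomDirection` (axial angle uniform on \eqn{[0, \pi)}),
#'   `Orthogonal` (perpendicular to the cell's previous division plane;
#'   random for founders), and `StrainPerpendicular` (perpendicular to the
#'   cell strain axis; Hofmeister's rule; random when strain is isotropic).
#'
#' Rules are named `"<Direction>x<Center>"` or with the field's
#' cross-product spelling, e.g. `"ShortestPathCOM"`,
#' `"RandomDirectionRandom"`; `"RandomRandom"` is accepted as an alias of
#' the latter.
#'
#' @param rule A rule name string, e.g. `"ShortestPathCOM"`.
#' @return A list of class `"division_rule"` with `center_mechanism`,
#'   `direction_mechanism` and `name`.
#' @examples
#' division_rule("ShortestPathCOM")
#' division_rule("OrthogonalRandom")
#' @export
division_rule <- function(rule) {
  key <- gsub("[^A-Za-z]", "", rule)
  dirs <- c("ShortestPath", "RandomDirection", "Orthogonal", "StrainPerpendicular")
  if (key %in% c("RandomRandom", "RandomxRandom")) key <- "RandomDirectionRandom"
  hit <- NULL
  for (d in dirs) {
    for (cm in c("COM", "Random")) {
      # accept both "<Dir><Center>" and "<Dir>x<Center>" spellings
      if (key %in% c(paste0(d, cm), paste0(d, "x", cm))) hit <- c(d, cm)
    }
  }
  if (is.null(hit)) {
    stop(sprintf("unknown division rule '%s'; see ?division_rule for names", rule),
         call. = FALSE)
  }
  structure(list(direction_mechanism = hit[1L], center_mechanism = hit[2L],
                 name = paste0(hit[1L], "x", hit[2L])),
            class = "division_rule")
}

#' @export
print.division_rule <- function(x, ...) {
  cat(sprintf("<division_rule> %s (direction) x %s (center)\n",
              x$direction_mechanism, x$center_mechanism))
  invisible(x)
}

#' Division-center mechanisms
#'
#' `center_com()` returns the area centroid of the mother cell;
#' `center_random()` a uniform random interior point.
#'
#' @param poly The mother cell polygon.
#' @return A length-2 numeric point.
#' @export
center_com <- function(poly) unname(polygon_centroid(poly))

#' @rdname center_com
#' @export
center_random <- function(poly) unname(random_point_in_polygon(poly, 1L))

#' Shortest-path division direction
#'
#' Finds the axial direction minimizing the length of the chord through
#' `center`, by evaluating the chord length on a uniform angular grid over
#' \eqn{[0, \pi)} followed by golden-section refinement in the best
#' bracket. Ties (e.g. near-circular cells) resolve toward the smaller
#' angle.
#'
#' @param poly Mother cell polygon.
#' @param center Division center (inside the polygon).
#' @param n_grid Number of grid angles.
#' @return Axial angle in \eqn{[0, \pi)}.
#' @export
direction_shortest_path <- function(poly, center, n_grid = 720L) {
  m <- as_poly_matrix(poly)
  if (signed_area(m) < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  grid <- pi * (seq_len(n_grid) - 1L) / n_grid
  len <- chord_lengths(m, center, grid)
  len[is.na(len)] <- Inf
  best <- which.min(len)
  # golden-section refinement in the bracket around the best grid angle
  h <- pi / n_grid
  lo <- grid[best] - h; hi <- grid[best] + h
  f <- function(a) {
    v <- chord_lengths(m, center, a %% pi)
    if (is.na(v)) Inf else v
  }
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  for (i in 1:40) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
    if ((b - a) < 1e-10) break
  }
  ((a + b) / 2) %% pi
}

#' Random, orthogonal and strain-perpendicular direction mechanisms
#'
#' `direction_random()` draws an axial angle uniformly on \eqn{[0, \pi)}.
#' `direction_orthogonal()` rotates the cell's previous division plane by
#' \eqn{\pi/2}; cells without division history fall back to a random
#' direction. `direction_strain_perpendicular()` rotates the cell strain
#' axis ([strain_direction()]) by \eqn{\pi/2}; an isotropic (all-relaxed)
#' cell falls back to a random direction.
#'
#' @param t A tissue.
#' @param cell Cell index.
#' @param signed Passed to [strain_direction()].
#' @return Axial angle in \eqn{[0, \pi)}.
#' @export
direction_random <- function() {
  stats::runif(1L, 0, pi)
}

#' @rdname direction_random
#' @export
direction_orthogonal <- function(t, cell) {
  prev <- t$cells[[cell]]$dir
  if (is.null(prev) || is.na(prev)) return(direction_random())
  (prev + pi / 2) %% pi
}

#' @rdname direction_random
#' @export
direction_strain_perpendicular <- function(t, cell, signed = FALSE) {
  th <- strain_direction(t, cell, signed = signed)
  if (is.na(th)) return(direction_random())
  (th + pi / 2) %% pi
}

#' Compose a division plane for a cell under a rule
#'
#' Applies the rule's center mechanism, then its direction mechanism; for
#' `ShortestPath` the chord-length minimization runs through the chosen
#' center, so `ShortestPathxRandom` minimizes the chord through the random
#' point.
#'
#' @param t A tissue.
#' @param cell Mother cell index.
#' @param rule A [division_rule()].
#' @param signed_strain Passed to the strain mechanism.
#' @return A [division_plane()].
#' @export
make_plane <- function(t, cell, rule, signed_strain = FALSE) {
  poly <- cell_polygon(t, cell)
  center <- switch(rule$center_mechanism,
                   COM = center_com(poly),
                   Random = center_random(poly))
  ang <- switch(rule$direction_mechanism,
                ShortestPath = direction_shortest_path(poly, center),
                RandomDirection = direction_random(),
                Orthogonal = direction_orthogonal(t, cell),
                StrainPerpendicular = direction_strain_perpendicular(t, cell, signed_strain))
  division_plane(center, ang)
}
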