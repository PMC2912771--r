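# Shared fixtures, built in code.

# 7-cell rosette: central regular hexagon surrounded by six quadrilateral
# cells sharing its walls; outer ring closed by rim walls. All junctions
# are three-way.
make_rosette <- function(r_in = 1, r_out = 2) {
  th <- pi / 2 + 2 * pi * (0:5) / 6
  inner <- cbind(r_in * cos(th), r_in * sin(th))
  outer <- cbind(r_out * cos(th), r_out * sin(th))
  pos <- rbind(inner, outer)                       # vertices 1:6 inner, 7:12 outer
  nxt <- c(2:6, 1)
  hex_w <- seq_len(6)                              # wall i: inner i -> inner i+1
  rad_w <- 6 + seq_len(6)                          # wall 6+i: inner i -> outer i
  rim_w <- 12 + seq_len(6)                         # wall 12+i: outer i -> outer i+1
  walls <- list(
    v1 = c(1:6, 1:6, 7:12),
    v2 = c(nxt, 7:12, 6 + nxt),
    rest_length = rep(1, 18))
  len <- sqrt(rowSums((pos[walls$v2, ] - pos[walls$v1, ])^2))
  walls$rest_length <- len
  cells <- vector("list", 7)
  cells[[1]] <- list(vs = 1:6, ws = hex_w, dir = NA_real_)
  for (i in 1:6) {
    j <- if (i == 6) 1L else i + 1L
    # outer cell i: inner i+1 <- inner i ... CCW: inner i, outer i, outer i+1, inner i+1
    cells[[i + 1]] <- list(vs = c(i, 6L + i, 6L + j, j),
                           ws = c(rad_w[i], rim_w[i], rad_w[j], hex_w[i]),
                           dir = NA_real_)
  }
  tt <- new_tissue(pos, walls, cells)
  tt$cells <- lapply(tt$cells, function(cl) merisim:::orient_cell_ccw(tt, cl))
  validate_tissue(tt)
  tt
}

# star-shaped simple polygon with random radii (simple by construction)
random_simple_polygon <- function(n = 7, r_min = 0.5, r_max = 1.5) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  while (min(diff(c(ang, ang[1] + 2 * pi))) < 0.05) {
    ang <- sort(stats::runif(n, 0, 2 * pi))
  }
  r <- stats::runif(n, r_min, r_max)
  polygon2d(r * cos(ang), r * sin(ang))
}

random_convex_polygon <- function(n = 12) {
  pts <- matrix(stats::rnorm(2 * n * 3), ncol = 2)
  hull <- grDevices::chull(pts)
  polygon2d(pts[hull, , drop = FALSE])
}

# Monte-Carlo area oracle: fraction of bounding-box samples inside
mc_polygon_area <- function(p, n = 1e6) {
  m <- merisim:::as_poly_matrix(p)
  xr <- range(m[, 1]); yr <- range(m[, 2])
  px <- stats::runif(n, xr[1], xr[2]); py <- stats::runif(n, yr[1], yr[2])
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- rep(FALSE, n)
  for (i in seq_len(nrow(m))) {
    crosses <- ((y[i] > py) != (yn[i] > py)) &
      (px < x[i] + (py - y[i]) * (xn[i] - x[i]) / (yn[i] - y[i]))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  mean(inside) * diff(xr) * diff(yr)
}

# Lazily grown steady-state tissue shared across tests (~220 cells).
.fixture_env <- new.env(parent = emptyenv())
get_steady_tissue <- function() {
  if (is.null(.fixture_env$steady)) {
    set.seed(4242)
    f <- make_founder(6)
    grown <- simulate_tissue(f, model_params(), "ShortestPathCOM",
                             t_end = 4000, stop_cells = 150)
    .fixture_env$steady <- simulate_tissue(grown$final, model_params(),
                                           "ShortestPathCOM", t_end = 40)$final
  }
  .fixture_env$steady
}

# Reduced initial-state library + per-rule steady-state continuations,
# shared by the acceptance-criteria tests (built once per test run).
get_rule_batch <- function() {
  if (is.null(.fixture_env$batch)) {
    set.seed(2024)
    lib <- generate_initial_states(founder_sides = c(5L, 7L),
                                   snapshots_per_founder = 3L,
                                   snapshot_interval = 10,
                                   cell_trigger = 150L)
    rules <- c("ShortestPathCOM", "OrthogonalCOM", "RandomDirectionCOM",
               "StrainPerpendicularCOM", "ShortestPathRandom",
               "RandomDirectionRandom", "OrthogonalRandom")
    batch <- lapply(rules, function(r) {
      lapply(lib, function(st) {
        snapshot_stats(simulate_tissue(st, model_params(), r, t_end = 60)$final)
      })
    })
    names(batch) <- rules
    .fixture_env$batch <- batch
  }
  .fixture_env$batch
}
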