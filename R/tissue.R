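#' Tissue state
#'
#' The shared mesh data model: a 2-D cell sheet represented by vertices
#' (wall junctions), walls (springs with a resting length), and cells
#' (ordered wall cycles). Vertices, walls and cells are indexed compactly
#' from 1; indices are renumbered when boundary cells are removed.
#'
#' @param pos Numeric matrix (n x 2) of vertex positions.
#' @param walls List with integer vectors `v1`, `v2` and numeric
#'   `rest_length`, one entry per wall.
#' @param cells List of cells; each cell is a list with `vs` (ordered CCW
#'   vertex cycle), `ws` (ordered wall cycle, `ws[j]` joining `vs[j]` to
#'   `vs[j+1]`), and `dir` (axial angle of the last division plane in
#'   \eqn{[0, \pi)}, or `NA` for founders).
#' @param sim_time Simulation time carried by the state.
#' @param rng_state The `.Random.seed` vector captured with the state, or
#'   `NULL`.
#' @return An object of class `"tissue"`.
#' @seealso [make_founder()], [split_cell()], [remove_outside_cells()]
#' @export
new_tissue <- function(pos, walls, cells, sim_time = 0, rng_state = NULL) {
  storage.mode(pos) <- "double"
  colnames(pos) <- c("x", "y")
  t <- structure(
    list(pos = pos,
         walls = list(v1 = as.integer(walls$v1), v2 = as.integer(walls$v2),
                      rest_length = as.double(walls$rest_length)),
         cells = cells,
         sim_time = sim_time,
         rng_state = rng_state),
    class = "tissue")
  t
}

#' @export
print.tissue <- function(x, ...) {
  cat(sprintf("<tissue> %d cells, %d walls, %d vertices, t = %.4g\n",
              length(x$cells), length(x$walls$v1), nrow(x$pos), x$sim_time))
  invisible(x)
}

n_cells <- function(t) length(t$cells)
n_walls <- function(t) length(t$walls$v1)
n_vertices <- function(t) nrow(t$pos)

#' Extract a cell outline as a polygon
#'
#' @param t A [new_tissue()] object.
#' @param cell Cell index.
#' @return A CCW coordinate matrix of the cell's vertex cycle.
#' @export
cell_polygon <- function(t, cell) {
  vs <- t$cells[[cell]]$vs
  if (length(vs) < 3L) stop("broken cell cycle: fewer than 3 vertices", call. = FALSE)
  m <- t$pos[vs, , drop = FALSE]
  m
}

cell_areas <- function(t) {
  vapply(t$cells, function(cl) abs(signed_area(t$pos[cl$vs, , drop = FALSE])), 0)
}

# wall index -> number of incident cells (and which)
wall_cell_incidence <- function(t) {
  nw <- n_walls(t)
  cw <- unlist(lapply(t$cells, `[[`, "ws"), use.names = FALSE)
  ci <- rep.int(seq_along(t$cells), vapply(t$cells, function(cl) length(cl$ws), 0L))
  cnt <- tabulate(cw, nbins = nw)
  first <- integer(nw); second <- integer(nw)
  # deterministic fill: first occurrence then second
  o <- order(cw, ci)
  cw_o <- cw[o]; ci_o <- ci[o]
  dup <- duplicated(cw_o)
  first[cw_o[!dup]] <- ci_o[!dup]
  second[cw_o[dup]] <- ci_o[dup]
  list(count = cnt, c1 = first, c2 = second)
}

#' Cell adjacency and boundary queries
#'
#' `neighbor_count()` is the number of distinct cells sharing a wall with
#' the given cell — for an interior cell this equals its number of walls,
#' the "number of neighbors" of cell-packing topology. `boundary_cells()`
#' returns the indices of cells owning at least one wall with no cell on
#' the other side; these are excluded from all tissue statistics because
#' the removal boundary distorts them. `interior_cells()` is the
#' complement.
#'
#' @param t A tissue.
#' @param cell Cell index.
#' @return `neighbor_count()`: an integer. `boundary_cells()`,
#'   `interior_cells()`: integer vectors of cell indices.
#' @export
neighbor_count <- function(t, cell) {
  inc <- wall_cell_incidence(t)
  ws <- t$cells[[cell]]$ws
  other <- ifelse(inc$c1[ws] == cell, inc$c2[ws], inc$c1[ws])
  length(unique(other[other != 0L]))
}

#' @rdname neighbor_count
#' @export
boundary_cells <- function(t) {
  inc <- wall_cell_incidence(t)
  naked <- which(inc$count == 1L)
  sort(unique(inc$c1[naked]))
}

#' @rdname neighbor_count
#' @export
interior_cells <- function(t) {
  setdiff(seq_along(t$cells), boundary_cells(t))
}

# neighbor counts for all cells at once (vector)
neighbor_counts_all <- function(t) {
  inc <- wall_cell_incidence(t)
  vapply(seq_along(t$cells), function(i) {
    ws <- t$cells[[i]]$ws
    other <- ifelse(inc$c1[ws] == i, inc$c2[ws], inc$c1[ws])
    length(unique(other[other != 0L]))
  }, 0L)
}

orient_cell_ccw <- function(t, cl) {
  if (signed_area(t$pos[cl$vs, , drop = FALSE]) < 0) {
    n <- length(cl$vs)
    cl$vs <- rev(cl$vs)
    cl$ws <- c(rev(cl$ws[-n]), cl$ws[n])
  }
  cl
}

#' Divide a cell along a division plane
#'
#' Splits the mother cell by the chord of its polygon through the plane's
#' center along its direction. Two new vertices are inserted on the two cut
#' walls; each cut wall is replaced by two walls whose resting lengths
#' split the old resting length in proportion to the realized sub-lengths;
#' the new wall's resting length equals its realized length (it is born
#' unstressed). Cells on the far side of a cut wall gain the new vertex in
#' their cycle. Both daughters record the division plane direction for the
#' orthogonal rule.
#'
#' If a new vertex would fall within `d_threshold` of an existing junction
#' vertex (which would create a four-way junction, forbidden in the model),
#' it is slid along its wall to exactly `d_threshold` from that junction;
#' walls shorter than `2 * d_threshold` abort the division.
#'
#' @param t A tissue.
#' @param cell Index of the mother cell.
#' @param plane A [division_plane()].
#' @param d_threshold Minimum distance between a new vertex and an existing
#'   junction.
#' @return The modified tissue with attribute `"daughters"` giving the two
#'   daughter indices (the mother's slot and a new final slot), or `NULL`
#'   if the division was aborted (logged as a warning-level message via
#'   `attr(, "aborted")`).
#' @export
split_cell <- function(t, cell, plane, d_threshold = 0.1,
                       short_wall = c("abort", "midpoint")) {
  short_wall <- match.arg(short_wall)
  cl <- t$cells[[cell]]
  vs <- cl$vs; ws <- cl$ws
  n <- length(vs)
  m <- t$pos[vs, , drop = FALSE]
  ch <- tryCatch(
    chord_through_point(m, plane$center, plane$dir),
    error = function(e) NULL)
  if (is.null(ch)) return(structure(t, aborted = "no valid chord"))

  # order the two cut edges along the cycle
  if (ch$edge1 < ch$edge2) {
    eA <- ch$edge1; pA <- ch$p1; eB <- ch$edge2; pB <- ch$p2
  } else {
    eA <- ch$edge2; pA <- ch$p2; eB <- ch$edge1; pB <- ch$p1
  }

  place_on_wall <- function(e, pnew) {
    a <- m[e, ]; b <- m[if (e == n) 1L else e + 1L, ]
    l <- sqrt(sum((b - a)^2))
    if (l < 2 * d_threshold) {
      if (short_wall == "abort") return(NULL)
      s <- l / 2
    } else {
      s <- sqrt(sum((pnew - a)^2))
      s <- min(max(s, d_threshold), l - d_threshold)
    }
    list(p = a + (s / l) * (b - a), frac = s / l)
  }
  plA <- place_on_wall(eA, pA)
  plB <- place_on_wall(eB, pB)
  if (is.null(plA) || is.null(plB)) {
    return(structure(t, aborted = "cut wall shorter than 2*d_threshold"))
  }

  nv <- n_vertices(t); nw <- n_walls(t)
  qA <- nv + 1L; qB <- nv + 2L
  t$pos <- rbind(t$pos, plA$p, plB$p)

  wA <- ws[eA]; wB <- ws[eB]
  # wall wA joins vs[eA] -> vs[eA+1] in this cell's orientation; the stored
  # wall may list the endpoints either way, so split by stored order.
  split_wall <- function(w, q, frac_from_cycle_start, cyc_start_vertex) {
    L0 <- t$walls$rest_length[w]
    v1 <- t$walls$v1[w]; v2 <- t$walls$v2[w]
    frac <- if (v1 == cyc_start_vertex) frac_from_cycle_start else 1 - frac_from_cycle_start
    # reuse slot w for (v1 -> q), new wall for (q -> v2)
    t$walls$v2[w] <<- q
    t$walls$rest_length[w] <<- L0 * frac
    t$walls$v1 <<- c(t$walls$v1, q)
    t$walls$v2 <<- c(t$walls$v2, v2)
    t$walls$rest_length <<- c(t$walls$rest_length, L0 * (1 - frac))
    length(t$walls$v1)   # index of the new (q -> v2) wall
  }
  wA2 <- split_wall(wA, qA, plA$frac, vs[eA])
  wB2 <- split_wall(wB, qB, plB$frac, vs[eB])
  # in cycle order, the piece starting at vs[e] and the piece ending at vs[e+1]
  pieceA_first <- if (t$walls$v1[wA] == vs[eA] || t$walls$v2[wA] == vs[eA]) c(wA, wA2) else c(wA2, wA)
  pieceB_first <- if (t$walls$v1[wB] == vs[eB] || t$walls$v2[wB] == vs[eB]) c(wB, wB2) else c(wB2, wB)

  # new dividing wall, born at its realized length
  new_len <- sqrt(sum((plA$p - plB$p)^2))
  t$walls$v1 <- c(t$walls$v1, qA)
  t$walls$v2 <- c(t$walls$v2, qB)
  t$walls$rest_length <- c(t$walls$rest_length, new_len)
  wN <- length(t$walls$v1)

  dir_angle <- unname(atan2(plB$p[2L] - plA$p[2L], plB$p[1L] - plA$p[1L]) %% pi)

  seg <- function(from, to) if (from > to) integer() else seq.int(from, to)
  # daughter 1: qA -> vs[eA+1 .. eB] -> qB -> qA
  d1 <- list(
    vs = c(qA, vs[seg(eA + 1L, eB)], qB),
    ws = c(pieceA_first[2L], ws[seg(eA + 1L, eB - 1L)], pieceB_first[1L], wN),
    dir = dir_angle)
  # daughter 2: qB -> vs[eB+1 .. n], vs[1 .. eA] -> qA -> qB
  idx2 <- c(seg(eB + 1L, n), seg(1L, eA))
  d2 <- list(
    vs = c(qB, vs[idx2], qA),
    ws = c(pieceB_first[2L], ws[c(seg(eB + 1L, n), seg(1L, eA - 1L))], pieceA_first[1L], wN),
    dir = dir_angle)

  # neighbors across the cut walls gain the new vertex + split wall pair
  patch_neighbor <- function(t, wall_old, wall_new, q, owner) {
    for (j in seq_along(t$cells)) {
      if (j == owner) next
      cl2 <- t$cells[[j]]
      k <- match(wall_old, cl2$ws)
      if (is.na(k)) next
      n2 <- length(cl2$vs)
      # neighbor traverses the old wall from cl2$vs[k] to cl2$vs[k+1]
      start_v <- cl2$vs[k]
      pieces <- if (t$walls$v1[wall_old] == start_v || t$walls$v2[wall_old] == start_v) {
        c(wall_old, wall_new)
      } else {
        c(wall_new, wall_old)
      }
      cl2$vs <- append(cl2$vs, q, after = k)
      cl2$ws <- append(cl2$ws[-k], pieces, after = k - 1L)
      t$cells[[j]] <- cl2
      break
    }
    t
  }
  t <- patch_neighbor(t, wA, wA2, qA, cell)
  t <- patch_neighbor(t, wB, wB2, qB, cell)

  t$cells[[cell]] <- orient_cell_ccw(t, d1)
  t$cells[[length(t$cells) + 1L]] <- orient_cell_ccw(t, d2)
  structure(t, daughters = c(cell, length(t$cells)))
}

#' Remove cells outside a threshold radius
#'
#' Deletes every cell whose area centroid lies farther than `R` from the
#' origin, together with walls and vertices no surviving cell uses, then
#' renumbers indices compactly. This is the model's boundary condition: the
#' planar sheet only approximates the curved meristem surface near the
#' summit, so distant cells are dropped.
#'
#' @param t A tissue.
#' @param R Removal radius (must be positive).
#' @return The pruned tissue with attribute `"removed"` (count).
#' @export
remove_outside_cells <- function(t, R) {
  stopifnot(R > 0)
  cen <- vapply(t$cells, function(cl) {
    ctd <- polygon_centroid(t$pos[cl$vs, , drop = FALSE])
    sqrt(sum(ctd^2))
  }, 0)
  drop <- which(cen > R)
  if (!length(drop)) return(structure(t, removed = 0L))
  keep_cells <- setdiff(seq_along(t$cells), drop)
  t$cells <- t$cells[keep_cells]
  t <- compact_tissue(t)
  structure(t, removed = length(drop))
}

# drop unreferenced walls/vertices and renumber
compact_tissue <- function(t) {
  used_w <- sort(unique(unlist(lapply(t$cells, `[[`, "ws"), use.names = FALSE)))
  wmap <- integer(n_walls(t)); wmap[used_w] <- seq_along(used_w)
  t$walls$v1 <- t$walls$v1[used_w]
  t$walls$v2 <- t$walls$v2[used_w]
  t$walls$rest_length <- t$walls$rest_length[used_w]
  used_v <- sort(unique(c(t$walls$v1, t$walls$v2)))
  vmap <- integer(nrow(t$pos)); vmap[used_v] <- seq_along(used_v)
  t$pos <- t$pos[used_v, , drop = FALSE]
  t$walls$v1 <- vmap[t$walls$v1]
  t$walls$v2 <- vmap[t$walls$v2]
  t$cells <- lapply(t$cells, function(cl) {
    cl$vs <- vmap[cl$vs]; cl$ws <- wmap[cl$ws]; cl
  })
  t
}

#' Validate tissue referential and topological integrity
#'
#' Checks that every wall references existing distinct vertices with a
#' positive resting length, every cell's wall cycle closes through its
#' vertex cycle, every wall has one or two incident cells, no vertex has
#' more than three incident walls (no four-way junctions), and every cell
#' polygon has positive area.
#'
#' @param t A tissue.
#' @return `TRUE` invisibly; stops with a descriptive error otherwise.
#' @export
validate_tissue <- function(t) {
  nv <- n_vertices(t); nw <- n_walls(t)
  w <- t$walls
  if (any(w$v1 < 1L | w$v1 > nv | w$v2 < 1L | w$v2 > nv)) {
    stop("integrity: wall references a missing vertex", call. = FALSE)
  }
  if (any(w$v1 == w$v2)) stop("integrity: wall joins a vertex to itself", call. = FALSE)
  if (any(w$rest_length <= 0)) stop("integrity: non-positive resting length", call. = FALSE)
  deg <- tabulate(c(w$v1, w$v2), nbins = nv)
  if (any(deg > 3L)) stop("integrity: four-vertex present (vertex with >3 walls)", call. = FALSE)
  if (any(deg == 0L)) stop("integrity: orphan vertex", call. = FALSE)
  inc <- wall_cell_incidence(t)
  if (any(inc$count < 1L | inc$count > 2L)) {
    stop("integrity: wall with 0 or >2 incident cells", call. = FALSE)
  }
  for (i in seq_along(t$cells)) {
    cl <- t$cells[[i]]
    n <- length(cl$vs)
    if (n < 3L || length(cl$ws) != n) stop("integrity: open cell cycle", call. = FALSE)
    for (j in seq_len(n)) {
      a <- cl$vs[j]; b <- cl$vs[if (j == n) 1L else j + 1L]
      wj <- cl$ws[j]
      ends <- c(w$v1[wj], w$v2[wj])
      if (!setequal(ends, c(a, b))) {
        stop(sprintf("integrity: cell %d wall %d does not join consecutive vertices", i, wj),
             call. = FALSE)
      }
    }
    if (signed_area(t$pos[cl$vs, , drop = FALSE]) <= 0) {
      stop(sprintf("integrity: cell %d not CCW-positive", i), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Tidy per-cell view of a tissue
#'
#' @param x A tissue.
#' @param ... Unused.
#' @return A tibble with one row per cell: index, number of walls, number
#'   of neighbors, area, perimeter, centroid coordinates, shape measure and
#'   whether the cell touches the tissue boundary.
#' @export
tidy.tissue <- function(x, ...) {
  bnd <- boundary_cells(x)
  nb <- neighbor_counts_all(x)
  rows <- lapply(seq_along(x$cells), function(i) {
    m <- cell_polygon(x, i)
    a <- polygon_area(m)
    per <- sum(sqrt(rowSums((m[c(2:nrow(m), 1L), ] - m)^2)))
    ctd <- polygon_centroid(m)
    tibble::tibble(cell = i, n_walls = nrow(m), n_neighbors = nb[i],
                   area = a, perimeter = per,
                   x = ctd[[1L]], y = ctd[[2L]],
                   shape = a / per^2, boundary = i %in% bnd)
  })
  dplyr::bind_rows(rows)
}
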