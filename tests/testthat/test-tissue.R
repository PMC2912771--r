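test_that("founder construction and cell polygon extraction", {
  f <- make_founder(6)
  expect_identical(length(f$cells), 1L)
  expect_identical(merisim:::n_walls(f), 6L)
  poly <- cell_polygon(f, 1)
  expect_identical(nrow(poly), 6L)
  expect_equal(polygon_area(poly), 0.5, tolerance = 1e-12)  # default founder area
  expect_error(make_founder(2), "3 to 15")
  expect_error(make_founder(16), "3 to 15")
  validate_tissue(f)
})

test_that("neighbor counts and boundary detection on a hand-built rosette", {
  ros <- make_rosette()
  expect_identical(neighbor_count(ros, 1), 6L)          # center sees six cells
  expect_identical(sort(boundary_cells(ros)), 2:7)      # outer ring is boundary
  expect_identical(interior_cells(ros), 1L)
  for (i in 2:7) expect_identical(neighbor_count(ros, i), 3L)
  f <- make_founder(5)
  expect_identical(neighbor_count(f, 1), 0L)
  expect_identical(boundary_cells(f), 1L)
})

test_that("splitting a square cell down the middle halves area and rest lengths", {
  f <- new_tissue(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                  walls = list(v1 = 1:4, v2 = c(2, 3, 4, 1),
                               rest_length = rep(1, 4)),
                  cells = list(list(vs = 1:4, ws = 1:4, dir = NA_real_)))
  plane <- division_plane(unname(polygon_centroid(cell_polygon(f, 1))), pi / 2)
  t2 <- split_cell(f, 1, plane, d_threshold = 0.1)
  expect_null(attr(t2, "aborted"))
  expect_identical(length(t2$cells), 2L)
  a <- vapply(1:2, function(i) polygon_area(cell_polygon(t2, i)), 0)
  expect_equal(a, c(0.5, 0.5), tolerance = 1e-12)
  # each daughter shares exactly two vertices with its sibling
  shared <- intersect(t2$cells[[1]]$vs, t2$cells[[2]]$vs)
  expect_identical(length(shared), 2L)
  # cut walls split 0.5/0.5; new wall born at its realized length (1)
  expect_identical(merisim:::n_walls(t2), 7L)
  rl <- sort(t2$walls$rest_length)
  expect_equal(rl, c(rep(0.5, 4), 1, 1, 1), tolerance = 1e-12)
  expect_identical(neighbor_count(t2, 1), 1L)
  expect_identical(neighbor_count(t2, 2), 1L)
  # both daughters remember the division plane axis
  expect_equal(t2$cells[[1]]$dir, pi / 2, tolerance = 1e-12)
  expect_equal(t2$cells[[2]]$dir, pi / 2, tolerance = 1e-12)
  validate_tissue(t2)
})

test_that("split rest lengths are proportional to realized sub-lengths", {
  # rectangle 2 wide, 1 tall; wall rest lengths match realized lengths,
  # vertical cut at x = 0.6 splits the bottom/top walls 30%/70%
  pos <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  tt <- new_tissue(pos,
                   walls = list(v1 = 1:4, v2 = c(2, 3, 4, 1),
                                rest_length = c(2, 1, 2, 1)),
                   cells = list(list(vs = 1:4, ws = 1:4, dir = NA_real_)))
  plane <- division_plane(c(0.6, 0.5), pi / 2)
  t2 <- split_cell(tt, 1, plane, d_threshold = 0.1)
  expect_null(attr(t2, "aborted"))
  horiz <- which(abs(t2$pos[t2$walls$v1, 2] - t2$pos[t2$walls$v2, 2]) < 1e-12 &
                   t2$walls$rest_length < 2)
  expect_equal(sort(t2$walls$rest_length[horiz]), c(0.6, 0.6, 1.4, 1.4),
               tolerance = 1e-12)
  a <- vapply(1:2, function(i) polygon_area(cell_polygon(t2, i)), 0)
  expect_equal(sort(a), c(0.6, 1.4), tolerance = 1e-12)
})

test_that("four-vertex avoidance relocates new vertices to the threshold", {
  pos <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  tt <- new_tissue(pos,
                   walls = list(v1 = 1:4, v2 = c(2, 3, 4, 1),
                                rest_length = c(2, 1, 2, 1)),
                   cells = list(list(vs = 1:4, ws = 1:4, dir = NA_real_)))
  # near-vertical cut hitting the bottom wall 0.04 from its left end
  plane <- division_plane(c(0.04, 0.5), pi / 2)
  t2 <- split_cell(tt, 1, plane, d_threshold = 0.1)
  expect_null(attr(t2, "aborted"))
  newv <- t2$pos[5:6, , drop = FALSE]
  # relocated to exactly 0.1 from the corner, along the wall
  expect_equal(sort(newv[, 1]), c(0.1, 0.1), tolerance = 1e-9)
  # area is still conserved because the vertex slides along the old wall
  a <- vapply(1:2, function(i) polygon_area(cell_polygon(t2, i)), 0)
  expect_equal(sum(a), 2, tolerance = 1e-12)

  # wall shorter than 2*d_threshold: division aborted, state unchanged
  small <- make_founder(4, circumradius = 0.12)
  plane2 <- division_plane(unname(polygon_centroid(cell_polygon(small, 1))), 0)
  t3 <- split_cell(small, 1, plane2, d_threshold = 0.1)
  expect_identical(attr(t3, "aborted"), "cut wall shorter than 2*d_threshold")
  expect_identical(length(t3$cells), 1L)
})

test_that("division updates the neighbor across each cut wall", {
  ros <- make_rosette()
  plane <- division_plane(c(0, 0), 0)   # horizontal cut through the center cell
  t2 <- split_cell(ros, 1, plane, d_threshold = 0.05)
  expect_null(attr(t2, "aborted"))
  validate_tissue(t2)
  expect_identical(length(t2$cells), 8L)
  # total area conserved
  tot0 <- sum(merisim:::cell_areas(ros))
  expect_equal(sum(merisim:::cell_areas(t2)), tot0, tolerance = 1e-9)
  # exactly two of the six outer cells gained a vertex (4 -> 5); the two
  # daughters (slots 1 and 8) are pentagons as well
  n_vs <- vapply(t2$cells, function(cl) length(cl$vs), 0L)
  expect_identical(sum(n_vs[2:7] == 5L), 2L)
  expect_identical(n_vs[c(1L, 8L)], c(5L, 5L))
})

test_that("cell removal prunes by centroid radius and keeps integrity", {
  ros <- make_rosette()
  t2 <- remove_outside_cells(ros, R = 100)
  expect_identical(attr(t2, "removed"), 0L)
  expect_identical(length(t2$cells), 7L)

  # outer-ring centroids sit near r = 1.5; removing beyond 1.2 keeps only
  # the center cell
  t3 <- remove_outside_cells(ros, R = 1.2)
  expect_identical(attr(t3, "removed"), 6L)
  expect_identical(length(t3$cells), 1L)
  validate_tissue(t3)
  expect_identical(merisim:::n_walls(t3), 6L)

  # single far-away cell: tissue empties
  f <- make_founder(6)
  f$pos[, 1] <- f$pos[, 1] + 20
  t4 <- remove_outside_cells(f, R = 7)
  expect_identical(attr(t4, "removed"), 1L)
  expect_identical(length(t4$cells), 0L)
})

test_that("repeated random divisions conserve area and mesh invariants", {
  set.seed(61)
  tt <- make_founder(6, circumradius = 2)
  for (i in 1:40) {
    areas <- merisim:::cell_areas(tt)
    ci <- which.max(areas)
    plane <- make_plane(tt, ci, division_rule("RandomDirectionRandom"))
    tot0 <- sum(areas)
    t2 <- split_cell(tt, ci, plane, d_threshold = 0.02)
    if (!is.null(attr(t2, "aborted"))) next
    tt <- t2
    expect_equal(sum(merisim:::cell_areas(tt)), tot0, tolerance = 1e-9)
  }
  validate_tissue(tt)
  deg <- tabulate(c(tt$walls$v1, tt$walls$v2), nbins = nrow(tt$pos))
  expect_true(all(deg <= 3))
  inc <- merisim:::wall_cell_incidence(tt)
  expect_true(all(inc$count %in% 1:2))
})

test_that("tidy.tissue reports one row per cell with consistent geometry", {
  ros <- make_rosette()
  td <- tidy(ros)
  expect_identical(nrow(td), 7L)
  expect_identical(td$n_neighbors[1], 6L)
  expect_false(td$boundary[1])
  expect_true(all(td$boundary[2:7]))
  expect_equal(td$shape, td$area / td$perimeter^2)
})
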