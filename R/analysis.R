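#' Per-snapshot tissue statistics
#'
#' Gathers the statistics used to compare division rules, over interior
#' cells only (cells on the tissue boundary are excluded because the
#' removal boundary distorts them): neighbor counts, areas, the shape
#' measure (area over perimeter squared) and internal vertex angles.
#'
#' @param tissue A tissue state.
#' @return A list of class `"snapshot_stats"` with elements `cells` (a
#'   tibble: cell index, `n_neighbors`, `area`, `perimeter`, `shape`),
#'   `angles` (numeric vector of internal vertex angles of interior
#'   cells, radians), `n_total` and `mean_area_all` (mean cell area over
#'   *all* cells, the Lewis-law normalization constant), and `time`.
#' @export
snapshot_stats <- function(tissue) {
  ic <- interior_cells(tissue)
  if (!length(ic)) stop("no interior cells to gather statistics from", call. = FALSE)
  nb <- neighbor_counts_all(tissue)[ic]
  per_cell <- lapply(ic, function(i) {
    m <- cell_polygon(tissue, i)
    a <- polygon_area(m)
    per <- sum(sqrt(rowSums((m[c(2:nrow(m), 1L), , drop = FALSE] - m)^2)))
    list(area = a, perimeter = per, angles = internal_vertex_angles(m))
  })
  cells <- tibble::tibble(
    cell = ic,
    n_neighbors = nb,
    area = vapply(per_cell, `[[`, 0, "area"),
    perimeter = vapply(per_cell, `[[`, 0, "perimeter"))
  cells$shape <- cells$area / cells$perimeter^2
  all_areas <- cell_areas(tissue)
  structure(list(cells = cells,
                 angles = unlist(lapply(per_cell, `[[`, "angles"), use.names = FALSE),
                 n_total = length(tissue$cells),
                 mean_area_all = mean(all_areas),
                 time = tissue$sim_time),
            class = "snapshot_stats")
}

#' @export
print.snapshot_stats <- function(x, ...) {
  cat(sprintf("<snapshot_stats> %d interior cells (of %d) at t = %.4g\n",
              nrow(x$cells), x$n_total, x$time))
  invisible(x)
}

#' @export
tidy.snapshot_stats <- function(x, ...) x$cells

#' Neighbor-number distribution
#'
#' Normalized histogram of the number of neighbors over interior cells.
#'
#' @param x A `snapshot_stats` object or an integer vector of neighbor
#'   counts.
#' @return A tibble with columns `n` and `fraction` (summing to 1).
#' @export
neighbor_distribution <- function(x) {
  counts <- if (inherits(x, "snapshot_stats")) x$cells$n_neighbors else as.integer(x)
  if (!length(counts)) stop("empty neighbor-count sample", call. = FALSE)
  tab <- table(counts)
  tibble::tibble(n = as.integer(names(tab)),
                 fraction = as.numeric(tab) / length(counts))
}

#' Standard deviation and skewness of a neighbor-count sample
#'
#' Population standard deviation and the standardized third central moment
#' of the per-cell neighbor counts. A degenerate sample (all cells with
#' the same neighbor number) has zero standard deviation and its skewness
#' is reported as 0 with the `degenerate` flag set.
#'
#' @param x A `snapshot_stats` object or an integer vector of counts.
#' @return A tibble with one row: `mean`, `std`, `skewness`, `degenerate`.
#' @export
distribution_moments <- function(x) {
  counts <- if (inherits(x, "snapshot_stats")) x$cells$n_neighbors else as.numeric(x)
  mu <- mean(counts)
  m2 <- mean((counts - mu)^2)
  degenerate <- m2 < 1e-300
  skew <- if (degenerate) 0 else mean((counts - mu)^3) / m2^1.5
  tibble::tibble(mean = mu, std = sqrt(m2), skewness = skew, degenerate = degenerate)
}

#' Deviation of a neighbor distribution from a reference
#'
#' Quantifies how far a simulated neighbor-number distribution lies from a
#' reference (experimental) distribution. The default metric is the sum of
#' squared fraction differences over the union of observed neighbor
#' numbers, \eqn{D = \sum_n (f_n - f_n^{exp})^2}; `"l1"` (sum of absolute
#' differences) and `"chisq"` (squared differences scaled by the
#' reference, dropping classes absent from it) are selectable. Lower is a
#' better match; the rule *ranking* is the robust content of this
#' statistic, not its absolute value.
#'
#' @param f A tibble as from [neighbor_distribution()] (columns `n`,
#'   `fraction`), or a `snapshot_stats` object.
#' @param ref A reference distribution in the same format; defaults to
#'   [reference_distribution()].
#' @param method Deviation metric.
#' @return A single number.
#' @export
deviation <- function(f, ref = reference_distribution(),
                      method = c("sq", "l1", "chisq")) {
  method <- match.arg(method)
  if (inherits(f, "snapshot_stats")) f <- neighbor_distribution(f)
  stopifnot(all(c("n", "fraction") %in% names(f)), all(c("n", "fraction") %in% names(ref)))
  ns <- sort(union(f$n, ref$n))
  fv <- f$fraction[match(ns, f$n)]; fv[is.na(fv)] <- 0
  rv <- ref$fraction[match(ns, ref$n)]; rv[is.na(rv)] <- 0
  switch(method,
         sq = sum((fv - rv)^2),
         l1 = sum(abs(fv - rv)),
         chisq = sum(((fv - rv)^2 / rv)[rv > 0]))
}

#' Cell shape measure
#'
#' The ratio of cell area to squared total wall length (perimeter),
#' \eqn{s = A/P^2}: a dimensionless symmetry measure ranging from 0 for
#' flat cells to the isoperimetric limit \eqn{1/(4\pi) \approx 0.0796}
#' for circles. A regular hexagon scores \eqn{\sqrt{3}/24 \approx 0.072}.
#'
#' @param p A polygon (cell outline).
#' @return A single number in \eqn{(0, 1/(4\pi)]}.
#' @export
shape_measure <- function(p) {
  m <- as_poly_matrix(p)
  a <- polygon_area(m)
  per <- sum(sqrt(rowSums((m[c(2:nrow(m), 1L), , drop = FALSE] - m)^2)))
  a / per^2
}

#' Internal-angle histograms: observed and ideal
#'
#' `angle_distribution()` bins the observed internal vertex angles of
#' interior cells. `ideal_angle_distribution()` is the distribution the
#' angles would have if every cell were a regular polygon: a cell with
#' \eqn{n} walls contributes \eqn{n} angles of \eqn{(n-2)\pi/n}, weighted
#' by the neighbor-number fractions; this is the limit the tissue relaxes
#' toward when division is suppressed. `angle_tv_distance()` is the
#' total-variation distance between two histograms on the same bins.
#'
#' @param x A `snapshot_stats` object or numeric vector of angles
#'   (radians) for `angle_distribution()`; a neighbor distribution tibble
#'   (columns `n`, `fraction`) for `ideal_angle_distribution()`.
#' @param bins Number of equal-width bins over \eqn{(0, \pi]}.
#' @return A tibble with `mid` (bin midpoint, radians) and `density`
#'   (fractions summing to 1).
#' @export
angle_distribution <- function(x, bins = 36L) {
  ang <- if (inherits(x, "snapshot_stats")) x$angles else as.numeric(x)
  brk <- seq(0, pi, length.out = bins + 1L)
  ct <- tabulate(pmin(bins, pmax(1L, findInterval(ang, brk, rightmost.closed = TRUE))),
                 nbins = bins)
  tibble::tibble(mid = (brk[-1L] + brk[-(bins + 1L)]) / 2,
                 density = ct / sum(ct))
}

#' @rdname angle_distribution
#' @export
ideal_angle_distribution <- function(x, bins = 36L) {
  stopifnot(all(c("n", "fraction") %in% names(x)))
  w <- x$n * x$fraction          # each n-gon contributes n vertex angles
  w <- w / sum(w)
  ang <- (x$n - 2) * pi / x$n
  brk <- seq(0, pi, length.out = bins + 1L)
  bin <- pmin(bins, pmax(1L, findInterval(ang, brk, rightmost.closed = TRUE)))
  dens <- vapply(seq_len(bins), function(b) sum(w[bin == b]), 0)
  tibble::tibble(mid = (brk[-1L] + brk[-(bins + 1L)]) / 2, density = dens)
}

#' @rdname angle_distribution
#' @param p,q Two histograms on identical bins (tibbles with `density`).
#' @export
angle_tv_distance <- function(p, q) {
  stopifnot(nrow(p) == nrow(q))
  0.5 * sum(abs(p$density - q$density))
}

#' Lewis' law fit
#'
#' Lewis' law states that the mean cell area grows linearly with the
#' number of neighbors. Areas are normalized so that the mean over *all*
#' cells of the tissue equals one, then interior cells are grouped by
#' neighbor number and a least-squares line (weighted by class counts) is
#' fitted to the per-class mean normalized areas. The classical reference
#' line is \eqn{\bar A_n = (n-2)/4}, slope 1/4, which the fit is compared
#' against.
#'
#' @param stats A `snapshot_stats` object, or a list of them (pooled
#'   per-class after normalizing each snapshot by its own mean area).
#' @return An object of class `"lewis_fit"`: `by_n` (tibble of `n`,
#'   `mean_area`, `sd_area`, `count`), `slope`, `intercept`,
#'   `reference_slope` (0.25). Has [tidy()] and [glance()] methods.
#' @export
lewis_law <- function(stats) {
  if (inherits(stats, "snapshot_stats")) stats <- list(stats)
  df <- dplyr::bind_rows(lapply(stats, function(s) {
    tibble::tibble(n = s$cells$n_neighbors, a = s$cells$area / s$mean_area_all)
  }))
  by_n <- df |>
    dplyr::group_by(n) |>
    dplyr::summarise(mean_area = mean(a),
                     sd_area = stats::sd(a),
                     count = dplyr::n(), .groups = "drop")
  fit <- stats::lm(mean_area ~ n, data = by_n, weights = by_n$count)
  structure(list(by_n = by_n,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 reference_slope = 0.25,
                 fit = fit),
            class = "lewis_fit")
}

#' @export
print.lewis_fit <- function(x, ...) {
  cat(sprintf("<lewis_fit> slope %.3f (reference 0.25), intercept %.3f, %d classes\n",
              x$slope, x$intercept, nrow(x$by_n)))
  invisible(x)
}

#' @export
tidy.lewis_fit <- function(x, ...) {
  dplyr::mutate(x$by_n, reference = (n - 2) / 4)
}

#' @export
glance.lewis_fit <- function(x, ...) {
  r2 <- suppressWarnings(summary(x$fit)$r.squared)
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 reference_slope = x$reference_slope,
                 r_squared = r2,
                 n_classes = nrow(x$by_n))
}

#' Aggregate snapshot statistics for one division rule
#'
#' Across-snapshot mean and sample standard deviation of the per-snapshot
#' topology and geometry statistics: neighbor-number standard deviation
#' and skewness, mean shape measure, deviation from the reference
#' distribution, interior and total cell counts.
#'
#' @param stats_list A list of `snapshot_stats` (at least one; error bars
#'   need at least two).
#' @param rule Optional rule label carried into the output.
#' @param ref Reference distribution for the deviation measure (`NULL` to
#'   skip).
#' @param deviation_method Passed to [deviation()].
#' @return A one-row tibble with columns `rule`, `n_snapshots`,
#'   `std_mean`, `std_sd`, `skew_mean`, `skew_sd`, `shape_mean`,
#'   `shape_sd`, `deviation_mean`, `deviation_sd`, `cells_mean`,
#'   `cells_sd`, `interior_mean`.
#' @export
aggregate_stats <- function(stats_list, rule = NA_character_,
                            ref = reference_distribution(),
                            deviation_method = "sq") {
  stopifnot(length(stats_list) >= 1L)
  per <- dplyr::bind_rows(lapply(stats_list, function(s) {
    mom <- distribution_moments(s)
    dev <- if (is.null(ref)) NA_real_ else {
      deviation(neighbor_distribution(s), ref, method = deviation_method)
    }
    tibble::tibble(std = mom$std, skew = mom$skewness,
                   shape = mean(s$cells$shape), dev = dev,
                   cells = s$n_total, interior = nrow(s$cells))
  }))
  tibble::tibble(
    rule = rule, n_snapshots = nrow(per),
    std_mean = mean(per$std), std_sd = stats::sd(per$std),
    skew_mean = mean(per$skew), skew_sd = stats::sd(per$skew),
    shape_mean = mean(per$shape), shape_sd = stats::sd(per$shape),
    deviation_mean = mean(per$dev), deviation_sd = stats::sd(per$dev),
    cells_mean = mean(per$cells), cells_sd = stats::sd(per$cells),
    interior_mean = mean(per$interior))
}

#' Synthetic reference neighbor-number distribution
#'
#' The deviation measure compares simulated tissues against the
#' neighbor-number distribution of an epidermal tissue. The original
#' 110-cell *Arabidopsis* dataset is not publicly deposited (only its
#' summary moments are: standard deviation 0.90, skewness 0.53), so the
#' shipped default is a **synthetic stand-in**: a plausible epidermal
#' distribution (hexagon-dominated, more five- than seven-sided cells)
#' constructed to match those printed moments. Supply your own
#' two-column table (`n`, `fraction`) for comparisons against real data.
#'
#' @param synthetic_default If `TRUE` (default) return the synthetic
#'   stand-in described above.
#' @return A tibble with columns `n` and `fraction` summing to 1.
#' @export
reference_distribution <- function(synthetic_default = TRUE) {
  if (!synthetic_default) {
    stop("no experimental distribution is bundled; supply a (n, fraction) table",
         call. = FALSE)
  }
  # synthetic: hexagon-dominated, five- over seven-sided, constructed so
  # the sample moments match the printed summary (std 0.90, skew 0.53)
  tibble::tibble(
    n = 4:9,
    fraction = c(0.0222, 0.2586, 0.4894, 0.1635, 0.0596, 0.0067))
}
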