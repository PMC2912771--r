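#' Founder cell
#'
#' A single regular polygonal cell centered at the origin, stress-free:
#' every wall's resting length equals its realized length, so with the
#' radial force off the founder is a fixed point of the dynamics. By
#' default the circumradius is chosen so the founder's area is half the
#' standard division threshold.
#'
#' @param n_vertices Number of vertices, 3 to 15.
#' @param circumradius Circumradius; if `NULL`, derived so the polygon
#'   area equals `area`.
#' @param area Target founder area used when `circumradius` is `NULL`.
#' @return A single-cell [new_tissue()].
#' @export
make_founder <- function(n_vertices, circumradius = NULL, area = 0.5) {
  if (n_vertices < 3L || n_vertices > 15L) {
    stop("founder polygons have 3 to 15 vertices", call. = FALSE)
  }
  n <- as.integer(n_vertices)
  if (is.null(circumradius)) {
    circumradius <- sqrt(2 * area / (n * sin(2 * pi / n)))
  }
  poly <- regular_polygon(n, circumradius)
  pos <- as_poly_matrix(poly)
  v2 <- c(seq_len(n)[-1L], 1L)
  len <- sqrt(rowSums((pos[v2, , drop = FALSE] - pos)^2))
  new_tissue(
    pos,
    walls = list(v1 = seq_len(n), v2 = v2, rest_length = len),
    cells = list(list(vs = seq_len(n), ws = seq_len(n), dir = NA_real_)))
}

# Cash-Karp embedded Runge-Kutta 4(5) tableau
ck_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(3 / 10, -9 / 10, 6 / 5),
  c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
  c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096))
ck_b5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
ck_b4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)

# one adaptive Cash-Karp step; returns list(y, h_used, h_next, nfail)
rk45_step <- function(y, h, rhs, rel_tol, abs_tol, h_max, h_min = 1e-10) {
  k1 <- rhs(y)
  nfail <- 0L
  repeat {
    k2 <- rhs(y + h * ck_a[[1L]][1L] * k1)
    k3 <- rhs(y + h * (ck_a[[2L]][1L] * k1 + ck_a[[2L]][2L] * k2))
    k4 <- rhs(y + h * (ck_a[[3L]][1L] * k1 + ck_a[[3L]][2L] * k2 + ck_a[[3L]][3L] * k3))
    k5 <- rhs(y + h * (ck_a[[4L]][1L] * k1 + ck_a[[4L]][2L] * k2 +
                         ck_a[[4L]][3L] * k3 + ck_a[[4L]][4L] * k4))
    k6 <- rhs(y + h * (ck_a[[5L]][1L] * k1 + ck_a[[5L]][2L] * k2 +
                         ck_a[[5L]][3L] * k3 + ck_a[[5L]][4L] * k4 + ck_a[[5L]][5L] * k5))
    y5 <- y + h * (ck_b5[1L] * k1 + ck_b5[3L] * k3 + ck_b5[4L] * k4 + ck_b5[6L] * k6)
    y4 <- y + h * (ck_b4[1L] * k1 + ck_b4[3L] * k3 + ck_b4[4L] * k4 +
                     ck_b4[5L] * k5 + ck_b4[6L] * k6)
    sc <- abs_tol + rel_tol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1 || h <= h_min) {
      fac <- if (err > 0) 0.9 * err^(-0.2) else 5
      h_next <- min(h_max, h * min(5, max(0.2, fac)))
      return(list(y = y5, h_used = h, h_next = h_next, nfail = nfail))
    }
    h <- max(h_min, h * max(0.2, 0.9 * err^(-0.2)))
    nfail <- nfail + 1L
    if (nfail > 50L) stop("step size underflow in adaptive integrator", call. = FALSE)
  }
}

# divide every over-threshold cell (ascending index), repeating until none
# exceeds the threshold; returns tissue with attr "divisions" count
apply_divisions <- function(t, params, rule) {
  ndiv <- 0L
  repeat {
    areas <- cell_areas(t)
    over <- which(areas > params$area_threshold)
    if (!length(over)) break
    done_any <- FALSE
    for (ci in over) {
      plane <- make_plane(t, ci, rule, signed_strain = params$strain_signed)
      t2 <- split_cell(t, ci, plane, d_threshold = params$d_threshold)
      if (is.null(attr(t2, "aborted"))) {
        t <- t2
        ndiv <- ndiv + 1L
        done_any <- TRUE
      }
    }
    if (!done_any) break  # all aborted; retried after the next step
  }
  structure(t, divisions = ndiv)
}

#' Run a growth simulation
#'
#' Integrates the overdamped spring dynamics with an adaptive fifth-order
#' embedded Runge-Kutta (Cash-Karp) scheme. After every accepted step the
#' driver (1) divides every cell whose area exceeds the threshold, using
#' the given division rule (unless division is disabled), and (2) removes
#' cells whose centroids lie beyond the removal radius (unless removal is
#' disabled). Checking after each accepted step, with the step bounded by
#' `h_max`, bounds how far a cell can overshoot the threshold between
#' checks. Each topology change rebuilds the flat state vector and
#' restarts the integrator.
#'
#' Runs are fully reproducible: all randomness (random centers/directions
#' and fallbacks) flows from R's RNG, seeded once via `seed`.
#'
#' @param tissue Initial [new_tissue()] state.
#' @param params A [model_params()].
#' @param rule A [division_rule()] or rule name string.
#' @param t_end Simulation end time (relative to the tissue's `sim_time`).
#' @param snapshot_times Times (absolute, within the run) at which deep
#'   copies of the state are recorded; the final state is always appended.
#' @param seed Optional integer seed.
#' @param stop_cells Stop early once the total cell count reaches this
#'   value (used by initial-state generation); `Inf` to disable.
#' @return A list of class `"sim_result"` with `snapshots` (list of
#'   tissues), `final` (final tissue), `trace` (tibble of time, cell count,
#'   interior count, divisions, removals per event check), `params`,
#'   `rule`, `seed`.
#' @export
simulate_tissue <- function(tissue, params = model_params(),
                            rule = "ShortestPathCOM",
                            t_end = 100, snapshot_times = numeric(),
                            seed = NULL, stop_cells = Inf) {
  if (!inherits(rule, "division_rule")) rule <- division_rule(rule)
  if (!is.null(seed)) {
    set.seed(seed)
  } else if (!is.null(tissue$rng_state)) {
    assign(".Random.seed", tissue$rng_state, envir = globalenv())
  }
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1L)

  t0 <- tissue$sim_time
  t_stop <- t0 + t_end
  snap_times <- sort(unique(snapshot_times))
  snap_times <- snap_times[snap_times > t0 & snap_times <= t_stop]
  snapshots <- vector("list", 0L)
  trace_t <- trace_n <- trace_ni <- trace_div <- trace_rm <- numeric(0L)

  tt <- tissue
  time <- t0
  y <- pack_state(tt)
  rhs <- function(yy) ode_rhs(yy, tt, params)
  h <- min(params$h_max, 0.1)

  # event processing at t0 (founders may already exceed the threshold)
  tt <- unpack_state(tt, y)
  if (params$division_enabled) {
    tt <- apply_divisions(tt, params, rule)
  }
  if (params$removal_enabled) tt <- remove_outside_cells(tt, params$radius_threshold)
  y <- pack_state(tt)

  take_snapshot <- function(tt, time) {
    tt$sim_time <- time
    tt$rng_state <- get(".Random.seed", envir = globalenv())
    tt
  }

  while (time < t_stop - 1e-12) {
    h_cap <- t_stop - time
    pending <- snap_times[snap_times > time + 1e-12]
    if (length(pending)) h_cap <- min(h_cap, pending[1L] - time)
    st <- rk45_step(y, min(h, h_cap), rhs, params$rel_tol, params$abs_tol,
                    h_max = min(params$h_max, h_cap))
    y <- st$y
    time <- time + st$h_used
    h <- st$h_next
    tt <- unpack_state(tt, y)

    ndiv <- 0L; nrm <- 0L
    if (params$division_enabled) {
      tt <- apply_divisions(tt, params, rule)
      ndiv <- attr(tt, "divisions")
    }
    if (params$removal_enabled) {
      tt <- remove_outside_cells(tt, params$radius_threshold)
      nrm <- attr(tt, "removed")
    }
    if (ndiv > 0L || nrm > 0L) {
      y <- pack_state(tt)
      h <- min(h, params$h_max)
    }

    trace_t <- c(trace_t, time)
    trace_n <- c(trace_n, length(tt$cells))
    trace_ni <- c(trace_ni, length(interior_cells(tt)))
    trace_div <- c(trace_div, ndiv)
    trace_rm <- c(trace_rm, nrm)

    if (length(pending) && abs(time - pending[1L]) < 1e-9) {
      snapshots[[length(snapshots) + 1L]] <- take_snapshot(tt, time)
    }
    if (length(tt$cells) >= stop_cells) break
  }

  final <- take_snapshot(tt, time)
  structure(list(snapshots = snapshots, final = final,
                 trace = tibble::tibble(time = trace_t, n_cells = trace_n,
                                        n_interior = trace_ni,
                                        divisions = trace_div, removals = trace_rm),
                 params = params, rule = rule$name, seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> rule %s: %d snapshot(s), final t = %.4g, %d cells\n",
              x$rule, length(x$snapshots), x$final$sim_time, length(x$final$cells)))
  invisible(x)
}

#' Generate a library of initial tissue states
#'
#' Reproduces the initial-state protocol: for each founder polygon, run a
#' long simulation with the ShortestPath x COM rule (the rule used to
#' generate plant-like starting tissues) and capture evenly spaced
#' snapshots once the tissue first reaches the boundary-limited regime
#' (total cell count above `cell_trigger`). The full-scale protocol uses
#' founders of 3 to 15 vertices with 25 snapshots each (325 states);
#' reduced counts are supported for testing.
#'
#' @param founder_sides Integer vector of founder polygon vertex counts.
#' @param snapshots_per_founder Snapshots captured per founder.
#' @param params A [model_params()].
#' @param snapshot_interval Time between captured snapshots.
#' @param cell_trigger Total cell count marking the boundary-limited
#'   regime.
#' @param seed Integer seed for the whole generation run.
#' @param max_time Safety cap on the growth phase per founder.
#' @return A list of tissue states (length
#'   `length(founder_sides) * snapshots_per_founder`).
#' @export
generate_initial_states <- function(founder_sides = 3:15,
                                    snapshots_per_founder = 25L,
                                    params = model_params(),
                                    snapshot_interval = 10,
                                    cell_trigger = 150L,
                                    seed = NULL,
                                    max_time = 20000) {
  stopifnot(length(founder_sides) >= 1L, snapshots_per_founder >= 1L)
  if (!is.null(seed)) set.seed(seed)
  rule <- division_rule("ShortestPathCOM")
  states <- vector("list", 0L)
  for (n in founder_sides) {
    f <- make_founder(n)
    grown <- simulate_tissue(f, params, rule, t_end = max_time,
                             stop_cells = cell_trigger)
    st <- grown$final
    states[[length(states) + 1L]] <- st
    if (snapshots_per_founder > 1L) {
      for (k in seq_len(snapshots_per_founder - 1L)) {
        nxt <- simulate_tissue(st, params, rule, t_end = snapshot_interval)
        st <- nxt$final
        states[[length(states) + 1L]] <- st
      }
    }
  }
  states
}

#' Continue a tissue with cell division suppressed
#'
#' The oryzalin perturbation: microtubule depolymerization blocks division
#' while growth continues. Dynamics are identical to the standard run but
#' with division and boundary removal disabled (the division and removal
#' parameters are unused), so topology is frozen while walls keep growing
#' under tension; internal vertex angles relax toward the regular-polygon
#' ideal (120 degrees for hexagons).
#'
#' @param initial Tissue state from a prior dividing simulation.
#' @param params A [model_params()]; its division/removal switches are
#'   overridden off.
#' @param t_end Relaxation duration.
#' @param snapshot_times Optional intermediate snapshot times.
#' @param seed Optional seed (the run is deterministic; the seed only
#'   fixes the stored RNG state).
#' @return A `"sim_result"`.
#' @export
run_oryzalin <- function(initial, params = model_params(), t_end = 60,
                         snapshot_times = numeric(), seed = NULL) {
  params$division_enabled <- FALSE
  params$removal_enabled <- FALSE
  simulate_tissue(initial, params, rule = "ShortestPathCOM",
                  t_end = t_end, snapshot_times = snapshot_times, seed = seed)
}
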