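#' Model parameters
#'
#' The mechanical and event parameters of the growing-sheet model, with
#' the standard simulation values as defaults: wall spring stiffness
#' `spring_k` = 0.05, wall growth rate `growth_k` = 0.01 (per time unit),
#' radial turgor/growth force `radial_k` = 0.05, division area threshold
#' `area_threshold` = 1.0, four-vertex avoidance distance `d_threshold` =
#' 0.1, and removal radius `radius_threshold` = 7.0. The oryzalin
#' (no-division) preset keeps the three mechanical constants and disables
#' division and boundary removal, mirroring a microtubule-depolymerized
#' tissue that keeps growing without dividing.
#'
#' @param spring_k Wall spring stiffness (force per unit extension).
#' @param growth_k Rest-length growth rate constant (1/time).
#' @param radial_k Magnitude of the outward radial force on each vertex.
#' @param area_threshold Cell area that triggers division.
#' @param d_threshold Minimum distance between a new division vertex and an
#'   existing junction.
#' @param radius_threshold Centroid radius beyond which cells are removed.
#' @param division_enabled If `FALSE`, cells never divide (oryzalin mode).
#' @param removal_enabled If `FALSE`, cells are never removed at the
#'   boundary (used together with `division_enabled = FALSE`).
#' @param radial_mode `"linear"` (default): the radial force is
#'   proportional to the position vector, magnitude `radial_k * r`, i.e.
#'   uniform isotropic dilation of the sheet. `"constant"`: constant
#'   magnitude `radial_k` along the outward unit vector. Linear is the
#'   default because under the constant variant the total outward push
#'   grows with the vertex count and the resulting hoop tension squeezes
#'   boundary cells flat (eventually inverting them), and because only
#'   the linear variant lets the internal-angle distribution relax toward
#'   the regular-polygon ideal when division is suppressed.
#' @param strain_signed If `TRUE`, compressed walls contribute negative
#'   strain to the cell strain direction; by default strain is the relative
#'   extension clipped at zero.
#' @param rel_tol,abs_tol Local error tolerances of the adaptive
#'   Runge-Kutta integrator.
#' @param h_max Maximum integrator step, which also bounds the lag between
#'   consecutive division/removal checks.
#' @return A list of class `"model_params"`.
#' @export
model_params <- function(spring_k = 0.05, growth_k = 0.01, radial_k = 0.05,
                         area_threshold = 1.0, d_threshold = 0.1,
                         radius_threshold = 7.0,
                         division_enabled = TRUE, removal_enabled = TRUE,
                         radial_mode = c("linear", "constant"),
                         strain_signed = FALSE,
                         rel_tol = 1e-6, abs_tol = 1e-8, h_max = 1.0) {
  radial_mode <- match.arg(radial_mode)
  pos <- c(spring_k = spring_k, area_threshold = area_threshold,
           d_threshold = d_threshold, radius_threshold = radius_threshold,
           rel_tol = rel_tol, abs_tol = abs_tol, h_max = h_max)
  nonneg <- c(growth_k = growth_k, radial_k = radial_k)
  if (any(!is.finite(c(pos, nonneg))) || any(pos <= 0) || any(nonneg < 0)) {
    stop("model parameters must be positive (rates may be zero) and finite",
         call. = FALSE)
  }
  if (rel_tol >= 1 || abs_tol >= 1) stop("solver tolerances must be in (0, 1)", call. = FALSE)
  structure(list(spring_k = spring_k, growth_k = growth_k, radial_k = radial_k,
                 area_threshold = area_threshold, d_threshold = d_threshold,
                 radius_threshold = radius_threshold,
                 division_enabled = isTRUE(division_enabled),
                 removal_enabled = isTRUE(removal_enabled),
                 radial_mode = radial_mode,
                 strain_signed = isTRUE(strain_signed),
                 rel_tol = rel_tol, abs_tol = abs_tol, h_max = h_max),
            class = "model_params")
}

#' Wall spring forces on vertices
#'
#' Each wall is a linear spring of stiffness `k`: a wall of realized length
#' \eqn{l} and resting length \eqn{L^0} pulls its two endpoint vertices
#' together with force \eqn{k (l - L^0)} when stretched (and pushes them
#' apart when compressed). Forces obey Newton's third law pairwise, so they
#' sum to zero over the tissue.
#'
#' @param t A tissue.
#' @param k Spring stiffness.
#' @return An n-vertex x 2 matrix of force vectors.
#' @export
wall_forces <- function(t, k) {
  f <- matrix(0, n_vertices(t), 2L)
  fw <- wall_force_pairs(t$pos, t$walls$v1, t$walls$v2, t$walls$rest_length, k)
  acc <- rowsum(rbind(fw$f1, fw$f2), group = c(t$walls$v1, t$walls$v2))
  f[as.integer(rownames(acc)), ] <- acc
  f
}

# per-wall endpoint forces; f1 acts on v1, f2 = -f1 on v2
wall_force_pairs <- function(pos, v1, v2, L0, k) {
  dx <- pos[v2, 1L] - pos[v1, 1L]
  dy <- pos[v2, 2L] - pos[v1, 2L]
  len <- sqrt(dx * dx + dy * dy)
  if (any(len < 1e-12)) stop("coincident connected vertices: zero wall length", call. = FALSE)
  fmag <- k * (len - L0) / len
  list(f1 = cbind(fmag * dx, fmag * dy), f2 = cbind(-fmag * dx, -fmag * dy), len = len)
}

#' Radial turgor/growth force
#'
#' Turgor pressure and internal growth of the meristem are represented by
#' an outward radial body force on every vertex. In the default
#' `"linear"` mode the force is `k_r` times the position vector (uniform
#' isotropic dilation); in `"constant"` mode it has magnitude `k_r` along
#' the outward unit vector. A vertex at the origin feels no force.
#'
#' @param t A tissue.
#' @param k_r Radial force constant.
#' @param mode `"linear"` or `"constant"`.
#' @return An n-vertex x 2 matrix of force vectors.
#' @export
radial_forces <- function(t, k_r, mode = c("linear", "constant")) {
  mode <- match.arg(mode)
  r <- sqrt(t$pos[, 1L]^2 + t$pos[, 2L]^2)
  mag <- if (mode == "constant") ifelse(r > 0, k_r / r, 0) else k_r
  cbind(mag * t$pos[, 1L], mag * t$pos[, 2L])
}

#' Rest-length growth rates
#'
#' Cell walls grow under tension: the resting length of each wall increases
#' at rate \eqn{k_g \,\mathrm{ramp}(l - L^0)} where the ramp function
#' clips at zero, so compressed walls keep their resting length (growth is
#' irreversible).
#'
#' @param t A tissue.
#' @param k_g Growth rate constant.
#' @return Numeric vector of \eqn{dL^0/dt}, one per wall.
#' @export
rest_length_rates <- function(t, k_g) {
  dx <- t$pos[t$walls$v2, 1L] - t$pos[t$walls$v1, 1L]
  dy <- t$pos[t$walls$v2, 2L] - t$pos[t$walls$v1, 2L]
  len <- sqrt(dx * dx + dy * dy)
  k_g * pmax(0, len - t$walls$rest_length)
}

#' Cell strain direction by axial circular statistics
#'
#' The principal strain axis of a cell is estimated from its walls by the
#' standard axial (angle-doubled) circular mean,
#' \deqn{\theta = \tfrac12 \,\mathrm{atan2}\!\left(\sum_w s_w \sin 2\phi_w,\;
#'   \sum_w s_w \cos 2\phi_w\right),}
#' where \eqn{\phi_w} is the wall's axial direction and \eqn{s_w} its
#' strain magnitude (relative extension, clipped at zero unless
#' `signed = TRUE`). Doubling the angles identifies \eqn{\phi} with
#' \eqn{\phi + \pi}, as required for undirected wall axes.
#'
#' @param t A tissue.
#' @param cell Cell index.
#' @param signed Use signed strain instead of the zero-clipped default.
#' @return The strain axis angle in \eqn{[0, \pi)}, or `NA_real_` when all
#'   wall strains vanish (isotropic signal; callers fall back to a random
#'   direction).
#' @export
strain_direction <- function(t, cell, signed = FALSE) {
  ws <- t$cells[[cell]]$ws
  v1 <- t$walls$v1[ws]; v2 <- t$walls$v2[ws]
  dx <- t$pos[v2, 1L] - t$pos[v1, 1L]
  dy <- t$pos[v2, 2L] - t$pos[v1, 2L]
  len <- sqrt(dx * dx + dy * dy)
  L0 <- t$walls$rest_length[ws]
  s <- (len - L0) / L0
  if (!signed) s <- pmax(0, s)
  if (all(abs(s) < 1e-12)) return(NA_real_)
  phi <- atan2(dy, dx)
  (0.5 * atan2(sum(s * sin(2 * phi)), sum(s * cos(2 * phi)))) %% pi
}

#' Spring potential energy of a tissue
#'
#' \eqn{E = \tfrac{k}{2} \sum_w (l_w - L^0_w)^2}. With the radial force off
#' and growth frozen the overdamped dynamics are a gradient flow of this
#' potential, so it is non-increasing along trajectories.
#'
#' @param t A tissue.
#' @param k Spring stiffness.
#' @return Scalar energy.
#' @export
spring_energy <- function(t, k) {
  dx <- t$pos[t$walls$v2, 1L] - t$pos[t$walls$v1, 1L]
  dy <- t$pos[t$walls$v2, 2L] - t$pos[t$walls$v1, 2L]
  len <- sqrt(dx * dx + dy * dy)
  0.5 * k * sum((len - t$walls$rest_length)^2)
}

# ---- flat state <-> tissue -------------------------------------------------

pack_state <- function(t) {
  c(as.vector(t$pos), t$walls$rest_length)
}

unpack_state <- function(t, y) {
  nv <- n_vertices(t)
  t$pos[] <- y[seq_len(2L * nv)]
  t$walls$rest_length <- y[(2L * nv + 1L):length(y)]
  t
}

#' Right-hand side of the model ODE system
#'
#' Vertices live in a viscous medium: velocity equals force (drag
#' coefficient absorbed into the time unit), with wall spring forces plus
#' the radial growth force; resting lengths grow by the tension ramp. The
#' flat state vector holds all vertex coordinates followed by all wall
#' resting lengths.
#'
#' @param y Flat state vector (`2 * n_vertices` coordinates then
#'   `n_walls` resting lengths).
#' @param t A tissue providing the topology (its coordinates are ignored).
#' @param params A [model_params()] object.
#' @return `dy/dt` of the same length.
#' @export
ode_rhs <- function(y, t, params) {
  nv <- n_vertices(t)
  nw <- n_walls(t)
  pos <- matrix(y[seq_len(2L * nv)], nv, 2L)
  L0 <- y[(2L * nv + 1L):(2L * nv + nw)]
  v1 <- t$walls$v1; v2 <- t$walls$v2
  dx <- pos[v2, 1L] - pos[v1, 1L]
  dy_ <- pos[v2, 2L] - pos[v1, 2L]
  len <- sqrt(dx * dx + dy_ * dy_)
  fmag <- params$spring_k * (len - L0) / len
  acc <- rowsum(cbind(c(fmag * dx, -fmag * dx), c(fmag * dy_, -fmag * dy_)),
                group = c(v1, v2))
  f <- matrix(0, nv, 2L)
  f[as.integer(rownames(acc)), ] <- acc
  r <- sqrt(pos[, 1L]^2 + pos[, 2L]^2)
  rmag <- if (params$radial_mode == "constant") ifelse(r > 0, params$radial_k / r, 0) else params$radial_k
  f[, 1L] <- f[, 1L] + rmag * pos[, 1L]
  f[, 2L] <- f[, 2L] + rmag * pos[, 2L]
  dL0 <- params$growth_k * pmax(0, len - L0)
  out <- c(as.vector(f), dL0)
  if (any(!is.finite(out))) stop("non-finite force encountered in ODE right-hand side", call. = FALSE)
  out
}
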