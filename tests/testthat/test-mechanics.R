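test_that("wall forces follow Hooke's law and Newton's third law", {
  # two vertices joined by one wall at rest length: no force
  tt <- new_tissue(cbind(c(0, 1), c(0, 0)),
                   walls = list(v1 = 1L, v2 = 2L, rest_length = 1),
                   cells = list())
  f <- wall_forces(tt, k = 0.05)
  expect_equal(f, matrix(0, 2, 2))

  # stretched by delta: magnitude k*delta, directed inward
  tt$pos[2, 1] <- 1.3
  f <- wall_forces(tt, k = 0.05)
  expect_equal(f[1, ], c(0.05 * 0.3, 0), tolerance = 1e-12)
  expect_equal(f[2, ], c(-0.05 * 0.3, 0), tolerance = 1e-12)

  # compressed: pushes apart
  tt$pos[2, 1] <- 0.6
  f <- wall_forces(tt, k = 0.05)
  expect_true(f[1, 1] < 0 && f[2, 1] > 0)

  # hexagonal cell with all walls at rest: zero net force everywhere
  hexa <- make_founder(6)
  expect_equal(wall_forces(hexa, 0.05), matrix(0, 6, 2), tolerance = 1e-12)

  # forces sum to zero over any tissue (pairwise cancellation)
  set.seed(71)
  ros <- make_rosette()
  ros$pos <- ros$pos + matrix(rnorm(length(ros$pos), sd = 0.1), ncol = 2)
  expect_equal(colSums(wall_forces(ros, 0.05)), c(0, 0), tolerance = 1e-12)

  tt$pos[2, ] <- tt$pos[1, ]
  expect_error(wall_forces(tt, 0.05), "coincident")
})

test_that("radial force is outward with the configured magnitude profile", {
  tt <- new_tissue(cbind(c(1, 0, 0), c(0, 0, 2)),
                   walls = list(v1 = c(1L, 2L), v2 = c(2L, 3L), rest_length = c(1, 2)),
                   cells = list())
  f <- radial_forces(tt, k_r = 0.05)             # default: linear in r
  expect_equal(f[1, ], c(0.05, 0))
  expect_equal(f[2, ], c(0, 0))                  # origin: no force
  expect_equal(f[3, ], c(0, 0.1))                # magnitude k_r * r
  fc <- radial_forces(tt, k_r = 0.05, mode = "constant")
  expect_equal(fc[1, ], c(0.05, 0))
  expect_equal(fc[3, ], c(0, 0.05))              # unit-vector alternative

  # symmetric ring: net force on the center of mass vanishes
  th <- 2 * pi * (0:9) / 10
  ring <- new_tissue(cbind(cos(th), sin(th)),
                     walls = list(v1 = 1:10, v2 = c(2:10, 1), rest_length = rep(1, 10)),
                     cells = list())
  expect_equal(colSums(radial_forces(ring, 0.05)), c(0, 0), tolerance = 1e-12)
})

test_that("rest lengths grow under tension only (ramp clipping)", {
  tt <- new_tissue(cbind(c(0, 1, 3, 3.5), c(0, 0, 0, 0)),
                   walls = list(v1 = c(1L, 2L, 3L), v2 = c(2L, 3L, 4L),
                                rest_length = c(1, 1, 1.5)),
                   cells = list())
  r <- rest_length_rates(tt, k_g = 0.01)
  expect_equal(r[1], 0)            # at rest
  expect_equal(r[2], 0.01)         # stretched by 1
  expect_equal(r[3], 0)            # compressed: ramp clips to zero
})

test_that("strain direction follows axial circular statistics", {
  # cross of two walls: horizontal strained, vertical at rest
  mk <- function(strains, angles) {
    nv <- 2 * length(angles)
    pos <- do.call(rbind, lapply(angles, function(a) {
      rbind(c(0, 0), c(cos(a), sin(a)))
    }))
    pos <- pos + matrix(rep(seq_along(angles), each = 2) * 10, ncol = 2, nrow = nv)
    L0 <- 1 / (1 + strains)
    tt <- new_tissue(pos,
                     walls = list(v1 = seq(1, nv, by = 2), v2 = seq(2, nv, by = 2),
                                  rest_length = L0),
                     cells = list(list(vs = seq_len(nv), ws = seq_along(angles),
                                       dir = NA_real_)))
    tt
  }
  # only horizontal walls strained -> axis 0
  tt <- mk(strains = c(0.2, 0), angles = c(0, pi / 2))
  expect_equal(strain_direction(tt, 1), 0, tolerance = 1e-9)
  # only vertical walls strained -> axis pi/2
  tt <- mk(strains = c(0, 0.2), angles = c(0, pi / 2))
  expect_equal(strain_direction(tt, 1), pi / 2, tolerance = 1e-9)
  # walls at 0 and 90 degrees with strains 0.2 and 0.1:
  # 0.5*atan2(0.1*sin(pi) + 0.2*sin(0), 0.1*cos(pi) + 0.2*cos(0)) = 0
  tt <- mk(strains = c(0.2, 0.1), angles = c(0, pi / 2))
  expect_equal(strain_direction(tt, 1), 0, tolerance = 1e-9)
  # all walls at rest: isotropic signal
  tt <- mk(strains = c(0, 0), angles = c(0, pi / 2))
  expect_true(is.na(strain_direction(tt, 1)))
})

test_that("strain direction is rotation-equivariant and axial", {
  set.seed(81)
  base <- make_rosette()
  base$walls$rest_length <- base$walls$rest_length * runif(18, 0.7, 1.0)
  th0 <- strain_direction(base, 1)
  for (alpha in c(0.3, 1.1, 2.5)) {
    rot <- base
    Rm <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2)
    rot$pos <- base$pos %*% t(Rm)
    expect_equal((strain_direction(rot, 1) - th0) %% pi, alpha %% pi,
                 tolerance = 1e-9)
  }
  # flipping a wall's stored endpoint order changes nothing (axial symmetry)
  flip <- base
  flip$walls$v1[3] <- base$walls$v2[3]
  flip$walls$v2[3] <- base$walls$v1[3]
  expect_equal(strain_direction(flip, 1), th0, tolerance = 1e-12)
})

test_that("ODE right-hand side matches the potential gradient and fixed points", {
  f <- make_founder(6)
  p0 <- model_params(radial_k = 0, growth_k = 0)
  y <- merisim:::pack_state(f)
  expect_equal(ode_rhs(y, f, p0), rep(0, length(y)), tolerance = 1e-12)

  # single stretched wall: vertices approach while rest length grows
  tt <- new_tissue(cbind(c(0, 2), c(0, 0)),
                   walls = list(v1 = 1L, v2 = 2L, rest_length = 1),
                   cells = list())
  dy <- ode_rhs(merisim:::pack_state(tt), tt, model_params(radial_k = 0))
  expect_true(dy[1] > 0 && dy[2] < 0)   # x-coordinates converge
  expect_true(dy[5] > 0)                # rest length grows

  # numeric gradient oracle for the spring part
  set.seed(91)
  ros <- make_rosette()
  ros$pos <- ros$pos + matrix(rnorm(length(ros$pos), sd = 0.05), ncol = 2)
  y <- merisim:::pack_state(ros)
  nv <- nrow(ros$pos)
  dy <- ode_rhs(y, ros, model_params(radial_k = 0, growth_k = 0))
  en <- function(yy) spring_energy(merisim:::unpack_state(ros, yy), 0.05)
  h <- 1e-6
  for (i in sample(seq_len(2 * nv), 8)) {
    yp <- y; yp[i] <- yp[i] + h
    ym <- y; ym[i] <- ym[i] - h
    expect_equal(dy[i], -(en(yp) - en(ym)) / (2 * h), tolerance = 1e-5)
  }
})

test_that("spring energy is non-increasing in the no-growth overdamped limit", {
  set.seed(101)
  for (rep in 1:20) {
    ros <- make_rosette()
    ros$pos <- ros$pos + matrix(rnorm(length(ros$pos), sd = 0.15), ncol = 2)
    p <- model_params(radial_k = 0, growth_k = 0, division_enabled = FALSE,
                      removal_enabled = FALSE)
    e0 <- spring_energy(ros, p$spring_k)
    energies <- e0
    st <- ros
    for (kk in 1:5) {
      st <- simulate_tissue(st, p, t_end = 2)$final
      energies <- c(energies, spring_energy(st, p$spring_k))
    }
    expect_true(all(diff(energies) <= 1e-10))
  }
})

test_that("model parameter validation rejects bad values", {
  expect_error(model_params(spring_k = -1), "positive")
  expect_error(model_params(area_threshold = 0), "positive")
  expect_error(model_params(rel_tol = 2), "tolerances")
  p <- model_params(growth_k = 0, radial_k = 0)  # frozen growth is allowed
  expect_identical(p$growth_k, 0)
})
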