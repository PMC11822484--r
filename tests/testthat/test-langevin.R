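# overdamped Langevin engine: displacement terms, stepping, reproducibility

test_that("Box-Muller deviates are standard normal and uncorrelated", {
  set.seed(42)
  z <- box_muller(1e5)
  for (v in list(z$z1, z$z2)) {
    expect_lt(abs(mean(v)), 0.01)
    expect_lt(abs(var(v) - 1), 0.02)
  }
  expect_lt(abs(cor(z$z1, z$z2)), 0.01)
  # reproducible under the seed
  set.seed(42)
  expect_identical(box_muller(1e5), z)
})

test_that("Brownian displacement variance matches 2 k_B T dt / gamma", {
  gamma <- 4.16080853848e-9
  set.seed(7)
  d <- brownian_displacement(297, gamma, dt = 0.05, n = 1e5)
  v_expect <- 2 * 1.380649e-23 * 297 * 0.05 / gamma
  expect_lt(abs(var(d$dx) / v_expect - 1), 0.02)
  expect_lt(abs(var(d$dy) / v_expect - 1), 0.02)
  # variance linear in dt; zero step at dt = 0
  d2 <- brownian_displacement(297, gamma, dt = 0, n = 10)
  expect_true(all(d2$dx == 0))
  expect_error(brownian_displacement(297, gamma, dt = -1), "dt")
  expect_error(brownian_displacement(297, 0, dt = 0.05), "gamma")
})

test_that("thermophoretic drift is -D_T grad T dt", {
  p <- constant_dt_particle(1.08e-12)
  d <- thermophoretic_displacement(297, gx = 1e5, gy = 0, dt = 1, particle = p)
  expect_equal(d$dx, -1.08e-7)
  expect_equal(d$dy, 0)
  # flipping the gradient flips the displacement; zero gradient, zero drift
  d2 <- thermophoretic_displacement(297, gx = -1e5, gy = 0, dt = 1, particle = p)
  expect_equal(d2$dx, -d$dx)
  d0 <- thermophoretic_displacement(297, gx = 0, gy = 0, dt = 1, particle = p)
  expect_equal(c(d0$dx, d0$dy), c(0, 0))
})

test_that("thermophoretic force magnitude is gamma D_T |grad T|", {
  # gamma(297) * D_T(297) * 1e5 for the default particle
  f <- thermophoretic_force(297, gx = 1e5, gy = 0)
  expect_equal(f$F_N, 4.49367322156e-16, tolerance = 1e-9)
  expect_equal(f$Fx_N, f$F_N)
  # linear in |grad T|; zero at zero gradient
  f2 <- thermophoretic_force(297, gx = 2e5, gy = 0)
  expect_equal(f2$F_N, 2 * f$F_N)
  expect_equal(thermophoretic_force(297, 0, 0)$F_N, 0)
})

test_that("specular reflection mirrors overshoot back inside", {
  expect_equal(mstbds:::reflect_into(1.2e-6, -1e-6, 1e-6), 0.8e-6)
  expect_equal(mstbds:::reflect_into(-1.5e-6, -1e-6, 1e-6), -0.5e-6)
  expect_equal(mstbds:::reflect_into(0.3e-6, -1e-6, 1e-6), 0.3e-6)
  # multiple folds land inside
  x <- mstbds:::reflect_into(seq(-10e-6, 10e-6, by = 1e-7), -1e-6, 1e-6)
  expect_true(all(x >= -1e-6 & x <= 1e-6))
})

test_that("deterministic drift limit accumulates exactly", {
  # Brownian variance off, uniform gradient: n steps drift -D_T g n dt
  lin <- make_field_fixture("linear", amplitude = 1, scale = 10e-6,
                            half_extent = 30e-6, spacing = 1e-6)
  p <- constant_dt_particle(1e-12)
  tr <- simulate_particles(lin, p, n_particles = 5, duration = 10, dt = 0.1,
                           record_every = 1, seed = 3,
                           init_halfwidth = 1e-6, domain = 25e-6,
                           brownian = FALSE)
  g <- 1 / 10e-6
  drift <- -1e-12 * g * 10
  expect_equal(tr$x[nrow(tr$x), ] - tr$x[1, ], rep(drift, 5), tolerance = 1e-9)
  expect_equal(tr$y[nrow(tr$y), ], tr$y[1, ])
})

test_that("runs are seeded, conservative and bit-reproducible", {
  f <- small_gaussian_field()
  t1 <- simulate_particles(f, n_particles = 40, duration = 5, dt = 0.05,
                           record_every = 1, seed = 11, init_halfwidth = 20e-6,
                           domain = 25e-6)
  t2 <- simulate_particles(f, n_particles = 40, duration = 5, dt = 0.05,
                           record_every = 1, seed = 11, init_halfwidth = 20e-6,
                           domain = 25e-6)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  # different seed, different paths
  t3 <- simulate_particles(f, n_particles = 40, duration = 5, dt = 0.05,
                           record_every = 1, seed = 12, init_halfwidth = 20e-6,
                           domain = 25e-6)
  expect_false(identical(t1$x, t3$x))
  # all positions inside the domain at every frame; count conserved
  expect_true(all(abs(t1$x) <= 25e-6 + 1e-12))
  expect_true(all(is.finite(t1$x)) && all(is.finite(t1$y)))
  expect_equal(dim(t1$x), c(6, 40))
  # seed-matched Brownian control shares the initial frame
  tb <- simulate_particles(f, n_particles = 40, duration = 5, dt = 0.05,
                           record_every = 1, seed = 11, init_halfwidth = 20e-6,
                           domain = 25e-6, thermophoresis = FALSE)
  expect_identical(t1$x[1, ], tb$x[1, ])
})

test_that("zero-duration runs contain only the initial frame", {
  f <- small_gaussian_field()
  tr <- simulate_particles(f, n_particles = 10, duration = 0, seed = 1,
                           init_halfwidth = 20e-6, domain = 25e-6)
  expect_equal(nrow(tr$x), 1)
  expect_equal(tr$times, 0)
})

test_that("domains larger than the field are rejected", {
  f <- small_gaussian_field(half_extent = 20e-6)
  expect_error(simulate_particles(f, n_particles = 5, duration = 1,
                                  init_halfwidth = 25e-6, domain = 25e-6),
               "field")
  expect_error(simulate_particles(f, n_particles = 5, duration = 1,
                                  init_halfwidth = 30e-6, domain = 15e-6),
               "fit")
})

test_that("tidied trajectories are long tibbles in micrometres", {
  f <- small_gaussian_field()
  tr <- simulate_particles(f, n_particles = 3, duration = 2, dt = 0.1,
                           record_every = 1, seed = 5, init_halfwidth = 10e-6,
                           domain = 25e-6)
  d <- tidy(tr)
  expect_s3_class(d, "tbl_df")
  expect_equal(nrow(d), 3 * 3)
  expect_equal(d$x_um[d$particle_id == 2 & d$t_s == 0], tr$x[1, 2] * 1e6)
  # CSV round-trip preserves positions
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories_csv(tr, path)
  tr2 <- read_trajectories_csv(path)
  expect_equal(tr2$x, tr$x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tr2$times, tr$times)
})
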