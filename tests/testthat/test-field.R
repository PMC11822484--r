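# mid-plane field construction, sampling and exchange formats

test_that("flat and linear fixtures have the expected gradients", {
  flat <- make_field_fixture("flat", half_extent = 10e-6, spacing = 1e-6)
  expect_true(all(flat$gx == 0) && all(flat$gy == 0))
  lin <- make_field_fixture("linear", amplitude = 2, scale = 10e-6,
                            half_extent = 10e-6, spacing = 1e-6,
                            gradients = "numeric")
  s <- sample_field(lin, c(-3e-6, 0, 4.2e-6), c(1e-6, 0, -2e-6))
  expect_equal(s$gx_K_per_m, rep(2 / 10e-6, 3))
  expect_equal(s$gy_K_per_m, rep(0, 3))
})

test_that("1/r shell fixture gradient magnitude matches a/r^2", {
  a <- 5e-6; A <- 2
  sh <- make_field_fixture("shell", amplitude = A, scale = a,
                           half_extent = 20e-6, spacing = 0.5e-6)
  # nodal values outside the core: |grad T| = A a / r^2
  xs <- c(8e-6, 12.5e-6, 17e-6)
  s <- sample_field(sh, xs, rep(0, 3))
  expect_equal(abs(s$gx_K_per_m), A * a / xs^2, tolerance = 1e-9)
  expect_equal(s$T_K - sh$ambient, A * a / xs, tolerance = 1e-9)
})

test_that("bilinear sampling is exact at nodes and averages at midpoints", {
  f <- make_field_fixture("gaussian", amplitude = 3, scale = 5e-6,
                          half_extent = 10e-6, spacing = 1e-6)
  i <- 8; j <- 14
  s <- sample_field(f, f$x[i], f$y[j])
  expect_equal(s$T_K, f$T[i, j])
  expect_equal(s$gx_K_per_m, f$gx[i, j])
  # cell-centre value is the mean of the four corners
  sm <- sample_field(f, (f$x[i] + f$x[i + 1]) / 2, (f$y[j] + f$y[j + 1]) / 2)
  expect_equal(sm$T_K, mean(f$T[i:(i + 1), j:(j + 1)]))
  expect_error(sample_field(f, 11e-6, 0), "bounds")
})

test_that("mid-plane extraction revolves the radial profile", {
  qv <- volumetric_source(20.5e-3)
  sol <- solve_steady_temperature(q_v = qv, settings = coarse_settings())
  f <- midplane_field(sol, half_extent = 50e-6, spacing = 1e-6)
  # rotational symmetry: same radius, different directions
  s <- sample_field(f, c(20e-6, 0, -20e-6), c(0, 20e-6, 0))
  expect_lt(diff(range(s$T_K)) / (max(s$T_K) - f$ambient), 0.02)
  # field maximum matches the solver's axis value
  expect_equal(max(f$T) - f$ambient, sol$dT_max, tolerance = 0.03)
  # gradient peaks near the source edge and decays outward, order 1e5 K/m
  g <- sqrt(f$gx^2 + f$gy^2)
  pk <- which(g == max(g), arr.ind = TRUE)[1, ]
  r_peak <- sqrt(f$x[pk[1]]^2 + f$y[pk[2]]^2)
  expect_gt(max(g), 1e5); expect_lt(max(g), 1e6)
  expect_lt(abs(r_peak - 13.8e-6), 3e-6)
  expect_error(midplane_field(sol, half_extent = 400e-6), "beyond")
})

test_that("uniform solutions give zero mid-plane gradients", {
  sol <- solve_steady_temperature(q_v = 0, settings = coarse_settings())
  f <- midplane_field(sol, half_extent = 50e-6, spacing = 1e-6)
  expect_equal(max(abs(f$gx)), 0, tolerance = 1e-6)
  expect_equal(max(abs(f$gy)), 0, tolerance = 1e-6)
})

test_that("temperature maps import with unit conversion and validation", {
  f <- make_field_fixture("gaussian", amplitude = 2, scale = 4e-6,
                          half_extent = 10e-6, spacing = 1e-6,
                          ambient = 297.15, gradients = "numeric")
  d <- tidy(f)
  # long table in um / Celsius
  imp <- import_temperature_map(
    data.frame(x = d$x_um, y = d$y_um, T = d$T_K - 273.15),
    length_unit = "um", temp_unit = "C", ambient = 297.15)
  expect_equal(imp$T, f$T)
  expect_equal(imp$gx, f$gx, tolerance = 1e-9)
  # peak location and value of the generating closed form are preserved
  pk <- which(imp$T == max(imp$T), arr.ind = TRUE)
  expect_equal(c(imp$x[pk[1]], imp$y[pk[2]]), c(0, 0))
  expect_equal(max(imp$T) - imp$ambient, 2, tolerance = 1e-9)
  # constant maps have zero gradients
  flat <- import_temperature_map(
    data.frame(x = d$x_um, y = d$y_um, T = 297), length_unit = "um")
  expect_true(all(flat$gx == 0))
  # ragged grids are rejected
  expect_error(import_temperature_map(
    data.frame(x = c(0, 1, 0), y = c(0, 0, 1), T = 297)), "grid")
})

test_that("field exchange formats round-trip", {
  f <- make_field_fixture("gaussian", amplitude = 1.5, scale = 5e-6,
                          half_extent = 8e-6, spacing = 1e-6)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(f, csv)
  f2 <- read_field_csv(csv)
  expect_equal(f2$x, f$x); expect_equal(f2$T, f$T, tolerance = 1e-12)
  expect_equal(f2$ambient, f$ambient)
  rds <- withr::local_tempfile(fileext = ".rds")
  write_field_rds(f, rds)
  f3 <- read_field_rds(rds)
  expect_identical(f3$T, f$T)   # binary container is bit-stable
  expect_identical(f3$gx, f$gx)
})
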