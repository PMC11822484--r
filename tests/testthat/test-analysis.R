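# trajectory analysis: radial profiles, Soret inversion, forces, MSD

make_static_traj <- function(xy, times = c(0, 1, 2)) {
  n <- nrow(xy)
  structure(list(times = times,
                 x = matrix(rep(xy[, 1], each = length(times)),
                            length(times), n),
                 y = matrix(rep(xy[, 2], each = length(times)),
                            length(times), n),
                 config = list()),
            class = "mst_trajectories")
}

test_that("identical runs give unit ratio in every defined bin", {
  set.seed(1)
  xy <- cbind(runif(200, -40e-6, 40e-6), runif(200, -40e-6, 40e-6))
  tr <- make_static_traj(xy)
  prof <- radial_concentration(tr, tr, bins = 20, r_max = 60e-6,
                               window = c(0, 2))
  defined <- !is.na(prof$ratio)
  expect_true(any(defined))
  expect_true(all(prof$ratio[defined] == 1))
  expect_equal(attr(prof, "center_ratio"), 1)
})

test_that("bin ratios are plain count quotients and empty bins are NA", {
  # 8 thermophoretic vs 50 reference particles in the same annulus
  ring <- function(n, r) cbind(r * cos(seq_len(n)), r * sin(seq_len(n)))
  tr_tph <- make_static_traj(rbind(ring(8, 5e-6), ring(50, 45e-6)), times = 0)
  tr_ref <- make_static_traj(rbind(ring(50, 5e-6), ring(8, 45e-6)), times = 0)
  prof <- radial_concentration(tr_tph, tr_ref, bins = 5, r_max = 50e-6,
                               window = c(0, 0))
  expect_equal(prof$ratio[1], 8 / 50)
  expect_true(is.na(prof$ratio[2]))   # no reference counts there
  expect_equal(attr(prof, "center_ratio"), 0.16)
})

test_that("mismatched runs are rejected", {
  tr <- make_static_traj(cbind(0, 0))
  tr2 <- make_static_traj(cbind(c(0, 1e-6), c(0, 0)))
  expect_error(radial_concentration(tr, tr2), "particle count")
})

test_that("Soret inversion matches the depletion law", {
  expect_equal(signif(estimate_soret(0.141, 1.77), 2), 1.1)
  expect_equal(estimate_soret(0.141, 1.77), 1.10677705571, tolerance = 1e-9)
  expect_equal(estimate_soret(1, 5), 0)
  expect_equal(estimate_soret(exp(-2), 1), 2)
  expect_error(estimate_soret(0, 1), "positive")
  expect_error(estimate_soret(0.5, -1), "positive")
  expect_warning(st <- estimate_soret(1.2, 1), "thermophilic")
  expect_lt(st, 0)
})

test_that("mobility from Soret is linear and hits the reference value", {
  expect_equal(signif(estimate_dt_from_soret(1.1, 297), 3), 1.08e-12)
  expect_equal(estimate_dt_from_soret(0, 297), 0)
  expect_equal(estimate_dt_from_soret(2.2, 297),
               2 * estimate_dt_from_soret(1.1, 297))
})

test_that("equilibrium oracle evaluates exp(-S_T dT(r))", {
  flat <- make_field_fixture("flat", half_extent = 20e-6, spacing = 1e-6)
  eq <- equilibrium_profile(flat, 1.1, seq(0, 15e-6, by = 5e-6))
  expect_equal(eq$c_ratio, rep(1, 4))
  g <- make_field_fixture("gaussian", amplitude = 1.77, scale = 6e-6,
                          half_extent = 20e-6, spacing = 0.25e-6)
  eq2 <- equilibrium_profile(g, 1.1, c(0, 6e-6, 12e-6))
  # centre value exp(-1.1 * 1.77)
  expect_equal(eq2$c_ratio[1], 0.142701534675, tolerance = 1e-4)
  # nondecreasing in r for a radially nonincreasing hot spot
  expect_true(all(diff(eq2$c_ratio) >= 0))
})

test_that("force profile is zero on flat fields and linear in D_T", {
  flat <- make_field_fixture("flat", half_extent = 30e-6, spacing = 1e-6)
  fp <- force_profile(flat, n_particles = 500, seed = 2)
  expect_true(all(fp$mean_force_fN[!is.na(fp$mean_force_fN)] == 0))
  g <- small_gaussian_field()
  p1 <- particle_model()
  p2 <- particle_model(dt_table = dplyr::mutate(
    default_dt_table(), DT_m2_per_K_s = 2 * DT_m2_per_K_s))
  f1 <- force_profile(g, p1, n_particles = 800, half_width = 20e-6, seed = 5)
  f2 <- force_profile(g, p2, n_particles = 800, half_width = 20e-6, seed = 5)
  ok <- !is.na(f1$mean_force_fN) & f1$mean_force_fN > 0
  expect_equal(f2$mean_force_fN[ok], 2 * f1$mean_force_fN[ok])
  expect_equal(attr(f2, "peak_fN"), 2 * attr(f1, "peak_fN"))
})

test_that("MSD is zero for static particles and quadratic for pure drift", {
  xy <- cbind(seq(-5e-6, 5e-6, length.out = 10), rep(0, 10))
  static <- make_static_traj(xy, times = 0:5)
  m <- msd(static, lags = 1:3)
  expect_equal(m$msd_m2, rep(0, 3))
  # constant velocity v: MSD(t) = v^2 t^2
  v <- 2e-7
  times <- 0:10
  drift <- structure(list(
    times = times,
    x = outer(times * v, rep(1, 4)) + matrix(rep(c(0, 1e-6, 2e-6, 3e-6),
                                                 each = 11), 11, 4),
    y = matrix(0, 11, 4), config = list()), class = "mst_trajectories")
  m2 <- msd(drift, lags = c(1, 2, 4))
  expect_equal(m2$msd_m2, (v * c(1, 2, 4))^2)
  expect_error(msd(drift, lags = 0.5), "multiples")
})
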