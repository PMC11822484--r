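# shared small-scale fixtures; everything built in code at test time

# coarse but convergent solver settings for fast unit tests
coarse_settings <- function() {
  solver_settings(nr_source = 10, nr_near = 16, nr_far = 14,
                  nz_water = 4, nz_glass = 16)
}

# homogeneous configuration: glass given the water's (constant) conductivity,
# so the whole chamber is one uniform conductor
all_water_thermal <- function(k = 0.61) {
  thermal_model(k0 = k, k_slope = 0, T_ref = 298, k_glass = k,
                T_ambient = 297.15)
}

# particle with a constant D_T (two-row table), i.e. constant Soret number
constant_dt_particle <- function(DT = 1e-12, radius = 250e-9) {
  particle_model(radius = radius,
                 dt_table = tibble::tibble(T_K = c(250, 400),
                                           DT_m2_per_K_s = c(DT, DT)))
}

# small hot-spot field for equilibration-scale Langevin tests
small_gaussian_field <- function(amplitude = 1.5, sigma = 6e-6,
                                 half_extent = 30e-6) {
  make_field_fixture("gaussian", amplitude = amplitude, scale = sigma,
                     half_extent = half_extent, spacing = 0.5e-6)
}
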