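#' Dynamic viscosity of water
#'
#' Exponential (Andrade-type) approximation `mu(T) = A exp(B / T)` with
#' defaults fitted for liquid water: `A = 2.761e-6` Pa s, `B = 1713` K.
#' Strictly decreasing in temperature over the liquid range.
#'
#' @param T_K temperature \[K\]; vectorised.
#' @param prefactor pre-exponential factor \[Pa s\].
#' @param activation activation temperature \[K\].
#' @return dynamic viscosity \[Pa s\].
#' @examples
#' water_viscosity(297)  # ~8.8e-4 Pa s
#' @export
water_viscosity <- function(T_K, prefactor = 2.761e-6, activation = 1713) {
  if (any(T_K <= 0)) abort("`T_K` must be positive (absolute temperature).")
  prefactor * exp(activation / T_K)
}

#' Stokes drag friction coefficient for a sphere
#'
#' `gamma = 6 pi mu(T) a` for a sphere of radius `a` in water.
#'
#' @inheritParams water_viscosity
#' @param radius particle radius \[m\].
#' @return friction coefficient \[kg s^-1\].
#' @export
friction_coefficient <- function(T_K, radius = 250e-9) {
  if (any(radius <= 0)) abort("`radius` must be positive.")
  6 * pi * water_viscosity(T_K) * radius
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = k_B T / (6 pi mu(T) a)`.
#'
#' @inheritParams friction_coefficient
#' @return diffusion coefficient \[m^2 s^-1\].
#' @examples
#' einstein_diffusion(297, 250e-9)  # ~9.9e-13 m^2/s
#' @export
einstein_diffusion <- function(T_K, radius = 250e-9) {
  .kB * T_K / friction_coefficient(T_K, radius)
}

#' Default thermophoretic mobility table
#'
#' Temperature-dependent thermophoretic mobility `D_T(T)` for ~500 nm
#' polystyrene nanoparticles in water. Measured mobilities of aqueous
#' polystyrene colloids grow roughly linearly with temperature and vanish
#' near a common crossover at ~286 K; the default table is that linear
#' family, `D_T(T) = 0.1e-12 (T - 286.2) m^2 K^-1 s^-1`, anchored at
#' `D_T(297 K) = 1.08e-12 m^2 K^-1 s^-1`, tabulated over 290-320 K and
#' clamped outside. Substitute any published table via the `dt_table`
#' argument of [particle_model()] or [read_dt_table()].
#'
#' @return tibble with columns `T_K` and `DT_m2_per_K_s`.
#' @export
default_dt_table <- function() {
  tibble(
    T_K = c(290, 297, 310, 320),
    DT_m2_per_K_s = c(0.38e-12, 1.08e-12, 2.38e-12, 3.38e-12)
  )
}

#' Particle model: radius plus tabulated thermophoretic mobility
#'
#' @param radius particle radius \[m\] (default 250 nm, i.e. a 500 nm
#'   diameter polystyrene nanoparticle).
#' @param dt_table data frame with columns `T_K` (strictly increasing) and
#'   `DT_m2_per_K_s`; at least two rows.
#' @return an object of class `mst_particle`.
#' @export
particle_model <- function(radius = 250e-9, dt_table = default_dt_table()) {
  if (radius <= 0) abort("`radius` must be positive.")
  dt_table <- as_tibble(dt_table)
  if (!all(c("T_K", "DT_m2_per_K_s") %in% names(dt_table)))
    abort("`dt_table` needs columns `T_K` and `DT_m2_per_K_s`.")
  if (nrow(dt_table) < 2)
    abort("`dt_table` needs at least two rows for interpolation.")
  if (any(diff(dt_table$T_K) <= 0))
    abort("`dt_table$T_K` must be strictly increasing.")
  structure(list(radius = radius, dt_table = dt_table),
            class = "mst_particle")
}

#' @export
print.mst_particle <- function(x, ...) {
  cat(sprintf("<mst_particle> radius %.0f nm, D_T table with %d nodes over %g-%g K\n",
              x$radius * 1e9, nrow(x$dt_table),
              min(x$dt_table$T_K), max(x$dt_table$T_K)))
  invisible(x)
}

#' Interpolate the thermophoretic mobility at a temperature
#'
#' Piecewise-linear interpolation in the `D_T(T)` table, exact at table
#' nodes and clamped to the end values outside the tabulated range
#' (constant extrapolation avoids sign flips from short tables).
#'
#' @param T_K temperature \[K\]; vectorised.
#' @param particle an [particle_model()] object, or a bare table with the
#'   same columns.
#' @return thermophoretic mobility \[m^2 K^-1 s^-1\].
#' @export
interp_dt <- function(T_K, particle = particle_model()) {
  tab <- if (inherits(particle, "mst_particle")) particle$dt_table else as_tibble(particle)
  if (nrow(tab) < 2) abort("D_T table needs at least two rows.")
  approx(tab$T_K, tab$DT_m2_per_K_s, xout = T_K, rule = 2)$y
}

#' Soret coefficient from the particle model
#'
#' `S_T(T) = D_T(T) / D(T)` with `D` from the Stokes-Einstein relation.
#'
#' @inheritParams interp_dt
#' @return Soret coefficient \[K^-1\].
#' @examples
#' soret_coefficient(297)  # ~1.1 per K for the default particle
#' @export
soret_coefficient <- function(T_K, particle = particle_model()) {
  interp_dt(T_K, particle) / einstein_diffusion(T_K, particle$radius)
}

#' Read a thermophoretic-mobility table from delimited text
#'
#' Two columns `T_K, DT_m2_per_K_s`; lines starting with `#` are comments.
#'
#' @param path file path.
#' @return tibble suitable for [particle_model()].
#' @export
read_dt_table <- function(path) {
  tab <- read.csv(path, comment.char = "#")
  if (!all(c("T_K", "DT_m2_per_K_s") %in% names(tab)))
    abort(sprintf("'%s' must have columns T_K, DT_m2_per_K_s.", path))
  as_tibble(tab)
}
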