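#' Chamber geometry
#'
#' Layered sample chamber: a water film sandwiched between two identical
#' glass coverslips, heated by a cylindrical volumetric source spanning
#' the full water thickness on the axis.
#'
#' @param water_thickness water-layer thickness \[m\].
#' @param glass_thickness coverslip thickness \[m\] (each side).
#' @param source_diameter heated-cylinder diameter \[m\] (laser spot FWHM).
#' @param lateral_radius radial extent of the solved domain \[m\]. The
#'   default 300 um is large enough that the hot-spot temperature is
#'   insensitive (< 2 %) to doubling it.
#' @return object of class `mst_geometry`.
#' @export
chamber_geometry <- function(water_thickness = 8e-6,
                             glass_thickness = 150e-6,
                             source_diameter = 27.6e-6,
                             lateral_radius = 300e-6) {
  vals <- c(water_thickness, glass_thickness, source_diameter, lateral_radius)
  if (any(vals <= 0)) abort("all chamber lengths must be positive.")
  if (source_diameter / 2 >= lateral_radius)
    abort("`lateral_radius` must exceed the source radius.")
  structure(list(water_thickness = water_thickness,
                 glass_thickness = glass_thickness,
                 source_diameter = source_diameter,
                 lateral_radius = lateral_radius),
            class = "mst_geometry")
}

#' Thermal material model
#'
#' Water conductivity is linear in temperature,
#' `k_w(T) = k0 + k_slope (T - T_ref)`; glass conductivity is constant
#' (borosilicate default 1.14 W m^-1 K^-1). The outer chamber surfaces are
#' held at the ambient temperature.
#'
#' @param k0 water conductivity at `T_ref` \[W m^-1 K^-1\].
#' @param k_slope temperature slope of the water conductivity
#'   \[W m^-1 K^-2\].
#' @param T_ref reference temperature for the water model \[K\].
#' @param k_glass glass conductivity \[W m^-1 K^-1\].
#' @param T_ambient ambient (boundary) temperature \[K\]; default 24 C.
#' @return object of class `mst_thermal`.
#' @export
thermal_model <- function(k0 = 0.61, k_slope = 0.0012, T_ref = 298,
                          k_glass = 1.14, T_ambient = 297.15) {
  if (k0 <= 0 || k_glass <= 0) abort("conductivities must be positive.")
  if (T_ambient <= 0) abort("`T_ambient` must be positive.")
  structure(list(k0 = k0, k_slope = k_slope, T_ref = T_ref,
                 k_glass = k_glass, T_ambient = T_ambient),
            class = "mst_thermal")
}

#' Heat-solver discretisation settings
#'
#' Cell counts for the graded axisymmetric finite-volume mesh, and the
#' Picard (fixed-point) iteration used for the temperature-dependent
#' water conductivity.
#'
#' @param nr_source radial cells inside the source radius.
#' @param nr_near radial cells between the source edge and ~4 source radii
#'   (geometrically graded; finest at the source edge where the gradient
#'   peaks).
#' @param nr_far radial cells from there to the domain edge.
#' @param nz_water axial cells in the water half-layer.
#' @param nz_glass axial cells in the glass (geometrically graded; finest
#'   at the water/glass interface).
#' @param tol convergence tolerance on the max temperature update \[K\].
#' @param max_iter Picard iteration cap.
#' @return object of class `mst_solver_settings`.
#' @export
solver_settings <- function(nr_source = 18, nr_near = 30, nr_far = 24,
                            nz_water = 6, nz_glass = 30,
                            tol = 1e-6, max_iter = 100) {
  counts <- c(nr_source, nr_near, nr_far, nz_water, nz_glass)
  if (any(counts < 3)) abort("all mesh cell counts must be at least 3.")
  if (tol <= 0) abort("`tol` must be positive.")
  structure(list(nr_source = nr_source, nr_near = nr_near, nr_far = nr_far,
                 nz_water = nz_water, nz_glass = nz_glass,
                 tol = tol, max_iter = max_iter),
            class = "mst_solver_settings")
}

# faces of a geometrically graded segment: n cells from a to b with
# successive width ratio `grow` (grow = 1 gives a uniform segment)
seg_faces <- function(a, b, n, grow = 1) {
  if (abs(grow - 1) < 1e-12) return(seq(a, b, length.out = n + 1))
  w1 <- (b - a) * (grow - 1) / (grow^n - 1)
  a + c(0, cumsum(w1 * grow^(0:(n - 1))))
}

build_mesh <- function(geometry, settings) {
  a <- geometry$source_diameter / 2
  R <- geometry$lateral_radius
  hw2 <- geometry$water_thickness / 2
  hg <- geometry$glass_thickness
  r_mid <- min(4 * a, a + 0.6 * (R - a))
  r_faces <- c(
    seg_faces(0, a, settings$nr_source),
    seg_faces(a, r_mid, settings$nr_near, grow = 1.08)[-1],
    seg_faces(r_mid, R, settings$nr_far, grow = 1.15)[-1]
  )
  z_faces <- c(
    seg_faces(0, hw2, settings$nz_water),
    seg_faces(hw2, hw2 + hg, settings$nz_glass, grow = 1.15)[-1]
  )
  list(r_faces = r_faces, z_faces = z_faces,
       r = (head(r_faces, -1) + tail(r_faces, -1)) / 2,
       z = (head(z_faces, -1) + tail(z_faces, -1)) / 2)
}

#' Solve steady-state heat conduction in the chamber
#'
#' Finite-volume solve of `div(k(T) grad T) + Q = 0` in axisymmetric
#' (r, z) coordinates on the upper half of the chamber (the mid-plane
#' z = 0 is a symmetry plane). The source density `q_v` is applied inside
#' the cylinder `r < d/2`, `|z| < water_thickness/2`; the outer radial and
#' top glass surfaces are Dirichlet at ambient. The nonlinear water
#' conductivity is handled by Picard iteration on the assembled sparse
#' system.
#'
#' @param geometry [chamber_geometry()].
#' @param thermal [thermal_model()].
#' @param q_v volumetric source density \[W m^-3\], from
#'   [volumetric_source()].
#' @param settings [solver_settings()].
#' @return object of class `mst_heat` with the cell-centre temperature
#'   matrix `T` (radial x axial), mesh vectors, the hot-spot rise
#'   `dT_max`, Picard iteration diagnostics and a discrete energy-balance
#'   report (`energy$rel_err` is |boundary flux - source| / source).
#' @examples
#' \donttest{
#' sol <- solve_steady_temperature(q_v = volumetric_source(20.5e-3))
#' glance(sol)
#' }
#' @export
solve_steady_temperature <- function(geometry = chamber_geometry(),
                                     thermal = thermal_model(),
                                     q_v,
                                     settings = solver_settings()) {
  if (q_v < 0) abort("`q_v` must be non-negative.")
  mesh <- build_mesh(geometry, settings)
  rf <- mesh$r_faces; zf <- mesh$z_faces
  rc <- mesh$r; zc <- mesh$z
  nr <- length(rc); nz <- length(zc)
  dr <- diff(rf); dz <- diff(zf)
  hw2 <- geometry$water_thickness / 2
  a <- geometry$source_diameter / 2
  Tamb <- thermal$T_ambient

  is_water <- zc < hw2 - 1e-15           # per axial layer
  ring_area <- pi * (tail(rf, -1)^2 - head(rf, -1)^2)   # per radial cell
  vol <- outer(ring_area, dz)            # cell volumes [nr, nz]

  src <- outer(rc < a, is_water) * q_v   # W m^-3 per cell
  b_src <- as.vector(src * vol)

  idx <- function(i, j) i + (j - 1L) * nr

  kfun <- function(Tm) {
    kw <- thermal$k0 + thermal$k_slope * (Tm - thermal$T_ref)
    if (any(kw[, is_water] <= 0))
      abort("water conductivity became non-positive during the solve.")
    k <- matrix(thermal$k_glass, nr, nz)
    k[, is_water] <- kw[, is_water]
    k
  }

  Tm <- matrix(Tamb, nr, nz)
  converged <- FALSE
  max_update <- NA_real_
  Gb_out <- NULL; Gb_top <- NULL

  for (it in seq_len(settings$max_iter)) {
    k <- kfun(Tm)

    # radial internal faces (between i and i+1)
    i1 <- rep(1:(nr - 1), nz); j1 <- rep(1:nz, each = nr - 1)
    d1 <- rf[i1 + 1] - rc[i1]; d2 <- rc[i1 + 1] - rf[i1 + 1]
    kf <- (d1 + d2) / (d1 / k[cbind(i1, j1)] + d2 / k[cbind(i1 + 1, j1)])
    Gr <- kf * (2 * pi * rf[i1 + 1] * dz[j1]) / (d1 + d2)

    # axial internal faces (between j and j+1)
    i2 <- rep(1:nr, nz - 1); j2 <- rep(1:(nz - 1), each = nr)
    e1 <- zf[j2 + 1] - zc[j2]; e2 <- zc[j2 + 1] - zf[j2 + 1]
    kfz <- (e1 + e2) / (e1 / k[cbind(i2, j2)] + e2 / k[cbind(i2, j2 + 1)])
    Gz <- kfz * ring_area[i2] / (e1 + e2)

    # Dirichlet boundaries: outer radius and top glass surface
    jb <- 1:nz
    Gb_out <- k[cbind(rep(nr, nz), jb)] * (2 * pi * rf[nr + 1] * dz[jb]) /
      (rf[nr + 1] - rc[nr])
    ib <- 1:nr
    Gb_top <- k[cbind(ib, rep(nz, nr))] * ring_area[ib] /
      (zf[nz + 1] - zc[nz])

    p1 <- idx(i1, j1); q1 <- idx(i1 + 1, j1)
    p2 <- idx(i2, j2); q2 <- idx(i2, j2 + 1)
    n_cells <- nr * nz
    diag_terms <- numeric(n_cells)
    add_at <- function(v, at, x) { tv <- tapply(x, at, sum); v[as.integer(names(tv))] <- v[as.integer(names(tv))] + tv; v }
    diag_terms <- add_at(diag_terms, p1, Gr)
    diag_terms <- add_at(diag_terms, q1, Gr)
    diag_terms <- add_at(diag_terms, p2, Gz)
    diag_terms <- add_at(diag_terms, q2, Gz)
    bnd <- numeric(n_cells)
    bnd[idx(nr, jb)] <- bnd[idx(nr, jb)] + Gb_out
    bnd[idx(ib, nz)] <- bnd[idx(ib, nz)] + Gb_top
    diag_terms <- diag_terms + bnd

    A <- Matrix::sparseMatrix(
      i = c(seq_len(n_cells), p1, q1, p2, q2),
      j = c(seq_len(n_cells), q1, p1, q2, p2),
      x = c(diag_terms, -Gr, -Gr, -Gz, -Gz),
      dims = c(n_cells, n_cells)
    )
    rhs <- b_src + bnd * Tamb
    T_new <- matrix(as.vector(Matrix::solve(A, rhs)), nr, nz)

    max_update <- max(abs(T_new - Tm))
    Tm <- T_new
    if (max_update < settings$tol) { converged <- TRUE; break }
  }
  if (!converged)
    abort(sprintf(
      "heat solve did not converge in %d Picard iterations (last max update %.3g K).",
      settings$max_iter, max_update))

  flux_out <- sum(Gb_out * (Tm[nr, ] - Tamb)) + sum(Gb_top * (Tm[, nz] - Tamb))
  source_W <- q_v * pi * a^2 * hw2
  energy <- list(source_W = source_W, boundary_W = flux_out,
                 rel_err = if (source_W > 0) abs(flux_out - source_W) / source_W else 0)

  structure(list(r = rc, z = zc, r_faces = rf, z_faces = zf, T = Tm,
                 ambient = Tamb, dT_max = max(Tm) - Tamb, q_v = q_v,
                 geometry = geometry, thermal = thermal, settings = settings,
                 iterations = it, max_update = max_update, energy = energy),
            class = "mst_heat")
}

#' @export
print.mst_heat <- function(x, ...) {
  cat(sprintf(
    "<mst_heat> %d x %d cells, q_v = %.3g W/m^3, dT_max = %.4g K (%d Picard iterations, energy balance %.2e)\n",
    length(x$r), length(x$z), x$q_v, x$dT_max, x$iterations, x$energy$rel_err))
  invisible(x)
}

#' @rdname solve_steady_temperature
#' @param x an `mst_heat` solution.
#' @param ... unused.
#' @method glance mst_heat
#' @export
glance.mst_heat <- function(x, ...) {
  tibble(dT_max_K = x$dT_max, ambient_K = x$ambient, q_v_W_m3 = x$q_v,
         iterations = x$iterations, energy_rel_err = x$energy$rel_err,
         nr = length(x$r), nz = length(x$z))
}

#' @rdname solve_steady_temperature
#' @method tidy mst_heat
#' @export
tidy.mst_heat <- function(x, ...) {
  tibble(
    r_um = rep(x$r, times = length(x$z)) * 1e6,
    z_um = rep(x$z, each = length(x$r)) * 1e6,
    T_K = as.vector(x$T),
    dT_K = as.vector(x$T) - x$ambient
  )
}
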