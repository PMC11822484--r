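#' Standard normal deviates by the Box-Muller transform
#'
#' Draws `n` pairs of independent N(0, 1) deviates from the underlying
#' uniform stream via the Box-Muller transform
#' `z1 = sqrt(-2 log u1) cos(2 pi u2)`, `z2 = sqrt(-2 log u1) sin(2 pi u2)`.
#' The simulation contract is only that displacements are standard normal;
#' this generator is the default and is reproducible under `set.seed()`.
#'
#' @param n number of pairs.
#' @return list with numeric vectors `z1`, `z2`, each length `n`.
#' @export
box_muller <- function(n) {
  u1 <- runif(n)
  u2 <- runif(n)
  r <- sqrt(-2 * log(u1))
  list(z1 = r * cos(2 * pi * u2), z2 = r * sin(2 * pi * u2))
}

#' Brownian displacement over one time step
#'
#' Each component is N(0, 2 k_B T_room dt / gamma): the random-force
#' temperature is approximated by the room temperature, so the Brownian
#' step variance is position-independent.
#'
#' @param T_room room temperature \[K\].
#' @param gamma friction coefficient \[kg s^-1\].
#' @param dt time step \[s\].
#' @param n number of particles.
#' @param normals optional list `list(z1, z2)` of standard normal deviates
#'   (length `n` each); drawn by [box_muller()] when omitted.
#' @return list with displacement vectors `dx`, `dy` \[m\].
#' @export
brownian_displacement <- function(T_room, gamma, dt, n = 1, normals = NULL) {
  if (dt < 0 || gamma <= 0) abort("`dt` must be >= 0 and `gamma` > 0.")
  sigma <- sqrt(2 * .kB * T_room * dt / gamma)
  if (is.null(normals)) normals <- box_muller(n)
  list(dx = sigma * normals$z1, dy = sigma * normals$z2)
}

#' Thermophoretic drift displacement over one time step
#'
#' `-D_T(T) grad T dt`: antiparallel to the temperature gradient for a
#' positive (thermophobic) mobility.
#'
#' @param T_K local temperature \[K\]; vectorised.
#' @param gx,gy local temperature-gradient components \[K m^-1\].
#' @param dt time step \[s\].
#' @param particle an [particle_model()] object.
#' @return list with displacement vectors `dx`, `dy` \[m\].
#' @export
thermophoretic_displacement <- function(T_K, gx, gy, dt,
                                        particle = particle_model()) {
  if (dt < 0) abort("`dt` must be non-negative.")
  dT <- interp_dt(T_K, particle)
  list(dx = -dT * gx * dt, dy = -dT * gy * dt)
}

#' Thermophoretic force
#'
#' `F_tph = gamma(T) D_T(T) grad T` (the drag force balancing the
#' thermophoretic drift velocity); reported with components and magnitude.
#'
#' @inheritParams thermophoretic_displacement
#' @return tibble with columns `Fx_N`, `Fy_N`, `F_N` (magnitude).
#' @export
thermophoretic_force <- function(T_K, gx, gy, particle = particle_model()) {
  g <- friction_coefficient(T_K, particle$radius)
  dT <- interp_dt(T_K, particle)
  Fx <- g * dT * gx
  Fy <- g * dT * gy
  tibble(Fx_N = Fx, Fy_N = Fy, F_N = sqrt(Fx^2 + Fy^2))
}

# fold a coordinate into [lo, hi] by specular reflection
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  out <- x < lo | x > hi
  if (any(out)) {
    y <- (x[out] - lo) %% (2 * w)
    y <- ifelse(y > w, 2 * w - y, y)
    x[out] <- lo + y
  }
  x
}

#' Simulate seeded 2D overdamped Langevin trajectories
#'
#' Integrates `r_{i+1} = r_i - D_T(T_i) grad(T_i) dt + dr_B` for `n`
#' non-interacting particles over a static temperature field, with
#' Brownian steps of per-axis variance `2 k_B T_room dt / gamma(T_room)`
#' generated by Box-Muller, first-order (bilinear) field interpolation at
#' each particle position, and specular reflection at the domain walls.
#' Runs with the same seed are bit-identical; a Brownian-only control run
#' with the same seed sees the identical random-displacement sequence.
#'
#' @param field an [temperature_field()] covering the domain.
#' @param particle an [particle_model()] object.
#' @param n_particles number of particles (default 1000).
#' @param duration simulated time \[s\] (default 1200).
#' @param dt time step \[s\] (default 0.05; the RMS Brownian step is then
#'   ~0.4 um, far below the field length scale).
#' @param record_every recording interval \[s\] (default 1).
#' @param seed integer seed for the uniform stream.
#' @param init_halfwidth half-width of the square initialisation region
#'   \[m\] (default 50 um: particles start uniform in 100 x 100 um^2).
#' @param domain half-width of the square reflecting domain \[m\];
#'   defaults to `init_halfwidth` (a closed chamber the size of the
#'   initialisation region).
#' @param T_room room temperature for the Brownian term \[K\].
#' @param thermophoresis logical; `FALSE` gives the Brownian-only control.
#' @param brownian logical; `FALSE` disables the random force (the
#'   deterministic drift limit, used for verification).
#' @return object of class `mst_trajectories`: recorded times and
#'   position matrices (frames x particles), plus the run configuration.
#' @export
simulate_particles <- function(field, particle = particle_model(),
                               n_particles = 1000, duration = 1200,
                               dt = 0.05, record_every = 1, seed = 1,
                               init_halfwidth = 50e-6, domain = init_halfwidth,
                               T_room = 297, thermophoresis = TRUE,
                               brownian = TRUE) {
  if (dt <= 0 || record_every < dt || (duration > 0 && duration < record_every))
    if (duration > 0) abort("need 0 < dt <= record_every <= duration.")
  if (n_particles < 1) abort("`n_particles` must be at least 1.")
  if (init_halfwidth > domain) abort("`init_halfwidth` must fit inside `domain`.")
  if (domain > min(max(field$x), -min(field$x), max(field$y), -min(field$y)))
    abort("`domain` extends beyond the field grid; enlarge the field.")

  set.seed(seed)
  n_steps <- round(duration / dt)
  rec_stride <- max(1L, round(record_every / dt))
  n_frames <- if (n_steps == 0) 1L else floor(n_steps / rec_stride) + 1L
  times <- (seq_len(n_frames) - 1L) * rec_stride * dt

  x <- runif(n_particles, -init_halfwidth, init_halfwidth)
  y <- runif(n_particles, -init_halfwidth, init_halfwidth)
  X <- matrix(NA_real_, n_frames, n_particles)
  Y <- matrix(NA_real_, n_frames, n_particles)
  X[1, ] <- x; Y[1, ] <- y

  gamma_room <- friction_coefficient(T_room, particle$radius)
  sigma <- if (brownian) sqrt(2 * .kB * T_room * dt / gamma_room) else 0

  # dt stability check: worst-case drift per step vs one grid cell
  if (thermophoresis) {
    gmax <- max(sqrt(field$gx^2 + field$gy^2))
    dt_drift <- max(interp_dt(range(field$T), particle)) * gmax * dt
    cell <- field$x[2] - field$x[1]
    if (dt_drift > cell)
      warn(sprintf(
        "single-step thermophoretic drift (%.3g m) exceeds one grid cell; consider dt <= %.3g s.",
        dt_drift, dt * cell / dt_drift))
  }

  frame <- 1L
  if (n_steps > 0) {
    for (s in seq_len(n_steps)) {
      z <- box_muller(n_particles)
      if (thermophoresis) {
        f <- bilinear_sample(field, x, y)
        dT <- interp_dt(f$T, particle)
        x <- x - dT * f$gx * dt + sigma * z$z1
        y <- y - dT * f$gy * dt + sigma * z$z2
      } else {
        x <- x + sigma * z$z1
        y <- y + sigma * z$z2
      }
      x <- reflect_into(x, -domain, domain)
      y <- reflect_into(y, -domain, domain)
      if (s %% rec_stride == 0L) {
        frame <- frame + 1L
        X[frame, ] <- x
        Y[frame, ] <- y
      }
    }
  }

  structure(list(
    times = times, x = X, y = Y,
    config = list(n_particles = n_particles, duration = duration, dt = dt,
                  record_every = record_every, seed = seed,
                  init_halfwidth = init_halfwidth, domain = domain,
                  T_room = T_room, thermophoresis = thermophoresis,
                  brownian = brownian, radius = particle$radius)),
    class = "mst_trajectories")
}

#' @export
print.mst_trajectories <- function(x, ...) {
  cat(sprintf(
    "<mst_trajectories> %d particles, %d frames over %g s (dt = %g s, seed = %s, thermophoresis %s)\n",
    ncol(x$x), nrow(x$x), max(x$times), x$config$dt, x$config$seed,
    if (x$config$thermophoresis) "on" else "off"))
  invisible(x)
}

#' @rdname simulate_particles
#' @param x an `mst_trajectories` object.
#' @param ... unused.
#' @method tidy mst_trajectories
#' @export
tidy.mst_trajectories <- function(x, ...) {
  n <- ncol(x$x)
  tibble(
    particle_id = rep(seq_len(n), each = nrow(x$x)),
    t_s = rep(x$times, times = n),
    x_um = as.vector(x$x) * 1e6,
    y_um = as.vector(x$y) * 1e6
  )
}

#' @rdname simulate_particles
#' @method glance mst_trajectories
#' @export
glance.mst_trajectories <- function(x, ...) {
  tibble(n_particles = ncol(x$x), n_frames = nrow(x$x),
         duration_s = max(x$times), dt_s = x$config$dt,
         seed = x$config$seed, thermophoresis = x$config$thermophoresis)
}

#' Write / read trajectories as delimited text
#'
#' Columns `particle_id, t_s, x_um, y_um`; a `#` header records the run
#' configuration fingerprint.
#'
#' @param traj an `mst_trajectories` object.
#' @param path file path.
#' @export
write_trajectories_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- traj$config
  writeLines(c("# mstbds trajectories",
               sprintf("# config: %s", jsonlite::toJSON(cfg, auto_unbox = TRUE))),
             con)
  d <- tidy(traj)
  write.table(
    data.frame(d$particle_id, format(d$t_s, digits = 17),
               format(d$x_um, digits = 17), format(d$y_um, digits = 17)),
    con, sep = ",", row.names = FALSE, quote = FALSE,
    col.names = c("particle_id", "t_s", "x_um", "y_um"))
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  cfg_line <- grep("^# config:", hdr, value = TRUE)
  cfg <- if (length(cfg_line))
    jsonlite::fromJSON(sub("^# config: ", "", cfg_line[1])) else list()
  d <- read.csv(path, comment.char = "#")
  ids <- sort(unique(d$particle_id))
  times <- sort(unique(d$t_s))
  d <- d[order(d$particle_id, d$t_s), ]
  X <- matrix(d$x_um * 1e-6, length(times), length(ids))
  Y <- matrix(d$y_um * 1e-6, length(times), length(ids))
  structure(list(times = times, x = X, y = Y, config = cfg),
            class = "mst_trajectories")
}
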