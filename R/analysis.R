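#' Radial concentration profile relative to a Brownian-only control
#'
#' Accumulates per-bin particle occupancies over all recorded frames in a
#' time window for a thermophoretic run and its seed-matched Brownian-only
#' control, and reports the per-bin ratio `N_tph / N_ref` — the relative
#' concentration `c/c0` as a function of radial distance from the heat
#' source axis. Bins with zero reference counts have `ratio = NA` (never
#' silently 0). The "centre value" attached to the result is the ratio of
#' the innermost bin with nonzero reference counts (set
#' `pool_center = TRUE` to pool the innermost three such bins, which is
#' flagged in the output).
#'
#' @param traj_tph thermophoretic `mst_trajectories` run.
#' @param traj_ref Brownian-only control run (same timing, particle count
#'   and seed).
#' @param bins number of equal radial bins.
#' @param r_max outer radius of the binning \[m\] (default 100 um).
#' @param window length-2 time window \[s\] over which frames are pooled
#'   (default 600-1200 s, the equilibrated half of the default run).
#' @param pool_center pool the innermost 3 defined bins for the centre
#'   value.
#' @return a tibble of class `mst_radial_profile` with columns
#'   `bin_center_um`, `counts_tph`, `counts_ref`, `ratio`, and attributes
#'   `center_ratio`, `center_pooled`, `window`.
#' @export
radial_concentration <- function(traj_tph, traj_ref, bins = 100,
                                 r_max = 100e-6, window = c(600, 1200),
                                 pool_center = FALSE) {
  for (tr in list(traj_tph, traj_ref))
    if (!inherits(tr, "mst_trajectories"))
      abort("trajectories must be mst_trajectories objects.")
  if (ncol(traj_tph$x) != ncol(traj_ref$x))
    abort("the two runs must have the same particle count.")
  if (length(traj_tph$times) != length(traj_ref$times) ||
      max(abs(traj_tph$times - traj_ref$times)) > 1e-9)
    abort("the two runs must share recording times.")
  edges <- seq(0, r_max, length.out = bins + 1)
  keep <- traj_tph$times >= window[1] & traj_tph$times <= window[2]
  if (!any(keep)) abort("`window` contains no recorded frames.")
  count_frames <- function(tr) {
    r <- sqrt(tr$x[keep, , drop = FALSE]^2 + tr$y[keep, , drop = FALSE]^2)
    h <- findInterval(r, edges, rightmost.closed = TRUE)
    tabulate(h[h >= 1 & h <= bins], nbins = bins)
  }
  n_tph <- count_frames(traj_tph)
  n_ref <- count_frames(traj_ref)
  ratio <- ifelse(n_ref > 0, n_tph / n_ref, NA_real_)
  defined <- which(n_ref > 0)
  if (length(defined) == 0) abort("no radial bin has reference counts.")
  if (pool_center) {
    sel <- defined[seq_len(min(3, length(defined)))]
    center <- sum(n_tph[sel]) / sum(n_ref[sel])
  } else {
    center <- ratio[defined[1]]
  }
  out <- tibble(
    bin_center_um = (head(edges, -1) + tail(edges, -1)) / 2 * 1e6,
    counts_tph = n_tph,
    counts_ref = n_ref,
    ratio = ratio
  )
  structure(out,
            class = c("mst_radial_profile", class(out)),
            center_ratio = center,
            center_pooled = pool_center,
            window = window,
            n_frames = sum(keep))
}

#' @rdname radial_concentration
#' @param x an `mst_radial_profile`.
#' @param ... unused.
#' @method glance mst_radial_profile
#' @export
glance.mst_radial_profile <- function(x, ...) {
  tibble(center_ratio = attr(x, "center_ratio"),
         center_pooled = attr(x, "center_pooled"),
         window_start_s = attr(x, "window")[1],
         window_end_s = attr(x, "window")[2],
         n_frames = attr(x, "n_frames"))
}

#' Soret coefficient from the exponential depletion law
#'
#' At equilibrium over a small temperature rise the depletion obeys
#' `c/c0 = exp(-S_T (T - T0))`; inverting gives
#' `S_T = -log(c_ratio) / delta_T`.
#'
#' @param c_ratio central relative concentration `c/c0` (> 0).
#' @param delta_T spot temperature rise \[K\] (> 0).
#' @return Soret coefficient \[K^-1\]; negative (with a warning) for
#'   `c_ratio > 1`, the thermophilic accumulation regime.
#' @examples
#' estimate_soret(0.141, 1.77)  # ~1.1 per K
#' @export
estimate_soret <- function(c_ratio, delta_T) {
  if (any(c_ratio <= 0)) abort("`c_ratio` must be positive.")
  if (any(delta_T <= 0)) abort("`delta_T` must be positive.")
  if (any(c_ratio > 1))
    warn("c_ratio > 1: thermophilic (accumulation) regime, S_T < 0.")
  -log(c_ratio) / delta_T
}

#' Thermophoretic mobility from a Soret coefficient
#'
#' `D_T = S_T D(T)` with the Stokes-Einstein diffusion coefficient of the
#' particle.
#'
#' @param S_T Soret coefficient \[K^-1\].
#' @param T_K temperature \[K\].
#' @param particle an [particle_model()] object (only the radius is used).
#' @return thermophoretic mobility \[m^2 K^-1 s^-1\].
#' @export
estimate_dt_from_soret <- function(S_T, T_K = 297, particle = particle_model()) {
  S_T * einstein_diffusion(T_K, particle$radius)
}

#' Closed-form equilibrium depletion profile
#'
#' For a constant Soret coefficient the drift-diffusion steady state over
#' a static field is `c(r)/c0 = exp(-S_T (T(r) - T_ambient))`. Evaluated
#' on the field's radial mid-plane profile (sampled along +x, exact for
#' revolved fields); serves as the independent oracle for long-time
#' simulations.
#'
#' @param field an [temperature_field()] object.
#' @param S_T constant Soret coefficient \[K^-1\].
#' @param radii radial distances \[m\].
#' @return tibble with `r_um`, `T_K`, `c_ratio`.
#' @export
equilibrium_profile <- function(field, S_T, radii) {
  s <- bilinear_sample(field, radii, rep(0, length(radii)))
  tibble(r_um = radii * 1e6, T_K = s$T,
         c_ratio = exp(-S_T * (s$T - field$ambient)))
}

#' Radial profile of the mean absolute thermophoretic force
#'
#' Samples positions uniformly in a square region, evaluates the local
#' thermophoretic force magnitude `gamma(T) D_T(T) |grad T|`, and averages
#' within equal radial bins. Empty bins are reported as `NA`.
#'
#' @param field an [temperature_field()] object.
#' @param particle an [particle_model()] object.
#' @param n_particles number of sampled positions (default 3000).
#' @param half_width half-width of the square sampling region \[m\]
#'   (default 25 um: a 50 x 50 um^2 area).
#' @param bins number of radial bins.
#' @param r_max outer binning radius \[m\] (default 50 um).
#' @param seed integer seed for the position sampling.
#' @return a tibble of class `mst_force_profile` with `bin_center_um`,
#'   `n`, `mean_force_fN`; attribute `peak_fN` is the profile maximum.
#' @export
force_profile <- function(field, particle = particle_model(),
                          n_particles = 3000, half_width = 25e-6,
                          bins = 100, r_max = 50e-6, seed = 1) {
  if (half_width > min(max(field$x), -min(field$x), max(field$y), -min(field$y)))
    abort("sampling region extends beyond the field grid.")
  set.seed(seed)
  x <- runif(n_particles, -half_width, half_width)
  y <- runif(n_particles, -half_width, half_width)
  s <- bilinear_sample(field, x, y)
  Fmag <- friction_coefficient(s$T, particle$radius) *
    interp_dt(s$T, particle) * sqrt(s$gx^2 + s$gy^2)
  edges <- seq(0, r_max, length.out = bins + 1)
  h <- findInterval(sqrt(x^2 + y^2), edges, rightmost.closed = TRUE)
  ok <- h >= 1 & h <= bins
  n_bin <- tabulate(h[ok], nbins = bins)
  sum_bin <- as.vector(tapply(Fmag[ok], factor(h[ok], levels = seq_len(bins)), sum))
  mean_f <- ifelse(n_bin > 0, ifelse(is.na(sum_bin), 0, sum_bin) / n_bin, NA_real_)
  out <- tibble(
    bin_center_um = (head(edges, -1) + tail(edges, -1)) / 2 * 1e6,
    n = n_bin,
    mean_force_fN = mean_f * 1e15
  )
  structure(out,
            class = c("mst_force_profile", class(out)),
            peak_fN = max(mean_f, na.rm = TRUE) * 1e15)
}

#' @rdname force_profile
#' @param x an `mst_force_profile`.
#' @param ... unused.
#' @method glance mst_force_profile
#' @export
glance.mst_force_profile <- function(x, ...) {
  tibble(peak_fN = attr(x, "peak_fN"),
         peak_r_um = x$bin_center_um[which.max(x$mean_force_fN)],
         n_sampled = sum(x$n))
}

#' Ensemble- and time-averaged mean squared displacement
#'
#' For each lag the squared displacement is averaged over all particles
#' and all admissible start frames. For free 2D Brownian motion the MSD is
#' `4 D t`; the slope calibrates the Einstein relation.
#'
#' @param traj an `mst_trajectories` object.
#' @param lags lag times \[s\]; must be multiples of the recording
#'   interval within the recorded range.
#' @return tibble with `lag_s`, `msd_m2`, `msd_um2`.
#' @export
msd <- function(traj, lags) {
  dt_rec <- if (length(traj$times) > 1) traj$times[2] - traj$times[1] else
    abort("trajectories contain a single frame; no lags available.")
  n_frames <- nrow(traj$x)
  steps <- round(lags / dt_rec)
  if (any(abs(steps * dt_rec - lags) > 1e-9) || any(steps < 1) ||
      any(steps >= n_frames))
    abort("`lags` must be multiples of the recording interval within range.")
  vals <- vapply(steps, function(k) {
    i0 <- seq_len(n_frames - k)
    dx <- traj$x[i0 + k, , drop = FALSE] - traj$x[i0, , drop = FALSE]
    dy <- traj$y[i0 + k, , drop = FALSE] - traj$y[i0, , drop = FALSE]
    mean(dx^2 + dy^2)
  }, numeric(1))
  tibble(lag_s = lags, msd_m2 = vals, msd_um2 = vals * 1e12)
}
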