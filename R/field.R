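#' Construct a 2D mid-plane temperature field
#'
#' A regular Cartesian grid of temperatures with precomputed gradient
#' grids, the coupling object between the heat-conduction stage and the
#' particle simulator. Gradients default to second-order central
#' differences of `T` (one-sided at the edges), matching the convention of
#' differentiating the temperature map once and then sampling.
#'
#' @param x,y strictly increasing, uniformly spaced axis coordinates \[m\].
#' @param T temperature matrix \[K\], dim `c(length(x), length(y))`.
#' @param gx,gy optional gradient matrices \[K m^-1\]; computed from `T`
#'   when omitted.
#' @param ambient ambient temperature \[K\]; defaults to `min(T)`.
#' @return object of class `mst_field`.
#' @export
temperature_field <- function(x, y, T, gx = NULL, gy = NULL, ambient = min(T)) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) abort("axes need at least 2 nodes.")
  for (ax in list(x, y)) {
    d <- diff(ax)
    if (any(d <= 0)) abort("axes must be strictly increasing.")
    if (max(d) - min(d) > 1e-9 * max(d)) abort("axes must be uniformly spaced.")
  }
  T <- as.matrix(T)
  if (!all(dim(T) == c(length(x), length(y))))
    abort("dim(T) must be c(length(x), length(y)).")
  if (min(T) < ambient - 1e-6)
    warn("field contains temperatures below ambient; check inputs.")
  if (is.null(gx) || is.null(gy)) {
    g <- grid_gradient(x, y, T)
    gx <- g$gx; gy <- g$gy
  }
  if (!all(dim(gx) == dim(T)) || !all(dim(gy) == dim(T)))
    abort("gradient grids must have the same shape as T.")
  structure(list(x = x, y = y, T = T, gx = gx, gy = gy, ambient = ambient),
            class = "mst_field")
}

# central differences on a regular grid, one-sided at the edges
grid_gradient <- function(x, y, T) {
  nx <- length(x); ny <- length(y)
  dx <- x[2] - x[1]; dy <- y[2] - y[1]
  gx <- T; gx[2:(nx - 1), ] <- (T[3:nx, ] - T[1:(nx - 2), ]) / (2 * dx)
  gx[1, ] <- (T[2, ] - T[1, ]) / dx
  gx[nx, ] <- (T[nx, ] - T[nx - 1, ]) / dx
  gy <- T; gy[, 2:(ny - 1)] <- (T[, 3:ny] - T[, 1:(ny - 2)]) / (2 * dy)
  gy[, 1] <- (T[, 2] - T[, 1]) / dy
  gy[, ny] <- (T[, ny] - T[, ny - 1]) / dy
  list(gx = gx, gy = gy)
}

#' @export
print.mst_field <- function(x, ...) {
  cat(sprintf(
    "<mst_field> %d x %d grid over [%.1f, %.1f] x [%.1f, %.1f] um, dT_max = %.4g K\n",
    length(x$x), length(x$y), min(x$x) * 1e6, max(x$x) * 1e6,
    min(x$y) * 1e6, max(x$y) * 1e6, max(x$T) - x$ambient))
  invisible(x)
}

#' @rdname temperature_field
#' @param ... unused.
#' @method tidy mst_field
#' @export
tidy.mst_field <- function(x, ...) {
  tibble(
    x_um = rep(x$x, times = length(x$y)) * 1e6,
    y_um = rep(x$y, each = length(x$x)) * 1e6,
    T_K = as.vector(x$T),
    dT_K = as.vector(x$T) - x$ambient,
    gx_K_per_m = as.vector(x$gx),
    gy_K_per_m = as.vector(x$gy)
  )
}

#' Extract the mid-plane Cartesian temperature field from a heat solution
#'
#' Revolves the radial mid-plane profile of an axisymmetric solution onto
#' a square Cartesian grid centred on the source axis. The z = 0 value is
#' recovered from the first two cell layers by an even (symmetric)
#' quadratic extrapolation; the r = 0 value likewise. Gradients are then
#' computed on the Cartesian grid by central differences.
#'
#' @param solution an `mst_heat` object from [solve_steady_temperature()].
#' @param half_extent half-width of the square output grid \[m\].
#' @param spacing grid spacing \[m\].
#' @return an [temperature_field()] object.
#' @export
midplane_field <- function(solution, half_extent = 52e-6, spacing = 0.5e-6) {
  if (!inherits(solution, "mst_heat")) abort("`solution` must be an mst_heat object.")
  if (sqrt(2) * half_extent > max(solution$r_faces))
    abort("requested grid extends beyond the solved radius.")
  # even extrapolation in z to the symmetry plane
  z1 <- solution$z[1]; z2 <- solution$z[2]
  Tr <- solution$T[, 1] + (solution$T[, 1] - solution$T[, 2]) * z1^2 / (z2^2 - z1^2)
  # even extrapolation in r to the axis
  r1 <- solution$r[1]; r2 <- solution$r[2]
  T0 <- Tr[1] + (Tr[1] - Tr[2]) * r1^2 / (r2^2 - r1^2)
  r_nodes <- c(0, solution$r)
  T_nodes <- c(T0, Tr)
  ax <- seq(-half_extent, half_extent, by = spacing)
  rr <- sqrt(outer(ax^2, ax^2, "+"))
  Tm <- matrix(approx(r_nodes, T_nodes, xout = pmin(rr, max(r_nodes)))$y,
               length(ax), length(ax))
  temperature_field(ax, ax, Tm, ambient = solution$ambient)
}

#' Sample temperature and gradient at arbitrary positions
#'
#' Bilinear interpolation of `T` and of the precomputed gradient grids;
#' exact at grid nodes. Positions must lie inside the grid bounds.
#'
#' @param field an [temperature_field()] object.
#' @param x,y position coordinates \[m\]; vectorised.
#' @return tibble with columns `T_K`, `gx_K_per_m`, `gy_K_per_m`.
#' @export
sample_field <- function(field, x, y) {
  s <- bilinear_sample(field, x, y)
  tibble(T_K = s$T, gx_K_per_m = s$gx, gy_K_per_m = s$gy)
}

# internal fast path returning a plain list of vectors
bilinear_sample <- function(field, x, y) {
  fx <- field$x; fy <- field$y
  nx <- length(fx); ny <- length(fy)
  if (any(x < fx[1] | x > fx[nx] | y < fy[1] | y > fy[ny]))
    abort("position outside the field grid bounds.")
  dx <- fx[2] - fx[1]; dy <- fy[2] - fy[1]
  i <- pmin(pmax(floor((x - fx[1]) / dx) + 1, 1), nx - 1)
  j <- pmin(pmax(floor((y - fy[1]) / dy) + 1, 1), ny - 1)
  tx <- (x - fx[i]) / dx
  ty <- (y - fy[j]) / dy
  p <- i + (j - 1) * nx
  blend <- function(M) {
    (1 - tx) * (1 - ty) * M[p] + tx * (1 - ty) * M[p + 1] +
      (1 - tx) * ty * M[p + nx] + tx * ty * M[p + nx + 1]
  }
  list(T = blend(field$T), gx = blend(field$gx), gy = blend(field$gy))
}

#' Analytic temperature-field fixtures
#'
#' Closed-form fields used in tests and benchmarks: `flat` (ambient
#' everywhere), `linear` (uniform gradient along x), `gaussian` (hot spot
#' `dT = A exp(-(x^2+y^2)/(2 s^2))`) and `shell` (`dT = A * s / max(r, s)`,
#' the 1/r far field of a compact source). Gradients are the exact
#' derivatives of the closed form (set `gradients = "numeric"` for central
#' differences instead).
#'
#' @param type one of `"flat"`, `"linear"`, `"gaussian"`, `"shell"`.
#' @param amplitude temperature amplitude A \[K\].
#' @param scale length scale s \[m\] (Gaussian sigma, shell radius, or the
#'   length over which the linear field rises by `amplitude`).
#' @param half_extent half-width of the square grid \[m\].
#' @param spacing grid spacing \[m\].
#' @param ambient ambient temperature \[K\].
#' @param gradients `"analytic"` or `"numeric"`.
#' @return an [temperature_field()] object.
#' @export
make_field_fixture <- function(type = c("flat", "linear", "gaussian", "shell"),
                               amplitude = 1, scale = 10e-6,
                               half_extent = 52e-6, spacing = 0.5e-6,
                               ambient = 297.15,
                               gradients = c("analytic", "numeric")) {
  type <- match.arg(type)
  gradients <- match.arg(gradients)
  # the linear ramp dips below the nominal ambient; its reference level is
  # the grid minimum
  ref_ambient <- if (type == "linear")
    ambient - abs(amplitude) * half_extent / scale else ambient
  ax <- seq(-half_extent, half_extent, by = spacing)
  X <- matrix(ax, length(ax), length(ax))
  Y <- t(X)
  R <- sqrt(X^2 + Y^2)
  zero <- matrix(0, length(ax), length(ax))
  f <- switch(type,
    flat = list(T = zero, gx = zero, gy = zero),
    linear = list(T = amplitude * X / scale,
                  gx = zero + amplitude / scale, gy = zero),
    gaussian = {
      dT <- amplitude * exp(-R^2 / (2 * scale^2))
      list(T = dT, gx = -X / scale^2 * dT, gy = -Y / scale^2 * dT)
    },
    shell = {
      inside <- R < scale
      dT <- amplitude * scale / pmax(R, scale)
      g <- -amplitude * scale / pmax(R, scale)^3
      g[inside] <- 0
      list(T = dT, gx = g * X, gy = g * Y)
    }
  )
  if (gradients == "numeric")
    temperature_field(ax, ax, ambient + f$T, ambient = ref_ambient)
  else
    temperature_field(ax, ax, ambient + f$T, gx = f$gx, gy = f$gy,
                      ambient = ref_ambient)
}

#' Import an externally measured 2D temperature map
#'
#' Builds an [temperature_field()] from a long table of gridded
#' temperatures, e.g. exported from a FEM tool or from fluorescence
#' thermometry. The table must cover a full rectangular grid.
#'
#' @param data data frame with columns `x`, `y`, `T` (and optionally `gx`,
#'   `gy`).
#' @param length_unit `"m"` or `"um"` for the axis columns.
#' @param temp_unit `"K"` or `"C"` for the temperature column.
#' @param ambient ambient temperature \[K\]; defaults to the map minimum.
#' @return an [temperature_field()] object.
#' @export
import_temperature_map <- function(data, length_unit = c("m", "um"),
                                   temp_unit = c("K", "C"), ambient = NULL) {
  length_unit <- match.arg(length_unit)
  temp_unit <- match.arg(temp_unit)
  data <- as_tibble(data)
  if (!all(c("x", "y", "T") %in% names(data)))
    abort("`data` needs columns x, y, T.")
  scl <- if (length_unit == "um") 1e-6 else 1
  off <- if (temp_unit == "C") 273.15 else 0
  x <- sort(unique(data$x)) * scl
  y <- sort(unique(data$y)) * scl
  if (nrow(data) != length(x) * length(y))
    abort("`data` is not a full rectangular grid.")
  ord <- order(data$y, data$x)
  d <- data[ord, ]
  expect_x <- rep(x, times = length(y))
  if (max(abs(d$x * scl - expect_x)) > 1e-12 * max(abs(x)))
    abort("`data` is ragged: x coordinates differ between rows of the grid.")
  Tm <- matrix(d$T + off, length(x), length(y))
  gx <- if ("gx" %in% names(data)) matrix(d$gx, length(x), length(y)) else NULL
  gy <- if ("gy" %in% names(data)) matrix(d$gy, length(x), length(y)) else NULL
  if (is.null(ambient)) ambient <- min(Tm)
  temperature_field(x, y, Tm, gx = gx, gy = gy, ambient = ambient)
}

#' Write / read a temperature field as delimited text
#'
#' CSV with `#`-prefixed header lines declaring units and the ambient
#' temperature, then columns `x,y,T,gx,gy` (axes in micrometres,
#' temperatures in kelvin). [read_field_csv()] inverts [write_field_csv()].
#'
#' @param field an [temperature_field()] object.
#' @param path file path.
#' @return `write_field_csv()` returns `path` invisibly; `read_field_csv()`
#'   returns the field.
#' @export
write_field_csv <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# mstbds temperature field",
               "# length_unit: um",
               "# temp_unit: K",
               sprintf("# ambient: %.17g", field$ambient),
               "x,y,T,gx,gy"), con)
  d <- tidy(field)
  write.table(
    data.frame(x = format(d$x_um, digits = 17),
               y = format(d$y_um, digits = 17),
               T = format(d$T_K, digits = 17),
               gx = format(d$gx_K_per_m, digits = 17),
               gy = format(d$gy_K_per_m, digits = 17)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  amb_line <- grep("^# ambient:", hdr, value = TRUE)
  ambient <- if (length(amb_line)) as.numeric(sub("^# ambient:", "", amb_line[1])) else NULL
  d <- read.csv(path, comment.char = "#")
  import_temperature_map(d, length_unit = "um", temp_unit = "K",
                         ambient = ambient)
}

#' @rdname write_field_csv
#' @details `write_field_rds()` / `read_field_rds()` provide a binary
#'   container holding the same named arrays; its round-trip is
#'   bit-stable.
#' @export
write_field_rds <- function(field, path) {
  saveRDS(unclass(field), path)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_rds <- function(path) {
  f <- readRDS(path)
  temperature_field(f$x, f$y, f$T, gx = f$gx, gy = f$gy, ambient = f$ambient)
}
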