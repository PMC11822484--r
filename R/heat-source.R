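#' Laser power absorbed by the water layer
#'
#' Beer-Lambert absorption over one pass through the water film:
#' `P_abs = P_in (1 - exp(-alpha L))`.
#'
#' @param power_in incident laser power \[W\].
#' @param alpha absorption coefficient of water at the laser wavelength
#'   \[m^-1\] (default 967, water at 1560 nm).
#' @param path optical path length \[m\] (the water thickness).
#' @return absorbed power \[W\], bounded by `[0, power_in]`.
#' @examples
#' absorbed_power(20.5e-3)  # ~1.58e-4 W
#' @export
absorbed_power <- function(power_in, alpha = 967, path = 8e-6) {
  if (any(power_in < 0) || any(alpha < 0) || any(path < 0))
    abort("`power_in`, `alpha` and `path` must be non-negative.")
  power_in * (1 - exp(-alpha * path))
}

#' Volumetric heat-source density of the laser-heated cylinder
#'
#' The absorbed power is deposited uniformly in a cylinder whose diameter
#' is the in-plane FWHM of the focused beam and whose height is the water
#' thickness: `Q_V = P_abs / (pi (d/2)^2 L)`.
#'
#' @inheritParams absorbed_power
#' @param diameter heated-cylinder diameter \[m\] (laser spot FWHM,
#'   default 27.6 um).
#' @return volumetric power density \[W m^-3\].
#' @examples
#' volumetric_source(20.5e-3)  # ~3.3e10 W/m^3
#' @export
volumetric_source <- function(power_in, alpha = 967, path = 8e-6,
                              diameter = 27.6e-6) {
  if (any(diameter <= 0) || any(path <= 0))
    abort("`diameter` and `path` must be positive.")
  absorbed_power(power_in, alpha, path) / (pi * (diameter / 2)^2 * path)
}
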