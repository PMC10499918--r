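#' Acoustic material properties for KRM computations
#'
#' Bundles the sound speeds and densities of the ambient water, the fish
#' body tissue and the swimbladder gas. The defaults are the standard
#' parameter set for temperate pelagic fish in Mediterranean shelf water:
#' \eqn{c_w = 1509}, \eqn{c_{fb} = 1570}, \eqn{c_{sb} = 345} m/s and
#' \eqn{\rho_w = 1026}, \eqn{\rho_{fb} = 1070}, \eqn{\rho_{sb} = 1.24}
#' kg/m^3.
#'
#' @param c_w,c_fb,c_sb Sound speed (m/s) in water, fish body, swimbladder.
#' @param rho_w,rho_fb,rho_sb Density (kg/m^3) of water, fish body,
#'   swimbladder.
#'
#' @return An object of class `material_set`: a named list with the six
#'   parameters.
#' @examples
#' mats <- material_set()
#' mats$c_w
#' @export
material_set <- function(c_w = 1509, c_fb = 1570, c_sb = 345,
                         rho_w = 1026, rho_fb = 1070, rho_sb = 1.24) {
  vals <- c(c_w = c_w, c_fb = c_fb, c_sb = c_sb,
            rho_w = rho_w, rho_fb = rho_fb, rho_sb = rho_sb)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all material parameters must be strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "material_set")
}

#' @export
print.material_set <- function(x, ...) {
  cat("<material_set>\n")
  cat(sprintf("  water:       c = %7.2f m/s  rho = %9.3f kg/m3\n", x$c_w, x$rho_w))
  cat(sprintf("  fish body:   c = %7.2f m/s  rho = %9.3f kg/m3\n", x$c_fb, x$rho_fb))
  cat(sprintf("  swimbladder: c = %7.2f m/s  rho = %9.3f kg/m3\n", x$c_sb, x$rho_sb))
  invisible(x)
}

#' Plane-wave reflection coefficient between two fluid media
#'
#' Normal-incidence pressure reflection coefficient
#' \eqn{R = (Z_2 - Z_1) / (Z_2 + Z_1)} with acoustic impedance
#' \eqn{Z = \rho c}. Antisymmetric under exchange of the two media.
#'
#' @param rho1,c1 Density (kg/m^3) and sound speed (m/s) of the incidence
#'   medium.
#' @param rho2,c2 Density and sound speed of the transmission medium.
#' @return Dimensionless reflection coefficient in (-1, 1).
#' @examples
#' # water -> fish body
#' reflection_coefficient(1026, 1509, 1070, 1570)
#' @export
reflection_coefficient <- function(rho1, c1, rho2, c2) {
  vals <- c(rho1, c1, rho2, c2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("densities and sound speeds must be strictly positive", call. = FALSE)
  }
  z1 <- rho1 * c1
  z2 <- rho2 * c2
  (z2 - z1) / (z2 + z1)
}

#' Acoustic wavenumber
#'
#' @param f Frequency in Hz.
#' @param c Sound speed in m/s.
#' @return Wavenumber \eqn{k = 2 \pi f / c} in rad/m.
#' @export
wavenumber <- function(f, c) {
  if (any(f <= 0) || any(c <= 0)) stop("f and c must be positive", call. = FALSE)
  2 * pi * f / c
}

#' Convert between backscattering cross-section and target strength
#'
#' `sigma_bs_to_ts()` computes \eqn{TS = 10 \log_{10}(\sigma_{bs})} in dB
#' re 1 m^2; `ts_to_sigma_bs()` inverts it. The spherical-spreading
#' convention \eqn{\sigma = 4\pi\,\sigma_{bs}} gives the equivalent form
#' \eqn{TS = 10 \log_{10}(\sigma / 4\pi)}.
#'
#' @param sigma_bs Backscattering cross-section in m^2.
#' @param ts Target strength in dB re 1 m^2.
#' @return A numeric vector.
#' @examples
#' ts_to_sigma_bs(sigma_bs_to_ts(2e-5))
#' @export
sigma_bs_to_ts <- function(sigma_bs) {
  if (any(sigma_bs < 0, na.rm = TRUE)) {
    stop("sigma_bs must be non-negative", call. = FALSE)
  }
  10 * log10(sigma_bs)
}

#' @rdname sigma_bs_to_ts
#' @export
ts_to_sigma_bs <- function(ts) 10^(ts / 10)
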