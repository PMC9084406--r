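# Mie theory for a homogeneous sphere: series coefficients, amplitude
# functions, the 4-element scattering matrix table and bulk optical
# properties of a monodisperse sphere suspension.

#' Describe a population of identical spherical scatterers
#'
#' Bundles the physical parameters of a monodisperse suspension of
#' homogeneous spheres: radius, number density, the (real) refractive
#' indices of sphere and host, and the vacuum wavelength. These are the
#' inputs from which scattering coefficient, anisotropy and the angular
#' scattering (Mueller) matrix are derived.
#'
#' @param radius_um Sphere radius in micrometres (> 0).
#' @param density_per_um3 Volumetric number density in spheres per cubic
#'   micrometre (>= 0).
#' @param n_sphere Real refractive index of the sphere material.
#' @param n_background Real refractive index of the host medium.
#' @param wavelength_nm Vacuum wavelength in nanometres.
#' @return An object of class \code{"scatterer_spec"}.
#' @examples
#' scatterer_spec(0.05, 19.11, 1.59, 1.33, 632.8)
#' @export
scatterer_spec <- function(radius_um, density_per_um3, n_sphere,
                           n_background, wavelength_nm) {
  stopifnot(is.numeric(radius_um), length(radius_um) == 1L, radius_um > 0,
            is.numeric(density_per_um3), density_per_um3 >= 0,
            is.numeric(n_sphere), n_sphere > 0,
            is.numeric(n_background), n_background > 0,
            is.numeric(wavelength_nm), wavelength_nm > 0)
  structure(list(radius_um = radius_um,
                 density_per_um3 = density_per_um3,
                 n_sphere = n_sphere,
                 n_background = n_background,
                 wavelength_nm = wavelength_nm),
            class = "scatterer_spec")
}

#' @export
print.scatterer_spec <- function(x, ...) {
  cat(sprintf(
    "Sphere population: r = %g um, rho = %g um^-3, n_sph = %g, n = %g, lambda = %g nm\n",
    x$radius_um, x$density_per_um3, x$n_sphere, x$n_background,
    x$wavelength_nm))
  mi <- mie_input(x)
  cat(sprintf("  size parameter x = %.6g, relative index m = %.6g\n",
              mi$size_parameter, mi$relative_index))
  invisible(x)
}

#' Size parameter and relative refractive index of a sphere spec
#'
#' @param spec A \code{\link{scatterer_spec}}.
#' @return List with \code{size_parameter} (x = 2 pi r n / lambda) and
#'   \code{relative_index} (m = n_sph / n).
#' @export
mie_input <- function(spec) {
  stopifnot(inherits(spec, "scatterer_spec"))
  lambda_um <- spec$wavelength_nm / 1000
  list(size_parameter = 2 * pi * spec$radius_um * spec$n_background / lambda_um,
       relative_index = spec$n_sphere / spec$n_background)
}

# Wiscombe truncation: enough terms for ~1e-8 convergence of the series.
mie_nmax <- function(x) as.integer(ceiling(x + 4 * x^(1/3) + 2))

#' Mie series coefficients a_n, b_n for a homogeneous sphere
#'
#' Computes the electric and magnetic partial-wave coefficients of the
#' Lorenz--Mie series by upward recurrence of the Riccati--Bessel
#' functions psi and chi, with the logarithmic derivative of psi at the
#' interior argument obtained by downward recurrence (started well above
#' the truncation order for stability). Only real relative indices are
#' supported: the spheres and host are taken non-absorbing, absorption
#' being a bulk property of the medium.
#'
#' @param size_parameter x = 2 pi r n_background / lambda (> 0).
#' @param relative_index m = n_sphere / n_background (> 0).
#' @param n_terms Number of series terms; default is the Wiscombe
#'   criterion \code{ceiling(x + 4 x^(1/3) + 2)}.
#' @return List with complex vectors \code{a} and \code{b} of length
#'   \code{n_terms}.
#' @examples
#' mie_coefficients(0.66, 1.1955)
#' @export
mie_coefficients <- function(size_parameter, relative_index,
                             n_terms = NULL) {
  x <- size_parameter
  m <- relative_index
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("size_parameter must be a positive finite number")
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop("relative_index must be a positive finite number")
  nmax <- if (is.null(n_terms)) mie_nmax(x) else as.integer(n_terms)
  stopifnot(nmax >= 1L)

  # D_n(mx) = psi_n'(mx)/psi_n(mx), downward recurrence from nmax + 15
  mx <- m * x
  nstart <- nmax + 15L
  D <- numeric(nstart + 1L)              # D[k+1] = D_k
  for (k in nstart:1L) {
    D[k] <- k / mx - 1 / (D[k + 1L] + k / mx)
  }
  if (!all(is.finite(D)))
    stop("overflow in logarithmic-derivative recurrence (x = ", x,
         ", m = ", m, ")")

  # Riccati-Bessel psi_n(x), chi_n(x) by upward recurrence
  psi <- numeric(nmax + 1L)              # psi[k+1] = psi_k, k = 0..nmax
  chi <- numeric(nmax + 1L)
  psi0 <- sin(x); psi[1L] <- sin(x) / x - cos(x)
  chi0 <- cos(x); chi[1L] <- cos(x) / x + sin(x)
  psim1 <- psi0; chim1 <- chi0
  if (nmax >= 2L) {
    for (k in 2L:nmax) {
      psi[k] <- (2 * k - 1) / x * psi[k - 1L] -
        (if (k == 2L) psi0 else psi[k - 2L])
      chi[k] <- (2 * k - 1) / x * chi[k - 1L] -
        (if (k == 2L) chi0 else chi[k - 2L])
    }
  }
  psi_nm1 <- c(psi0, psi[seq_len(nmax - 1L)])   # psi_{n-1}, n = 1..nmax
  chi_nm1 <- c(chi0, chi[seq_len(nmax - 1L)])
  psi_n <- psi[seq_len(nmax)]
  chi_n <- chi[seq_len(nmax)]
  xi_n <- complex(real = psi_n, imaginary = -chi_n)
  xi_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)

  n <- seq_len(nmax)
  Dn <- D[n + 1L]
  fa <- Dn / m + n / x
  fb <- Dn * m + n / x
  a <- (fa * psi_n - psi_nm1) / (fa * xi_n - xi_nm1)
  b <- (fb * psi_n - psi_nm1) / (fb * xi_n - xi_nm1)
  if (!all(is.finite(c(Re(a), Im(a), Re(b), Im(b)))))
    stop("non-finite Mie coefficients (x = ", x, ", m = ", m, ")")
  list(a = a, b = b)
}

#' Angular amplitude functions S1, S2
#'
#' Sums the Mie series with the angular functions pi_n and tau_n
#' (computed by the standard upward recurrence in cos(theta)) to give the
#' two complex scattering amplitudes at each requested angle.
#'
#' @param coeffs Output of \code{\link{mie_coefficients}}.
#' @param theta Scattering angles in radians, each in [0, pi].
#' @return List with complex vectors \code{S1} and \code{S2}, one entry
#'   per angle.
#' @export
mie_amplitudes <- function(coeffs, theta) {
  if (any(theta < 0 | theta > pi))
    stop("theta must lie in [0, pi]")
  a <- coeffs$a; b <- coeffs$b
  nmax <- length(a)
  n <- seq_len(nmax)
  fac <- (2 * n + 1) / (n * (n + 1))
  mu <- cos(theta)
  nt <- length(mu)
  S1 <- complex(length.out = nt)
  S2 <- complex(length.out = nt)
  # pi_n, tau_n recurrences, vectorized over angle
  pim1 <- rep(0, nt)   # pi_0
  pin <- rep(1, nt)    # pi_1
  for (k in n) {
    taun <- k * mu * pin - (k + 1) * pim1
    S1 <- S1 + fac[k] * (a[k] * pin + b[k] * taun)
    S2 <- S2 + fac[k] * (a[k] * taun + b[k] * pin)
    pinew <- ((2 * k + 1) * mu * pin - (k + 1) * pim1) / k
    pim1 <- pin
    pin <- pinew
  }
  list(S1 = S1, S2 = S2)
}

#' Tabulated single-sphere scattering matrix
#'
#' Builds the four independent elements s11, s12, s33, s34 of the
#' scattering Mueller matrix of a homogeneous sphere on an evenly spaced
#' theta grid covering [0, pi] (endpoints included). The identifications
#' are the standard ones:
#' \deqn{s11 = (|S1|^2 + |S2|^2)/2, \quad s12 = (|S2|^2 - |S1|^2)/2,}
#' \deqn{s33 = Re(S2 S1^*), \quad s34 = Im(S2 S1^*).}
#' All four elements are scaled by one common factor chosen so that
#' \code{2 pi * integral(s11 sin(theta)) = 1} on the stored grid
#' (trapezoidal rule), making s11 a proper phase function. Rejection
#' sampling depends only on ratios, so the normalisation is
#' observable-neutral; fixing it makes tables comparable across media.
#'
#' @param spec A \code{\link{scatterer_spec}}.
#' @param n_angles Number of grid points (default 1000).
#' @return Object of class \code{"smatrix_table"}: list with
#'   \code{theta}, \code{s11}, \code{s12}, \code{s33}, \code{s34},
#'   \code{n_angles}, the normalisation constant applied, and the spec.
#' @export
scattering_matrix_table <- function(spec, n_angles = 1000L) {
  stopifnot(inherits(spec, "scatterer_spec"), n_angles >= 2L)
  mi <- mie_input(spec)
  co <- mie_coefficients(mi$size_parameter, mi$relative_index)
  theta <- seq(0, pi, length.out = n_angles)
  amp <- mie_amplitudes(co, theta)
  S1 <- amp$S1; S2 <- amp$S2
  s11 <- (Mod(S1)^2 + Mod(S2)^2) / 2
  s12 <- (Mod(S2)^2 - Mod(S1)^2) / 2
  cross <- S2 * Conj(S1)
  s33 <- Re(cross)
  s34 <- Im(cross)
  integral <- 2 * pi * trapz_grid(theta, s11 * sin(theta))
  norm <- 1 / integral
  structure(list(theta = theta,
                 s11 = s11 * norm, s12 = s12 * norm,
                 s33 = s33 * norm, s34 = s34 * norm,
                 n_angles = as.integer(n_angles),
                 norm_constant = norm,
                 spec = spec),
            class = "smatrix_table")
}

#' @export
print.smatrix_table <- function(x, ...) {
  cat(sprintf("Scattering matrix table: %d angles on [0, pi]\n", x$n_angles))
  cat(sprintf("  s11(0) = %.4g, s11(pi) = %.4g, normalisation constant %.4g\n",
              x$s11[1], x$s11[x$n_angles], x$norm_constant))
  invisible(x)
}

# trapezoid on a (possibly non-uniform) grid
trapz_grid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Bulk optical properties of a sphere suspension
#'
#' Derives the scattering coefficient and anisotropy of a monodisperse
#' suspension from the Mie series: the scattering cross-section
#' \code{Csca = (2 pi / k^2) sum (2n+1)(|a_n|^2 + |b_n|^2)} with
#' \code{k = 2 pi n_background / lambda}, and the asymmetry parameter g
#' from the standard coefficient cross-terms. Units are centralised here:
#' radius in micrometres and density in spheres per cubic micrometre give
#' cross-sections in square micrometres and hence \code{mus} in inverse
#' micrometres, exported as mm^-1 (factor 1000). Absorption is a bulk
#' property supplied directly, not derived from the (real-index) spheres.
#'
#' @param spec A \code{\link{scatterer_spec}}.
#' @param mua_per_mm Bulk absorption coefficient in mm^-1 (default 0).
#' @return Object of class \code{"bulk_optics"}: list with
#'   \code{mua_per_mm}, \code{mus_per_mm}, \code{anisotropy},
#'   \code{musp_per_mm} (= mus (1 - g)), \code{n_background}, and the
#'   scattering cross-section \code{csca_um2}.
#' @examples
#' # superficial-layer medium of the two-layer slab benchmark
#' bulk_properties(scatterer_spec(0.05, 19.11, 1.59, 1.33, 632.8), 0.001)
#' @export
bulk_properties <- function(spec, mua_per_mm = 0) {
  stopifnot(inherits(spec, "scatterer_spec"),
            is.numeric(mua_per_mm), mua_per_mm >= 0)
  mi <- mie_input(spec)
  x <- mi$size_parameter
  co <- mie_coefficients(x, mi$relative_index)
  a <- co$a; b <- co$b
  n <- seq_along(a)
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  # asymmetry parameter
  ac <- c(a[-1], 0); bc <- c(b[-1], 0)
  gq <- (4 / x^2) * sum(n * (n + 2) / (n + 1) *
                          Re(a * Conj(ac) + b * Conj(bc)) +
                        (2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- if (qsca > 0) gq / qsca else 0
  csca_um2 <- qsca * pi * spec$radius_um^2
  mus_per_mm <- spec$density_per_um3 * csca_um2 * 1000
  structure(list(mua_per_mm = mua_per_mm,
                 mus_per_mm = mus_per_mm,
                 anisotropy = g,
                 musp_per_mm = mus_per_mm * (1 - g),
                 n_background = spec$n_background,
                 csca_um2 = csca_um2),
            class = "bulk_optics")
}

#' @export
print.bulk_optics <- function(x, ...) {
  cat(sprintf(
    "Bulk optics: mua = %g mm^-1, mus = %.4g mm^-1, g = %.4g, mus' = %.4g mm^-1, n = %g\n",
    x$mua_per_mm, x$mus_per_mm, x$anisotropy, x$musp_per_mm,
    x$n_background))
  invisible(x)
}

#' Write / read a scattering-matrix table
#'
#' Tables are cacheable: writing and re-reading reproduces the arrays
#' bit-for-bit, so precomputation can be done once per medium. The
#' container is R's portable binary serialisation.
#'
#' @param table An \code{"smatrix_table"}.
#' @param path File path.
#' @return \code{read_smatrix_table} returns the table;
#'   \code{write_smatrix_table} returns \code{path} invisibly.
#' @export
write_smatrix_table <- function(table, path) {
  stopifnot(inherits(table, "smatrix_table"))
  saveRDS(table, path, version = 2)
  invisible(path)
}

#' @rdname write_smatrix_table
#' @export
read_smatrix_table <- function(path) {
  tab <- readRDS(path)
  if (!inherits(tab, "smatrix_table"))
    stop("file does not contain a scattering-matrix table: ", path)
  tab
}
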