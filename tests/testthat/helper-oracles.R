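# Independent oracles used across the suite. These deliberately take
# different computational routes from the package: Mie coefficients via
# half-integer-order Bessel functions (base R besselJ/besselY) instead
# of the downward log-derivative recurrence, direction updates via
# axis-angle rotation matrices, Stokes updates via explicit 4x4 Mueller
# products, and a vectorised scalar (unpolarized) slab Monte Carlo.

# --- Mie via Riccati-Bessel functions from besselJ / besselY ----------

ricatti_psi <- function(n, x) sqrt(pi * x / 2) * besselJ(x, n + 0.5)
ricatti_chi <- function(n, x) -sqrt(pi * x / 2) * besselY(x, n + 0.5)

oracle_mie_coefficients <- function(x, m, nmax) {
  n <- seq_len(nmax)
  psi_x <- ricatti_psi(n, x);  psi_xm1 <- ricatti_psi(n - 1, x)
  chi_x <- ricatti_chi(n, x);  chi_xm1 <- ricatti_chi(n - 1, x)
  psi_mx <- ricatti_psi(n, m * x); psi_mxm1 <- ricatti_psi(n - 1, m * x)
  # derivatives from psi_n'(x) = psi_{n-1}(x) - n/x psi_n(x)
  dpsi_x <- psi_xm1 - n / x * psi_x
  dchi_x <- chi_xm1 - n / x * chi_x
  dpsi_mx <- psi_mxm1 - n / (m * x) * psi_mx
  xi_x <- complex(real = psi_x, imaginary = -chi_x)
  dxi_x <- complex(real = dpsi_x, imaginary = -dchi_x)
  a <- (m * psi_mx * dpsi_x - psi_x * dpsi_mx) /
       (m * psi_mx * dxi_x - xi_x * dpsi_mx)
  b <- (psi_mx * dpsi_x - m * psi_x * dpsi_mx) /
       (psi_mx * dxi_x - m * xi_x * dpsi_mx)
  list(a = a, b = b)
}

# Rayleigh-limit scattering cross-section (um^2) for radius r_um
rayleigh_csca <- function(x, m, r_um) {
  (8 / 3) * x^4 * Mod((m^2 - 1) / (m^2 + 2))^2 * pi * r_um^2
}

# --- Mueller / rotation oracles ---------------------------------------

mueller_rot <- function(psi) {
  c2 <- cos(2 * psi); s2 <- sin(2 * psi)
  matrix(c(1, 0, 0, 0,
           0, c2, -s2, 0,
           0, s2, c2, 0,
           0, 0, 0, 1), 4, 4)   # column-major: acts as rotate_stokes
}

mueller_M <- function(s11, s12, s33, s34) {
  matrix(c(s11, s12, 0, 0,
           s12, s11, 0, 0,
           0, 0, s33, -s34,
           0, 0, s34, s33), 4, 4)
}

# axis-angle rotation matrix (Rodrigues)
axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# meridian basis built independently by Gram-Schmidt: e_par is the unit
# vector in span(u, z) orthogonal to u with positive component along the
# "away from +z pole" sense used by the package; x-z fallback at +/-z.
oracle_meridian <- function(u) {
  z <- c(0, 0, 1)
  if (sum(u[1:2]^2) < 1e-12) {
    epar <- c(1, 0, 0)
  } else {
    v <- u * u[3] - z
    epar <- v / sqrt(sum(v^2))
  }
  list(e_par = epar, e_perp = pracma::cross(u, epar))
}

# full scattering update by explicit matrix products (independent of the
# C++ path): returns list(direction, stokes)
oracle_scatter <- function(u, S, theta, phi, s11, s12, s33, s34) {
  fr <- oracle_meridian(u)
  epar_s <- cos(phi) * fr$e_par + sin(phi) * fr$e_perp
  eperp_s <- -sin(phi) * fr$e_par + cos(phi) * fr$e_perp
  u2 <- axis_angle(eperp_s, theta) %*% u   # rotate u towards epar_s by theta
  u2 <- as.numeric(u2) / sqrt(sum(u2^2))
  epar_after <- pracma::cross(eperp_s, u2)
  fr2 <- oracle_meridian(u2)
  cg <- sum(epar_after * fr2$e_par)
  sg <- sum(pracma::cross(epar_after, fr2$e_par) * u2)
  gamma <- atan2(sg, cg)
  Sout <- mueller_rot(gamma) %*% mueller_M(s11, s12, s33, s34) %*%
    mueller_rot(phi) %*% S
  list(direction = u2, stokes = as.numeric(Sout / Sout[1]))
}

# --- phase-function quadrature ---------------------------------------

# expected bin probabilities of (theta_cell, phi) under the discretized
# polarized phase function, for chi-squared tests of the sampler
phase_bin_probs <- function(table, stokes, theta_breaks_idx, n_phi_bins) {
  ng <- table$n_angles
  edges <- c(0, (table$theta[-ng] + table$theta[-1]) / 2, pi)
  mu_hi <- cos(edges[-(ng + 1)]); mu_lo <- cos(edges[-1])
  wmu <- mu_hi - mu_lo                      # per-cell integral of sin
  phib <- seq(0, 2 * pi, length.out = n_phi_bins + 1)
  I <- stokes[1]; Q <- stokes[2]; U <- stokes[3]
  nb_t <- length(theta_breaks_idx) - 1
  probs <- matrix(0, nb_t, n_phi_bins)
  for (bt in seq_len(nb_t)) {
    cells <- (theta_breaks_idx[bt] + 1):theta_breaks_idx[bt + 1]
    for (bp in seq_len(n_phi_bins)) {
      p1 <- phib[bp]; p2 <- phib[bp + 1]
      int_c <- (sin(2 * p2) - sin(2 * p1)) / 2
      int_s <- (cos(2 * p1) - cos(2 * p2)) / 2
      probs[bt, bp] <- sum(
        wmu[cells] * (table$s11[cells] * I * (p2 - p1) +
                      table$s12[cells] * (Q * int_c + U * int_s)))
    }
  }
  probs / sum(probs)
}

# --- scalar (unpolarized) slab Monte Carlo ----------------------------

# Reference intensity-only MC in a laterally infinite slab of thickness
# L_mm with scattering mus and no absorption; the zenith angle is drawn
# from the continuous s11 sin(theta) marginal by inverse transform on a
# fine grid, azimuth uniform. Returns exit radius and face per photon.
scalar_slab_mc <- function(n, mus, L_mm, table, max_steps = 10000) {
  cdf <- cumsum(table$s11 * sin(table$theta))
  cdf <- cdf / cdf[length(cdf)]
  draw_theta <- function(k) {
    approx(c(0, cdf), c(0, table$theta), xout = runif(k),
           ties = "ordered")$y
  }
  pos <- matrix(0, n, 3)
  dir <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  alive <- rep(TRUE, n)
  exit_face <- rep(NA_character_, n)
  exit_r <- rep(NA_real_, n)
  for (step in seq_len(max_steps)) {
    idx <- which(alive)
    if (!length(idx)) break
    s <- -log(runif(length(idx))) / mus
    newpos <- pos[idx, , drop = FALSE] + s * dir[idx, , drop = FALSE]
    up <- newpos[, 3] < 0
    dn <- newpos[, 3] > L_mm
    out <- up | dn
    if (any(out)) {
      oi <- idx[out]
      # exact crossing point
      t_hit <- ifelse(up[out],
                      (0 - pos[oi, 3]) / dir[oi, 3],
                      (L_mm - pos[oi, 3]) / dir[oi, 3])
      hx <- pos[oi, 1] + t_hit * dir[oi, 1]
      hy <- pos[oi, 2] + t_hit * dir[oi, 2]
      exit_face[oi] <- ifelse(up[out], "reflect", "transmit")
      exit_r[oi] <- sqrt(hx^2 + hy^2)
      alive[oi] <- FALSE
    }
    ii <- idx[!out]
    if (!length(ii)) next
    pos[ii, ] <- newpos[!out, , drop = FALSE]
    th <- draw_theta(length(ii))
    ph <- runif(length(ii)) * 2 * pi
    for (j in seq_along(ii)) {
      k <- ii[j]
      fr <- oracle_meridian(dir[k, ])
      ax <- -sin(ph[j]) * fr$e_par + cos(ph[j]) * fr$e_perp
      dir[k, ] <- as.numeric(axis_angle(ax, th[j]) %*% dir[k, ])
    }
  }
  data.frame(face = exit_face, r = exit_r)
}

# --- misc helpers ------------------------------------------------------

random_unit <- function() {
  u <- c(rnorm(1), rnorm(1), rnorm(1))
  u / sqrt(sum(u^2))
}

random_polarized_stokes <- function() {
  p <- random_unit()   # point on the Poincare sphere: fully polarized
  c(1, p)
}

bench_specs <- list(
  superficial = scatterer_spec(0.05, 19.11, 1.59, 1.33, 632.8),
  bottom = scatterer_spec(0.3, 2.198e-2, 1.59, 1.33, 632.8),
  inclusion = scatterer_spec(1, 1.11e-3, 1.59, 1.33, 632.8),
  homogeneous = scatterer_spec(1.015, 1.152e-4, 1.59, 1.33, 632.8)
)
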