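# R surface of the transport primitives. The hot loop lives in C++
# (src/transport.cpp); these wrappers expose each operation for
# composition and testing.

#' Mueller rotation of a Stokes vector to a new reference plane
#'
#' Rotating the reference frame by \code{psi} about the propagation
#' direction (right-handed looking along the beam) transforms
#' \code{Q' = Q cos 2psi + U sin 2psi},
#' \code{U' = -Q sin 2psi + U cos 2psi}; I and V are untouched.
#'
#' @param stokes Numeric [I, Q, U, V].
#' @param psi Rotation angle (radians).
#' @return Rotated Stokes vector.
#' @examples
#' rotate_stokes(c(1, 1, 0, 0), pi / 4)  # -> c(1, 0, -1, 0)
#' @export
rotate_stokes <- function(stokes, psi) {
  stopifnot(length(stokes) == 4L)
  cpp_rotate_stokes(as.numeric(stokes), psi)
}

#' New direction cosines after scattering by (theta, phi)
#'
#' The azimuth is measured from the photon's meridian plane, rotating
#' towards the perpendicular axis of the right-handed meridian triad;
#' for a photon travelling along +z with phi = 0 the new direction tilts
#' towards +x.
#'
#' @param direction Unit 3-vector.
#' @param theta Zenith scattering angle in [0, pi].
#' @param phi Azimuth scattering angle in [0, 2 pi).
#' @return Unit 3-vector at angle \code{theta} from \code{direction}.
#' @export
update_direction <- function(direction, theta, phi) {
  stopifnot(length(direction) == 3L,
            abs(sum(direction^2) - 1) < 1e-6,
            theta >= 0, theta <= pi)
  cpp_update_direction(as.numeric(direction), theta, phi)
}

#' Full polarized scattering update
#'
#' Applies the meridian-plane composition R(gamma) M(theta) R(phi) to
#' the packet's Stokes vector and rotates the direction, where R(phi)
#' re-references the Stokes vector from the old meridian into the
#' scattering plane, M(theta) is the single-sphere scattering matrix at
#' the sampled zenith angle, and R(gamma) re-references into the new
#' meridian plane (gamma found by vector algebra on the transported
#' frame). The result is renormalised to I = 1, which preserves the
#' degree of polarization thanks to the sphere identity
#' s11^2 - s12^2 = s33^2 + s34^2.
#'
#' @param direction Unit 3-vector.
#' @param stokes Meridian-frame Stokes vector with I = 1.
#' @param theta,phi Sampled scattering angles.
#' @param table An \code{"smatrix_table"}; matrix elements are looked up
#'   at the nearest grid angle.
#' @return List with \code{direction} and \code{stokes}.
#' @export
scatter_update <- function(direction, stokes, theta, phi, table) {
  stopifnot(inherits(table, "smatrix_table"))
  i <- smatrix_index(table, theta)
  cpp_scatter_update(as.numeric(direction), as.numeric(stokes), theta, phi,
                     table$s11[i], table$s12[i], table$s33[i], table$s34[i])
}

#' Nearest table index for a zenith angle
#'
#' Lookup convention for evenly spaced tables on [0, pi]:
#' \code{round(theta (N - 1) / pi) + 1}.
#'
#' @param table An \code{"smatrix_table"}.
#' @param theta Angle(s) in [0, pi].
#' @return Integer index (1-based).
#' @export
smatrix_index <- function(table, theta) {
  as.integer(round(theta * (table$n_angles - 1L) / pi)) + 1L
}

#' Sample scattering angle pairs from the polarized phase function
#'
#' Draws (theta, phi) from the target
#' \code{P(theta, phi) = s11 I + s12 (Q cos 2phi + U sin 2phi)} weighted
#' by sin(theta), theta discretised to the table grid. The azimuth
#' integral of the s12 term vanishes, so theta has the exact marginal
#' \code{s11(theta) sin(theta)}: it is drawn by inverse transform from
#' the tabulated cell weights, and the azimuth-dependent factor is
#' accepted by rejection against the bound \code{s11 + |s12|} (at least
#' 50\% acceptance since \code{|s12| <= s11}). Uses R's RNG stream.
#'
#' @param stokes Meridian-frame Stokes vector, I = 1.
#' @param table An \code{"smatrix_table"}.
#' @param n Number of samples.
#' @return n x 2 matrix of (theta, phi); attribute \code{"trials"}
#'   carries the total number of candidate draws.
#' @export
sample_scattering_angles <- function(stokes, table, n = 1L) {
  stopifnot(inherits(table, "smatrix_table"), n >= 1)
  aux <- smatrix_sampling_aux(table)
  m <- cpp_sample_angles(as.numeric(stokes), table$s11, table$s12,
                         aux$cdf, aux$edge_mu, aux$envelope,
                         as.integer(n))
  colnames(m) <- c("theta", "phi")
  m
}

#' Sample a free path in scattering optical depth
#'
#' \code{tau = -log(xi)} with \code{xi ~ U(0,1)}: the exponential
#' free-path law in units of scattering optical depth, consumed across
#' voxels of differing mus by \code{\link{traverse}}.
#'
#' @param n Number of draws.
#' @return Positive optical depths.
#' @export
sample_path_optical_depth <- function(n = 1L) -log(runif(n))

#' March a ray through the voxel grid until an event
#'
#' Consumes the given scattering optical depth voxel-by-voxel (each
#' segment of length l in a voxel with scattering coefficient mus uses
#' mus * l) and attenuates the weight by exp(-mua * l) per segment.
#' Stops at a scattering site or where the ray leaves the domain.
#'
#' @param position,direction Start point (mm) and unit direction.
#' @param tau Scattering optical depth to consume.
#' @param domain A \code{\link{domain_model}}.
#' @return List: \code{event} (\code{"scatter"}, \code{"detect"},
#'   \code{"transmit"}, \code{"side"}, \code{"ambient"}),
#'   \code{position}, remaining \code{weight}, \code{absorbed} weight,
#'   geometric \code{path_length} (mm) and the \code{medium} index at a
#'   scattering event.
#' @export
traverse <- function(position, direction, tau, domain) {
  stopifnot(inherits(domain, "domain_model"), tau > 0)
  arr <- domain_arrays(domain)
  cpp_trace_first_event(as.numeric(position), as.numeric(direction), tau,
                        as.integer(domain$grid$labels), domain$grid$dims,
                        domain$grid$voxel_size_mm, arr$mua, arr$mus,
                        identical(domain$boundary_xy, "cyclic"))
}

#' Continuous absorption over a path segment
#'
#' @param weight Packet weight.
#' @param length_mm Segment length (mm).
#' @param mua_per_mm Absorption coefficient (mm^-1).
#' @return List with the surviving \code{weight} and the
#'   \code{deposited} weight.
#' @export
absorb <- function(weight, length_mm, mua_per_mm) {
  stopifnot(length_mm >= 0, mua_per_mm >= 0)
  w <- weight * exp(-mua_per_mm * length_mm)
  list(weight = w, deposited = weight - w)
}

#' Russian roulette for low-weight packets
#'
#' Below the weight threshold a packet survives with probability
#' \code{p_survive} and is boosted by \code{1 / p_survive}, otherwise it
#' is terminated (weight 0); expectation is preserved. Defaults follow
#' common MC practice (threshold 1e-4, survival 0.1).
#'
#' @param weight Current weight.
#' @param w_threshold Threshold below which roulette applies.
#' @param p_survive Survival probability.
#' @param n Number of independent trials (for testing the expectation).
#' @return Vector of post-roulette weights.
#' @export
roulette <- function(weight, w_threshold = 1e-4, p_survive = 0.1, n = 1L) {
  stopifnot(weight > 0, p_survive > 0, p_survive <= 1)
  cpp_roulette(weight, w_threshold, p_survive, as.integer(n))
}

#' Rotate an escaping packet's Stokes vector into the detector frame
#'
#' The detector's reference axis is the global +x axis projected on the
#' plane normal to the exit direction, so co-polarized detection of the
#' [1,1,0,0] sources reads positive Q. I and V are invariant under the
#' rotation.
#'
#' @param stokes Meridian-frame Stokes vector.
#' @param direction Exit unit direction (negative z-component for the
#'   z = 0 detector).
#' @return Detector-frame Stokes vector.
#' @export
detector_rotate <- function(stokes, direction) {
  stopifnot(length(stokes) == 4L, length(direction) == 3L)
  cpp_detector_rotate(as.numeric(stokes), as.numeric(direction))
}

#' Launch a photon packet
#'
#' Initialises weight 1, the configured incident Stokes vector
#' (renormalised to I = 1, referenced to the meridian plane of the
#' launch direction), and a position nudged 1e-9 mm into the domain.
#' Planar sources draw the position uniformly over their rectangle
#' using R's RNG.
#'
#' @param source Source entry of a parsed config.
#' @return List with \code{position_mm}, \code{direction},
#'   \code{weight}, \code{stokes}, \code{alive}.
#' @export
launch <- function(source) {
  pos <- source$position_mm
  if (identical(source$type, "planar"))
    pos <- pos + c(runif(2) * source$extent_mm, 0)
  dir <- source$direction / sqrt(sum(source$direction^2))
  s <- source$stokes / source$stokes[1]
  list(position_mm = pos + 1e-9 * dir, direction = dir, weight = 1,
       stokes = s, alive = TRUE)
}
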