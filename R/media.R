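# Voxelated domain representation and host-side media preprocessing:
# per-label media are resolved into transport-ready bulk optics and
# scattering-matrix tables before any photon is launched.

#' Construct a voxel grid
#'
#' The domain is a regular grid of cubic voxels. Voxel \code{(i,j,k)}
#' (0-based) spans the half-open box \code{[i h, (i+1) h) x ...} in mm,
#' so every continuous position belongs to exactly one voxel (floor
#' division). Label 0 is reserved for ambient space: a photon entering a
#' label-0 voxel escapes.
#'
#' @param dims Integer vector (Nx, Ny, Nz) of voxel counts.
#' @param voxel_size_mm Edge length of the cubic voxels (mm).
#' @param labels Integer array of media labels, dimension \code{dims};
#'   defaults to all 1.
#' @return Object of class \code{"voxel_grid"}.
#' @export
voxel_grid <- function(dims, voxel_size_mm, labels = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L),
            is.numeric(voxel_size_mm), voxel_size_mm > 0)
  if (is.null(labels)) {
    labels <- array(1L, dim = dims)
  } else {
    labels <- array(as.integer(labels), dim = dims)
  }
  if (any(labels < 0L)) stop("labels must be non-negative integers")
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm,
                 labels = labels),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid: %d x %d x %d voxels of %g mm (%g x %g x %g mm)\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size_mm,
              x$dims[1] * x$voxel_size_mm, x$dims[2] * x$voxel_size_mm,
              x$dims[3] * x$voxel_size_mm))
  cat("  labels present:", paste(sort(unique(as.vector(x$labels))),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Label array for a z-layered slab
#'
#' Assigns labels 1, 2, ... to slabs separated by the given interface
#' depths; assignment is by voxel-centre z-coordinate, and a voxel whose
#' centre falls exactly on an interface belongs to the deeper layer.
#'
#' @param dims Voxel counts (Nx, Ny, Nz).
#' @param voxel_size_mm Voxel edge (mm).
#' @param interfaces_mm Sorted interface depths in (0, Nz h).
#' @return Integer array of dimension \code{dims}.
#' @export
layered_labels <- function(dims, voxel_size_mm, interfaces_mm = numeric(0)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), voxel_size_mm > 0)
  depth <- dims[3] * voxel_size_mm
  if (length(interfaces_mm)) {
    if (is.unsorted(interfaces_mm, strictly = TRUE))
      stop("interfaces_mm must be strictly increasing")
    if (any(interfaces_mm <= 0 | interfaces_mm >= depth))
      stop("interfaces_mm must lie strictly inside the domain depth (0, ",
           depth, ")")
  }
  zc <- (seq_len(dims[3]) - 0.5) * voxel_size_mm
  # centre exactly on an interface -> deeper layer
  layer <- 1L + vapply(zc, function(z) sum(z >= interfaces_mm), integer(1))
  labels <- array(0L, dim = dims)
  for (k in seq_len(dims[3])) labels[, , k] <- layer[k]
  labels
}

#' Stamp a spherical inclusion into a label array
#'
#' Voxels whose centres lie within \code{radius_mm} of the centre are
#' assigned \code{label} (centre-in-sphere rasterisation).
#'
#' @param labels Integer label array.
#' @param voxel_size_mm Voxel edge (mm).
#' @param center_mm Sphere centre (mm).
#' @param radius_mm Sphere radius (mm).
#' @param label Label to assign.
#' @return Modified label array.
#' @export
sphere_labels <- function(labels, voxel_size_mm, center_mm, radius_mm,
                          label) {
  dims <- dim(labels)
  cx <- (seq_len(dims[1]) - 0.5) * voxel_size_mm
  cy <- (seq_len(dims[2]) - 0.5) * voxel_size_mm
  cz <- (seq_len(dims[3]) - 0.5) * voxel_size_mm
  dx2 <- (cx - center_mm[1])^2
  dy2 <- (cy - center_mm[2])^2
  dz2 <- (cz - center_mm[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius_mm^2
  labels[inside] <- as.integer(label)
  labels
}

#' Build a transport-ready medium record
#'
#' A medium is given either by a sphere population (from which the
#' scattering coefficient, anisotropy and the tabulated scattering
#' matrix are precomputed by Mie theory) or directly by bulk optics. A
#' directly specified medium with \code{mus > 0} must carry a scattering
#' matrix table; a non-scattering medium needs none.
#'
#' @param mua_per_mm Absorption coefficient (mm^-1).
#' @param n_background Refractive index of the medium.
#' @param spec Optional \code{\link{scatterer_spec}}.
#' @param mus_per_mm,anisotropy Direct bulk optics (used when
#'   \code{spec} is absent).
#' @param table Optional \code{"smatrix_table"} for a directly specified
#'   scattering medium.
#' @param n_angles Grid size for a sphere-derived table.
#' @return Object of class \code{"medium_record"} with elements
#'   \code{bulk}, \code{matrix} (possibly NULL) and \code{source_spec}.
#' @export
medium_record <- function(mua_per_mm, n_background = 1.33, spec = NULL,
                          mus_per_mm = NULL, anisotropy = NULL,
                          table = NULL, n_angles = 1000L) {
  stopifnot(is.numeric(mua_per_mm), mua_per_mm >= 0)
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "scatterer_spec"))
    bulk <- bulk_properties(spec, mua_per_mm)
    mat <- if (bulk$mus_per_mm > 0) scattering_matrix_table(spec, n_angles)
           else NULL
    return(structure(list(bulk = bulk, matrix = mat, source_spec = spec),
                     class = "medium_record"))
  }
  if (is.null(mus_per_mm)) stop("provide either a scatterer spec or bulk optics")
  stopifnot(mus_per_mm >= 0)
  if (mus_per_mm > 0 && is.null(table))
    stop("a scattering medium specified by bulk optics requires a ",
         "scattering matrix table (or use a sphere spec)")
  g <- if (is.null(anisotropy)) 0 else anisotropy
  bulk <- structure(list(mua_per_mm = mua_per_mm, mus_per_mm = mus_per_mm,
                         anisotropy = g,
                         musp_per_mm = mus_per_mm * (1 - g),
                         n_background = n_background,
                         csca_um2 = NA_real_),
                    class = "bulk_optics")
  structure(list(bulk = bulk, matrix = table, source_spec = NULL),
            class = "medium_record")
}

#' Assemble a validated domain model
#'
#' Combines a voxel grid, the per-label media and the boundary handling
#' into the object the transport loop consumes. Every label present in
#' the volume (other than ambient 0) must have a medium record, and every
#' scattering medium must carry a matrix table. Detection happens on the
#' z = 0 facet; the opposite facet is an escape facet; the four lateral
#' facets are either escape or cyclic.
#'
#' @param grid A \code{\link{voxel_grid}}.
#' @param media List of \code{\link{medium_record}}s; entry \code{m}
#'   serves label \code{m}.
#' @param boundary_xy \code{"escape"} or \code{"cyclic"}.
#' @return Object of class \code{"domain_model"}.
#' @export
domain_model <- function(grid, media, boundary_xy = c("escape", "cyclic")) {
  boundary_xy <- match.arg(boundary_xy)
  stopifnot(inherits(grid, "voxel_grid"))
  if (!length(media) || !all(vapply(media, inherits, logical(1),
                                    "medium_record")))
    stop("media must be a non-empty list of medium_record objects")
  present <- setdiff(sort(unique(as.vector(grid$labels))), 0L)
  if (length(present) && max(present) > length(media))
    stop("label ", max(present), " present in the volume but only ",
         length(media), " media defined")
  for (m in present) {
    rec <- media[[m]]
    if (rec$bulk$mus_per_mm > 0 && is.null(rec$matrix))
      stop("medium ", m, " scatters but has no scattering matrix table")
  }
  structure(list(grid = grid, media = media, boundary_xy = boundary_xy),
            class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  print(x$grid)
  for (m in seq_along(x$media)) {
    cat(sprintf("  medium %d: ", m)); print(x$media[[m]]$bulk)
  }
  cat("  lateral boundary:", x$boundary_xy, "\n")
  invisible(x)
}

# Sampling tables for the phase-function sampler: the theta grid is cut
# into nearest-index cells; edge_mu holds the cell-edge cosines and cdf
# the cumulative cell weights s11_i (cos a_i - cos b_i), i.e. the exact
# zenith marginal of the polarized phase function. The envelope bounds
# the azimuth factor: max(1 + |s12|/s11).
smatrix_sampling_aux <- function(table) {
  th <- table$theta
  ng <- table$n_angles
  edges <- c(0, (th[-ng] + th[-1]) / 2, pi)
  edge_mu <- cos(edges)
  w <- table$s11 * (edge_mu[-(ng + 1L)] - edge_mu[-1L])
  cdf <- cumsum(w) / sum(w)
  cdf[ng] <- 1
  list(cdf = cdf, edge_mu = edge_mu,
       envelope = 1 + max(abs(table$s12) / table$s11))
}

# transport-ready arrays for the C++ loop
domain_arrays <- function(domain, n_angles = NULL) {
  media <- domain$media
  nm <- length(media)
  ng <- NULL
  for (rec in media)
    if (!is.null(rec$matrix)) { ng <- rec$matrix$n_angles; break }
  if (is.null(ng)) ng <- if (is.null(n_angles)) 2L else n_angles
  s11 <- s12 <- s33 <- s34 <- matrix(0, ng, nm)
  cdfm <- matrix(seq_len(ng) / ng, ng, nm)
  envelope <- rep(1, nm)
  edge_mu <- cos(seq(0, pi, length.out = ng + 1L))
  for (m in seq_len(nm)) {
    tab <- media[[m]]$matrix
    if (!is.null(tab)) {
      if (tab$n_angles != ng)
        stop("all media must share the same theta-grid size (medium ", m,
             " has ", tab$n_angles, ", expected ", ng, ")")
      s11[, m] <- tab$s11; s12[, m] <- tab$s12
      s33[, m] <- tab$s33; s34[, m] <- tab$s34
      aux <- smatrix_sampling_aux(tab)
      cdfm[, m] <- aux$cdf
      edge_mu <- aux$edge_mu
      envelope[m] <- aux$envelope
    }
  }
  list(mua = vapply(media, function(r) r$bulk$mua_per_mm, numeric(1)),
       mus = vapply(media, function(r) r$bulk$mus_per_mm, numeric(1)),
       s11 = s11, s12 = s12, s33 = s33, s34 = s34,
       cdfm = cdfm, edge_mu = edge_mu, envelope = envelope)
}
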