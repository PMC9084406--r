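# Simulation configuration: schema validation, defaults, and assembly of
# the domain model from a config list or JSON file.

#' Parse and validate a simulation configuration
#'
#' Accepts a JSON file path or an R list with the same structure and
#' returns a validated configuration with defaults filled in. The schema:
#' \preformatted{
#' {
#'   "domain":  {"dims": [nx,ny,nz], "voxel_size_mm": h,
#'               "labels": <array, optional>,
#'               "shapes": [ {"type":"layers","interfaces_mm":[...]},
#'                           {"type":"sphere","center_mm":[...],
#'                            "radius_mm":r,"label":m} ] },
#'   "media":   [ {"mua": a, "n": n,
#'                 either "r_um","rho_per_um3","n_sphere"
#'                 or     "mus","g","matrix_file"} , ... ],
#'   "source":  {"type":"pencil"|"planar", "position_mm":[x,y,z],
#'               "direction":[ux,uy,uz], "stokes":[I,Q,U,V],
#'               "extent_mm":[wx,wy]  (planar only)},
#'   "boundary": {"xy": "escape"|"cyclic"},
#'   "detector": {"pixels":[px,py], "origin_mm":[x0,y0],
#'                "size_mm":[wx,wy]},
#'   "photons": N, "seed": s, "wavelength_nm": lambda,
#'   "n_angles": 1000
#' }
#' }
#' The incident Stokes vector must satisfy \code{I > 0} and
#' \code{Q^2 + U^2 + V^2 <= I^2}; the source direction is normalised.
#'
#' @param config Path to a JSON file, or a list.
#' @return A validated config list of class \code{"sim_config"}.
#' @export
parse_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")

  need <- function(key) {
    if (is.null(config[[key]]))
      stop("config is missing required entry \"", key, "\"")
    config[[key]]
  }
  dom <- need("domain")
  media <- need("media")
  src <- need("source")
  if (is.null(dom$dims) || length(dom$dims) != 3L)
    stop("domain$dims must be three voxel counts")
  if (is.null(dom$voxel_size_mm) || dom$voxel_size_mm <= 0)
    stop("domain$voxel_size_mm must be positive")

  if (is.data.frame(media)) media <- split(media, seq_len(nrow(media)))
  if (!length(media)) stop("config entry \"media\" must be non-empty")
  for (i in seq_along(media)) {
    m <- as.list(media[[i]])
    if (is.null(m$mua) || m$mua < 0)
      stop("media[", i, "]: \"mua\" must be present and non-negative")
    if (is.null(m$n)) m$n <- 1.33
    sphere <- !is.null(m$r_um)
    if (sphere) {
      if (is.null(m$rho_per_um3) || m$rho_per_um3 < 0)
        stop("media[", i, "]: sphere medium needs non-negative \"rho_per_um3\"")
      if (is.null(m$n_sphere)) stop("media[", i, "]: sphere medium needs \"n_sphere\"")
    } else {
      if (is.null(m$mus)) stop("media[", i, "]: provide \"r_um\" (spheres) or \"mus\"")
      if (m$mus < 0) stop("media[", i, "]: \"mus\" must be non-negative")
      if (m$mus > 0 && is.null(m$matrix_file) && is.null(m$table))
        stop("media[", i, "]: scattering medium given by bulk optics needs ",
             "\"matrix_file\" or an inline \"table\"")
    }
    media[[i]] <- m
  }
  config$media <- media

  src$type <- match.arg(src$type, c("pencil", "planar"))
  if (is.null(src$position_mm) || length(src$position_mm) != 3L)
    stop("source$position_mm must be a 3-vector (mm)")
  if (is.null(src$direction)) src$direction <- c(0, 0, 1)
  nd <- sqrt(sum(src$direction^2))
  if (nd == 0) stop("source$direction must be non-zero")
  src$direction <- src$direction / nd
  if (is.null(src$stokes)) src$stokes <- c(1, 1, 0, 0)
  S <- src$stokes
  if (length(S) != 4L || S[1] <= 0)
    stop("source$stokes must be [I,Q,U,V] with I > 0")
  if (sum(S[2:4]^2) > S[1]^2 * (1 + 1e-12))
    stop("source$stokes is overpolarized: Q^2+U^2+V^2 exceeds I^2")
  if (src$type == "planar") {
    if (is.null(src$extent_mm) || length(src$extent_mm) != 2L)
      stop("planar source needs extent_mm = [wx, wy]")
  }
  L <- dom$dims * dom$voxel_size_mm
  p <- src$position_mm
  inside <- all(p >= 0) && all(p <= L)
  if (src$type == "planar")
    inside <- inside && all(p[1:2] + src$extent_mm <= L[1:2] + 1e-9)
  if (!inside) stop("source lies outside the domain")
  config$source <- src

  if (is.null(config$boundary)) config$boundary <- list(xy = "escape")
  config$boundary$xy <- match.arg(config$boundary$xy, c("escape", "cyclic"))

  if (is.null(config$detector)) config$detector <- list()
  det <- config$detector
  if (is.null(det$pixels)) det$pixels <- c(100L, 100L)
  if (is.null(det$origin_mm)) det$origin_mm <- c(0, 0)
  if (is.null(det$size_mm)) det$size_mm <- L[1:2] - det$origin_mm
  stopifnot(all(det$pixels >= 1L), all(det$size_mm > 0))
  config$detector <- det

  if (is.null(config$photons)) config$photons <- 1e6
  if (config$photons < 0) stop("photons must be non-negative")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$wavelength_nm)) config$wavelength_nm <- 632.8
  if (is.null(config$n_angles)) config$n_angles <- 1000L
  class(config) <- c("sim_config", "list")
  config
}

#' Build the domain model described by a configuration
#'
#' Host-side preprocessing: resolves each media entry into a
#' transport-ready \code{\link{medium_record}} (running the Mie
#' precomputation for sphere-defined media), builds the label volume
#' from explicit labels or shape primitives, and validates that every
#' label present has a medium.
#'
#' @param config A \code{\link{parse_config}} result (or raw list/path,
#'   which is parsed first).
#' @return A \code{\link{domain_model}}.
#' @export
build_domain <- function(config) {
  if (!inherits(config, "sim_config")) config <- parse_config(config)
  dom <- config$domain
  dims <- as.integer(dom$dims)
  h <- dom$voxel_size_mm

  labels <- if (!is.null(dom$labels)) {
    array(as.integer(dom$labels), dim = dims)
  } else {
    array(1L, dim = dims)
  }
  if (!is.null(dom$shapes)) {
    shapes <- dom$shapes
    if (is.data.frame(shapes)) shapes <- split(shapes, seq_len(nrow(shapes)))
    for (sh in shapes) {
      sh <- as.list(sh)
      if (sh$type == "layers") {
        labels <- layered_labels(dims, h, unlist(sh$interfaces_mm))
      } else if (sh$type == "sphere") {
        labels <- sphere_labels(labels, h, unlist(sh$center_mm),
                                sh$radius_mm, sh$label)
      } else stop("unknown shape type: ", sh$type)
    }
  }

  media <- lapply(config$media, function(m) {
    if (!is.null(m$r_um)) {
      spec <- scatterer_spec(m$r_um, m$rho_per_um3, m$n_sphere, m$n,
                             config$wavelength_nm)
      medium_record(m$mua, m$n, spec = spec, n_angles = config$n_angles)
    } else {
      tab <- m$table
      if (is.null(tab) && !is.null(m$matrix_file))
        tab <- read_smatrix_table(m$matrix_file)
      medium_record(m$mua, m$n, mus_per_mm = m$mus, anisotropy = m$g,
                    table = tab)
    }
  })

  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(present) && max(present) > length(media))
    stop("label volume references medium ", max(present),
         " but only ", length(media), " media are configured")
  domain_model(voxel_grid(dims, h, labels), media, config$boundary$xy)
}
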