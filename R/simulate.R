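# The simulation driver: launch -> {traverse, absorb, scatter} -> detect
# over all photon packets, followed by detector finalisation and the
# energy audit.

#' Run a polarized-light Monte Carlo simulation
#'
#' Propagates photon packets through the voxelated domain described by
#' the configuration, tracking a meridian-plane Stokes vector per
#' packet, and accumulates backscattered I, Q, U, V on the z = 0
#' detector facet. The run is deterministic given the seed.
#'
#' @param config A configuration accepted by \code{\link{parse_config}}.
#' @param photons Optional override of the photon count.
#' @param seed Optional override of the RNG seed.
#' @param save_absorption Keep the per-voxel absorbed-weight grid
#'   (secondary output; off by default).
#' @param domain Optional prebuilt \code{\link{domain_model}} for the
#'   config, to amortise the Mie precomputation over repeated runs.
#' @return Object of class \code{"polmc_result"}; see
#'   \code{\link{finalize_detector}} for the detector quantities.
#' @examples
#' cfg <- benchmark_homogeneous(photons = 2000)
#' res <- run_simulation(cfg)
#' res$totals_per_photon
#' @export
run_simulation <- function(config, photons = NULL, seed = NULL,
                           save_absorption = FALSE, domain = NULL) {
  config <- parse_config(config)
  if (!is.null(photons)) config$photons <- photons
  if (!is.null(seed)) config$seed <- seed
  if (is.null(domain)) domain <- build_domain(config)
  stopifnot(inherits(domain, "domain_model"))
  arr <- domain_arrays(domain)
  src <- config$source
  det <- config$detector

  src_type <- if (src$type == "pencil") 0L else 1L
  extent <- if (src$type == "planar") src$extent_mm else c(0, 0)

  set.seed(config$seed)
  raw <- cpp_run_simulation(
    labels = as.integer(domain$grid$labels),
    dims = domain$grid$dims,
    voxel_size = domain$grid$voxel_size_mm,
    mua = arr$mua, mus = arr$mus,
    s11m = arr$s11, s12m = arr$s12, s33m = arr$s33, s34m = arr$s34,
    cdfm = arr$cdfm, edge_mu = arr$edge_mu, envelope = arr$envelope,
    src_type = src_type, src_pos = src$position_mm,
    src_dir = src$direction, src_extent = extent,
    src_stokes = src$stokes,
    cyclic_xy = identical(config$boundary$xy, "cyclic"),
    det_pixels = as.integer(det$pixels),
    det_origin = det$origin_mm, det_size = det$size_mm,
    n_photons = config$photons,
    w_threshold = 1e-4, p_survive = 0.1,
    save_absorption = save_absorption,
    rejection_guard = 1000000L)

  finalize_result(raw, config, domain)
}

finalize_result <- function(raw, config, domain) {
  n <- raw$n_photons
  if (n == 0) {
    # a zero-photon run is valid and empty; per-photon quantities are zero
    fin <- list(images = raw$images, images_per_photon = raw$images,
                totals = raw$totals, totals_per_photon = raw$totals,
                total_I_se = 0,
                total_QUV_se = c(Q = 0, U = 0, V = 0),
                off_detector_I = 0, n_photons = 0, reflected = 0,
                transmitted = 0, side_escaped = 0, ambient_escaped = 0,
                absorbed = 0)
  } else {
    fin <- finalize_detector(raw, n)
  }
  audit <- energy_audit(raw)
  res <- c(fin, list(
    audit = audit,
    rejection_acceptance = if (raw$n_rejection_trials > 0)
      raw$n_scatter / raw$n_rejection_trials else NA_real_,
    n_scatter = raw$n_scatter,
    absorption = raw$absorption,
    config = config,
    domain = domain))
  class(res) <- "polmc_result"
  res
}

#' Normalise detector accumulators per launched photon
#'
#' Divides the raw weighted-Stokes totals and images by the number of
#' launched packets, so a lossless, perfectly reflecting medium yields
#' total I of 1. Totals cover every packet escaping through the z = 0
#' facet; the pixel images cover the detector extent, with weight
#' landing outside tallied separately.
#'
#' @param raw Raw accumulator list from the transport loop.
#' @param n_photons Number of launched packets (> 0).
#' @return List with raw and per-photon images and totals, the
#'   per-photon standard error of total I, and escape/absorption
#'   tallies.
#' @export
finalize_detector <- function(raw, n_photons) {
  if (n_photons <= 0) stop("cannot finalize a detector with zero launched photons")
  n <- n_photons
  mean_d <- raw$sum_detected / n
  var_d <- max(raw$sum_detected_sq / n - mean_d^2, 0)
  quv_mean <- raw$totals[c("Q", "U", "V")] / n
  quv_se <- sqrt(pmax(raw$sum_sq_QUV / n - quv_mean^2, 0) / n)
  names(quv_se) <- c("Q", "U", "V")
  list(images = raw$images,
       images_per_photon = lapply(raw$images, function(m) m / n),
       totals = raw$totals,
       totals_per_photon = raw$totals / n,
       total_I_se = sqrt(var_d / n),
       total_QUV_se = quv_se,
       off_detector_I = raw$off_detector_I,
       n_photons = n,
       reflected = raw$totals[["I"]] / n,
       transmitted = raw$transmitted / n,
       side_escaped = raw$side_escaped / n,
       ambient_escaped = raw$ambient_escaped / n,
       absorbed = raw$absorbed / n)
}

# launched weight + roulette boosts must equal every sink, trajectory by
# trajectory; any gap beyond float accumulation indicates lost weight.
energy_audit <- function(raw) {
  n <- raw$n_photons
  sinks <- raw$totals[["I"]] + raw$transmitted + raw$side_escaped +
    raw$ambient_escaped + raw$absorbed + raw$roulette_killed +
    raw$stuck_weight
  sources <- n + raw$roulette_boosted
  list(launched = n,
       boosted = raw$roulette_boosted,
       detected = raw$totals[["I"]],
       transmitted = raw$transmitted,
       side_escaped = raw$side_escaped,
       ambient_escaped = raw$ambient_escaped,
       absorbed = raw$absorbed,
       roulette_killed = raw$roulette_killed,
       stuck = raw$stuck_weight,
       imbalance = (sources - sinks) / max(sources, 1),
       balanced = abs(sources - sinks) <= 1e-9 * max(sources, 1))
}

#' @export
print.polmc_result <- function(x, ...) {
  cat(sprintf("Polarized MC result: %g photons\n", x$n_photons))
  tp <- x$totals_per_photon
  cat(sprintf("  total per photon  I = %.6f +/- %.6f\n", tp[["I"]],
              x$total_I_se))
  cat(sprintf("                    Q = %#.6f  U = %#.6f  V = %#.6f\n",
              tp[["Q"]], tp[["U"]], tp[["V"]]))
  cat(sprintf("  transmitted %.4f, side %.4f, absorbed %.4f\n",
              x$transmitted, x$side_escaped, x$absorbed))
  cat(sprintf("  energy audit %s (relative imbalance %.2e)\n",
              if (x$audit$balanced) "balanced" else "NOT balanced",
              x$audit$imbalance))
  cat(sprintf("  rejection-sampler acceptance rate %.3f\n",
              x$rejection_acceptance))
  invisible(x)
}

#' Standard error of a per-photon total
#'
#' Helper for stochastic comparisons: given two runs, the combined
#' standard error of the difference of their per-photon total I.
#'
#' @param a,b \code{"polmc_result"} objects.
#' @return Standard error of \code{a$reflected - b$reflected}.
#' @export
combined_se <- function(a, b) sqrt(a$total_I_se^2 + b$total_I_se^2)
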