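#' Monte Carlo transport configuration
#'
#' @param n_packets number of photon packets to launch (>= 1).
#' @param seed integer seed; mandatory.  Each packet draws from its own
#'   counter-based RNG substream derived from (seed, packet index), so the
#'   simulation is deterministic and independent of execution order.
#' @param roulette_threshold packet weight below which Russian roulette is
#'   played, in (0, 1).
#' @param roulette_survival weight multiplier for surviving packets (> 1);
#'   survival probability is its reciprocal.
#' @param fresnel_at_air_interfaces logical; apply Fresnel
#'   reflection/refraction at voxel faces where the refractive index
#'   changes.  Default `FALSE` (index-matched boundaries).
#' @param max_steps collision cap per packet; a packet exceeding it has its
#'   weight moved to the ledger's roulette-imbalance entry.
#' @return A `transport_config` object.
#' @export
transport_config <- function(n_packets, seed,
                             roulette_threshold = 1e-4,
                             roulette_survival = 10,
                             fresnel_at_air_interfaces = FALSE,
                             max_steps = 100000L) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("transport_config requires an explicit integer seed")
  stopifnot(n_packets >= 1,
            roulette_threshold > 0, roulette_threshold < 1,
            roulette_survival > 1, max_steps >= 1)
  structure(list(n_packets = as.numeric(n_packets), seed = as.integer(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 fresnel_at_air_interfaces = fresnel_at_air_interfaces,
                 max_steps = as.integer(max_steps)),
            class = "transport_config")
}

#' Sample a scattering direction from the Henyey-Greenstein phase function
#'
#' Draws the deflection cosine from the Henyey-Greenstein distribution with
#' anisotropy `g` (mean cosine equal to `g`) and a uniform azimuth about
#' the incoming direction.  `g = 0` is isotropic; `g = 1` passes the
#' incoming direction through unchanged.
#'
#' @param g anisotropy in \[0, 1\].
#' @param incoming incoming unit direction (length 3).
#' @param n number of independent draws.
#' @param seed integer seed.
#' @return An `n x 3` matrix of unit direction vectors.
#' @export
sample_scatter_direction <- function(g, incoming, n = 1, seed = 1) {
  stopifnot(g >= 0, g <= 1, length(incoming) == 3, n >= 1)
  .hg_sample_cpp(g, as.numeric(incoming), as.integer(n), as.numeric(seed))
}

#' Launch photon packets from a source
#'
#' Samples launch states: for a disc source, position uniform over the
#' emitting face and direction cosine-weighted (Lambertian) about the
#' inward normal; for a point source, isotropic direction.  All packets
#' start with unit weight.
#'
#' @param source a `disc_source` or `point_source`.
#' @param n number of packets.
#' @param seed integer seed.
#' @return List with `position` (n x 3, mm), `direction` (n x 3, unit) and
#'   `weight` (all 1).
#' @export
launch_packets <- function(source, n = 1, seed = 1) {
  stopifnot(inherits(source, "light_source"), n >= 1)
  .launch_sample_cpp(as_engine_source(source), as.integer(n),
                     as.numeric(seed))
}

#' Run the photon-packet Monte Carlo simulation
#'
#' Transports photon packets from the given sources through the voxel
#' phantom, scoring fluence with the track-length estimator (photon-weight
#' times path length per voxel).  Absorption attenuates the packet weight
#' by the single-scattering albedo at each collision; scattering directions
#' follow Henyey-Greenstein, except in materials flagged as carrying a
#' reduced scattering coefficient, which are transported isotropically at
#' that rate (similarity relation).  Packets are allocated to sources in
#' proportion to emitted power.  Low-weight packets play Russian roulette.
#'
#' The returned map is in "raw" mode (photon-weight x mm per voxel);
#' convert to absolute fluence rate with [normalize_fluence()].  The weight
#' ledger satisfies launched = absorbed + escaped + rouletted exactly (the
#' roulette entry also absorbs the weight of packets hitting `max_steps`).
#'
#' @param phantom a `voxel_phantom`.
#' @param sources a single source or list of `disc_source` / `point_source`
#'   objects; centres must lie inside the grid.
#' @param config a [transport_config()].
#' @return A `fluence_map` object: `grid` (array, raw mode), `voxel_size`,
#'   `n_packets`, `total_power_mW`, `mode`, `ledger`,
#'   `packets_per_source`.
#' @export
simulate_fluence <- function(phantom, sources, config) {
  validate_phantom(phantom)
  stopifnot(inherits(config, "transport_config"))
  if (inherits(sources, "light_source")) sources <- list(sources)
  stopifnot(length(sources) >= 1,
            all(vapply(sources, inherits, TRUE, "light_source")))
  d <- dim(phantom$label_grid)
  ext <- d * phantom$voxel_size
  for (src in sources)
    if (any(src$center < 0) || any(src$center > ext))
      stop("source centre lies outside the phantom grid")

  res <- .mc_simulate_cpp(
    as.integer(phantom$label_grid), as.integer(d), phantom$voxel_size,
    material_matrix(phantom$material_table),
    lapply(sources, as_engine_source),
    config$n_packets, as.numeric(config$seed),
    config$roulette_threshold, config$roulette_survival,
    config$fresnel_at_air_interfaces, config$max_steps)

  total_power <- sum(vapply(sources, function(s) s$emitted_power, 0))
  structure(list(grid = array(res$fluence, dim = d),
                 voxel_size = phantom$voxel_size,
                 n_packets = config$n_packets,
                 total_power_mW = total_power,
                 mode = "raw",
                 ledger = res$ledger,
                 packets_per_source = res$packets_per_source),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("fluence_map (%s): %d x %d x %d voxels at %g mm\n",
              x$mode, d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  %g packets, %g mW total power; max value %.4g %s\n",
              x$n_packets, x$total_power_mW, max(x$grid),
              if (x$mode == "raw") "weight*mm" else "mW/cm^2"))
  lg <- x$ledger
  cat(sprintf("  ledger: launched %.6g = absorbed %.6g + escaped %.6g + rouletted %.6g\n",
              lg$launched, lg$absorbed, lg$escaped, lg$rouletted))
  invisible(x)
}

#' Convert a raw fluence map to absolute fluence rate
#'
#' Scales the track-length scores to fluence rate:
#' `value = raw * (total_power_mW / n_packets) / voxel_volume`, with the
#' mm -> cm unit conversion, yielding mW/cm^2.  The result is exactly
#' linear in the total source power.  A map can be normalized only once.
#'
#' @param raw_map a raw-mode `fluence_map`.
#' @param total_power_mW total source power, mW; defaults to the power
#'   recorded at simulation time.
#' @return A normalized `fluence_map` in mW/cm^2.
#' @export
normalize_fluence <- function(raw_map, total_power_mW = raw_map$total_power_mW) {
  stopifnot(inherits(raw_map, "fluence_map"))
  if (raw_map$mode != "raw")
    stop("fluence map is already normalized (double normalization rejected)")
  out <- raw_map
  # raw is weight*mm; / mm^3 * mW -> mW/mm^2; x100 -> mW/cm^2
  out$grid <- raw_map$grid * (total_power_mW / raw_map$n_packets) /
    raw_map$voxel_size^3 * 100
  out$total_power_mW <- total_power_mW
  out$mode <- "normalized"
  out
}

#' Check weight conservation of a simulation
#'
#' @param map a `fluence_map`.
#' @return Relative imbalance |launched - absorbed - escaped - rouletted| /
#'   launched.
#' @export
ledger_imbalance <- function(map) {
  lg <- map$ledger
  abs(lg$launched - lg$absorbed - lg$escaped - lg$rouletted) / lg$launched
}

#' Write a fluence map as NIfTI with a JSON ledger sidecar
#'
#' @param map a `fluence_map`.
#' @param prefix output path prefix (`<prefix>.nii`, `<prefix>_ledger.json`).
#' @return Paths, invisibly.
#' @export
write_fluence_map <- function(map, prefix) {
  stopifnot(inherits(map, "fluence_map"))
  nii <- paste0(prefix, ".nii")
  js <- paste0(prefix, "_ledger.json")
  img <- RNifti::asNifti(map$grid, pixdim = rep(map$voxel_size, 3),
                         datatype = "float")
  RNifti::writeNifti(img, nii)
  jsonlite::write_json(
    c(map$ledger,
      list(mode = map$mode, n_packets = map$n_packets,
           total_power_mW = map$total_power_mW,
           units = if (map$mode == "raw") "photon-weight*mm" else "mW/cm^2")),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(nifti = nii, ledger = js))
}
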