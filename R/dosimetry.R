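#' Dose-volume histogram of a fluence map
#'
#' For each fluence-rate level, the fraction of the masked (lung) volume
#' receiving at least that level — the "volume fraction at or above"
#' convention, matching statements like "fluence rates > 1 mW/cm2 across
#' ~25% of the lung".  Default levels are log-spaced over six decades below
#' the masked maximum, with 0 prepended so the curve starts at fraction 1.
#'
#' @param map a normalized `fluence_map` (raw maps are accepted; levels are
#'   then in raw units).
#' @param mask logical array matching the map grid, `TRUE` over the organ;
#'   see [lung_mask()].
#' @param levels ascending fluence-rate levels (>= 0), mW/cm^2.
#' @return A `dose_volume_histogram`: `levels`,
#'   `volume_fraction_at_or_above`, `mask_volume_mL`.
#' @export
dose_volume_histogram <- function(map, mask, levels = NULL) {
  stopifnot(inherits(map, "fluence_map"), is.logical(mask))
  if (!identical(dim(mask), dim(map$grid)))
    stop("mask dimensions do not match the fluence map")
  vals <- map$grid[mask]
  if (!length(vals)) stop("empty mask: no voxels to histogram")
  if (is.null(levels)) {
    top <- max(vals)
    if (top <= 0) top <- 1
    levels <- c(0, 10^seq(log10(top) - 6, log10(top), length.out = 121))
  }
  stopifnot(all(levels >= 0), !is.unsorted(levels))
  frac <- vapply(levels, function(l) mean(vals >= l), 0)
  structure(list(levels = levels,
                 volume_fraction_at_or_above = frac,
                 mask_volume_mL = length(vals) * map$voxel_size^3 / 1000),
            class = "dose_volume_histogram")
}

#' @export
print.dose_volume_histogram <- function(x, ...) {
  cat(sprintf("dose_volume_histogram over %.1f mL, %d levels\n",
              x$mask_volume_mL, length(x$levels)))
  invisible(x)
}

#' Volume fraction at or above one fluence-rate level
#'
#' @inheritParams dose_volume_histogram
#' @param level fluence-rate level, mW/cm^2 (>= 0).
#' @return Fraction of the masked volume with value >= `level`.
#' @export
volume_fraction_above <- function(map, mask, level) {
  stopifnot(length(level) == 1, level >= 0)
  dose_volume_histogram(map, mask, levels = level)$volume_fraction_at_or_above
}

#' Write a dose-volume histogram as CSV
#'
#' Columns `level_mW_per_cm2`, `volume_fraction_at_or_above`.
#'
#' @param dvh a `dose_volume_histogram`.
#' @param path output CSV path.
#' @export
write_dvh_csv <- function(dvh, path) {
  stopifnot(inherits(dvh, "dose_volume_histogram"))
  write.csv(data.frame(level_mW_per_cm2 = dvh$levels,
                       volume_fraction_at_or_above =
                         dvh$volume_fraction_at_or_above),
            path, row.names = FALSE)
  invisible(path)
}

#' Read out a fluence map at a detector probe
#'
#' Mean of the map over voxels whose centres lie within the probe's
#' sampling radius of its position, multiplied by the responsivity
#' correction; the standard error comes from the between-voxel spread.
#'
#' @param map a `fluence_map`.
#' @param probe a [detector_probe()].
#' @return List with `value`, `se` (same units as the map) and `n_voxels`.
#' @export
detector_readout <- function(map, probe) {
  stopifnot(inherits(map, "fluence_map"), inherits(probe, "detector_probe"))
  h <- map$voxel_size
  d <- dim(map$grid)
  r <- probe$sampling_radius
  lo <- pmax(floor((probe$position - r) / h), 0) + 1
  hi <- pmin(ceiling((probe$position + r) / h), d)
  if (any(lo > hi)) stop("detector sampling sphere contains no voxels")
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  gx <- (ii - 0.5) * h - probe$position[1]
  gy <- (jj - 0.5) * h - probe$position[2]
  gz <- (kk - 0.5) * h - probe$position[3]
  d2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  sel <- d2 <= r^2
  if (!any(sel)) {
    # tiny sampling radius: fall back to the voxel containing the tip
    v <- floor(probe$position / h) + 1
    if (any(v < 1) || any(v > d))
      stop("detector sampling sphere contains no voxels")
    vals <- map$grid[v[1], v[2], v[3]]
  } else {
    vals <- map$grid[ii, jj, kk][sel]
  }
  n <- length(vals)
  list(value = mean(vals) * probe$responsivity_correction,
       se = if (n > 1) sd(vals) / sqrt(n) * probe$responsivity_correction
            else NA_real_,
       n_voxels = n)
}

#' Fit the effective attenuation coefficient from detector readouts
#'
#' Ordinary least squares of log fluence against distance.  In mode
#' `"ln-r-times-fluence"` (default) the response is ln(r * Phi), the
#' geometry-corrected form that removes the 1/r spherical spreading of a
#' point-like source and recovers mu_eff exactly in the diffusion limit.
#' Mode `"ln-fluence"` regresses ln(Phi) directly, mirroring the raw
#' log-fluence-versus-distance plot of a measurement campaign; for
#' point-like geometries its estimate is biased above the true mu_eff by
#' roughly the mean of 1/r over the fitted range.
#'
#' @param readouts data frame (or list convertible to one) with columns
#'   `distance_mm` and `fluence` (> 0), at >= 2 distinct distances.
#' @param mode `"ln-r-times-fluence"` or `"ln-fluence"`.
#' @return An `attenuation_fit`: `mu_eff_estimate` (per mm; negative slope
#'   of the regression), `stderr`, `mode`, `n_points`.
#' @export
fit_effective_attenuation <- function(readouts,
                                      mode = c("ln-r-times-fluence",
                                               "ln-fluence")) {
  mode <- match.arg(mode)
  readouts <- as.data.frame(readouts)
  stopifnot(all(c("distance_mm", "fluence") %in% names(readouts)))
  bad <- which(readouts$fluence <= 0)
  if (length(bad))
    stop("non-positive fluence at distance(s) ",
         paste(readouts$distance_mm[bad], collapse = ", "),
         " mm: cannot take logarithms")
  if (length(unique(readouts$distance_mm)) < 2)
    stop("need at least 2 distinct distances")
  r <- readouts$distance_mm
  y <- if (mode == "ln-r-times-fluence") log(r * readouts$fluence)
       else log(readouts$fluence)
  fit <- lm(y ~ r)
  est <- -unname(coef(fit)[2])
  n <- nrow(readouts)
  se <- if (n > 2)
    sqrt(sum(residuals(fit)^2) / (n - 2) / sum((r - mean(r))^2))
  else 0
  structure(list(mu_eff_estimate = est, stderr = se, mode = mode,
                 n_points = nrow(readouts)),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf(
    "attenuation_fit (%s, n = %d): mu_eff = %.4f /mm (%.3f /cm), se %.4f /mm\n",
    x$mode, x$n_points, x$mu_eff_estimate, 10 * x$mu_eff_estimate, x$stderr))
  invisible(x)
}

#' Measured-versus-simulated concordance
#'
#' Least-squares line of measured on simulated fluence rates plus the
#' coefficient of determination, summarizing how well the simulation
#' predicts the measurements (identity line: slope 1, intercept 0, R^2 1).
#'
#' @param measured,simulated numeric vectors of equal length >= 2.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
concordance <- function(measured, simulated) {
  stopifnot(length(measured) == length(simulated), length(measured) >= 2)
  if (var(simulated) == 0)
    stop("simulated values have zero variance: concordance line undefined")
  fit <- lm(measured ~ simulated)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((measured - mean(measured))^2)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot)
}
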