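#' Build a synthetic voxelized thorax phantom
#'
#' Generates the simulation scene standing in for a CT-segmented thorax: a
#' half-ellipsoid left lung (flat mediastinal face, curved lateral surface)
#' of a requested volume, surrounded by ambient air, with a simplified
#' symmetric dichotomous bronchial tree carved out of the parenchyma as air.
#' The ellipsoid axes are calibrated so that the voxelized parenchyma
#' (lung-labelled voxels, airways excluded) matches the requested volume to
#' well within 2%.
#'
#' The airway tree is anatomically schematic: a main bronchus entering at
#' the hilum (flat face) followed by `bronchial_generations - 1` symmetric
#' bifurcations, child radius and length scaled by `branch_ratio` per
#' generation, branching plane rotating with a small seeded jitter.  A
#' generation whose airway diameter falls below one voxel cannot be
#' represented and raises an error naming the limiting generation.
#'
#' @param lung_volume_mL target parenchyma volume, mL (> 0).
#' @param voxel_size_mm isotropic voxel edge, mm, in \[0.5, 5\].
#' @param bronchial_generations number of airway generations to carve
#'   (0 = none, generation 1 = main bronchus), at most 8.
#' @param seed integer seed for the (small) random jitter of branch
#'   orientations; the result is fully deterministic given the seed.
#' @param axis_ratio relative semi-axis lengths (x = mediastinal-to-lateral
#'   half axis, y, z = cranio-caudal long axis).
#' @param margin_mm ambient-air padding around the lung, mm.
#' @param bronchus_radius_mm main-bronchus radius, mm.
#' @param branch_ratio child/parent radius and length ratio per generation.
#' @param branch_angle_deg half-angle between daughter branches, degrees.
#' @return An object of class `voxel_phantom`: integer `label_grid`
#'   (1 = ambient air, 2 = lung parenchyma, 3 = bronchial air,
#'   4 = absorber), `voxel_size` (mm), `material_table`, `lung_mask_label`,
#'   plus geometry metadata (`center`, `semi_axes`, `flat_face_x`, in mm).
#' @export
#' @examples
#' ph <- build_thorax_phantom(lung_volume_mL = 50, voxel_size_mm = 2,
#'                            bronchial_generations = 2, seed = 1)
#' ph
build_thorax_phantom <- function(lung_volume_mL = 700, voxel_size_mm = 1,
                                 bronchial_generations = 4, seed = 1,
                                 axis_ratio = c(1, 1, 1.6), margin_mm = 12,
                                 bronchus_radius_mm = 5, branch_ratio = 0.79,
                                 branch_angle_deg = 35) {
  stopifnot(lung_volume_mL > 0,
            voxel_size_mm >= 0.5, voxel_size_mm <= 5,
            bronchial_generations >= 0, bronchial_generations <= 8,
            length(axis_ratio) == 3, all(axis_ratio > 0))
  h <- voxel_size_mm
  V <- lung_volume_mL * 1000  # mm^3

  if (bronchial_generations > 0) {
    radii <- bronchus_radius_mm * branch_ratio^(seq_len(bronchial_generations) - 1)
    too_fine <- which(2 * radii < h)
    if (length(too_fine))
      stop(sprintf(
        "voxel size %g mm too coarse to resolve generation %d airways ",
        h, too_fine[1]),
        sprintf("(radius %.3g mm, diameter below one voxel)", radii[too_fine[1]]))
  }

  # analytic semi-axes for a half ellipsoid of volume V, then headroom
  s0 <- (3 * V / (2 * pi * prod(axis_ratio)))^(1 / 3)
  axes0 <- s0 * axis_ratio
  x0 <- margin_mm                      # flat mediastinal face plane
  yc <- margin_mm + 1.1 * axes0[2]
  zc <- margin_mm + 1.1 * axes0[3]
  nx <- ceiling((x0 + 1.1 * axes0[1] + margin_mm) / h)
  ny <- ceiling((yc + 1.1 * axes0[2] + margin_mm) / h)
  nz <- ceiling((zc + 1.1 * axes0[3] + margin_mm) / h)

  cx <- (seq_len(nx) - 0.5) * h
  cy <- (seq_len(ny) - 0.5) * h
  cz <- (seq_len(nz) - 0.5) * h

  ellipsoid_mask <- function(axes) {
    ex <- pmax(cx - x0, 0) / axes[1]   # flat face: x >= x0 half only
    inside_x <- cx >= x0
    ey <- (cy - yc) / axes[2]
    ez <- (cz - zc) / axes[3]
    q <- outer(outer(ex^2, ey^2, `+`), ez^2, `+`)
    q <= 1 & array(inside_x, dim = c(nx, ny, nz))
  }

  tree <- if (bronchial_generations > 0)
    airway_segments(bronchial_generations, bronchus_radius_mm, branch_ratio,
                    branch_angle_deg, seed,
                    start = c(x0, yc, zc + 0.25 * axes0[3]),
                    dir = c(1, 0, -0.45) / sqrt(1 + 0.45^2),
                    len0 = 0.45 * axes0[3])
  else list()

  # calibrate the axes so the carved parenchyma hits the target volume
  axes <- axes0
  carved_mm3 <- 0
  labels <- NULL
  for (iter in 1:4) {
    target <- V + carved_mm3
    for (k in 1:3) {
      m <- ellipsoid_mask(axes)
      got <- sum(m) * h^3
      if (got <= 0) stop("phantom grid too small for requested volume")
      axes <- axes * (target / got)^(1 / 3)
    }
    m <- ellipsoid_mask(axes)
    labels <- array(PHANTOM_LABELS[["ambient_air"]], dim = c(nx, ny, nz))
    labels[m] <- PHANTOM_LABELS[["lung"]]
    labels <- carve_airways(labels, tree, h)
    lung_n <- sum(labels == PHANTOM_LABELS[["lung"]])
    carved_new <- sum(m) * h^3 - lung_n * h^3
    if (abs(lung_n * h^3 - V) / V < 0.005) break
    carved_mm3 <- carved_new
  }

  structure(list(
    label_grid = labels,
    voxel_size = h,
    material_table = default_material_table(),
    lung_mask_label = unname(PHANTOM_LABELS[["lung"]]),
    labels = PHANTOM_LABELS,
    center = c(x0, yc, zc),
    semi_axes = axes,
    flat_face_x = x0,
    lung_voxels = sum(labels == PHANTOM_LABELS[["lung"]]),
    spec = list(lung_volume_mL = lung_volume_mL, voxel_size_mm = h,
                bronchial_generations = bronchial_generations, seed = seed)),
    class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$label_grid)
  cat(sprintf("voxel_phantom: %d x %d x %d voxels at %g mm\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  lung: %d voxels = %.1f mL (requested %.1f mL)\n",
              x$lung_voxels, x$lung_voxels * x$voxel_size^3 / 1000,
              x$spec$lung_volume_mL))
  cat(sprintf("  bronchial air: %d voxels; generations: %d\n",
              sum(x$label_grid == x$labels[["bronchial_air"]]),
              x$spec$bronchial_generations))
  invisible(x)
}

# recursive dichotomous airway centreline; returns list of
# (p0, p1, radius) segments.  Jitter drawn from a private RNG stream.
airway_segments <- function(generations, r0, ratio, angle_deg, seed,
                            start, dir, len0) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  segs <- list()
  recurse <- function(p0, d, len, r, gen) {
    p1 <- p0 + d * len
    segs[[length(segs) + 1]] <<- list(p0 = p0, p1 = p1, radius = r)
    if (gen >= generations) return(invisible())
    # branching plane: perpendicular pair, rotated per generation + jitter
    up <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    e1 <- up - sum(up * d) * d; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(d[2] * e1[3] - d[3] * e1[2],
            d[3] * e1[1] - d[1] * e1[3],
            d[1] * e1[2] - d[2] * e1[1])
    roll <- (gen %% 2) * pi / 2 + stats::runif(1, -0.15, 0.15)
    b <- cos(roll) * e1 + sin(roll) * e2
    a <- angle_deg * pi / 180 + stats::runif(1, -0.06, 0.06)
    for (sgn in c(-1, 1)) {
      dd <- cos(a) * d + sgn * sin(a) * b
      dd <- dd / sqrt(sum(dd^2))
      recurse(p1, dd, len * ratio, r * ratio, gen + 1)
    }
  }
  recurse(start, dir, len0, r0, 1)
  segs
}

# stamp air cylinders into lung-labelled voxels only
carve_airways <- function(labels, segs, h) {
  if (!length(segs)) return(labels)
  d <- dim(labels)
  for (s in segs) {
    lo <- pmax(floor((pmin(s$p0, s$p1) - s$radius - h) / h), 0) + 1
    hi <- pmin(ceiling((pmax(s$p0, s$p1) + s$radius + h) / h), d)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    gx <- (ii - 0.5) * h; gy <- (jj - 0.5) * h; gz <- (kk - 0.5) * h
    ax <- s$p1 - s$p0
    L2 <- sum(ax^2)
    X <- outer(outer(gx - s$p0[1], rep(0, length(jj)), `+`),
               rep(0, length(kk)), `+`)
    Y <- outer(outer(rep(0, length(ii)), gy - s$p0[2], `+`),
               rep(0, length(kk)), `+`)
    Z <- outer(outer(rep(0, length(ii)), rep(0, length(jj)), `+`),
               gz - s$p0[3], `+`)
    tt <- pmin(pmax((X * ax[1] + Y * ax[2] + Z * ax[3]) / L2, 0), 1)
    d2 <- (X - tt * ax[1])^2 + (Y - tt * ax[2])^2 + (Z - tt * ax[3])^2
    sub <- labels[ii, jj, kk]
    sub[d2 <= s$radius^2 & sub == PHANTOM_LABELS[["lung"]]] <-
      PHANTOM_LABELS[["bronchial_air"]]
    labels[ii, jj, kk] <- sub
  }
  labels
}

#' Logical mask of the lung parenchyma
#'
#' @param phantom a [build_thorax_phantom()] result.
#' @return Logical array, `TRUE` on lung-labelled voxels.
#' @export
lung_mask <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  phantom$label_grid == phantom$lung_mask_label
}

#' Homogeneous block phantom
#'
#' A rectangular grid filled with a single tissue, used for validation runs
#' against the infinite-medium diffusion oracle (pad the block well beyond
#' the deepest detector so boundary losses are negligible).
#'
#' @param side_mm edge length of the cubic block, mm.
#' @param voxel_size_mm voxel edge, mm.
#' @param props tissue filling the block.
#' @return A `voxel_phantom` whose every voxel is the given tissue.
#' @export
homogeneous_phantom <- function(side_mm, voxel_size_mm = 1,
                                props = lung_properties()) {
  n <- ceiling(side_mm / voxel_size_mm)
  labels <- array(2L, dim = c(n, n, n))
  structure(list(
    label_grid = labels,
    voxel_size = voxel_size_mm,
    material_table = default_material_table(lung = props),
    lung_mask_label = 2L,
    labels = PHANTOM_LABELS,
    center = rep(n * voxel_size_mm / 2, 3),
    semi_axes = rep(n * voxel_size_mm / 2, 3),
    flat_face_x = 0,
    lung_voxels = length(labels),
    spec = list(lung_volume_mL = length(labels) * voxel_size_mm^3 / 1000,
                voxel_size_mm = voxel_size_mm, bronchial_generations = 0,
                seed = NA)),
    class = "voxel_phantom")
}

validate_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  labs <- sort(unique(as.vector(phantom$label_grid)))
  if (!all(labs %in% seq_along(phantom$material_table)))
    stop("label grid contains labels missing from the material table: ",
         paste(setdiff(labs, seq_along(phantom$material_table)),
               collapse = ", "))
  invisible(phantom)
}

#' Place LED disc sources on the lung surface
#'
#' Distributes `n_sources` non-overlapping light-emitting discs tangent to
#' the curved (lateral) lung surface, inward normals along the local
#' surface normal, total emitted power split equally.  Placement is by
#' greedy farthest-point selection over a deterministic candidate grid on
#' the ellipsoid surface; it fails explicitly when the surface cannot host
#' the requested number of non-overlapping discs.
#'
#' @param phantom a [build_thorax_phantom()] result.
#' @param n_sources number of discs (>= 1).
#' @param diameter_mm disc diameter, mm (default the 5-cm LED discs).
#' @param total_power_mW total emitted power across all discs, mW.
#' @param wavelength_nm emission wavelength, nm.
#' @param standoff_mm gap between the lung surface and the emitting face.
#' @return List of `disc_source` objects (each also records its
#'   `surface_point`, the tangency point on the lung surface).
#' @export
place_disc_sources <- function(phantom, n_sources, diameter_mm = 50,
                               total_power_mW = 2430, wavelength_nm = 665,
                               standoff_mm = 1) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            n_sources >= 1, diameter_mm > 0, total_power_mW >= 0)
  ax <- phantom$semi_axes
  ctr <- phantom$center
  theta <- seq(30, 150, by = 6) * pi / 180
  phi <- seq(-70, 70, by = 10) * pi / 180
  cand <- expand.grid(theta = theta, phi = phi)
  p <- cbind(ctr[1] + ax[1] * sin(cand$theta) * cos(cand$phi),
             ctr[2] + ax[2] * sin(cand$theta) * sin(cand$phi),
             ctr[3] + ax[3] * cos(cand$theta))
  nrm <- cbind(sin(cand$theta) * cos(cand$phi) / ax[1],
               sin(cand$theta) * sin(cand$phi) / ax[2],
               cos(cand$theta) / ax[3])
  nrm <- nrm / sqrt(rowSums(nrm^2))

  picked <- which.max(p[, 1])  # lateral-most point first
  while (length(picked) < n_sources) {
    dmin <- apply(p, 1, function(q)
      min(sqrt(colSums((t(p[picked, , drop = FALSE]) - q)^2))))
    cand_best <- which.max(dmin)
    if (dmin[cand_best] < diameter_mm)
      stop(sprintf(
        "lung surface too small to host %d non-overlapping %g-mm discs ",
        n_sources, diameter_mm),
        sprintf("(placed %d)", length(picked)))
    picked <- c(picked, cand_best)
  }
  dd <- as.matrix(dist(p[picked, , drop = FALSE]))
  if (n_sources > 1 && min(dd[upper.tri(dd)]) < diameter_mm)
    stop("could not satisfy the non-overlap contract for the disc sources")

  lapply(picked, function(i) {
    src <- disc_source(center = p[i, ] + standoff_mm * nrm[i, ],
                       inward_normal = -nrm[i, ],
                       radius = diameter_mm / 2,
                       emitted_power = total_power_mW / n_sources,
                       wavelength = wavelength_nm)
    src$surface_point <- p[i, ]
    src
  })
}

#' Light sources
#'
#' `disc_source()` is a Lambertian-emitting disc (uniform emission
#' position over the face, cosine-weighted direction about the inward
#' normal), the model of the LED treatment discs.  `point_source()` is an
#' isotropic point emitter used for validation against diffusion theory.
#'
#' @param center,position mm coordinates of the disc centre / point.
#' @param inward_normal unit vector from the disc into the tissue.
#' @param radius disc radius, mm (> 0).
#' @param emitted_power,power_mW emitted power, mW (>= 0).
#' @param wavelength,wavelength_nm wavelength, nm.
#' @return A `disc_source` / `point_source` object.
#' @export
disc_source <- function(center, inward_normal, radius, emitted_power,
                        wavelength = 665) {
  stopifnot(length(center) == 3, length(inward_normal) == 3,
            radius > 0, emitted_power >= 0)
  nn <- sqrt(sum(inward_normal^2))
  if (abs(nn - 1) > 1e-6) stop("inward_normal must be a unit vector")
  structure(list(center = as.numeric(center),
                 inward_normal = as.numeric(inward_normal) / nn,
                 radius = radius, emitted_power = emitted_power,
                 wavelength = wavelength),
            class = c("disc_source", "light_source"))
}

#' @rdname disc_source
#' @export
point_source <- function(position, power_mW, wavelength_nm = 665) {
  stopifnot(length(position) == 3, power_mW >= 0)
  structure(list(center = as.numeric(position),
                 inward_normal = c(0, 0, 1), radius = 0,
                 emitted_power = power_mW, wavelength = wavelength_nm),
            class = c("point_source", "light_source"))
}

as_engine_source <- function(src) {
  list(type = if (inherits(src, "point_source")) 0L else 1L,
       center = src$center, normal = src$inward_normal,
       radius = src$radius, power = src$emitted_power)
}

#' Place isotropic fibre detectors along a source axis
#'
#' Detector probes are positioned on the source's inward-normal axis at the
#' requested tissue depths (measured from the tangency point on the lung
#' surface when available, else from the source centre).  Each requested
#' depth must land inside the lung parenchyma; depths that fall in ambient
#' air, bronchial air, or outside the grid fail with the offending distance
#' and label.
#'
#' @param phantom a `voxel_phantom`.
#' @param distances_mm depths along the axis, mm, all > 0.
#' @param source a `disc_source` or `point_source`.
#' @param sampling_radius_mm radius of the spherical sampling volume used
#'   by [detector_readout()], mm.
#' @return List of `detector_probe` objects.
#' @export
place_detectors <- function(phantom, distances_mm, source,
                            sampling_radius_mm = 1) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(source, "light_source"))
  if (any(distances_mm <= 0))
    stop("detector depth must be positive (on-surface probe ill-defined): ",
         paste(distances_mm[distances_mm <= 0], collapse = ", "))
  origin <- if (!is.null(source$surface_point)) source$surface_point
            else source$center
  h <- phantom$voxel_size
  d <- dim(phantom$label_grid)
  label_names <- names(phantom$labels)
  lapply(distances_mm, function(dist) {
    pos <- origin + dist * source$inward_normal
    v <- floor(pos / h) + 1
    if (any(v < 1) || any(v > d))
      stop(sprintf("detector at %g mm falls outside the phantom grid", dist))
    lab <- phantom$label_grid[v[1], v[2], v[3]]
    if (lab != phantom$lung_mask_label)
      stop(sprintf(
        "detector at %g mm is not in lung parenchyma (label %d: %s)",
        dist, lab, label_names[match(lab, phantom$labels)]))
    detector_probe(pos, sampling_radius_mm)
  })
}

#' Isotropic fibre detector probe
#'
#' @param position mm coordinates of the probe tip.
#' @param sampling_radius radius of the sphere over which the fluence map
#'   is averaged for the readout, mm (> 0).
#' @param responsivity_correction multiplicative calibration factor (> 0)
#'   applied to the readout, e.g. for the refractive index of the medium
#'   surrounding the probe tip.
#' @return A `detector_probe` object.
#' @export
detector_probe <- function(position, sampling_radius = 1,
                           responsivity_correction = 1) {
  stopifnot(length(position) == 3, sampling_radius > 0,
            responsivity_correction > 0)
  structure(list(position = as.numeric(position),
                 sampling_radius = sampling_radius,
                 responsivity_correction = responsivity_correction),
            class = "detector_probe")
}

#' Stamp absorbing backings behind disc sources
#'
#' Represents the non-reflective, non-emitting housing of each LED disc as
#' a slab of ideal absorber directly behind the emitting face, so light
#' escaping backwards is terminated rather than re-entering the scene.
#'
#' @param phantom a `voxel_phantom`.
#' @param sources list of `disc_source` objects.
#' @param thickness_mm slab thickness, mm.
#' @return The phantom with absorber-labelled voxels added.
#' @export
stamp_source_backing <- function(phantom, sources, thickness_mm = 3) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  h <- phantom$voxel_size
  d <- dim(phantom$label_grid)
  labels <- phantom$label_grid
  for (src in sources) {
    if (!inherits(src, "disc_source")) next
    lo <- pmax(floor((src$center - src$radius - thickness_mm - h) / h), 0) + 1
    hi <- pmin(ceiling((src$center + src$radius + thickness_mm + h) / h), d)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    gx <- (ii - 0.5) * h - src$center[1]
    gy <- (jj - 0.5) * h - src$center[2]
    gz <- (kk - 0.5) * h - src$center[3]
    X <- outer(outer(gx, rep(0, length(jj)), `+`), rep(0, length(kk)), `+`)
    Y <- outer(outer(rep(0, length(ii)), gy, `+`), rep(0, length(kk)), `+`)
    Z <- outer(outer(rep(0, length(ii)), rep(0, length(jj)), `+`), gz, `+`)
    ip <- X * src$inward_normal[1] + Y * src$inward_normal[2] +
      Z * src$inward_normal[3]
    r2 <- X^2 + Y^2 + Z^2 - ip^2
    sub <- labels[ii, jj, kk]
    sel <- ip < 0 & ip > -thickness_mm & r2 <= src$radius^2 &
      sub == PHANTOM_LABELS[["ambient_air"]]
    sub[sel] <- PHANTOM_LABELS[["absorber"]]
    labels[ii, jj, kk] <- sub
  }
  phantom$label_grid <- labels
  phantom
}

#' Write / read a phantom as NIfTI plus a YAML scene description
#'
#' The label grid goes to `<prefix>.nii` (int16, voxel size in the header);
#' materials, labels and geometry metadata go to `<prefix>.yaml`.
#'
#' @param phantom a `voxel_phantom`.
#' @param prefix output path prefix.
#' @return `write_phantom` returns the paths invisibly; `read_phantom`
#'   returns the reconstructed `voxel_phantom`.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  nii <- paste0(prefix, ".nii")
  yml <- paste0(prefix, ".yaml")
  img <- RNifti::asNifti(phantom$label_grid,
                         pixdim = rep(phantom$voxel_size, 3),
                         datatype = "int16")
  RNifti::writeNifti(img, nii)
  mats <- lapply(phantom$material_table, function(p)
    list(absorption_coeff = p$absorption_coeff,
         scattering_coeff = p$scattering_coeff,
         anisotropy = p$anisotropy,
         refractive_index = p$refractive_index,
         scattering_is_reduced = p$scattering_is_reduced))
  yaml::write_yaml(list(
    voxel_size_mm = phantom$voxel_size,
    lung_mask_label = phantom$lung_mask_label,
    labels = as.list(phantom$labels),
    materials = mats,
    center_mm = phantom$center,
    semi_axes_mm = phantom$semi_axes,
    flat_face_x_mm = phantom$flat_face_x,
    spec = phantom$spec), yml)
  invisible(c(nifti = nii, yaml = yml))
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  nii <- paste0(prefix, ".nii")
  yml <- paste0(prefix, ".yaml")
  img <- RNifti::readNifti(nii)
  meta <- yaml::read_yaml(yml)
  labels <- array(as.integer(img), dim = dim(img))
  mats <- lapply(meta$materials, function(m)
    material_optical_properties(m$absorption_coeff, m$scattering_coeff,
                                m$anisotropy, m$refractive_index,
                                m$scattering_is_reduced))
  structure(list(
    label_grid = labels,
    voxel_size = meta$voxel_size_mm,
    material_table = mats,
    lung_mask_label = meta$lung_mask_label,
    labels = unlist(meta$labels),
    center = unlist(meta$center_mm),
    semi_axes = unlist(meta$semi_axes_mm),
    flat_face_x = meta$flat_face_x_mm,
    lung_voxels = sum(labels == meta$lung_mask_label),
    spec = meta$spec), class = "voxel_phantom")
}
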