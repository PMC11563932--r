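#' Optical properties of a material
#'
#' Bundle of the per-material optical coefficients consumed by the transport
#' engine: absorption coefficient, scattering coefficient, scattering
#' anisotropy (mean cosine of the single-scattering deflection) and
#' refractive index, all at the treatment wavelength.
#'
#' When `scattering_is_reduced = TRUE` the scattering coefficient is taken
#' to be the reduced (transport-scaled) coefficient mu_s' = mu_s (1 - g);
#' transport then proceeds with isotropic scattering (g = 0) at that rate,
#' by the similarity relation, and the stored `anisotropy` has no effect on
#' any fluence result.
#'
#' @param absorption_coeff absorption coefficient mu_a, per mm (>= 0).
#' @param scattering_coeff scattering coefficient, per mm (>= 0); reduced
#'   scattering mu_s' if `scattering_is_reduced`.
#' @param anisotropy mean scattering cosine g, in \[0, 1\].
#' @param refractive_index refractive index n (>= 1).
#' @param scattering_is_reduced logical; see Details.
#' @return An object of class `material_optical_properties`.
#' @export
#' @examples
#' lung_properties()
material_optical_properties <- function(absorption_coeff, scattering_coeff,
                                        anisotropy, refractive_index,
                                        scattering_is_reduced = FALSE) {
  stopifnot(is.numeric(absorption_coeff), absorption_coeff >= 0,
            is.numeric(scattering_coeff), scattering_coeff >= 0,
            is.numeric(anisotropy), anisotropy >= 0, anisotropy <= 1,
            is.numeric(refractive_index), refractive_index >= 1,
            is.logical(scattering_is_reduced))
  structure(list(absorption_coeff = absorption_coeff,
                 scattering_coeff = scattering_coeff,
                 anisotropy = anisotropy,
                 refractive_index = refractive_index,
                 scattering_is_reduced = scattering_is_reduced),
            class = "material_optical_properties")
}

#' @export
print.material_optical_properties <- function(x, ...) {
  cat(sprintf(
    "material: mu_a = %g /mm, %s = %g /mm, g = %g%s, n = %g\n",
    x$absorption_coeff,
    if (x$scattering_is_reduced) "mu_s'" else "mu_s",
    x$scattering_coeff, x$anisotropy,
    if (x$scattering_is_reduced) " (ignored: reduced-scattering mode)" else "",
    x$refractive_index))
  invisible(x)
}

#' Reduced scattering coefficient of a material
#'
#' mu_s' = mu_s (1 - g), or the stored coefficient unchanged when the
#' material is already in reduced-scattering mode.
#'
#' @param props a [material_optical_properties()] object.
#' @return Reduced scattering coefficient, per mm.
#' @export
reduced_scattering <- function(props) {
  stopifnot(inherits(props, "material_optical_properties"))
  if (props$scattering_is_reduced) props$scattering_coeff
  else props$scattering_coeff * (1 - props$anisotropy)
}

#' Reference tissue optical properties
#'
#' Optical properties of the materials making up the simulation scene for
#' red-light (630-665 nm) transport in the flushed porcine lung.  The lung
#' scattering value is carried as the reduced scattering coefficient: this
#' is the only reading under which the diffusion-theory effective
#' attenuation of lung tissue comes out at the 3.79 cm^-1 used throughout
#' the pipeline (see [effective_attenuation()]).  A full (mu_s, g)
#' parameterisation for lung is available via `lung_properties(reduced =
#' FALSE)`, which divides the reduced coefficient by (1 - g).
#'
#' @param reduced logical; return the reduced-scattering parameterisation
#'   (default) or the equivalent full (mu_s, g) one.
#' @return A `material_optical_properties` object.
#' @export
lung_properties <- function(reduced = TRUE) {
  musp <- 0.965
  g <- 0.93
  if (reduced)
    material_optical_properties(0.0473, musp, g, 1.36,
                                scattering_is_reduced = TRUE)
  else
    material_optical_properties(0.0473, musp / (1 - g), g, 1.36)
}

#' @rdname lung_properties
#' @export
air_properties <- function() {
  material_optical_properties(0, 0, 1, 1)
}

#' @rdname lung_properties
#' @export
muscle_properties <- function() {
  material_optical_properties(0.052, 7.356, 0.93, 1.37)
}

#' @rdname lung_properties
#' @export
bone_properties <- function() {
  material_optical_properties(0.014, 1.58, 0, 1.56)
}

#' @rdname lung_properties
#' @export
absorber_properties <- function() {
  # ideal beam dump used for the non-emitting backing of the LED discs
  material_optical_properties(1e8, 0.1, 0, 1)
}

# canonical label assignment used by the phantom builder
PHANTOM_LABELS <- c(ambient_air = 1L, lung = 2L, bronchial_air = 3L,
                    absorber = 4L)

default_material_table <- function(lung = lung_properties()) {
  list(ambient_air = air_properties(),
       lung = lung,
       bronchial_air = air_properties(),
       absorber = absorber_properties())
}

# material table (named list, label order) -> numeric matrix for the engine
material_matrix <- function(material_table) {
  m <- t(vapply(material_table, function(p) {
    stopifnot(inherits(p, "material_optical_properties"))
    c(p$absorption_coeff, p$scattering_coeff, p$anisotropy,
      p$refractive_index, as.numeric(p$scattering_is_reduced))
  }, numeric(5)))
  colnames(m) <- c("mua", "mus", "g", "n", "reduced")
  m
}
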