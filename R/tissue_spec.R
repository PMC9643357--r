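#' Specification of a synthetic tissue field
#'
#' Describes the stated world the simulator draws from: field geometry, cell
#' numbers and class mix, nucleus sizes, per-class marker emissions, the
#' contact-dependent GZMK effect, autofluorescence, erythrocyte artifacts and
#' additive Gaussian noise.
#'
#' Cell classes are `cd8` (CD8+ T cell, green membrane signal and GZMK
#' far-red signal on its peri-nuclear annulus), `neutrophil` (CD66b+, red
#' annulus signal) and `other` (autofluorescence only). A CD8+ cell whose
#' true nearest-neutrophil centroid distance is at most `contact_radius_um`
#' is "in contact" and its GZMK emission is `gzmk_base * gzmk_contact_fold`;
#' otherwise it is `gzmk_base`.
#'
#' @param field_size_um length-2 positive numeric, field width and height in
#'   microns.
#' @param pixel_size_um positive pixel pitch in microns (0.1625 matches a
#'   40x spinning-disk acquisition, 0.32 a 20x widefield one).
#' @param n_cells number of nuclei to place.
#' @param fraction_cd8,fraction_neutrophil class proportions; the remainder
#'   is the `other` class. Must sum to at most 1.
#' @param nucleus_radius_um length-2 numeric `c(mean, sd)` of nucleus radius.
#' @param band_width_um annulus thickness used both to render membrane
#'   signal and (downstream) to measure it.
#' @param contact_radius_um centroid distance at or below which a CD8+ cell
#'   counts as in contact with a neutrophil.
#' @param gzmk_base baseline GZMK emission of a non-contact CD8+ cell.
#' @param gzmk_contact_fold multiplier (>= 0) applied to GZMK emission of
#'   contact CD8+ cells.
#' @param marker_intensity nested list `class -> channel -> c(mean, sd)` of
#'   annulus emissions; see defaults in the function body.
#' @param dapi_intensity nuclear DAPI emission `c(mean, sd)`.
#' @param autofluorescence_level intensity added to every cell's pixels in
#'   the green, red and far-red channels.
#' @param n_rbc number of erythrocyte artifact disks.
#' @param rbc_radius_um erythrocyte disk radius.
#' @param rbc_intensity named vector of per-channel erythrocyte emissions.
#' @param noise_sd standard deviation of i.i.d. additive Gaussian pixel
#'   noise (clipped at zero).
#' @param seed integer seed for all randomness in the simulator.
#' @return object of class `tissue_spec` (a validated list).
#' @export
#' @examples
#' spec <- tissue_spec(n_cells = 10, field_size_um = c(120, 120))
#' spec$fraction_cd8
tissue_spec <- function(field_size_um = c(200, 200),
                        pixel_size_um = 0.1625,
                        n_cells = 100,
                        fraction_cd8 = 0.3,
                        fraction_neutrophil = 0.3,
                        nucleus_radius_um = c(3, 0.3),
                        band_width_um = 1,
                        contact_radius_um = 10,
                        gzmk_base = 100,
                        gzmk_contact_fold = 2,
                        marker_intensity = NULL,
                        dapi_intensity = c(200, 10),
                        autofluorescence_level = 5,
                        n_rbc = 0,
                        rbc_radius_um = 3,
                        rbc_intensity = c(green = 150, red = 60, farred = 40),
                        noise_sd = 5,
                        seed = 1L) {
  if (is.null(marker_intensity)) {
    marker_intensity <- list(
      cd8        = list(green = c(100, 5), red = c(0, 0), farred = c(0, 0)),
      neutrophil = list(green = c(0, 0), red = c(100, 5), farred = c(0, 0)),
      other      = list(green = c(0, 0), red = c(0, 0), farred = c(0, 0)))
  }
  spec <- list(field_size_um = as.numeric(field_size_um),
               pixel_size_um = pixel_size_um,
               n_cells = as.integer(n_cells),
               fraction_cd8 = fraction_cd8,
               fraction_neutrophil = fraction_neutrophil,
               nucleus_radius_um = as.numeric(nucleus_radius_um),
               band_width_um = band_width_um,
               contact_radius_um = contact_radius_um,
               gzmk_base = gzmk_base,
               gzmk_contact_fold = gzmk_contact_fold,
               marker_intensity = marker_intensity,
               dapi_intensity = as.numeric(dapi_intensity),
               autofluorescence_level = autofluorescence_level,
               n_rbc = as.integer(n_rbc),
               rbc_radius_um = rbc_radius_um,
               rbc_intensity = rbc_intensity,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "tissue_spec"
  validate_tissue_spec(spec)
}

validate_tissue_spec <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  with(spec, {
    if (length(field_size_um) != 2 || any(field_size_um <= 0))
      stop("field_size_um must be two positive lengths")
    if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
    if (n_cells < 0) stop("n_cells must be >= 0")
    if (fraction_cd8 < 0 || fraction_neutrophil < 0 ||
        fraction_cd8 + fraction_neutrophil > 1 + 1e-12)
      stop("class fractions must be nonnegative and sum to <= 1")
    if (length(nucleus_radius_um) != 2 || nucleus_radius_um[1] <= 0 ||
        nucleus_radius_um[2] < 0)
      stop("nucleus_radius_um must be c(mean > 0, sd >= 0)")
    if (band_width_um <= 0) stop("band_width_um must be > 0")
    if (contact_radius_um <= 0) stop("contact_radius_um must be > 0")
    if (gzmk_base < 0 || gzmk_contact_fold < 0)
      stop("GZMK parameters must be >= 0")
    if (autofluorescence_level < 0 || noise_sd < 0 || n_rbc < 0)
      stop("autofluorescence_level, noise_sd and n_rbc must be >= 0")
    for (cls in c("cd8", "neutrophil", "other")) {
      mi <- marker_intensity[[cls]]
      if (is.null(mi)) stop("marker_intensity missing class ", cls)
      for (ch in c("green", "red", "farred")) {
        v <- mi[[ch]]
        if (is.null(v) || length(v) != 2 || v[1] < 0 || v[2] < 0)
          stop("marker_intensity$", cls, "$", ch, " must be c(mean>=0, sd>=0)")
      }
    }
  })
  # crude capacity sanity check: total nucleus footprint must fit the field
  area <- prod(spec$field_size_um)
  need <- spec$n_cells * pi * (2 * spec$nucleus_radius_um[1])^2
  if (spec$n_cells > 0 && need > area)
    stop("field too small to place ", spec$n_cells,
         " non-overlapping nuclei of mean radius ",
         spec$nucleus_radius_um[1], " um")
  spec
}

#' @export
print.tissue_spec <- function(x, ...) {
  cat("tissue_spec:", x$n_cells, "cells on",
      paste(x$field_size_um, collapse = " x "), "um field,",
      "pixel", x$pixel_size_um, "um\n")
  cat("  fractions: cd8", x$fraction_cd8, "neutrophil", x$fraction_neutrophil,
      "other", 1 - x$fraction_cd8 - x$fraction_neutrophil, "\n")
  cat("  GZMK base", x$gzmk_base, "contact fold", x$gzmk_contact_fold,
      "within", x$contact_radius_um, "um; noise sd", x$noise_sd, "\n")
  invisible(x)
}
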