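#' Place non-overlapping disk nuclei in a field
#'
#' Rejection-samples nucleus centers uniformly inside the field (with a
#' margin of one radius so every disk lies fully inside) until `n_cells`
#' pairwise non-overlapping disks are placed or the attempt budget is
#' exhausted. Cell classes are assigned by largest-remainder rounding of the
#' class fractions and then randomly shuffled, so class counts are
#' deterministic for a given spec.
#'
#' @param spec a [tissue_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @param max_attempts_per_cell rejection budget per cell before a capacity
#'   error is raised.
#' @return data.frame with columns `cell_id`, `x_um`, `y_um`, `radius_um`,
#'   `type` (factor cd8/neutrophil/other).
#' @export
place_nuclei <- function(spec, seed = spec$seed, max_attempts_per_cell = 500) {
  spec <- validate_tissue_spec(spec)
  set.seed(as.integer(seed))
  n <- spec$n_cells
  empty <- data.frame(cell_id = integer(), x_um = numeric(),
                      y_um = numeric(), radius_um = numeric(),
                      type = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  fw <- spec$field_size_um[1]
  fh <- spec$field_size_um[2]
  rmu <- spec$nucleus_radius_um[1]
  rsd <- spec$nucleus_radius_um[2]

  xs <- ys <- rs <- numeric(n)
  placed <- 0L
  attempts <- 0L
  budget <- max_attempts_per_cell * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > budget)
      stop("capacity error: placed only ", placed, " of ", n,
           " nuclei after ", budget, " attempts; enlarge the field or ",
           "reduce n_cells")
    r <- rnorm(1, rmu, rsd)
    if (r < 0.25 * rmu) next  # reject degenerate radii
    if (2 * r >= fw || 2 * r >= fh) next
    x <- runif(1, r, fw - r)
    y <- runif(1, r, fh - r)
    if (placed > 0L) {
      i <- seq_len(placed)
      if (any((xs[i] - x)^2 + (ys[i] - y)^2 <= (rs[i] + r)^2)) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y; rs[placed] <- r
  }

  n_cd8 <- floor(spec$fraction_cd8 * n)
  n_neu <- floor(spec$fraction_neutrophil * n)
  # largest-remainder top-up toward the target fractions
  rem <- c(cd8 = spec$fraction_cd8 * n - n_cd8,
           neutrophil = spec$fraction_neutrophil * n - n_neu)
  extra <- round(sum(rem))
  if (extra > 0) {
    for (nm in names(sort(rem, decreasing = TRUE))[seq_len(extra)]) {
      if (nm == "cd8") n_cd8 <- n_cd8 + 1 else n_neu <- n_neu + 1
    }
  }
  n_oth <- n - n_cd8 - n_neu
  types <- sample(c(rep("cd8", n_cd8), rep("neutrophil", n_neu),
                    rep("other", n_oth)))

  data.frame(cell_id = seq_len(n), x_um = xs, y_um = ys, radius_um = rs,
             type = types, stringsAsFactors = FALSE)
}

# Brute-force nearest-neutrophil distance for every row of `placement`.
# Returns NA when the field holds no neutrophil.
truth_nearest_neutrophil <- function(placement) {
  neut <- placement[placement$type == "neutrophil", , drop = FALSE]
  n <- nrow(placement)
  d <- rep(NA_real_, n)
  if (nrow(neut) == 0L) return(d)
  for (i in seq_len(n)) {
    dd <- sqrt((neut$x_um - placement$x_um[i])^2 +
               (neut$y_um - placement$y_um[i])^2)
    dd[neut$cell_id == placement$cell_id[i]] <- Inf  # not its own neighbor
    d[i] <- if (all(is.infinite(dd))) NA_real_ else min(dd)
  }
  d
}

# Draw per-cell emission levels (cell-constant, pixel noise comes later).
draw_emissions <- function(placement, spec) {
  n <- nrow(placement)
  emis <- matrix(0, n, 3, dimnames = list(NULL, c("green", "red", "farred")))
  for (i in seq_len(n)) {
    mi <- spec$marker_intensity[[placement$type[i]]]
    for (ch in colnames(emis)) {
      v <- mi[[ch]]
      emis[i, ch] <- if (v[2] > 0) max(0, rnorm(1, v[1], v[2])) else v[1]
    }
  }
  emis
}

#' Ground truth table for a placement
#'
#' Computes, per cell, the true nearest-neutrophil distance (brute force over
#' all pairs), the contact indicator (CD8+ cells within
#' `spec$contact_radius_um` of a neutrophil) and the true GZMK emission.
#' Emission draws consume the RNG stream, so call under the seed discipline
#' used by [render_field()].
#' @param placement output of [place_nuclei()].
#' @param spec the [tissue_spec()].
#' @param emissions optional pre-drawn per-cell emission matrix.
#' @return data.frame, one row per cell (the GroundTruthTable).
#' @export
ground_truth_table <- function(placement, spec, emissions = NULL) {
  if (is.null(emissions)) emissions <- draw_emissions(placement, spec)
  d <- truth_nearest_neutrophil(placement)
  is_cd8 <- placement$type == "cd8"
  contact <- is_cd8 & !is.na(d) & d <= spec$contact_radius_um
  gzmk <- ifelse(is_cd8,
                 spec$gzmk_base *
                   ifelse(contact, spec$gzmk_contact_fold, 1),
                 emissions[, "farred"])
  data.frame(cell_id = placement$cell_id,
             type = placement$type,
             x_um = placement$x_um, y_um = placement$y_um,
             nucleus_radius_um = placement$radius_um,
             true_gzmk_emission = gzmk,
             true_nearest_neutrophil_distance_um = d,
             is_contact = contact,
             stringsAsFactors = FALSE)
}

# Add value `v` to matrix `img` over the disk/annulus of one cell.
# `shape` selects pixels with rmin < d <= rmax from the cell center,
# d measured between pixel centers in um. Returns modified img.
paint_region_idx <- function(dim_px, px, x, y, rmin, rmax) {
  nr <- dim_px[1]; nc <- dim_px[2]
  c0 <- max(1L, floor((x - rmax) / px + 0.5))
  c1 <- min(nc, ceiling((x + rmax) / px + 0.5))
  r0 <- max(1L, floor((y - rmax) / px + 0.5))
  r1 <- min(nr, ceiling((y + rmax) / px + 0.5))
  if (c1 < c0 || r1 < r0) return(integer())
  cols <- c0:c1; rows <- r0:r1
  xc <- (cols - 0.5) * px
  yc <- (rows - 0.5) * px
  d2 <- outer(yc - y, xc - x, function(a, b) a^2 + b^2)
  sel <- which(d2 <= rmax^2 & d2 > rmin^2, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(integer())
  (cols[sel[, 2]] - 1L) * nr + rows[sel[, 1]]
}

#' Render a multi-channel field from a placement
#'
#' Produces the four-channel raster (dapi, green, red, farred), the nucleus
#' label mask, and the ground-truth table. DAPI is painted on nucleus disks;
#' class marker emissions and GZMK are painted on the 1-band annulus
#' (`spec$band_width_um` wide) around each nucleus; autofluorescence is
#' added over each whole cell (disk plus annulus) in green/red/farred;
#' erythrocyte disks add their emissions; finally i.i.d. Gaussian noise of
#' sd `spec$noise_sd` is added to every pixel of every non-DAPI channel and
#' the result clipped at zero.
#'
#' @param spec a [tissue_spec()].
#' @param placement optional placement from [place_nuclei()]; generated from
#'   `spec` when omitted.
#' @param seed seed controlling emission draws, RBC placement and noise.
#' @param patient_id,field_id identifiers stamped on the field.
#' @return list with elements `field` (a [multichannel_field()]), `labels`
#'   (integer nucleus label matrix) and `truth` (ground-truth data.frame).
#' @export
render_field <- function(spec, placement = NULL, seed = spec$seed,
                         patient_id = "P1", field_id = "F1") {
  spec <- validate_tissue_spec(spec)
  if (is.null(placement)) placement <- place_nuclei(spec, seed = seed)
  set.seed(as.integer(seed) + 1L)  # decouple raster RNG from placement RNG
  px <- spec$pixel_size_um
  nc <- max(1L, round(spec$field_size_um[1] / px))
  nr <- max(1L, round(spec$field_size_um[2] / px))
  dims <- c(nr, nc)
  chans <- list(dapi = matrix(0, nr, nc), green = matrix(0, nr, nc),
                red = matrix(0, nr, nc), farred = matrix(0, nr, nc))
  labels <- matrix(0L, nr, nc)

  emissions <- draw_emissions(placement, spec)
  truth <- ground_truth_table(placement, spec, emissions)
  dapi_lvl <- if (spec$dapi_intensity[2] > 0 && nrow(placement) > 0)
    pmax(0, rnorm(nrow(placement), spec$dapi_intensity[1],
                  spec$dapi_intensity[2]))
  else rep(spec$dapi_intensity[1], nrow(placement))

  for (i in seq_len(nrow(placement))) {
    nuc <- paint_region_idx(dims, px, placement$x_um[i], placement$y_um[i],
                            -1, placement$radius_um[i])
    labels[nuc] <- placement$cell_id[i]
    chans$dapi[nuc] <- chans$dapi[nuc] + dapi_lvl[i]
  }

  # membrane emissions are painted on exactly the measurement band (the
  # nearest-nucleus pixel-center ring), so the rendered ground truth and the
  # downstream band quantification share one geometry and each band pixel
  # carries a single cell's emission
  band <- make_band_mask(labels, band_params(spec$band_width_um, "ring"), px)
  bidx <- which(band > 0L)
  band_of <- split(bidx, band[bidx])
  nidx <- which(labels > 0L)
  nuc_of <- split(nidx, labels[nidx])
  for (i in seq_len(nrow(placement))) {
    id <- as.character(placement$cell_id[i])
    ann <- band_of[[id]]
    cell <- c(nuc_of[[id]], ann)
    for (ch in c("green", "red", "farred")) {
      v <- if (ch == "farred" && placement$type[i] == "cd8")
        truth$true_gzmk_emission[i] else emissions[i, ch]
      if (v > 0 && length(ann)) chans[[ch]][ann] <- chans[[ch]][ann] + v
      if (spec$autofluorescence_level > 0)
        chans[[ch]][cell] <- chans[[ch]][cell] + spec$autofluorescence_level
    }
  }

  if (spec$n_rbc > 0) {
    for (k in seq_len(spec$n_rbc)) {
      x <- runif(1, 0, spec$field_size_um[1])
      y <- runif(1, 0, spec$field_size_um[2])
      disk <- paint_region_idx(dims, px, x, y, -1, spec$rbc_radius_um)
      for (ch in names(spec$rbc_intensity)) {
        chans[[ch]][disk] <- chans[[ch]][disk] + spec$rbc_intensity[[ch]]
      }
    }
  }

  if (spec$noise_sd > 0) {
    for (ch in c("green", "red", "farred")) {
      chans[[ch]] <- pmax(chans[[ch]] +
                            matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc),
                          0)
    }
  }

  field <- multichannel_field(chans, pixel_size_um = px,
                              patient_id = patient_id, field_id = field_id)
  list(field = field, labels = labels, truth = truth)
}

#' Simulate ground truth tables without rasterizing images
#'
#' Fast path used for large replicate studies (e.g. null calibration of the
#' Touching-vs-Near test): places nuclei, derives true distances, categories
#' and GZMK emissions, and models the *measured* band-mean GZMK as the true
#' emission plus autofluorescence plus Gaussian measurement error of sd
#' `noise_sd / sqrt(n_band_pixels)` (the per-pixel noise averaged over a
#' band of the analytic annulus area). No images are produced.
#'
#' @inheritParams render_field
#' @return data.frame: the ground-truth table plus a `gzmk_mean` column of
#'   simulated band measurements.
#' @export
simulate_truth_field <- function(spec, seed = spec$seed,
                                 patient_id = "P1", field_id = "F1") {
  placement <- place_nuclei(spec, seed = seed)
  set.seed(as.integer(seed) + 1L)
  truth <- ground_truth_table(placement, spec)
  px <- spec$pixel_size_um
  band_px <- pmax(1, pi * ((truth$nucleus_radius_um + spec$band_width_um)^2 -
                             truth$nucleus_radius_um^2) / px^2)
  meas_sd <- spec$noise_sd / sqrt(band_px)
  truth$gzmk_mean <- pmax(0, truth$true_gzmk_emission +
                            spec$autofluorescence_level +
                            rnorm(nrow(truth), 0, meas_sd))
  truth$patient_id <- patient_id
  truth$field_id <- field_id
  truth
}
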