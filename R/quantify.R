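#' Per-cell intensity features over a measurement region
#'
#' Computes, for every label of `region_mask` with at least one pixel, the
#' two per-cell intensity features for each channel of the field: mean
#' intensity (average pixel value over the region) and raw integrated
#' density (sum of pixel values; equals mean times pixel count). Cells
#' present in the nucleus mask but with an empty measurement region are
#' omitted with a warning.
#'
#' @param field a [multichannel_field()].
#' @param region_mask integer label matrix (typically from
#'   [make_band_mask()]), aligned to the field raster.
#' @param geometry optional per-cell geometry data.frame (from
#'   [cell_geometry()] on the nucleus mask) merged into the output.
#' @param expected_ids optional vector of cell ids expected to be measurable
#'   (used for the empty-region warning).
#' @return data.frame with one row per measured cell: `cell_id`,
#'   `patient_id`, `field_id`, `n_pixels`, `band_area_um2`, `clipped`, and
#'   per channel `mean_<channel>` and `rid_<channel>` columns, plus any
#'   geometry columns supplied.
#' @export
quantify_cells <- function(field, region_mask, geometry = NULL,
                           expected_ids = NULL) {
  stopifnot(inherits(field, "multichannel_field"))
  if (!identical(dim(region_mask)[1:2], field_dim(field)))
    stop("region mask dimensions do not match field raster")
  idx <- which(region_mask > 0L)
  lab <- as.integer(region_mask[idx])
  ids <- sort(unique(lab))
  if (!is.null(expected_ids)) {
    missing_ids <- setdiff(expected_ids, ids)
    if (length(missing_ids))
      warning("omitting ", length(missing_ids),
              " cell(s) with empty measurement region: ",
              paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  f <- factor(lab, levels = ids)
  n_px <- as.integer(table(f))
  px_area <- field$pixel_size_um^2
  out <- data.frame(cell_id = ids,
                    patient_id = field$patient_id,
                    field_id = field$field_id,
                    n_pixels = n_px,
                    band_area_um2 = n_px * px_area,
                    stringsAsFactors = FALSE)
  clip <- attr(region_mask, "clipped")
  out$clipped <- if (is.null(clip)) FALSE else
    unname(clip[as.character(ids)])
  for (ch in names(field$channels)) {
    v <- field$channels[[ch]][idx]
    rid <- as.numeric(rowsum(v, f))
    out[[paste0("rid_", ch)]] <- rid
    out[[paste0("mean_", ch)]] <- rid / n_px
  }
  if (!is.null(geometry))
    out <- merge(geometry, out, by = "cell_id", sort = TRUE)
  out[order(out$cell_id), , drop = FALSE]
}

#' Optional raster preprocessing hook
#'
#' Gaussian blur and rolling-ball-style background subtraction, both off by
#' default: the source acquisition pipeline applied unspecified denoising
#' and background subtraction, so no attempt is made to reconstruct it.
#' The background estimate is a grey-opening approximation (minimum then
#' maximum filter with a square structuring element of the given radius).
#'
#' @param field a [multichannel_field()].
#' @param gaussian_sigma_um blur sigma in microns (0 = off).
#' @param background_radius_um background subtraction radius (0 = off).
#' @return the preprocessed field.
#' @export
preprocess_field <- function(field, gaussian_sigma_um = 0,
                             background_radius_um = 0) {
  stopifnot(inherits(field, "multichannel_field"))
  px <- field$pixel_size_um
  for (ch in names(field$channels)) {
    m <- field$channels[[ch]]
    if (gaussian_sigma_um > 0)
      m <- gaussian_blur(m, gaussian_sigma_um / px)
    if (background_radius_um > 0) {
      r <- max(1L, round(background_radius_um / px))
      bg <- running_extreme(running_extreme(m, r, min), r, max)
      m <- pmax(0, m - bg)
    }
    field$channels[[ch]] <- m
  }
  field
}

# separable Gaussian blur, sigma in pixels, truncated at 3 sigma
gaussian_blur <- function(m, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  conv1 <- function(mat) {  # along rows (dim 1), edge-replicated
    n <- nrow(mat)
    pad <- rbind(mat[rep(1L, r), , drop = FALSE], mat,
                 mat[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(k))
      out <- out + k[j] * pad[(j - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

# separable running min/max with a (2r+1)-square window, edge-replicated
running_extreme <- function(m, r, fun) {
  ext1 <- function(mat) {
    n <- nrow(mat)
    pad <- rbind(mat[rep(1L, r), , drop = FALSE], mat,
                 mat[rep(n, r), , drop = FALSE])
    out <- mat
    for (i in seq_len(n)) {
      out[i, ] <- apply(pad[i:(i + 2 * r), , drop = FALSE], 2, fun)
    }
    out
  }
  t(ext1(t(ext1(m))))
}
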