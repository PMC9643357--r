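#' Multi-channel fluorescence field
#'
#' Container for one field of view: named 2D intensity channels sharing one
#' raster geometry, the physical pixel size, and patient/field identifiers.
#' Pixel (row i, col j), 1-based, has its center at physical coordinates
#' x = (j - 0.5) * pixel_size_um, y = (i - 0.5) * pixel_size_um.
#'
#' @param channels named list of nonnegative numeric matrices with identical
#'   dimensions (conventional names: dapi, green, red, farred).
#' @param pixel_size_um positive pixel pitch in microns.
#' @param patient_id,field_id identifiers carried into all per-cell tables.
#' @return object of class `multichannel_field`.
#' @export
multichannel_field <- function(channels, pixel_size_um,
                               patient_id = "P1", field_id = "F1") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a named list of matrices")
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1)
    stop("all channels must share identical raster dimensions")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (any(vapply(channels, function(m) any(m < 0), logical(1))))
    stop("channel intensities must be nonnegative")
  structure(list(channels = channels,
                 pixel_size_um = pixel_size_um,
                 patient_id = patient_id, field_id = field_id),
            class = "multichannel_field")
}

#' @export
print.multichannel_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("multichannel_field", x$patient_id, "/", x$field_id, ":",
      paste(names(x$channels), collapse = ", "), "|",
      d[1], "x", d[2], "px @", x$pixel_size_um, "um\n")
  invisible(x)
}

field_dim <- function(field) dim(field$channels[[1]])

#' Write a field bundle to disk
#'
#' Emits `channels.tif` (multi-page float32 TIFF, one page per channel),
#' `labels.tif` (16-bit label TIFF) when a mask is given, `metadata.json`
#' recording channel order, pixel size and identifiers, and optionally the
#' ground truth as `truth.csv`.
#'
#' @param field a [multichannel_field()].
#' @param dir output directory (created if needed).
#' @param labels optional integer nucleus label matrix.
#' @param truth optional ground-truth data.frame.
#' @return `dir`, invisibly.
#' @export
write_field <- function(field, dir, labels = NULL, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tiff(field$channels, file.path(dir, "channels.tif"), "float64")
  meta <- list(channels = names(field$channels),
               pixel_size_um = field$pixel_size_um,
               patient_id = field$patient_id, field_id = field$field_id)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(labels))
    write_tiff(labels, file.path(dir, "labels.tif"), "uint16")
  if (!is.null(truth))
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a field (and optional label mask) from disk
#'
#' Accepts either a directory written by [write_field()] or explicit paths.
#' Channel pages are matched to names positionally; dimension mismatches
#' between channels, or between channels and mask, are rejected.
#'
#' @param path field directory, or a channels TIFF path.
#' @param labels_path optional label TIFF path (defaults to `labels.tif`
#'   next to the channels file when present).
#' @param channel_names channel names when no metadata sidecar exists.
#' @param pixel_size_um pixel size override; required without metadata.
#' @param patient_id,field_id identifier overrides.
#' @return list with `field` (a [multichannel_field()]) and `labels`
#'   (integer matrix or NULL).
#' @export
read_field <- function(path, labels_path = NULL, channel_names = NULL,
                       pixel_size_um = NULL, patient_id = NULL,
                       field_id = NULL) {
  if (dir.exists(path)) {
    chan_path <- file.path(path, "channels.tif")
    meta_path <- file.path(path, "metadata.json")
    if (is.null(labels_path) && file.exists(file.path(path, "labels.tif")))
      labels_path <- file.path(path, "labels.tif")
  } else {
    chan_path <- path
    meta_path <- file.path(dirname(path), "metadata.json")
  }
  if (!file.exists(chan_path)) stop("channels TIFF not found: ", chan_path)
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  channel_names <- channel_names %||% meta$channels
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  patient_id <- patient_id %||% meta$patient_id %||% "P1"
  field_id <- field_id %||% meta$field_id %||% "F1"
  if (is.null(pixel_size_um))
    stop("pixel_size_um not given and no metadata sidecar found")

  pages <- read_tiff(chan_path)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(pages))
  if (length(pages) != length(channel_names))
    stop("channel count mismatch: TIFF has ", length(pages),
         " pages but ", length(channel_names), " names declared")
  names(pages) <- channel_names
  field <- multichannel_field(pages, pixel_size_um, patient_id, field_id)

  labels <- NULL
  if (!is.null(labels_path)) {
    lp <- read_tiff(labels_path)
    if (length(lp) != 1) stop("label mask must be a single-page TIFF")
    labels <- lp[[1]]
    if (!identical(dim(labels), field_dim(field)))
      stop("label mask dimensions ", paste(dim(labels), collapse = "x"),
           " do not match field ", paste(field_dim(field), collapse = "x"))
    storage.mode(labels) <- "integer"
  }
  list(field = field, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference nucleus segmenter for synthetic images
#'
#' Otsu threshold on the DAPI channel followed by 4-connected component
#' labeling and a minimum-area filter. Suitable only for the well-separated
#' disk nuclei produced by the simulator, not for real tissue (where a
#' trained star-convex or comparable model should supply the label mask).
#'
#' @param field a [multichannel_field()] with a `dapi` channel.
#' @param min_area_um2 components smaller than this are dropped.
#' @return integer label matrix.
#' @export
segment_nuclei_otsu <- function(field, min_area_um2 = 3) {
  dapi <- field$channels$dapi
  if (is.null(dapi)) stop("field has no dapi channel")
  thr <- otsu_threshold(dapi)
  labels <- label_components_cpp(dapi > thr)
  px_area <- field$pixel_size_um^2
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes * px_area >= min_area_um2)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0
  out[nz] <- relab[labels[nz]]
  out
}

# Otsu's between-class-variance-maximizing threshold on a 256-bin histogram.
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.vector(x)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1]) / diff(rng) * n_bins)),
                n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / n_bins * diff(rng)
}
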