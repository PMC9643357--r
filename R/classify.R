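#' Marker classification configuration
#'
#' Thresholds and rule constants for marker positivity. All comparisons in
#' the classifiers are strict (`>`), so a cell sitting exactly on a stated
#' boundary (ratio green/red = 4, ratio red/green = 2, positive area =
#' 3 um2) is negative.
#'
#' @param cd8_rid_threshold raw-integrated-density threshold in the green
#'   channel, usually from [calibrate_threshold()] on autofluorescence-only
#'   cells.
#' @param cd66b_rid_threshold analogous red-channel threshold.
#' @param ratio_green_over_red_min erythrocyte correction for CD8: a cell is
#'   CD8+ only if rid_green / rid_red exceeds this (default 4).
#' @param ratio_red_over_green_min erythrocyte correction for CD66b
#'   (default 2).
#' @param autofluor_quantile quantile of the autofluorescence-only RID
#'   distribution used by [calibrate_threshold()] (default 0.99).
#' @param alpha_sma_min_positive_area_um2 minimum classifier-positive area
#'   for an alpha-SMA+ call (default 3 um2).
#' @param pixel_classifier_thresholds named per-channel intensity cutoffs
#'   for the pixel-classifier rules.
#' @param rbc_discard_channels channels that must all have positive area
#'   > 0 for a cell to be discarded as erythrocyte-overlapping.
#' @param min_negatives minimum autofluorescence-only sample size accepted
#'   by [calibrate_threshold()].
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(cd8_rid_threshold = 0,
                              cd66b_rid_threshold = 0,
                              ratio_green_over_red_min = 4,
                              ratio_red_over_green_min = 2,
                              autofluor_quantile = 0.99,
                              alpha_sma_min_positive_area_um2 = 3,
                              pixel_classifier_thresholds = NULL,
                              rbc_discard_channels = c("green", "red",
                                                       "farred"),
                              min_negatives = 20L) {
  stopifnot(cd8_rid_threshold >= 0, cd66b_rid_threshold >= 0,
            ratio_green_over_red_min > 0, ratio_red_over_green_min > 0,
            autofluor_quantile > 0, autofluor_quantile < 1,
            alpha_sma_min_positive_area_um2 >= 0)
  structure(list(cd8_rid_threshold = cd8_rid_threshold,
                 cd66b_rid_threshold = cd66b_rid_threshold,
                 ratio_green_over_red_min = ratio_green_over_red_min,
                 ratio_red_over_green_min = ratio_red_over_green_min,
                 autofluor_quantile = autofluor_quantile,
                 alpha_sma_min_positive_area_um2 =
                   alpha_sma_min_positive_area_um2,
                 pixel_classifier_thresholds = pixel_classifier_thresholds,
                 rbc_discard_channels = rbc_discard_channels,
                 min_negatives = as.integer(min_negatives)),
            class = "classifier_config")
}

#' Calibrate a positivity threshold from autofluorescence-only cells
#'
#' Replaces the by-eye comparison of positive-cell and autofluorescence-only
#' RID values with a reproducible rule: the empirical quantile (linear
#' interpolation, R type 7) of the negative-control distribution.
#'
#' @param negative_rid_values raw integrated densities of cells expressing
#'   only autofluorescence (pooled per patient).
#' @param quantile_p quantile in (0,1), default 0.99.
#' @param min_negatives minimum usable sample size.
#' @return the threshold (scalar).
#' @export
calibrate_threshold <- function(negative_rid_values, quantile_p = 0.99,
                                min_negatives = 20L) {
  v <- negative_rid_values[!is.na(negative_rid_values)]
  if (length(v) < min_negatives)
    stop("only ", length(v), " autofluorescence-only values supplied ",
         "(need >= ", min_negatives, "); set the threshold manually")
  if (any(v < 0)) stop("negative-control RID values must be >= 0")
  if (quantile_p <= 0 || quantile_p >= 1) stop("quantile must be in (0,1)")
  unname(quantile(v, quantile_p, type = 7))
}

positivity_call <- function(cell_id, marker, positive, reason) {
  data.frame(cell_id = cell_id, marker = marker, positive = positive,
             reason = reason, stringsAsFactors = FALSE)
}

# shared ratio-gated classifier: signal channel must beat the RID threshold
# and the signal/other ratio must exceed the erythrocyte-correction minimum;
# ratio with a zero denominator and a positive numerator passes (+Inf).
ratio_gate <- function(cell_id, marker, rid_signal, rid_other,
                       threshold, ratio_min) {
  n <- length(rid_signal)
  reason <- rep("pass", n)
  ratio <- ifelse(rid_other == 0,
                  ifelse(rid_signal > 0, Inf, 0),
                  rid_signal / rid_other)
  reason[ratio <= ratio_min] <- "ratio_fail"
  reason[rid_signal <= threshold] <- "below_threshold"  # threshold dominates
  positivity_call(cell_id, marker, reason == "pass", reason)
}

#' Call CD8 positivity on band features
#'
#' A cell is CD8+ iff its green raw integrated density strictly exceeds the
#' calibrated threshold and its green/red RID ratio strictly exceeds the
#' erythrocyte-correction minimum (default 4).
#'
#' @param features a [quantify_cells()] row or table with `rid_green` and
#'   `rid_red`.
#' @param cfg a [classifier_config()].
#' @return data.frame of positivity calls (`cell_id`, `marker`, `positive`,
#'   `reason`), one row per input cell.
#' @export
classify_cd8 <- function(features, cfg) {
  stopifnot(all(c("rid_green", "rid_red") %in% names(features)))
  ratio_gate(features$cell_id, "cd8", features$rid_green, features$rid_red,
             cfg$cd8_rid_threshold, cfg$ratio_green_over_red_min)
}

#' Call CD66b positivity on band features
#'
#' Mirror of [classify_cd8()]: red RID above threshold and red/green ratio
#' strictly greater than the minimum (default 2).
#'
#' @inheritParams classify_cd8
#' @export
classify_cd66b <- function(features, cfg) {
  stopifnot(all(c("rid_green", "rid_red") %in% names(features)))
  ratio_gate(features$cell_id, "cd66b", features$rid_red, features$rid_green,
             cfg$cd66b_rid_threshold, cfg$ratio_red_over_green_min)
}

# classifier-positive area per cell (um2) in one channel
positive_area_by_cell <- function(field, region_mask, channel, cutoff) {
  img <- field$channels[[channel]]
  if (is.null(img)) stop("field has no channel '", channel, "'")
  idx <- which(region_mask > 0L)
  lab <- as.integer(region_mask[idx])
  ids <- sort(unique(lab))
  pos <- img[idx] > cutoff
  cnt <- as.integer(rowsum(as.integer(pos), factor(lab, levels = ids)))
  setNames(cnt * field$pixel_size_um^2, ids)
}

#' Area-based marker positivity (alpha-SMA workflow)
#'
#' Per cell, counts expansion-region pixels whose intensity in the marker
#' channel strictly exceeds the pixel-classifier cutoff; the cell is
#' positive iff that area (pixel count times pixel area, um2) strictly
#' exceeds `alpha_sma_min_positive_area_um2`.
#'
#' @param field a [multichannel_field()].
#' @param expansion_mask label matrix from [make_band_mask()] in expansion
#'   mode.
#' @param cfg a [classifier_config()] with `pixel_classifier_thresholds`
#'   naming the marker channel.
#' @param channel marker channel name (default "green" for alpha-SMA).
#' @return positivity-call data.frame with an extra `positive_area_um2`
#'   column.
#' @export
classify_area_based <- function(field, expansion_mask, cfg,
                                channel = "green") {
  cutoff <- cfg$pixel_classifier_thresholds[[channel]]
  if (is.null(cutoff))
    stop("pixel_classifier_thresholds has no cutoff for channel '",
         channel, "'")
  area <- positive_area_by_cell(field, expansion_mask, channel, cutoff)
  ids <- as.integer(names(area))
  pos <- area > cfg$alpha_sma_min_positive_area_um2
  out <- positivity_call(ids, "alpha_sma", unname(pos),
                         ifelse(pos, "pass", "area_fail"))
  out$positive_area_um2 <- unname(area)
  out
}

#' Discard cells overlapping erythrocytes (multi-channel positivity rule)
#'
#' A cell is discarded iff its pixel-classifier positive area is strictly
#' greater than zero in *every* channel of `cfg$rbc_discard_channels`
#' simultaneously.
#'
#' @inheritParams classify_area_based
#' @return integer vector of discarded cell ids.
#' @export
rbc_overlap_discard <- function(field, expansion_mask, cfg) {
  chans <- cfg$rbc_discard_channels
  cuts <- cfg$pixel_classifier_thresholds
  if (is.null(cuts) || !all(chans %in% names(cuts)))
    stop("pixel_classifier_thresholds must cover all rbc_discard_channels")
  areas <- lapply(chans, function(ch)
    positive_area_by_cell(field, expansion_mask, ch, cuts[[ch]]))
  ids <- as.integer(names(areas[[1]]))
  all_pos <- Reduce(`&`, lapply(areas, function(a) a > 0))
  ids[all_pos]
}

#' Assign a cell type from CD8 and CD66b calls
#'
#' CD8+ cells are typed `cd8`, CD66b+ cells `neutrophil`, the rest `other`.
#' The two ratio gates (green/red > 4 and red/green > 2) cannot both hold,
#' so the calls are mutually exclusive by construction.
#'
#' @param features band feature table.
#' @param cfg a [classifier_config()].
#' @return `features` with added `cd8_positive`, `cd66b_positive` and
#'   `type` columns.
#' @export
classify_cells <- function(features, cfg) {
  cd8 <- classify_cd8(features, cfg)
  cd66b <- classify_cd66b(features, cfg)
  features$cd8_positive <- cd8$positive
  features$cd8_reason <- cd8$reason
  features$cd66b_positive <- cd66b$positive
  features$cd66b_reason <- cd66b$reason
  features$type <- ifelse(features$cd8_positive, "cd8",
                          ifelse(features$cd66b_positive, "neutrophil",
                                 "other"))
  features
}
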