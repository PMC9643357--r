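#' Nearest neutrophil for each query cell within one field of view
#'
#' Distances are centroid-to-centroid Euclidean distances in microns; the
#' search never crosses fields of view. Ties are broken toward the smaller
#' neutrophil cell id. Fields with no neutrophil yield absent (`NA`)
#' distances.
#'
#' @param cells data.frame of query cells (usually CD8+) with `cell_id`,
#'   `x_um`, `y_um`; one field only.
#' @param neutrophils data.frame of CD66b+ cells in the same field with the
#'   same columns.
#' @return `cells` with added `nearest_neutrophil_id` and `distance_um`.
#' @export
nearest_neutrophil <- function(cells, neutrophils) {
  n <- nrow(cells)
  cells$nearest_neutrophil_id <- rep(NA_integer_, n)
  cells$distance_um <- rep(NA_real_, n)
  if (n == 0L || nrow(neutrophils) == 0L) return(cells)
  ord <- order(neutrophils$cell_id)
  neutrophils <- neutrophils[ord, , drop = FALSE]
  d2 <- outer(cells$x_um, neutrophils$x_um, "-")^2 +
        outer(cells$y_um, neutrophils$y_um, "-")^2
  # exclude self-pairing when a query cell is itself in the neutrophil set
  self <- outer(cells$cell_id, neutrophils$cell_id, "==")
  d2[self] <- Inf
  j <- apply(d2, 1, which.min)  # first minimum = smallest id after sorting
  dmin <- sqrt(d2[cbind(seq_len(n), j)])
  has <- is.finite(dmin)
  cells$nearest_neutrophil_id[has] <- neutrophils$cell_id[j[has]]
  cells$distance_um[has] <- dmin[has]
  cells
}

#' Distance category: Touching / Near / excluded
#'
#' Distances below `max_touch` (default 10 um) are `touching`; distances in
#' the half-open interval from `max_touch` to `max_near` (default 20 um)
#' are `near`; larger or absent distances are `excluded`.
#'
#' @param distance_um nonnegative distances (NA allowed).
#' @param max_touch,max_near category cutoffs in microns.
#' @return character vector of categories.
#' @export
categorize_distance <- function(distance_um, max_touch = 10, max_near = 20) {
  if (max_touch >= max_near) stop("max_touch must be < max_near")
  if (any(distance_um < 0, na.rm = TRUE)) stop("distances must be >= 0")
  out <- rep("excluded", length(distance_um))
  out[!is.na(distance_um) & distance_um < max_touch] <- "touching"
  out[!is.na(distance_um) & distance_um >= max_touch &
        distance_um < max_near] <- "near"
  out
}

#' Build the proximity table for typed cells across fields
#'
#' Splits cells by field, finds each query cell's nearest neutrophil
#' (type == "neutrophil"), and assigns Touching/Near/excluded categories.
#' Query cells default to CD8+ cells; set `query_type` to analyse another
#' group (e.g. CD8-negative cells for the contact comparison).
#'
#' @param cells data.frame with `cell_id`, `patient_id`, `field_id`,
#'   `x_um`, `y_um`, `type` and a GZMK intensity column.
#' @param query_type cell type analysed against neutrophils.
#' @param gzmk_col name of the GZMK band mean-intensity column.
#' @param max_touch,max_near category cutoffs in microns.
#' @return proximity data.frame: one row per query cell with
#'   `nearest_neutrophil_id`, `distance_um`, `category`, `gzmk_mean`.
#' @export
proximity_table <- function(cells, query_type = "cd8",
                            gzmk_col = "mean_farred",
                            max_touch = 10, max_near = 20) {
  stopifnot(gzmk_col %in% names(cells))
  by_field <- split(cells, interaction(cells$patient_id, cells$field_id,
                                       drop = TRUE))
  out <- do.call(rbind, lapply(by_field, function(fc) {
    q <- fc[fc$type == query_type, , drop = FALSE]
    nn <- fc[fc$type == "neutrophil", , drop = FALSE]
    nearest_neutrophil(q, nn)
  }))
  rownames(out) <- NULL
  out$category <- categorize_distance(out$distance_um, max_touch, max_near)
  out$gzmk_mean <- out[[gzmk_col]]
  out
}

# pooled-variance (classical) or Welch unpaired two-tailed t test,
# implemented in closed form; cross-checked against stats::t.test in tests
two_group_t <- function(x, y, var_equal = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 values")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       mean_x = mx, mean_y = my, sd_x = sqrt(vx), sd_y = sqrt(vy),
       n_x = nx, n_y = ny)
}

#' Compare GZMK in CD8+ vs CD8-negative cells close to neutrophils
#'
#' Restricts both groups to cells whose nearest-neutrophil distance is
#' below `max_touch` (default 10 um) and compares their GZMK band mean
#' intensities with an unpaired two-tailed t test (classical
#' pooled-variance by default; Welch via `var_equal = FALSE`).
#'
#' @param cd8_prox proximity table for CD8+ cells ([proximity_table()]).
#' @param noncd8_prox proximity table for the CD8-negative comparison
#'   group.
#' @param max_touch pairing cutoff in microns.
#' @param var_equal classical pooled t (TRUE) or Welch (FALSE).
#' @return list with per-group n/mean/sd, `t`, `df`, `p`.
#' @export
contact_comparison_cd8_vs_noncd8 <- function(cd8_prox, noncd8_prox,
                                             max_touch = 10,
                                             var_equal = TRUE) {
  g1 <- cd8_prox$gzmk_mean[!is.na(cd8_prox$distance_um) &
                             cd8_prox$distance_um < max_touch]
  g2 <- noncd8_prox$gzmk_mean[!is.na(noncd8_prox$distance_um) &
                                noncd8_prox$distance_um < max_touch]
  if (length(g1) == 0) stop("no CD8+ cells within ", max_touch,
                            " um of a neutrophil")
  if (length(g2) == 0) stop("no CD8-negative cells within ", max_touch,
                            " um of a neutrophil")
  tt <- two_group_t(g1, g2, var_equal)
  list(group = c("cd8", "non_cd8"),
       n = c(tt$n_x, tt$n_y), mean = c(tt$mean_x, tt$mean_y),
       sd = c(tt$sd_x, tt$sd_y),
       mean_ratio = tt$mean_x / tt$mean_y,
       t = tt$t, df = tt$df, p = tt$p)
}

#' Normalize GZMK per patient to the Near-category mean
#'
#' Each cell's GZMK intensity is divided by the mean GZMK intensity of the
#' Near-category cells of the same patient, so the Near-category mean of
#' the normalized values is exactly 1 for every patient. Patients without
#' Near cells cannot be normalized: their rows get `gzmk_norm = NA` and a
#' warning is emitted.
#'
#' @param prox proximity table with `patient_id`, `category`, `gzmk_mean`.
#' @return `prox` with an added `gzmk_norm` column.
#' @export
normalize_per_patient <- function(prox) {
  stopifnot(all(c("patient_id", "category", "gzmk_mean") %in% names(prox)))
  prox$gzmk_norm <- NA_real_
  for (p in unique(prox$patient_id)) {
    sel <- prox$patient_id == p
    near <- sel & prox$category == "near"
    if (!any(near)) {
      warning("patient ", p, " has no Near-category cells; ",
              "excluded from normalized analysis")
      next
    }
    prox$gzmk_norm[sel] <- prox$gzmk_mean[sel] / mean(prox$gzmk_mean[near])
  }
  prox
}

#' Compare normalized GZMK between Touching and Near cells
#'
#' Pools normalized cells across patients and applies the unpaired
#' two-tailed t test between the Touching and Near categories.
#'
#' @param prox normalized proximity table ([normalize_per_patient()]).
#' @param var_equal classical pooled t (TRUE) or Welch (FALSE).
#' @return list with per-category n/mean/sd, the Touching/Near mean ratio,
#'   `t`, `df`, `p`.
#' @export
touching_vs_near <- function(prox, var_equal = TRUE) {
  ok <- !is.na(prox$gzmk_norm)
  tv <- prox$gzmk_norm[ok & prox$category == "touching"]
  nv <- prox$gzmk_norm[ok & prox$category == "near"]
  if (length(tv) == 0) stop("no Touching-category cells after normalization")
  if (length(nv) == 0) stop("no Near-category cells after normalization")
  tt <- two_group_t(tv, nv, var_equal)
  list(category = c("touching", "near"),
       n = c(tt$n_x, tt$n_y), mean = c(tt$mean_x, tt$mean_y),
       sd = c(tt$sd_x, tt$sd_y),
       mean_ratio = tt$mean_x / tt$mean_y,
       t = tt$t, df = tt$df, p = tt$p)
}
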