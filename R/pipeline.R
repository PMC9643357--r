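#' Load and validate a pipeline configuration
#'
#' Accepts a list, a JSON file, or a YAML file (YAML requires the `yaml`
#' package). Unknown fields are kept; missing fields fall back to defaults.
#'
#' @param config list or path to a JSON/YAML config file.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs need the 'yaml' package; use JSON instead")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- list(
    seed = 1L,
    out_dir = "periband_out",
    simulate = NULL,      # list(n_patients, n_fields_per_patient, spec = ...)
    fields = NULL,        # character vector of field directories
    band = list(band_width_um = 1, mode = "ring"),
    classify = list(cd8_rid_threshold = "auto",
                    cd66b_rid_threshold = "auto",
                    autofluor_quantile = 0.99,
                    ratio_green_over_red_min = 4,
                    ratio_red_over_green_min = 2),
    proximity = list(max_touch = 10, max_near = 20),
    drop_clipped = FALSE)
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$simulate) && is.null(cfg$fields))
    stop("config must provide either 'simulate' or 'fields'")
  if (!is.null(cfg$fields)) {
    missing <- cfg$fields[!dir.exists(cfg$fields)]
    if (length(missing))
      stop("field directory does not exist: ",
           paste(missing, collapse = ", "))
  }
  pr <- cfg$proximity
  if (pr$max_touch <= 0 || pr$max_near <= 0 || pr$max_touch >= pr$max_near)
    stop("proximity cutoffs must satisfy 0 < max_touch < max_near (got ",
         pr$max_touch, ", ", pr$max_near, ")")
  if (cfg$band$band_width_um <= 0) stop("band width must be positive")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# analyse one field: band, quantify, classify; returns the cell table
analyze_field <- function(field, labels, cfg, truth = NULL) {
  bp <- band_params(cfg$band$band_width_um, cfg$band$mode)
  band <- make_band_mask(labels, bp, field$pixel_size_um)
  geom <- cell_geometry(labels, field$pixel_size_um)
  feats <- quantify_cells(field, band, geometry = geom,
                          expected_ids = geom$cell_id)
  if (!is.null(truth))
    feats$true_type <- truth$type[match(feats$cell_id, truth$cell_id)]
  feats
}

# per-patient CD8/CD66b threshold calibration from autofluorescence-only
# cells (ground-truth 'other' cells in simulation mode)
calibrate_patient_thresholds <- function(cells, cl) {
  cfg_out <- list()
  for (p in unique(cells$patient_id)) {
    sub <- cells[cells$patient_id == p, , drop = FALSE]
    neg <- sub[!is.na(sub$true_type) & sub$true_type == "other", ,
               drop = FALSE]
    cd8_thr <- if (identical(cl$cd8_rid_threshold, "auto"))
      calibrate_threshold(neg$rid_green, cl$autofluor_quantile)
    else cl$cd8_rid_threshold
    cd66b_thr <- if (identical(cl$cd66b_rid_threshold, "auto"))
      calibrate_threshold(neg$rid_red, cl$autofluor_quantile)
    else cl$cd66b_rid_threshold
    cfg_out[[p]] <- classifier_config(
      cd8_rid_threshold = cd8_thr,
      cd66b_rid_threshold = cd66b_thr,
      ratio_green_over_red_min = cl$ratio_green_over_red_min,
      ratio_red_over_green_min = cl$ratio_red_over_green_min,
      autofluor_quantile = cl$autofluor_quantile)
  }
  cfg_out
}

#' Run the full quantification and proximity pipeline
#'
#' simulate (or ingest) -> band mask -> per-cell quantification ->
#' positivity calls -> nearest-neutrophil proximity -> per-patient
#' normalization -> Touching-vs-Near and CD8-vs-non-CD8 comparisons.
#' Writes `cells.csv`, `proximity.csv`, `summary.json` and `manifest.json`
#' into the output directory; rerunning with the same config and seed
#' reproduces identical tables.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @param write_images in simulation mode, also write each simulated field
#'   bundle (TIFFs + metadata + truth) under the output directory.
#' @return list with `cells`, `proximity`, `summary`, `thresholds`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config, write_images = FALSE) {
  cfg <- pipeline_config(if (inherits(config, "pipeline_config"))
    unclass(config) else config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  cells <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    spec <- do.call(tissue_spec, c(sim$spec %||% list(),
                                   list(seed = cfg$seed)))
    n_pat <- sim$n_patients %||% 1L
    n_fld <- sim$n_fields_per_patient %||% 1L
    k <- 0L
    for (p in seq_len(n_pat)) {
      for (f in seq_len(n_fld)) {
        k <- k + 1L
        pid <- sprintf("P%02d", p)
        fid <- sprintf("F%02d", f)
        sim_field <- render_field(spec, seed = cfg$seed + 1000L * k,
                                  patient_id = pid, field_id = fid)
        if (write_images)
          write_field(sim_field$field,
                      file.path(cfg$out_dir, paste0(pid, "_", fid)),
                      labels = sim_field$labels, truth = sim_field$truth)
        feats <- analyze_field(sim_field$field, sim_field$labels, cfg,
                               truth = sim_field$truth)
        cells <- rbind(cells, feats)
      }
    }
  } else {
    for (d in cfg$fields) {
      fr <- read_field(d)
      if (is.null(fr$labels))
        stop("field ", d, " has no label mask (labels.tif); ",
             "external segmentation is required")
      truth_path <- file.path(d, "truth.csv")
      truth <- if (file.exists(truth_path)) read.csv(truth_path) else NULL
      feats <- analyze_field(fr$field, fr$labels, cfg, truth = truth)
      cells <- rbind(cells, feats)
    }
  }
  if (is.null(cells$true_type)) cells$true_type <- NA_character_
  if (cfg$drop_clipped) cells <- cells[!cells$clipped, , drop = FALSE]

  thresholds <- calibrate_patient_thresholds(cells, cfg$classify)
  classified <- do.call(rbind, lapply(split(cells, cells$patient_id),
    function(sub) classify_cells(sub, thresholds[[sub$patient_id[1]]])))
  rownames(classified) <- NULL
  classified <- classified[order(classified$patient_id,
                                 classified$field_id,
                                 classified$cell_id), , drop = FALSE]

  pr <- cfg$proximity
  prox <- proximity_table(classified, query_type = "cd8",
                          max_touch = pr$max_touch, max_near = pr$max_near)
  prox <- normalize_per_patient(prox)
  summary <- list(
    n_cells = nrow(classified),
    n_cd8 = sum(classified$cd8_positive),
    n_neutrophil = sum(classified$type == "neutrophil"),
    category_counts = as.list(table(prox$category)))
  summary$touching_vs_near <- tryCatch(touching_vs_near(prox),
                                       error = function(e) conditionMessage(e))
  noncd8 <- proximity_table(classified, query_type = "other",
                            max_touch = pr$max_touch, max_near = pr$max_near)
  summary$cd8_vs_noncd8 <- tryCatch(
    contact_comparison_cd8_vs_noncd8(prox, noncd8, pr$max_touch),
    error = function(e) conditionMessage(e))

  write.csv(classified, file.path(cfg$out_dir, "cells.csv"),
            row.names = FALSE)
  write.csv(prox, file.path(cfg$out_dir, "proximity.csv"),
            row.names = FALSE)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(config_hash = config_hash(cfg),
                   seed = cfg$seed,
                   package_version =
                     as.character(utils::packageVersion("periband")),
                   n_cells = nrow(classified))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  list(cells = classified, proximity = prox, summary = summary,
       thresholds = thresholds, out_dir = cfg$out_dir)
}

# md5 of the canonical JSON serialization of the config
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
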