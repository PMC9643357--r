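# Stated validation worlds: fixed simulation conditions used by the
# acceptance tests and by scripts/acceptance.R. Parameters are part of the
# package's stated world (cell numbers per field, contact fold 2, pixel
# noise at 20% of the GZMK baseline) and are not tuning knobs.

#' Simulation world for the parameter-recovery study
#'
#' One field of view: 300 x 300 um at 0.32 um pixels carrying 400 nuclei
#' (150 CD8+, 150 CD66b+ neutrophils, 100 autofluorescence-only cells), a
#' contact-dependent GZMK fold of `gzmk_contact_fold` within 10 um, pixel
#' noise sd equal to 20% of the GZMK baseline, and 5% autofluorescence.
#'
#' @param seed simulation seed.
#' @param gzmk_contact_fold contact effect size (2 for recovery, 1 for the
#'   null calibration).
#' @return a [tissue_spec()].
#' @export
validation_spec <- function(seed = 1L, gzmk_contact_fold = 2) {
  tissue_spec(field_size_um = c(300, 300), pixel_size_um = 0.32,
              n_cells = 400, fraction_cd8 = 0.375,
              fraction_neutrophil = 0.375,
              gzmk_base = 100, gzmk_contact_fold = gzmk_contact_fold,
              contact_radius_um = 10,
              noise_sd = 20, autofluorescence_level = 5, n_rbc = 0,
              seed = as.integer(seed))
}

#' Parameter-recovery study on fully rendered fields
#'
#' Simulates a cohort of `n_patients * n_fields_per_patient` fields under
#' [validation_spec()], runs the complete image pipeline (band mask,
#' quantification, per-patient threshold calibration, classification,
#' nearest-neutrophil proximity, per-patient Near normalization) and
#' returns the pooled Touching/Near comparison of normalized GZMK.
#'
#' @param seed study seed.
#' @param n_patients,n_fields_per_patient cohort layout (default 5 x 4 = 20
#'   fields).
#' @return list: the [touching_vs_near()] result plus category counts.
#' @export
run_parameter_recovery <- function(seed = 1L, n_patients = 5L,
                                   n_fields_per_patient = 4L) {
  cfg <- list(seed = as.integer(seed),
              out_dir = file.path(tempdir(), paste0("periband_rec_", seed)),
              simulate = list(
                n_patients = n_patients,
                n_fields_per_patient = n_fields_per_patient,
                spec = list(field_size_um = c(300, 300),
                            pixel_size_um = 0.32, n_cells = 400,
                            fraction_cd8 = 0.375,
                            fraction_neutrophil = 0.375,
                            gzmk_base = 100, gzmk_contact_fold = 2,
                            contact_radius_um = 10,
                            noise_sd = 20, autofluorescence_level = 5,
                            n_rbc = 0)))
  res <- run_pipeline(cfg)
  out <- res$summary$touching_vs_near
  if (!is.list(out)) stop("touching-vs-near comparison failed: ", out)
  out$category_counts <- res$summary$category_counts
  out
}

#' Null calibration of the Touching-vs-Near test
#'
#' Simulates `n_cohorts` independent cohorts under [validation_spec()] with
#' contact fold 1 (no effect) at the placement level
#' ([simulate_truth_field()]), runs the per-patient normalization and the
#' pooled-variance t test on each, and counts rejections at `alpha`.
#'
#' @param seed study seed.
#' @param n_cohorts number of replicate cohorts.
#' @param n_patients,n_fields_per_patient cohort layout.
#' @param alpha nominal test level.
#' @return list with `n_cohorts`, `n_reject`, `rejection_rate`.
#' @export
run_null_calibration <- function(seed = 1L, n_cohorts = 200L,
                                 n_patients = 5L,
                                 n_fields_per_patient = 4L, alpha = 0.05) {
  spec <- validation_spec(seed, gzmk_contact_fold = 1)
  reject <- logical(n_cohorts)
  k <- 0L
  for (r in seq_len(n_cohorts)) {
    rows <- vector("list", n_patients * n_fields_per_patient)
    for (p in seq_len(n_patients)) {
      for (f in seq_len(n_fields_per_patient)) {
        k <- k + 1L
        rows[[(p - 1L) * n_fields_per_patient + f]] <-
          simulate_truth_field(spec, seed = as.integer(seed) + 17L * k,
                               patient_id = sprintf("P%02d", p),
                               field_id = sprintf("F%02d", f))
      }
    }
    truth <- do.call(rbind, rows)
    cd8 <- truth[truth$type == "cd8", , drop = FALSE]
    cd8$distance_um <- cd8$true_nearest_neutrophil_distance_um
    cd8$category <- categorize_distance(cd8$distance_um)
    cd8 <- suppressWarnings(normalize_per_patient(cd8))
    reject[r] <- touching_vs_near(cd8)$p < alpha
  }
  list(n_cohorts = n_cohorts, n_reject = sum(reject),
       rejection_rate = mean(reject))
}

#' Classification recovery against simulated ground truth
#'
#' Renders one [validation_spec()]-sized field either noiseless or with
#' pixel noise at one fifth of the class separation (marker emission 100 vs
#' autofluorescence baseline), calibrates thresholds on the true
#' autofluorescence-only cells, classifies every cell, and reports the
#' agreement with the simulator's true types.
#'
#' @param seed simulation seed.
#' @param noise_sd pixel noise sd (0 = noiseless; 19 = one fifth of the
#'   95-intensity class separation).
#' @return list with `accuracy`, `n_cells`.
#' @export
run_classification_recovery <- function(seed = 1L, noise_sd = 0) {
  spec <- tissue_spec(field_size_um = c(300, 300), pixel_size_um = 0.32,
                      n_cells = 400, fraction_cd8 = 0.375,
                      fraction_neutrophil = 0.375,
                      gzmk_base = 100, gzmk_contact_fold = 2,
                      noise_sd = noise_sd, autofluorescence_level = 5,
                      n_rbc = 0, seed = as.integer(seed))
  sim <- render_field(spec, seed = as.integer(seed))
  band <- make_band_mask(sim$labels,
                         band_params(spec$band_width_um, "ring"),
                         spec$pixel_size_um)
  feats <- quantify_cells(sim$field, band)
  truth_type <- sim$truth$type[match(feats$cell_id, sim$truth$cell_id)]
  neg <- feats[truth_type == "other", , drop = FALSE]
  cfg <- classifier_config(
    cd8_rid_threshold = calibrate_threshold(neg$rid_green),
    cd66b_rid_threshold = calibrate_threshold(neg$rid_red))
  cl <- classify_cells(feats, cfg)
  list(accuracy = mean(cl$type == truth_type), n_cells = nrow(cl))
}
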