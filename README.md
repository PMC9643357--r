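# periband

Per-cell quantification of multiplex immunofluorescence tissue images and
spatial analysis of immune cell contacts, built around the question: does a
CD8+ T cell's granzyme K (GZMK) content depend on how close the cell sits to
a CD66b+ neutrophil?

`periband` is aimed at image analysts working on tissue microscopy of the
tumor microenvironment. It implements, as a tested and reusable R pipeline:

- **Peri-nuclear band quantification.** Starting from an integer nucleus
  label mask (from any external segmenter, or the built-in Otsu reference
  segmenter for synthetic images), marker fluorescence is measured in a band
  of thickness 1 µm around each nucleus (ring mode), or over a 1 µm
  whole-cell expansion (expansion mode). For each cell and channel the two
  standard features are reported: *mean intensity* (average pixel value) and
  *raw integrated density* (RID, the pixel sum; RID = mean × n pixels).
- **Calibrated marker positivity with erythrocyte corrections.** A cell is
  CD8+ iff its green RID exceeds a threshold calibrated on
  autofluorescence-only cells (empirical quantile, default 0.99, per
  patient) *and* its green/red RID ratio is strictly greater than 4;
  CD66b+ mirrors this with red/green > 2. Red blood cells fluoresce in
  several channels, which is what the ratio rules remove. An area-based
  pixel-classifier rule (positive area > 3 µm² over the cell expansion) is
  provided for the αSMA workflow, together with the discard rule for cells
  whose expansion has classifier-positive area > 0 simultaneously in green,
  red and far-red.
- **Nearest-neutrophil proximity.** Per field of view, each CD8+ cell gets
  the centroid-to-centroid distance to its nearest CD66b+ cell (a min
  filter over all pairwise distances; never across fields). Cells are
  binned as **Touching** (< 10 µm) or **Near** (10–20 µm); each cell's GZMK
  intensity is normalized to the mean GZMK of that patient's Near cells, so
  the Near mean is 1 per patient; groups are compared with the classical
  unpaired two-tailed pooled-variance t test (Welch optional).
- **Small cytometry / transcriptomics statistics.** Integrated MFI
  (iMFI = MFI × cluster frequency, min–max rescaled 0–100 per marker),
  discarding of under-represented clusters (< 0.5 %), per-cell gene
  signature scores (signature counts / total counts, with an
  80th-percentile emphasis flag), and the cytolytic index
  √(GZMA × PRF1).
- **A synthetic tissue simulator** that renders multi-channel fields
  (dapi/green/red/farred) of disk nuclei of three classes (CD8+,
  neutrophil, other) with membrane-band marker emission, a tunable
  contact-dependent GZMK fold, autofluorescence, erythrocyte artifacts and
  Gaussian noise — with an exact ground-truth table, so every downstream
  stage can be validated against known truth.

Images are multi-page TIFFs (one page per channel); a minimal baseline TIFF
reader/writer is built in (uncompressed little-endian grayscale: uint16,
float32, float64), validated against Python's `tifffile`.

## Worked example

Simulate one field with a contact-dependent GZMK fold of 2 within 10 µm,
quantify the 1 µm band, calibrate thresholds on the autofluorescence-only
cells, classify, and test Touching vs Near:

```r
library(periband)

spec <- tissue_spec(field_size_um = c(200, 200), pixel_size_um = 0.32,
                    n_cells = 150, fraction_cd8 = 0.35,
                    fraction_neutrophil = 0.35, gzmk_base = 100,
                    gzmk_contact_fold = 2, noise_sd = 10, seed = 11)
sim  <- render_field(spec, patient_id = "P01", field_id = "F01")
band <- make_band_mask(sim$labels, band_params(1, "ring"), spec$pixel_size_um)
feats <- quantify_cells(sim$field, band,
                        geometry = cell_geometry(sim$labels, spec$pixel_size_um))

truth_type <- sim$truth$type[match(feats$cell_id, sim$truth$cell_id)]
neg <- feats[truth_type == "other", ]          # autofluorescence-only cells
cfg <- classifier_config(
  cd8_rid_threshold   = calibrate_threshold(neg$rid_green),
  cd66b_rid_threshold = calibrate_threshold(neg$rid_red))
cells <- classify_cells(feats, cfg)
table(cells$type)
#>        cd8 neutrophil      other
#>         53         52         45        # all 150 match the ground truth

prox <- normalize_per_patient(proximity_table(cells))
table(prox$category)
#> excluded     near touching
#>       12       36        5
res <- touching_vs_near(prox)
#> touching/near normalized GZMK ratio 1.953 (t = 296.06, df = 39, p = 5.52e-67)
```

The ratio ≈ 1.95 recovers the simulated fold of 2: Touching CD8+ cells carry
200 + 5 (autofluorescence) intensity units of GZMK on their band against
100 + 5 for Near cells, and 205/105 ≈ 1.95.

The same analysis runs as a configured pipeline
(`run_pipeline(config)`, JSON/YAML config, deterministic for a fixed seed,
with CSV/JSON outputs and a run manifest) or from the command line:

```sh
Rscript inst/exec/periband run --config cfg.json --out out_dir
```

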