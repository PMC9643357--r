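test_that("place_nuclei honors degenerate inputs, determinism and capacity", {
  expect_identical(nrow(place_nuclei(quiet_spec(n_cells = 0))), 0L)

  spec <- quiet_spec(n_cells = 25, field_size_um = c(100, 100))
  a <- place_nuclei(spec, seed = 5)
  b <- place_nuclei(spec, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, place_nuclei(spec, seed = 6)))

  # disks pairwise non-overlapping and fully inside the field
  d <- as.matrix(dist(a[, c("x_um", "y_um")]))
  rr <- outer(a$radius_um, a$radius_um, "+")
  diag(d) <- Inf
  expect_true(all(d > rr))
  expect_true(all(a$x_um - a$radius_um >= 0 & a$x_um + a$radius_um <= 100))
  expect_true(all(a$y_um - a$radius_um >= 0 & a$y_um + a$radius_um <= 100))

  # class counts follow the stated fractions deterministically
  # (0.3 * 25 = 7.5 each; largest-remainder hands the single extra to cd8)
  expect_identical(sum(a$type == "cd8"), 8L)
  expect_identical(sum(a$type == "neutrophil"), 7L)

  expect_error(tissue_spec(n_cells = 500, field_size_um = c(50, 50)),
               "too small")
  expect_error(place_nuclei(quiet_spec(n_cells = 60,
                                       field_size_um = c(130, 130)),
                            max_attempts_per_cell = 1),
               "capacity")
})

test_that("ground-truth nearest-neutrophil distances match the brute oracle", {
  spec <- quiet_spec(n_cells = 60, field_size_um = c(200, 200), seed = 9)
  pl <- place_nuclei(spec)
  truth <- ground_truth_table(pl, spec)
  neut <- pl[pl$type == "neutrophil", ]
  oracle <- brute_nn(pl$x_um, pl$y_um, neut$x_um, neut$y_um, neut$cell_id)
  oracle$distance[match(neut$cell_id, pl$cell_id)] <- vapply(
    seq_len(nrow(neut)), function(j) {
      d <- sqrt((neut$x_um[-j] - neut$x_um[j])^2 +
                (neut$y_um[-j] - neut$y_um[j])^2)
      if (length(d)) min(d) else NA_real_
    }, numeric(1))
  expect_equal(truth$true_nearest_neutrophil_distance_um, oracle$distance)
  expect_identical(truth$is_contact,
                   truth$type == "cd8" &
                     truth$true_nearest_neutrophil_distance_um <=
                       spec$contact_radius_um)
})

test_that("null effect and neutrophil-free worlds behave as stated", {
  spec <- quiet_spec(gzmk_contact_fold = 1, seed = 3)
  truth <- ground_truth_table(place_nuclei(spec), spec)
  cd8 <- truth[truth$type == "cd8", ]
  expect_true(length(unique(cd8$true_gzmk_emission)) == 1)

  spec0 <- quiet_spec(fraction_neutrophil = 0, seed = 3)
  truth0 <- ground_truth_table(place_nuclei(spec0), spec0)
  expect_false(any(truth0$is_contact))
  expect_true(all(is.na(truth0$true_nearest_neutrophil_distance_um)))
})

test_that("rendering is deterministic and noiseless annuli carry the exact emissions", {
  spec <- quiet_spec(n_cells = 18, field_size_um = c(150, 150), seed = 21)
  s1 <- render_field(spec)
  s2 <- render_field(spec)
  expect_identical(s1$field$channels, s2$field$channels)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$truth, s2$truth)

  # hand placement far apart: annulus pixel values equal the specified emissions
  pl <- data.frame(cell_id = 1:3, x_um = c(20, 60, 100),
                   y_um = c(20, 60, 100), radius_um = 3,
                   type = c("cd8", "neutrophil", "other"))
  sim <- render_field(quiet_spec(n_cells = 3, field_size_um = c(120, 120)),
                      placement = pl)
  band <- make_band_mask(sim$labels, band_params(1, "ring"),
                         spec$pixel_size_um)
  for (id in 1:3) {
    px_green <- sim$field$channels$green[band == id]
    px_red <- sim$field$channels$red[band == id]
    px_far <- sim$field$channels$farred[band == id]
    want <- switch(pl$type[id],
                   cd8 = c(100, 0, spec$gzmk_base),
                   neutrophil = c(0, 100, 0),
                   other = c(0, 0, 0))
    expect_identical(unique(px_green), want[1])
    expect_identical(unique(px_red), want[2])
    expect_identical(unique(px_far), want[3])
  }
  # dapi confined to nucleus disks
  expect_true(all(sim$field$channels$dapi[sim$labels == 0] == 0))
  expect_true(all(sim$field$channels$dapi[sim$labels > 0] > 0))
})

test_that("measured contact/non-contact GZMK ratio recovers the fold at zero noise", {
  spec <- quiet_spec(n_cells = 40, field_size_um = c(300, 300),
                     fraction_cd8 = 0.4, fraction_neutrophil = 0.4,
                     gzmk_contact_fold = 2, seed = 14)
  sim <- render_field(spec)
  band <- make_band_mask(sim$labels, band_params(1, "ring"),
                         spec$pixel_size_um)
  feats <- quantify_cells(sim$field, band)
  m <- merge(feats, sim$truth, by = "cell_id")
  cd8 <- m[m$type == "cd8" &
             !is.na(m$true_nearest_neutrophil_distance_um), ]
  contact <- cd8$mean_farred[cd8$is_contact]
  free <- cd8$mean_farred[!cd8$is_contact]
  expect_gt(length(contact), 0)
  expect_gt(length(free), 0)
  expect_equal(mean(contact) / mean(free), spec$gzmk_contact_fold,
               tolerance = 0.01)
})

test_that("erythrocyte disks stain their channels but never the label mask", {
  spec <- quiet_spec(n_cells = 5, field_size_um = c(100, 100), n_rbc = 4,
                     seed = 8)
  sim <- render_field(spec)
  n_lab <- length(unique(sim$labels[sim$labels > 0]))
  expect_identical(n_lab, 5L)
  # rbc adds green where no cell annulus exists
  rbc_px <- sim$field$channels$green >=
    unname(spec$rbc_intensity["green"])
  expect_gt(sum(rbc_px), 0)
})
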