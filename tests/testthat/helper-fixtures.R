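# shared fixtures: deterministic specs, noiseless emissions, brute oracles

# marker emissions with zero cell-to-cell spread (exact expectations)
exact_intensities <- function(cd8_green = 100, neut_red = 100) {
  list(cd8        = list(green = c(cd8_green, 0), red = c(0, 0),
                         farred = c(0, 0)),
       neutrophil = list(green = c(0, 0), red = c(neut_red, 0),
                         farred = c(0, 0)),
       other      = list(green = c(0, 0), red = c(0, 0), farred = c(0, 0)))
}

quiet_spec <- function(...) {
  args <- modifyList(
    list(field_size_um = c(120, 120), pixel_size_um = 0.32, n_cells = 40,
         fraction_cd8 = 0.3, fraction_neutrophil = 0.3,
         marker_intensity = exact_intensities(),
         dapi_intensity = c(200, 0),
         autofluorescence_level = 0, noise_sd = 0, n_rbc = 0, seed = 42),
    list(...))
  do.call(tissue_spec, args)
}

# independent O(n^2) scalar-loop nearest-neighbor oracle
brute_nn <- function(qx, qy, nx, ny, nid) {
  out_d <- numeric(length(qx))
  out_i <- integer(length(qx))
  for (i in seq_along(qx)) {
    best <- Inf
    bid <- NA_integer_
    for (j in seq_along(nx)) {
      d <- sqrt((qx[i] - nx[j])^2 + (qy[i] - ny[j])^2)
      if (d < best || (d == best && nid[j] < bid)) {
        best <- d
        bid <- nid[j]
      }
    }
    out_d[i] <- best
    out_i[i] <- bid
  }
  list(distance = out_d, id = out_i)
}

# disk label mask drawn directly (independent of the simulator's painter)
disk_mask <- function(dim_px, px, cx, cy, r, label = 1L) {
  m <- matrix(0L, dim_px[1], dim_px[2])
  for (i in seq_len(dim_px[1])) {
    for (j in seq_len(dim_px[2])) {
      x <- (j - 0.5) * px
      y <- (i - 0.5) * px
      if ((x - cx)^2 + (y - cy)^2 <= r^2) m[i, j] <- label
    }
  }
  m
}

toy_field <- function(channels, px = 1, patient = "P1", field = "F1") {
  multichannel_field(channels, pixel_size_um = px,
                     patient_id = patient, field_id = field)
}
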