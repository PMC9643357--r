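cells_df <- function(x, y, id = seq_along(x), type = "cd8",
                     patient = "P1", field = "F1", gzmk = 1) {
  data.frame(cell_id = id, patient_id = patient, field_id = field,
             x_um = x, y_um = y, type = type, mean_farred = gzmk,
             stringsAsFactors = FALSE)
}

test_that("nearest neutrophil: geometry, absence, and the O(n^2) oracle", {
  q <- cells_df(0, 0, id = 1L)
  nn <- cells_df(c(5, 30), 0, id = c(10L, 11L), type = "neutrophil")
  out <- nearest_neutrophil(q, nn)
  expect_equal(out$distance_um, 5)
  expect_identical(out$nearest_neutrophil_id, 10L)

  none <- nearest_neutrophil(q, nn[0, ])
  expect_true(is.na(none$distance_um))

  set.seed(31)
  q2 <- cells_df(runif(120, 0, 300), runif(120, 0, 300), id = 1:120)
  n2 <- cells_df(runif(80, 0, 300), runif(80, 0, 300), id = 201:280,
                 type = "neutrophil")
  got <- nearest_neutrophil(q2, n2)
  oracle <- brute_nn(q2$x_um, q2$y_um, n2$x_um, n2$y_um, n2$cell_id)
  expect_equal(got$distance_um, oracle$distance)
  expect_identical(got$nearest_neutrophil_id, oracle$id)
})

test_that("distance categories use <10 and [10, 20) half-open windows", {
  expect_identical(categorize_distance(c(5, 15, 25)),
                   c("touching", "near", "excluded"))
  expect_identical(categorize_distance(c(9.99, 10, 19.999, 20, NA)),
                   c("touching", "near", "near", "excluded", "excluded"))
  expect_error(categorize_distance(-1), ">= 0")
  expect_error(categorize_distance(5, max_touch = 20, max_near = 10),
               "max_touch")
})

test_that("distances are rigid-motion invariant and scale linearly", {
  set.seed(12)
  q <- cells_df(runif(40, 0, 100), runif(40, 0, 100), 1:40)
  nn <- cells_df(runif(25, 0, 100), runif(25, 0, 100), 101:125,
                 type = "neutrophil")
  base <- nearest_neutrophil(q, nn)$distance_um
  th <- 0.7
  rot <- function(df) {
    x <- df$x_um * cos(th) - df$y_um * sin(th) + 13
    y <- df$x_um * sin(th) + df$y_um * cos(th) - 4
    df$x_um <- x; df$y_um <- y; df
  }
  expect_equal(nearest_neutrophil(rot(q), rot(nn))$distance_um, base)
  sc <- function(df) { df$x_um <- 3 * df$x_um; df$y_um <- 3 * df$y_um; df }
  expect_equal(nearest_neutrophil(sc(q), sc(nn))$distance_um, 3 * base)
})

test_that("proximity never pairs across fields and categories partition cells", {
  q <- rbind(cells_df(0, 0, 1L, field = "F1", gzmk = 2),
             cells_df(0, 0, 2L, field = "F2", gzmk = 2))
  nn <- cells_df(3, 0, 3L, type = "neutrophil", field = "F2")
  tab <- proximity_table(rbind(q, nn))
  f1 <- tab[tab$field_id == "F1", ]
  expect_true(is.na(f1$distance_um))
  expect_identical(f1$category, "excluded")
  expect_equal(tab$distance_um[tab$field_id == "F2"], 3)

  # same field label under different patients must not pool either
  qa <- cells_df(0, 0, 1L, patient = "PA", field = "F1", gzmk = 2)
  nb <- cells_df(1, 0, 2L, type = "neutrophil", patient = "PB",
                 field = "F1")
  tab3 <- proximity_table(rbind(qa, nb))
  expect_true(is.na(tab3$distance_um[tab3$patient_id == "PA"]))

  set.seed(7)
  mixed <- cells_df(runif(90, 0, 150), runif(90, 0, 150), 1:90,
                    type = sample(c("cd8", "neutrophil", "other"), 90, TRUE))
  tab2 <- proximity_table(mixed)
  expect_identical(nrow(tab2), sum(mixed$type == "cd8"))
  expect_identical(sum(table(tab2$category)), nrow(tab2))
})

test_that("pooled and Welch t statistics agree with stats::t.test", {
  x <- c(12.1, 9.8, 11.4, 10.2, 13.0)
  y <- c(8.4, 9.9, 7.7, 10.6, 8.8)
  got <- periband:::two_group_t(x, y, var_equal = TRUE)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  gotw <- periband:::two_group_t(x, y, var_equal = FALSE)
  refw <- t.test(x, y)
  expect_equal(gotw$t, unname(refw$statistic))
  expect_equal(gotw$df, unname(refw$parameter))
  expect_equal(gotw$p, refw$p.value)
})

test_that("CD8 vs non-CD8 contact comparison behaves at the null and the noiseless fold", {
  set.seed(9)
  mk_prox <- function(n, gz, type) {
    df <- cells_df(runif(n), runif(n), seq_len(n), type = type, gzmk = gz)
    df$distance_um <- runif(n, 0, 9)
    df$gzmk_mean <- gz
    df
  }
  null <- contact_comparison_cd8_vs_noncd8(
    mk_prox(400, rnorm(400, 10), "cd8"),
    mk_prox(400, rnorm(400, 10), "other"))
  expect_lt(abs(null$t), 2.5)
  expect_gt(null$p, 0.01)

  fold <- contact_comparison_cd8_vs_noncd8(
    mk_prox(50, 200, "cd8"), mk_prox(50, 100, "other"))
  expect_equal(fold$mean_ratio, 2)

  far <- mk_prox(10, 100, "other")
  far$distance_um <- 50
  expect_error(contact_comparison_cd8_vs_noncd8(mk_prox(10, 1, "cd8"), far),
               "CD8-negative")
})

test_that("per-patient normalization pins the Near mean at exactly 1", {
  prox <- data.frame(patient_id = c("A", "A", "A", "B", "B"),
                     category = c("near", "near", "touching", "near",
                                  "touching"),
                     gzmk_mean = c(2, 4, 6, 10, 5))
  out <- normalize_per_patient(prox)
  expect_equal(out$gzmk_norm, c(2 / 3, 4 / 3, 2, 1, 0.5))
  expect_equal(mean(out$gzmk_norm[out$patient_id == "A" &
                                    out$category == "near"]), 1)

  allsame <- data.frame(patient_id = "A", category = rep("near", 4),
                        gzmk_mean = 7)
  expect_equal(normalize_per_patient(allsame)$gzmk_norm, rep(1, 4))

  nonear <- data.frame(patient_id = c("A", "B"),
                       category = c("near", "touching"),
                       gzmk_mean = c(1, 2))
  expect_warning(out2 <- normalize_per_patient(nonear), "no Near")
  expect_true(is.na(out2$gzmk_norm[out2$patient_id == "B"]))
})

test_that("touching vs near recovers a noiseless fold and rejects empty input", {
  prox <- data.frame(patient_id = rep(c("A", "B"), each = 6),
                     category = rep(c("touching", "near", "near"), 4),
                     gzmk_mean = rep(c(8, 4, 4, 20, 10, 10), 2))
  out <- touching_vs_near(normalize_per_patient(prox))
  expect_equal(out$mean_ratio, 2)

  only_near <- data.frame(patient_id = "A", category = rep("near", 3),
                          gzmk_mean = 1:3)
  expect_error(touching_vs_near(normalize_per_patient(only_near)),
               "Touching")
})
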