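test_that("threshold calibration is the interpolated quantile of negatives", {
  expect_equal(calibrate_threshold(rep(5, 30)), 5)
  # brute-force type-7 quantile of 1..100 at p = 0.99:
  # h = (n-1)p + 1 = 99.01 -> x[99] + 0.01 * (x[100] - x[99]) = 99.01
  expect_equal(calibrate_threshold(1:100, 0.99), 99.01)
  expect_equal(calibrate_threshold(1:100, 0.5), 50.5)
  expect_error(calibrate_threshold(numeric(0)), "manual")
  expect_error(calibrate_threshold(1:5), "manual")
  expect_error(calibrate_threshold(1:100, 1.2), "quantile")
  expect_error(calibrate_threshold(c(1:30, -2)), ">= 0")
})

features_row <- function(rid_green, rid_red, id = 1L) {
  data.frame(cell_id = id, rid_green = rid_green, rid_red = rid_red)
}

test_that("CD8 rule: green threshold and strict green/red > 4", {
  cfg <- classifier_config(cd8_rid_threshold = 10)
  call <- classify_cd8(features_row(50, 10), cfg)      # ratio 5
  expect_true(call$positive)
  expect_identical(call$reason, "pass")
  expect_false(classify_cd8(features_row(40, 10), cfg)$positive)  # ratio 4
  expect_identical(classify_cd8(features_row(40, 10), cfg)$reason,
                   "ratio_fail")
  low <- classify_cd8(features_row(5, 0.5), cfg)       # ratio 10, below thr
  expect_false(low$positive)
  expect_identical(low$reason, "below_threshold")
  expect_true(classify_cd8(features_row(50, 0), cfg)$positive)  # ratio +Inf
  # threshold is strict: rid exactly at threshold is negative
  expect_false(classify_cd8(features_row(10, 1), cfg)$positive)
})

test_that("CD66b rule mirrors CD8 with red/green > 2", {
  cfg <- classifier_config(cd66b_rid_threshold = 10)
  expect_true(classify_cd66b(features_row(10, 30), cfg)$positive)  # ratio 3
  expect_false(classify_cd66b(features_row(15, 30), cfg)$positive) # ratio 2
  zero <- classify_cd66b(features_row(5, 0), cfg)
  expect_false(zero$positive)
  expect_identical(zero$reason, "below_threshold")
})

test_that("raising the threshold never turns a negative cell positive", {
  set.seed(6)
  feats <- data.frame(cell_id = 1:200,
                      rid_green = rexp(200, 1 / 50),
                      rid_red = rexp(200, 1 / 20))
  thr <- sort(runif(10, 0, 100))
  prev <- rep(TRUE, 200)
  for (t in thr) {
    cur <- classify_cd8(feats, classifier_config(cd8_rid_threshold = t))
    expect_true(all(cur$positive <= prev))
    prev <- cur$positive
  }
  # exactly one reason per call, reasons partition the cells
  call <- classify_cd8(feats, classifier_config(cd8_rid_threshold = 30))
  expect_identical(sum(table(call$reason)), 200L)
  expect_identical(call$positive, call$reason == "pass")
})

test_that("area-based positivity counts classifier pixels times pixel area", {
  px <- 0.32
  img <- matrix(0, 12, 12)
  region <- matrix(0L, 12, 12)
  region[2:7, 2:7] <- 1L          # 36-px expansion region
  img[2:5, 2:6] <- 10             # 20 region pixels above cutoff
  f <- toy_field(list(green = img), px = px)
  cfg <- classifier_config(pixel_classifier_thresholds = list(green = 5))
  call <- classify_area_based(f, region, cfg)
  expect_equal(call$positive_area_um2, 20 * px^2)   # 2.048 um2
  expect_false(call$positive)                       # below the 3 um2 rule
  expect_identical(call$reason, "area_fail")

  # boundary handling with exact pixel areas: px = 0.5 -> 0.25 um2 / px
  img2 <- matrix(0, 12, 12); region2 <- matrix(0L, 12, 12)
  region2[1:5, 1:5] <- 1L
  img2[1:4, 1:3] <- 10            # 12 px -> 3.0 um2 exactly
  f2 <- toy_field(list(green = img2), px = 0.5)
  expect_false(classify_area_based(f2, region2, cfg)$positive)
  img2[5, 1] <- 10                # 13 px -> 3.25 um2
  f3 <- toy_field(list(green = img2), px = 0.5)
  expect_true(classify_area_based(f3, region2, cfg)$positive)
  expect_false(classify_area_based(
    toy_field(list(green = matrix(0, 12, 12)), px = 0.5),
    region2, cfg)$positive)
})

test_that("erythrocyte discard requires positive area in all three channels", {
  px <- 0.5
  region <- matrix(0L, 10, 10)
  region[2:5, 2:5] <- 1L
  region[7:9, 7:9] <- 2L
  mk <- function(cells) {
    img <- matrix(0, 10, 10)
    if (1 %in% cells) img[3, 3] <- 10
    if (2 %in% cells) img[8, 8] <- 10
    img
  }
  cfg <- classifier_config(
    pixel_classifier_thresholds = list(green = 5, red = 5, farred = 5))
  # cell 1 positive in all three -> discarded; cell 2 lacks farred -> kept
  f <- toy_field(list(green = mk(1:2), red = mk(1:2), farred = mk(1)),
                 px = px)
  expect_identical(rbc_overlap_discard(f, region, cfg), 1L)
  blank <- toy_field(list(green = mk(NULL), red = mk(NULL),
                          farred = mk(NULL)), px = px)
  expect_length(rbc_overlap_discard(blank, region, cfg), 0)
  expect_error(rbc_overlap_discard(f, region, classifier_config()), "cover")
})

test_that("classify_cells assigns mutually exclusive types", {
  cfg <- classifier_config(cd8_rid_threshold = 10, cd66b_rid_threshold = 10)
  feats <- data.frame(cell_id = 1:3,
                      rid_green = c(100, 2, 3),
                      rid_red = c(5, 100, 4))
  out <- classify_cells(feats, cfg)
  expect_identical(out$type, c("cd8", "neutrophil", "other"))
  expect_false(any(out$cd8_positive & out$cd66b_positive))
})
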