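test_that("even-width split halves the image and round-trips", {
  img <- const_image(50, 100, c(255, 255, 255))
  img$pixels[, 1:30, ] <- 0L
  halves <- split_image(img)
  expect_equal(dim(halves$left$pixels), c(50, 50, 3))
  expect_equal(dim(halves$right$pixels), c(50, 50, 3))
  glued <- array(0L, dim = c(50, 100, 3))
  glued[, 1:50, ] <- halves$left$pixels
  glued[, 51:100, ] <- halves$right$pixels
  expect_identical(glued, img$pixels)
})

test_that("odd-width split drops the final column", {
  img <- const_image(10, 101, c(0, 0, 0))
  img$pixels[, 101, ] <- 255L   # marker column that must disappear
  halves <- split_image(img)
  expect_equal(dim(halves$left$pixels)[2], 50)
  expect_equal(dim(halves$right$pixels)[2], 50)
  expect_true(all(halves$right$pixels == 0))
  expect_error(split_image(const_image(5, 1, c(0, 0, 0))), "width")
})

test_that("split halves carry half-epoch window metadata", {
  img <- const_image(10, 100, c(255, 255, 255))
  img$meta <- list(start_s = 10, end_s = 20)
  halves <- split_image(img)
  expect_equal(halves$left$meta$start_s, 10)
  expect_equal(halves$left$meta$end_s, 15)
  expect_equal(halves$right$meta$start_s, 15)
  expect_equal(halves$right$meta$end_s, 20)
})

test_that("ictal-content rule keeps ES segments by interval overlap only", {
  ann <- event_annotation("ES", ictal_intervals = list(c(6, 9)),
                          duration_s = 60)
  r <- ictal_content_filter(list(start_s = 5, end_s = 10), ann, 2)
  expect_equal(r$status, "kept")
  expect_equal(r$ictal_overlap_s, 3)

  ann2 <- event_annotation("ES", ictal_intervals = list(c(4, 9)),
                           duration_s = 60)
  r2 <- ictal_content_filter(list(start_s = 0, end_s = 5), ann2, 2)
  expect_equal(r2$status, "dropped_ictal_rule")
  expect_equal(r2$ictal_overlap_s, 1)

  pnes <- event_annotation("PNES", duration_s = 60)
  expect_equal(ictal_content_filter(list(start_s = 0, end_s = 5),
                                    pnes, 2)$status, "kept")
  expect_error(ictal_content_filter(list(start_s = 0, end_s = 5),
                                    NULL, 2), "annotation")
})

test_that("EMG filter sums all channels and applies a strict threshold", {
  cfg <- prep_config(reference_area_px = 224 * 224)
  black <- const_image(224, 224, c(0, 0, 0))
  expect_equal(emg_density_filter(black, cfg)$status, "dropped_emg")
  expect_equal(emg_density_filter(black, cfg)$pixel_sum, 0)

  white <- const_image(224, 224, c(255, 255, 255))
  r <- emg_density_filter(white, cfg)
  expect_equal(r$pixel_sum, 224 * 224 * 3 * 255)   # 38,384,640
  expect_equal(r$status, "kept")
})

test_that("EMG threshold scales with image area", {
  cfg <- prep_config()  # threshold 18e6 at reference area 540000
  img <- const_image(100, 100, c(255, 255, 255))
  r <- emg_density_filter(img, cfg)
  expect_equal(r$threshold, 18e6 * (100 * 100) / 540000)
})

test_that("EMG filter boundary is exact: sum == threshold is kept", {
  cfg <- prep_config(reference_area_px = 224 * 224)  # threshold 18e6 exact
  at <- const_image(224, 224, c(0, 0, 0))
  flat <- at$pixels
  q <- 18e6 %/% 255
  flat[seq_len(q)] <- 255L
  flat[q + 1L] <- as.integer(18e6 %% 255)
  at$pixels <- flat
  expect_equal(sum(at$pixels), 18e6)
  expect_equal(emg_density_filter(at, cfg)$status, "kept")

  below <- at
  below$pixels[q + 1L] <- below$pixels[q + 1L] - 1L
  expect_equal(emg_density_filter(below, cfg)$status, "dropped_emg")
})

test_that("EMG filter is monotone under brightening", {
  set.seed(41)
  # threshold at half the maximum possible sum so random images fall on
  # both sides of it
  cfg <- prep_config(emg_threshold = 50 * 50 * 3 * 255 / 2,
                     reference_area_px = 50 * 50)
  statuses <- character(0)
  for (rep in 1:30) {
    px <- array(sample(0:255, 50 * 50 * 3, replace = TRUE),
                dim = c(50, 50, 3))
    r1 <- emg_density_filter(plot_image(px), cfg)
    brighter <- plot_image(pmin(px + sample(0:60, 1), 255L))
    r2 <- emg_density_filter(brighter, cfg)
    expect_gte(r2$pixel_sum, r1$pixel_sum)
    expect_false(r1$status == "kept" && r2$status == "dropped_emg")
    statuses <- c(statuses, r1$status)
  }
  expect_setequal(unique(statuses), c("kept", "dropped_emg"))
})

test_that("padding centres content on a square canvas of the pad colour", {
  img <- const_image(300, 500, c(0, 0, 0))
  out <- pad_to_square(img, c(255, 0, 0))
  expect_equal(dim(out$pixels), c(500, 500, 3))
  expect_equal(unname(out$pixels[1, 1, ]), c(255L, 0L, 0L))
  expect_equal(unname(out$pixels[500, 500, ]), c(255L, 0L, 0L))
  expect_true(all(out$pixels[101:400, , ] == 0))
  expect_true(all(out$pixels[1:100, , 1] == 255))
  expect_true(all(out$pixels[1:100, , 2] == 0))

  sq <- const_image(64, 64, c(10, 20, 30))
  expect_identical(pad_to_square(sq)$pixels, sq$pixels)
})

test_that("resize-and-normalise maps constants exactly and averages locally", {
  white <- const_image(448, 448, c(255, 255, 255))
  expect_true(all(resize_and_normalize(white, 224) == 1))
  black <- const_image(100, 100, c(0, 0, 0))
  expect_true(all(resize_and_normalize(black, 224) == 0))

  # bilinear interpolation preserves linear images: a horizontal ramp
  # resizes to the same ramp (closed-form oracle)
  ramp <- const_image(448, 448, c(0, 0, 0))
  ramp_vals <- round(seq(0, 255, length.out = 448))
  for (ch in 1:3)
    ramp$pixels[, , ch] <- matrix(rep(ramp_vals, each = 448), 448, 448)
  out <- resize_and_normalize(ramp, 224)
  row <- out[100, , 1]
  expect_true(all(diff(row) >= 0))
  expect_true(all(row[10:214] > 0 & row[10:214] < 1))
  fit <- stats::lm(row[10:214] ~ seq_len(205))
  expect_lt(max(abs(stats::resid(fit))), 0.005)

  expect_error(resize_and_normalize(const_image(10, 20, c(0, 0, 0))),
               "square")
})

test_that("split assignment is event-level, seeded and proportional", {
  ids <- sprintf("E%02d", 1:57)
  all_train <- assign_splits(ids, c(train = 1, validation = 0, test = 0))
  expect_true(all(all_train$split == "train"))

  s1 <- assign_splits(ids, seed = 5)
  s2 <- assign_splits(ids, seed = 5)
  expect_identical(s1, s2)
  # 57 events at 0.6/0.2/0.2 with largest-remainder rounding
  expect_equal(sort(as.vector(table(s1$split))), c(11, 12, 34))
  expect_false(anyDuplicated(s1$event_id) > 0)
  expect_error(assign_splits(ids, c(train = 0.5, validation = 0.2,
                                    test = 0.2)), "sum to 1")
})
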