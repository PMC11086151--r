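test_that("zero-amplitude background is identically zero", {
  cfg <- generator_config(alpha_amp_uv = 0, noise_amp_uv = 0,
                          duration_s = 5)
  rec <- generate_background(cfg)
  expect_equal(max(abs(rec$data)), 0)
  expect_equal(dim(rec$data), c(21L, 5 * 250L))
})

test_that("generator output is a pure function of config and seed", {
  cfg <- generator_config(duration_s = 4, seed = 9L)
  a <- generate_background(cfg, event_id = "E7")
  b <- generate_background(cfg, event_id = "E7")
  expect_identical(a$data, b$data)
  # different event id -> different substream
  c <- generate_background(cfg, event_id = "E8")
  expect_false(identical(a$data, c$data))
})

test_that("background spectrum peaks in the alpha band", {
  cfg <- generator_config(alpha_amp_uv = 30, alpha_band = c(8, 12),
                          duration_s = 60, seed = 3L)
  rec <- generate_background(cfg)
  sp <- stats::spec.pgram(stats::ts(rec$data["O1", ], frequency = cfg$fs),
                          spans = 25, plot = FALSE)
  peak <- sp$freq[which.max(sp$spec)]
  expect_gte(peak, 8)
  expect_lte(peak, 12)
})

test_that("generator config rejects invalid amplitudes and frequencies", {
  expect_error(generator_config(alpha_amp_uv = -1), "amplitudes")
  expect_error(generator_config(alpha_amp_uv = NaN), "amplitudes")
  expect_error(generator_config(fs = 250, artifact_band = c(35, 130)),
               "below fs/2")
})

test_that("ictal injection raises within-interval RMS on a max-weight channel", {
  cfg <- generator_config(alpha_amp_uv = 20, noise_amp_uv = 0,
                          ictal_amp_uv = 200, duration_s = 60, seed = 5L)
  rec <- generate_background(cfg)
  out <- inject_ictal(rec, c(20, 50), cfg)
  x <- out$recording$data["T3", ]   # weight 1 channel
  inside <- x[(20 * 250 + 1):(50 * 250)]
  outside <- x[1:(19 * 250)]
  expect_gt(sqrt(mean(inside^2)) / sqrt(mean(outside^2)), 3)
  expect_equal(out$annotation$event_type, "ES")
  expect_equal(out$annotation$ictal_intervals, matrix(c(20, 50), ncol = 2))
})

test_that("zero-weight ictal injection changes nothing but the annotation", {
  cfg <- generator_config(duration_s = 30, seed = 2L)
  cfg$channel_weights[] <- 0
  rec <- generate_background(cfg)
  out <- inject_ictal(rec, c(5, 20), cfg)
  expect_identical(out$recording$data, rec$data)
  expect_equal(nrow(out$annotation$ictal_intervals), 1L)
})

test_that("intervals outside the recording are rejected", {
  cfg <- generator_config(duration_s = 30, seed = 2L)
  rec <- generate_background(cfg)
  expect_error(inject_ictal(rec, c(10, 40), cfg), "inside the recording")
  expect_error(inject_movement_artifact(rec, c(-1, 5), cfg),
               "inside the recording")
})

test_that("overlapping ictal intervals are rejected", {
  cfg <- generator_config(duration_s = 30, seed = 2L)
  rec <- generate_background(cfg)
  out <- inject_ictal(rec, c(5, 15), cfg)
  expect_error(inject_ictal(out$recording, c(10, 20), cfg, out$annotation),
               "overlaps")
})

test_that("zero-amplitude artifact leaves the recording unchanged", {
  cfg <- generator_config(duration_s = 20, seed = 4L)
  rec <- generate_background(cfg)
  out <- inject_movement_artifact(rec, c(5, 10), cfg, amp_uv = 0)
  expect_identical(out$recording$data, rec$data)
  expect_equal(out$annotation$artifact_intervals,
               matrix(c(5, 10), ncol = 2))
})

test_that("disjoint artifact intervals are recorded in order", {
  cfg <- generator_config(duration_s = 30, seed = 4L)
  rec <- generate_background(cfg)
  a <- inject_movement_artifact(rec, c(3, 6), cfg)
  b <- inject_movement_artifact(a$recording, c(12, 15), cfg, a$annotation)
  expect_equal(b$annotation$artifact_intervals,
               matrix(c(3, 12, 6, 15), ncol = 2))
})

test_that("cohort has requested sizes, labels and distinct ids", {
  cfg <- generator_config(duration_s = 12, seed = 8L)
  expect_length(generate_cohort(cfg, 0, 0), 0L)
  cohort <- generate_cohort(cfg, 4, 3)
  man <- cohort_manifest(cohort)
  expect_equal(nrow(man), 7L)
  expect_equal(sum(man$event_type == "ES"), 4L)
  expect_false(anyDuplicated(man$event_id) > 0)
  # label consistency: ES <=> non-empty ictal intervals
  expect_true(all((man$event_type == "ES") == (man$n_ictal > 0)))
  # same seed twice -> identical manifests
  man2 <- cohort_manifest(generate_cohort(cfg, 4, 3))
  expect_identical(man, man2)
})

test_that("generated amplitudes survive the 1 px/uV rendering contract", {
  # a 100 uV deflection must span about 100 pixel rows when rendered
  fs <- 250
  trace <- rep(0, fs * 2)
  trace[fs] <- 100
  rec <- trace_recording(trace = trace, fs = fs, n = fs * 2)
  rec$data["F7", ] <- 0
  drec <- derive_montage(rec, single_derivation_montage("Fp1", "F7"))
  cfg <- render_config(width_px = 500, epoch_s = 2, lane_spacing_px = 256)
  img <- render_epoch(drec, list(start_s = 0, end_s = 2), cfg)
  dark_rows <- which(apply(img$pixels[, , 1] < 255, 1, any))
  expect_equal(max(dark_rows) - min(dark_rows), 100, tolerance = 0.02)
})
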