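test_that("trim retains the central window and validates length", {
  p <- quick_protocol(50)
  rec <- simulate_recording(noiseless_params(), p)
  trimmed <- trim_recording(rec, p)
  expect_equal(n_samples(trimmed), oculobox:::n_samples_trimmed(p))
  expect_equal(trimmed$timestamps[1], p$trim_margin)

  p0 <- stimulus_protocol(sampling_rate = 50, total_duration = 200,
                          trim_margin = 0)
  rec0 <- toy_recording(rnorm(50 * 200), protocol = p0)
  expect_identical(trim_recording(rec0, p0)$left_x, rec0$left_x)

  short <- toy_recording(rnorm(100), protocol = p)
  expect_error(trim_recording(short, p), "does not match")
})

test_that("detect_blinks enumerates maximal invalid runs", {
  p <- quick_protocol(50)
  n <- 500
  v <- rep(TRUE, n)
  rec <- toy_recording(rnorm(n), valid = v, protocol = p)
  expect_equal(nrow(detect_blinks(rec)), 0)

  v[101:250] <- FALSE  # one run of 150
  rec <- toy_recording(rnorm(n), valid = v, protocol = p)
  b <- detect_blinks(rec)
  expect_equal(nrow(b), 1)
  expect_equal(b$end - b$start, 150)
  expect_equal(b$start, 100)  # 0-based half-open

  # two runs separated by a single valid sample stay distinct
  v <- rep(TRUE, n); v[10:12] <- FALSE; v[14:20] <- FALSE
  rec <- toy_recording(rnorm(n), valid = v, protocol = p)
  b <- detect_blinks(rec)
  expect_equal(nrow(b), 2)
  expect_equal(b$start, c(9, 13))
  expect_equal(b$end, c(12, 20))

  # either eye's invalidity counts
  rec$valid_right[400] <- FALSE
  expect_equal(nrow(detect_blinks(rec)), 3)
})

test_that("blink margins widen and clip correctly", {
  mask <- rep(TRUE, 2000)
  blinks <- data.frame(start = 1000, end = 1100)
  out <- apply_blink_margins(mask, blinks, 200)
  expect_false(any(out[801:1300]))   # 0-based [800, 1300)
  expect_true(out[800])
  expect_true(out[1301])

  out0 <- apply_blink_margins(mask, blinks, 0)
  expect_equal(sum(!out0), 100)

  edge <- apply_blink_margins(mask, data.frame(start = 50, end = 60), 200)
  expect_false(any(edge[1:260]))
  expect_true(edge[261])
})

test_that("per-eye centering is independent across eyes", {
  p <- quick_protocol(50)
  n <- oculobox:::n_samples_trimmed(p)
  set.seed(1)
  base <- rnorm(n)
  rec <- toy_recording(base + 5, base, base, base, protocol = p,
                       trimmed = TRUE)
  clean <- transform_per_eye(rec)
  expect_equal(median(clean$left_x), 0)
  expect_equal(median(clean$left_y), 0)
  # right eye never saw the left eye's offset
  expect_equal(clean$right_x, clean$left_x)
  expect_equal(clean$left_x, clean$right_y)

  centered <- toy_recording(base - median(base), protocol = p, trimmed = TRUE)
  expect_equal(transform_per_eye(centered)$left_x, centered$left_x)

  none_valid <- toy_recording(rep(NA_real_, n), valid = rep(FALSE, n),
                              protocol = p, trimmed = TRUE)
  expect_error(transform_per_eye(none_valid), "no valid samples")
})

test_that("segmentation assigns cycles, sides, and conserves samples", {
  p <- stimulus_protocol()
  n <- oculobox:::n_samples_trimmed(p)
  rec <- toy_recording(numeric(n), protocol = p, trimmed = TRUE)
  seg <- segment_recording(rec, p)
  expect_equal(as.integer(table(seg$cycle)), rep(20000L, 5))
  expect_equal(sum(table(seg$cycle, seg$side)), n)
  # t = 38 s and t = 78 s: same phase, cycles 0 and 1
  i38 <- which(abs(rec$timestamps - 38) < 1e-9)
  i78 <- which(abs(rec$timestamps - 78) < 1e-9)
  expect_equal(seg$phase[i38], seg$phase[i78])
  expect_equal(seg$cycle[c(i38, i78)], c(0, 1))
  expect_equal(seg$cycle[1], 0)
  expect_equal(seg$side[1], p$side_order[1])
})

test_that("trial-triggered average: worked pair, idempotence, masked cycles", {
  # two cycle-synchronized pairs (-2.0, 0.1) and (-2.0, -0.1) average to (-2, 0)
  p2 <- stimulus_protocol(sampling_rate = 1, total_duration = 100,
                          trim_margin = 10, n_cycles = 2)
  n <- oculobox:::n_samples_trimmed(p2)  # 80 samples, 2 cycles of 40
  x <- numeric(n); y <- numeric(n)
  slot <- 29L  # same within-cycle index in both cycles (second 38 and 78)
  x[slot] <- -2.0; y[slot] <- 0.1
  x[slot + 40L] <- -2.0; y[slot + 40L] <- -0.1
  rec <- toy_recording(x, y, protocol = p2, trimmed = TRUE)
  seg <- segment_recording(rec, p2)
  tta <- trial_triggered_average(rec, seg, n_bins_per_cycle = 40)
  row <- tta[tta$eye == "left" & tta$phase_bin == slot - 1L, ]
  expect_equal(row$x, -2)
  expect_equal(row$y, 0)
  expect_equal(row$n, 2L)

  # identical cycles: the average equals any single cycle
  p5 <- quick_protocol(10)
  nc <- oculobox:::samples_per_cycle(p5)
  one_cycle <- sin(seq_len(nc) / 7)
  rec5 <- toy_recording(rep(one_cycle, 5), protocol = p5, trimmed = TRUE)
  seg5 <- segment_recording(rec5, p5)
  tta5 <- trial_triggered_average(rec5, seg5, n_bins_per_cycle = nc)
  expect_equal(tta5$x[tta5$eye == "left"], one_cycle)

  # a fully masked cycle is excluded from the mean (3-cycle toy, by hand)
  p3 <- stimulus_protocol(sampling_rate = 1, total_duration = 140,
                          trim_margin = 10, n_cycles = 3)
  n3 <- oculobox:::n_samples_trimmed(p3)
  x3 <- c(rep(1, 40), rep(2, 40), rep(7, 40))
  valid <- c(rep(TRUE, 80), rep(FALSE, 40))
  x3[!valid] <- NA
  rec3 <- toy_recording(x3, valid = valid, protocol = p3, trimmed = TRUE)
  rec3$include_mask <- valid
  class(rec3) <- c("clean_recording", "raw_recording")
  seg3 <- segment_recording(rec3, p3)
  tta3 <- trial_triggered_average(rec3, seg3, n_bins_per_cycle = 40)
  expect_equal(unique(tta3$x[tta3$eye == "left"]), 1.5)  # mean of 1, 2 only
  expect_equal(unique(tta3$n[tta3$eye == "left"]), 2L)

  # empty bins are flagged missing, never zero-filled
  valid0 <- rep(c(TRUE, FALSE), length.out = 40)
  vall <- rep(valid0, 3)
  x0 <- ifelse(vall, 1, NA)
  rec0 <- toy_recording(x0, valid = vall, protocol = p3, trimmed = TRUE)
  seg0 <- segment_recording(rec0, p3)
  tta0 <- trial_triggered_average(rec0, seg0, n_bins_per_cycle = 40)
  left0 <- tta0[tta0$eye == "left", ]
  expect_true(all(is.na(left0$x[left0$n == 0])))
  expect_equal(sum(left0$n == 0), 20)
})

test_that("TTA is linear on fully valid recordings", {
  p <- quick_protocol(10)
  n <- oculobox:::n_samples_trimmed(p)
  set.seed(4)
  u <- rnorm(n); v <- rnorm(n)
  seg <- segment_recording(toy_recording(u, protocol = p, trimmed = TRUE), p)
  tta_of <- function(x) {
    r <- toy_recording(x, protocol = p, trimmed = TRUE)
    trial_triggered_average(r, seg, 40)$x
  }
  expect_equal(tta_of(2 * u + 3 * v), 2 * tta_of(u) + 3 * tta_of(v))
})

test_that("masked samples never influence any metric output", {
  p <- quick_protocol(25)
  rec <- simulate_recording(
    sim_subject_params("case", blink_rate = 20, seed = 21L), p)
  v1 <- compute_metric_vector(rec)
  # perturb coordinates inside invalid stretches only
  rec2 <- rec
  bad <- !rec$valid_left
  for (f in c("left_x", "left_y", "right_x", "right_y")) {
    rec2[[f]][bad] <- 1e6
    rec2[[f]][is.na(rec2[[f]])] <- 1e6
    rec2[[f]][!bad] <- rec[[f]][!bad]
  }
  v2 <- compute_metric_vector(rec2)
  expect_identical(v1, v2)
})
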