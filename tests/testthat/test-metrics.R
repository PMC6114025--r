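# Metric names printed in the reference screening tables; the registry must
# resolve every one of them.
TABLE_CONTRAST_NAMES <- c(
  "left_areamean_value", "left_areamedian_value", "left_blinkrate_value",
  "left_distBot_value", "left_distLef_value", "left_distRit_value",
  "left_distTop_value", "left_nblinks_value", "left_varYbot_value",
  "left_varYtop_value", "left_widthmean_value", "left_widthmedian_value",
  "right_areamedian_value", "right_aspectRatiomedian_value",
  "right_blinkrate_value", "right_distBot_value", "right_distLef_value",
  "right_distRit_value", "right_distTop_value", "right_nblinks_value",
  "right_varXrit_value", "right_varYtop_value", "right_widthmean_value",
  "right_widthmedian_value", "conj_boxscore_value", "conj_boxscore2_value",
  "conj_boxscore3_value", "conj_boxscore5_value", "conj_totVar_value",
  "conj_varAspect_value", "conj_varX_value", "conj_varXbot_value",
  "conj_varXlef_value", "conj_varXrit_value", "conj_varXtop_value",
  "conj_varY_value", "conj_varYbot_value", "conj_varYlef_value",
  "conj_varYrit_value", "conj_varYtop_value"
)
TABLE_CANDIDATE_EXTRAS <- c("right_aspectRatiomean_value")

test_that("registry has 89 metrics with the documented eye split", {
  reg <- metric_registry()
  expect_equal(nrow(reg), 89)
  expect_equal(as.integer(table(reg$eye)[c("left", "right", "conj")]),
               c(32L, 32L, 25L))
  expect_true(all(TABLE_CONTRAST_NAMES %in% reg$name))
  expect_true(all(TABLE_CANDIDATE_EXTRAS %in% reg$name))
  expect_true(all(grepl("^(left|right|conj)_.+_value$", reg$name)))
})

test_that("box geometry recovers the traverse extents in the noiseless limit", {
  p <- quick_protocol(50)
  prep <- preprocess_recording(simulate_recording(noiseless_params(), p))
  g <- box_geometry(prep$trajectory)
  for (eye in c("left", "right")) {
    expect_equal(g[[eye]]$widthmean, 34, tolerance = 1e-8)
    expect_equal(g[[eye]]$heightmean, 23, tolerance = 1e-8)
    expect_equal(g[[eye]]$aspectRatiomean, 23 / 34, tolerance = 1e-8)
    expect_equal(g[[eye]]$areamean, 34 * 23, tolerance = 1e-6)
    expect_equal(g[[eye]]$aspectRatiomedian, 23 / 34, tolerance = 1e-8)
  }
  # square path: aspect ratio 1
  psq <- stimulus_protocol(sampling_rate = 50, horizontal_traverse = 20,
                           vertical_traverse = 20)
  gsq <- box_geometry(
    preprocess_recording(simulate_recording(noiseless_params(), psq))$trajectory)
  expect_equal(gsq$left$aspectRatiomean, 1, tolerance = 1e-8)
})

test_that("distance and velocity per side match the noiseless path", {
  p <- quick_protocol(50)
  prep <- preprocess_recording(simulate_recording(noiseless_params(), p))
  dv <- segment_distance_velocity(prep$recording, prep$segments)
  # 5 cycles x 34 deg along the top side; 1% slack for the one-step gap at
  # each side boundary
  expect_equal(dv$left$dist[["top"]], 170, tolerance = 0.01)
  expect_equal(dv$left$velocity[["top"]], 3.4, tolerance = 0.01)
  expect_equal(dv$left$dist[["left"]], 115, tolerance = 0.01)
  expect_equal(dv$right$dist[["total"]],
               sum(dv$right$dist[c("top", "right", "bottom", "left")]))

  # stationary gaze: all distances zero
  n <- oculobox:::n_samples_trimmed(p)
  still <- toy_recording(rep(1.5, n), protocol = p, trimmed = TRUE)
  seg <- segment_recording(still, p)
  dv0 <- segment_distance_velocity(still, seg)
  expect_equal(unname(dv0$left$dist), rep(0, 5))
})

test_that("metrics scale and translate as Euclidean geometry dictates", {
  p <- quick_protocol(25)
  rec <- simulate_recording(sim_subject_params("case", seed = 31L), p)
  v <- compute_metric_vector(rec)

  scale_rec <- function(r, c_) {
    for (f in c("left_x", "left_y", "right_x", "right_y")) {
      r[[f]] <- r[[f]] * c_
    }
    r
  }
  v2 <- compute_metric_vector(scale_rec(rec, 2))
  expect_equal(v2["left_dist_value"], 2 * v["left_dist_value"])
  expect_equal(v2["right_distTop_value"], 2 * v["right_distTop_value"])
  expect_equal(v2["conj_varX_value"], 4 * v["conj_varX_value"])
  expect_equal(v2["left_varYbot_value"], 4 * v["left_varYbot_value"])

  # adding the same constant to both eyes changes no conjugate or variance
  # metric (centering removes it everywhere else too)
  shift_rec <- rec
  for (f in c("left_x", "right_x")) shift_rec[[f]] <- shift_rec[[f]] + 3
  for (f in c("left_y", "right_y")) shift_rec[[f]] <- shift_rec[[f]] + 1
  v3 <- compute_metric_vector(shift_rec)
  keep <- grep("var|conj|dist|velocity|width|height|area|aspect",
               names(v), value = TRUE)
  expect_equal(v3[keep], v[keep], tolerance = 1e-9)
})

test_that("conjugate variance recovers an injected i.i.d. offset", {
  p <- quick_protocol(50)
  n_tot <- oculobox:::n_samples_total(p)
  rec <- simulate_recording(noiseless_params(), p)
  set.seed(99)
  sigma <- 0.8
  rec$left_x <- rec$left_x + rnorm(n_tot, 0, sigma)
  v <- compute_metric_vector(rec)
  expect_equal(v[["conj_varX_value"]], sigma^2, tolerance = 0.05)
  expect_equal(v[["conj_totVar_value"]],
               v[["conj_varX_value"]] + v[["conj_varY_value"]])

  # perfectly conjugate recording: every conj variance is zero
  v0 <- compute_metric_vector(simulate_recording(noiseless_params(), p))
  conj_vars <- grep("^conj_var[XY]", names(v0), value = TRUE)
  expect_equal(unname(v0[conj_vars]), rep(0, length(conj_vars)))
})

test_that("blink metrics count intervals and convert to per-minute rates", {
  b0 <- structure(data.frame(start = integer(0), end = integer(0)),
                  class = c("blink_set", "data.frame"))
  expect_equal(blink_metrics(b0, 200), list(nblinks = 0L, blinkrate = 0))
  b10 <- data.frame(start = seq(0, 900, by = 100), end = seq(10, 910, by = 100))
  expect_equal(blink_metrics(b10, 200)$blinkrate, 3)
  # joint masking: both eyes report the same blink set
  p <- quick_protocol(25)
  v <- compute_metric_vector(
    simulate_recording(sim_subject_params("case", seed = 8L), p))
  expect_equal(v[["left_nblinks_value"]], v[["right_nblinks_value"]])
  expect_equal(v[["left_blinkrate_value"]], v[["right_blinkrate_value"]])
})

test_that("box scores: baseline, monotonicity, and mutual correlation", {
  cons <- unique(unlist(oculobox:::box_score_constituents()))
  zero <- as.data.frame(setNames(as.list(rep(0, length(cons))), cons))
  ref <- boxscore_reference(rbind(zero, zero, zero))
  sc0 <- box_scores(zero, ref)
  expect_equal(unname(unlist(sc0)), rep(0, 4))

  # strictly increasing every constituent strictly increases the scores
  base <- as.data.frame(setNames(as.list(seq_along(cons) / 10), cons))
  ref2 <- boxscore_reference(rbind(base, base * 2, base * 3))
  up <- base * 1.5
  s_lo <- box_scores(base, ref2)
  s_hi <- box_scores(up, ref2)
  expect_true(all(unlist(s_hi) > unlist(s_lo)))

  # simulated cohort: the four scores are highly mutually correlated
  fx <- simulated_metric_cohort(25, 25, rate = 25, seed = 77L)
  sc <- fx$metrics[, grep("boxscore", names(fx$metrics))]
  cors <- cor(sc, method = "spearman")
  expect_true(all(cors[upper.tri(cors)] > 0.8))
})

test_that("metric vector is complete, deterministic, and symmetric", {
  p <- quick_protocol(25)
  rec <- simulate_recording(sim_subject_params("case", seed = 15L), p)
  v <- compute_metric_vector(rec)
  expect_length(v, 89)
  expect_identical(names(v), metric_names())
  expect_identical(v, compute_metric_vector(rec))

  # left/right symmetric recording: per-eye geometry identical across eyes
  sym <- simulate_recording(noiseless_params(), p)
  vs <- compute_metric_vector(sym)
  for (m in c("widthmean", "heightmedian", "areamean", "aspectRatiomedian",
              "dist", "velocity")) {
    expect_equal(vs[[paste0("left_", m, "_value")]],
                 vs[[paste0("right_", m, "_value")]])
  }
  expect_equal(vs[["conj_distDiff_value"]], 0)
  expect_equal(vs[["conj_heightDiff_value"]], 0)
})
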