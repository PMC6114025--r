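SIDES <- c("top", "right", "bottom", "left")
SIDE_SUFFIX <- c(top = "Top", bottom = "Bot", left = "Lef", right = "Rit")
SIDE_SUFFIX_LC <- c(top = "top", bottom = "bot", left = "lef", right = "rit")

#' Registry of the 89 oculomotor metrics
#'
#' The full metric roster: 32 left-eye, 32 right-eye and 25 conjugate
#' measures, named `{left|right|conj}_{measure}{Side?}_value` with side
#' suffixes `Top/Bot/Lef/Rit` (or lowercase `top/bot/lef/rit` for the
#' variance family) and no suffix for totals. Per eye: box-trajectory
#' height/width/area/aspect ratio in mean and median variants (8), path
#' distance and velocity per side plus totals (10), residual variance of x
#' and y per side plus totals (10), blink count and rate (2), and the
#' variance composites totVar and varAspect (2). Conjugate: variance of the
#' left-minus-right difference per side plus totals for x and y (10), totVar
#' and varAspect (2), the four combinatorial BOX scores (4), and left-minus-
#' right differences of distance (per side and total), velocity, height,
#' width and aspect ratio (9).
#'
#' @return A data frame with columns `name`, `eye`, `measure`, `side`.
#' @export
metric_registry <- function() {
  rows <- list()
  add <- function(eye, measure, side = NA_character_, suffix = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = paste0(eye, "_", measure, suffix, "_value"),
      eye = eye, measure = measure, side = side, stringsAsFactors = FALSE)
  }
  for (eye in c("left", "right")) {
    for (m in c("heightmean", "heightmedian", "widthmean", "widthmedian",
                "areamean", "areamedian", "aspectRatiomean",
                "aspectRatiomedian")) add(eye, m)
    for (s in SIDES) add(eye, "dist", s, SIDE_SUFFIX[s])
    add(eye, "dist")
    for (s in SIDES) add(eye, "velocity", s, SIDE_SUFFIX[s])
    add(eye, "velocity")
    for (s in SIDES) add(eye, "varX", s, SIDE_SUFFIX_LC[s])
    add(eye, "varX")
    for (s in SIDES) add(eye, "varY", s, SIDE_SUFFIX_LC[s])
    add(eye, "varY")
    add(eye, "nblinks")
    add(eye, "blinkrate")
    add(eye, "totVar")
    add(eye, "varAspect")
  }
  for (s in SIDES) add("conj", "varX", s, SIDE_SUFFIX_LC[s])
  add("conj", "varX")
  for (s in SIDES) add("conj", "varY", s, SIDE_SUFFIX_LC[s])
  add("conj", "varY")
  add("conj", "totVar")
  add("conj", "varAspect")
  add("conj", "boxscore")
  add("conj", "boxscore2")
  add("conj", "boxscore3")
  add("conj", "boxscore5")
  for (s in SIDES) add("conj", "distDiff", s, SIDE_SUFFIX[s])
  add("conj", "distDiff")
  add("conj", "velDiff")
  add("conj", "heightDiff")
  add("conj", "widthDiff")
  add("conj", "aspectRatioDiff")
  out <- do.call(rbind, rows)
  stopifnot(nrow(out) == 89L, !anyDuplicated(out$name))
  out
}

#' Names of the 89 metrics
#' @return Character vector of length 89.
#' @export
metric_names <- function() metric_registry()$name

box_score_constituents <- function() {
  list(
    conj_boxscore_value = c("conj_varX_value", "conj_varY_value",
                            "conj_varAspect_value"),
    conj_boxscore2_value = c("conj_varX_value", "conj_varY_value"),
    conj_boxscore3_value = paste0("conj_var",
                                  rep(c("X", "Y"), each = 4),
                                  SIDE_SUFFIX_LC[SIDES], "_value"),
    conj_boxscore5_value = c("conj_totVar_value", "conj_varAspect_value")
  )
}

#' Box-trajectory geometry (heights, widths, areas, aspect ratios)
#'
#' Width is the difference between the central x position on the right-side
#' bins and on the left-side bins of the trial-triggered average; height the
#' difference between the central y on the top and bottom bins. "Mean" and
#' "median" variants use the corresponding statistic over non-empty bins.
#' Area = height * width; aspect ratio = height / width, flagged missing when
#' width is zero.
#'
#' @param trajectory a `box_trajectory` from [trial_triggered_average()].
#' @return Named list per eye of the 8 geometry values.
#' @export
box_geometry <- function(trajectory) {
  bin_side <- attr(trajectory, "side")
  out <- list()
  for (eye in c("left", "right")) {
    tr <- trajectory[trajectory$eye == eye & trajectory$n > 0L, ]
    sd_of <- bin_side[tr$phase_bin + 1L]
    g <- list()
    for (variant in c("mean", "median")) {
      f <- if (variant == "mean") mean else stats::median
      stat <- function(v, s) if (any(sd_of == s)) f(v[sd_of == s]) else NA_real_
      width <- stat(tr$x, "right") - stat(tr$x, "left")
      height <- stat(tr$y, "top") - stat(tr$y, "bottom")
      g[[paste0("width", variant)]] <- width
      g[[paste0("height", variant)]] <- height
      g[[paste0("area", variant)]] <- height * width
      g[[paste0("aspectRatio", variant)]] <-
        if (!is.na(width) && width == 0) NA_real_ else height / width
    }
    out[[eye]] <- g
  }
  out
}

# Per-cycle, per-eye geometry from raw included samples; used for the
# varAspect family (variance across cycles of the aspect ratio).
cycle_geometry <- function(recording, segments) {
  mask <- recording$include_mask
  if (is.null(mask)) mask <- recording$valid_left & recording$valid_right
  cycles <- sort(unique(segments$cycle))
  res <- list()
  for (eye in c("left", "right")) {
    x <- recording[[paste0(eye, "_x")]]
    y <- recording[[paste0(eye, "_y")]]
    aspect <- sapply(cycles, function(cy) {
      stat <- function(v, s) {
        sel <- mask & segments$cycle == cy & segments$side == s
        if (!any(sel)) return(NA_real_)
        mean(v[sel])
      }
      width <- stat(x, "right") - stat(x, "left")
      height <- stat(y, "top") - stat(y, "bottom")
      if (is.na(width) || width == 0) NA_real_ else height / width
    })
    res[[eye]] <- data.frame(cycle = cycles, aspect = aspect)
  }
  res
}

#' Path distance and velocity per side
#'
#' Distance is the Euclidean path length summed over consecutive valid sample
#' pairs that lie in the same side of the same cycle, accumulated across
#' cycles. Velocity is that distance divided by the total valid time spent in
#' the side. Sides with fewer than two valid samples are missing.
#'
#' @param recording a `clean_recording`.
#' @param segments output of [segment_recording()].
#' @return Named list per eye with `dist` and `velocity`, each a named vector
#'   over `c(SIDES, "total")`.
#' @export
segment_distance_velocity <- function(recording, segments) {
  mask <- recording$include_mask
  if (is.null(mask)) mask <- recording$valid_left & recording$valid_right
  n <- n_samples(recording)
  rate <- recording$protocol$sampling_rate
  i <- seq_len(n - 1L)
  pair_ok <- mask[i] & mask[i + 1L] &
    segments$side[i] == segments$side[i + 1L] &
    segments$cycle[i] == segments$cycle[i + 1L]
  out <- list()
  for (eye in c("left", "right")) {
    x <- recording[[paste0(eye, "_x")]]
    y <- recording[[paste0(eye, "_y")]]
    step <- sqrt(diff(x)^2 + diff(y)^2)
    dist <- numeric(0); vel <- numeric(0)
    for (s in SIDES) {
      sel <- pair_ok & segments$side[i] == s
      nv <- sum(mask & segments$side == s)
      if (nv < 2L) {
        dist[s] <- NA_real_; vel[s] <- NA_real_
      } else {
        dist[s] <- sum(step[sel])
        vel[s] <- dist[s] / (nv / rate)
      }
    }
    dist["total"] <- if (anyNA(dist[SIDES])) NA_real_ else sum(dist[SIDES])
    tot_time <- sum(mask) / rate
    vel["total"] <- if (is.na(dist["total"]) || tot_time == 0) NA_real_ else
      dist[["total"]] / tot_time
    out[[eye]] <- list(dist = dist, velocity = vel)
  }
  out
}

# Map each sample to its phase bin on the trajectory grid.
sample_phase_bin <- function(recording, n_bins) {
  n <- n_samples(recording)
  spc <- samples_per_cycle(recording$protocol)
  as.integer(floor(((seq_len(n) - 1L) %% spc) * (n_bins / spc)))
}

#' Variance metrics (per-eye residual and conjugate difference variances)
#'
#' Per-eye `varX`/`varY` are unbiased variances of the deviation of each
#' included sample from the trial-triggered mean at the same phase, so the
#' pursuit structure itself is not counted as noise (`per_eye_mode = "raw"`
#' uses the plain within-side variance instead). Conjugate variances are
#' variances of the left-minus-right difference over simultaneously valid
#' pairs. `totVar = varX + varY`; `varAspect` is the variance across cycles
#' of the per-cycle aspect ratio (for `conj`, of the left-minus-right
#' per-cycle aspect-ratio difference). Entries with fewer than two
#' contributing values are missing.
#'
#' @param recording a `clean_recording`.
#' @param trajectory its `box_trajectory`.
#' @param segments its segment index.
#' @param per_eye_mode `"residual"` (default) or `"raw"`.
#' @return Nested named list: `$left`, `$right`, `$conj`.
#' @export
variance_metrics <- function(recording, trajectory, segments,
                             per_eye_mode = c("residual", "raw")) {
  per_eye_mode <- match.arg(per_eye_mode)
  mask <- recording$include_mask
  if (is.null(mask)) mask <- recording$valid_left & recording$valid_right
  n_bins <- attr(trajectory, "n_bins")
  bin <- sample_phase_bin(recording, n_bins)

  safe_var <- function(v) if (length(v) < 2L) NA_real_ else stats::var(v)
  by_side <- function(values, sel_base) {
    out <- numeric(0)
    for (s in SIDES) {
      sel <- sel_base & segments$side == s
      out[s] <- safe_var(values[sel])
    }
    out["total"] <- safe_var(values[sel_base])
    out
  }

  res <- list()
  for (eye in c("left", "right")) {
    vals <- list()
    for (ax in c("x", "y")) {
      v <- recording[[paste0(eye, "_", ax)]]
      if (per_eye_mode == "residual") {
        tr <- trajectory[trajectory$eye == eye, ]
        ref <- tr[[ax]][bin + 1L]
        v <- v - ref
      }
      vals[[toupper(ax)]] <- by_side(v, mask)
    }
    res[[eye]] <- list(varX = vals$X, varY = vals$Y)
  }
  dx <- recording$left_x - recording$right_x
  dy <- recording$left_y - recording$right_y
  pair_ok <- mask & recording$valid_left & recording$valid_right
  res$conj <- list(varX = by_side(dx, pair_ok), varY = by_side(dy, pair_ok))

  geom <- cycle_geometry(recording, segments)
  aspect_diff <- geom$left$aspect - geom$right$aspect
  res$left$varAspect <- safe_var(geom$left$aspect[!is.na(geom$left$aspect)])
  res$right$varAspect <- safe_var(geom$right$aspect[!is.na(geom$right$aspect)])
  res$conj$varAspect <- safe_var(aspect_diff[!is.na(aspect_diff)])
  for (g in c("left", "right", "conj")) {
    res[[g]]$totVar <- res[[g]]$varX[["total"]] + res[[g]]$varY[["total"]]
  }
  res
}

#' Blink count and rate
#'
#' @param blinks a `blink_set`.
#' @param duration_s analyzed duration in seconds.
#' @return List with `nblinks` and `blinkrate` (blinks per minute).
#' @export
blink_metrics <- function(blinks, duration_s) {
  stopifnot(duration_s > 0)
  nb <- nrow(blinks)
  list(nblinks = nb, blinkrate = nb / (duration_s / 60))
}

#' Compute the 89-entry metric vector for one recording
#'
#' @param recording a full-length `raw_recording`, or the list returned by
#'   [preprocess_recording()].
#' @param protocol the matching [stimulus_protocol()]; ignored when a
#'   preprocessed list is supplied.
#' @param per_eye_mode variance mode passed to [variance_metrics()].
#' @param ... further arguments to [preprocess_recording()].
#' @return Named numeric vector of length 89 (the four BOX scores are `NA`
#'   until a reference population is available; see [add_box_scores()]).
#' @export
compute_metric_vector <- function(recording, protocol = NULL,
                                  per_eye_mode = "residual", ...) {
  if (inherits(recording, "raw_recording")) {
    if (is.null(protocol)) protocol <- recording$protocol
    prep <- preprocess_recording(recording, protocol, ...)
  } else {
    prep <- recording
  }
  rec <- prep$recording
  segs <- prep$segments
  traj <- prep$trajectory
  protocol <- rec$protocol

  geom <- box_geometry(traj)
  dv <- segment_distance_velocity(rec, segs)
  vv <- variance_metrics(rec, traj, segs, per_eye_mode = per_eye_mode)
  bl <- blink_metrics(prep$blinks, n_samples(rec) / protocol$sampling_rate)

  out <- stats::setNames(rep(NA_real_, 89L), metric_names())
  for (eye in c("left", "right")) {
    for (m in names(geom[[eye]])) {
      out[paste0(eye, "_", m, "_value")] <- geom[[eye]][[m]]
    }
    for (s in SIDES) {
      out[paste0(eye, "_dist", SIDE_SUFFIX[s], "_value")] <- dv[[eye]]$dist[[s]]
      out[paste0(eye, "_velocity", SIDE_SUFFIX[s], "_value")] <-
        dv[[eye]]$velocity[[s]]
      out[paste0(eye, "_varX", SIDE_SUFFIX_LC[s], "_value")] <-
        vv[[eye]]$varX[[s]]
      out[paste0(eye, "_varY", SIDE_SUFFIX_LC[s], "_value")] <-
        vv[[eye]]$varY[[s]]
    }
    out[paste0(eye, "_dist_value")] <- dv[[eye]]$dist[["total"]]
    out[paste0(eye, "_velocity_value")] <- dv[[eye]]$velocity[["total"]]
    out[paste0(eye, "_varX_value")] <- vv[[eye]]$varX[["total"]]
    out[paste0(eye, "_varY_value")] <- vv[[eye]]$varY[["total"]]
    out[paste0(eye, "_nblinks_value")] <- bl$nblinks
    out[paste0(eye, "_blinkrate_value")] <- bl$blinkrate
    out[paste0(eye, "_totVar_value")] <- vv[[eye]]$totVar
    out[paste0(eye, "_varAspect_value")] <- vv[[eye]]$varAspect
  }
  for (s in SIDES) {
    out[paste0("conj_varX", SIDE_SUFFIX_LC[s], "_value")] <- vv$conj$varX[[s]]
    out[paste0("conj_varY", SIDE_SUFFIX_LC[s], "_value")] <- vv$conj$varY[[s]]
    out[paste0("conj_distDiff", SIDE_SUFFIX[s], "_value")] <-
      dv$left$dist[[s]] - dv$right$dist[[s]]
  }
  out["conj_varX_value"] <- vv$conj$varX[["total"]]
  out["conj_varY_value"] <- vv$conj$varY[["total"]]
  out["conj_totVar_value"] <- vv$conj$totVar
  out["conj_varAspect_value"] <- vv$conj$varAspect
  out["conj_distDiff_value"] <- dv$left$dist[["total"]] - dv$right$dist[["total"]]
  out["conj_velDiff_value"] <-
    dv$left$velocity[["total"]] - dv$right$velocity[["total"]]
  out["conj_heightDiff_value"] <-
    geom$left$heightmean - geom$right$heightmean
  out["conj_widthDiff_value"] <- geom$left$widthmean - geom$right$widthmean
  out["conj_aspectRatioDiff_value"] <-
    geom$left$aspectRatiomean - geom$right$aspectRatiomean
  out
}

#' Reference statistics for the BOX scores
#'
#' Means and SDs of the BOX-score constituent metrics, normally computed on
#' the control group of the current dataset.
#'
#' @param metric_table data frame of metric columns (reference rows only).
#' @return List with named numeric vectors `mean` and `sd`.
#' @export
boxscore_reference <- function(metric_table) {
  cons <- unique(unlist(box_score_constituents()))
  mu <- vapply(cons, function(m) mean(metric_table[[m]], na.rm = TRUE),
               numeric(1))
  sdv <- vapply(cons, function(m) stats::sd(metric_table[[m]], na.rm = TRUE),
                numeric(1))
  list(mean = mu, sd = sdv)
}

#' Combinatorial BOX scores
#'
#' Each BOX score is the mean of the z-scores of a documented subset of the
#' conjugate variance metrics (z-scored against a reference population,
#' normally the controls of the current dataset): `boxscore` uses
#' {varX, varY, varAspect}; `boxscore2` {varX, varY}; `boxscore3` the eight
#' per-side variances; `boxscore5` {totVar, varAspect}. A reference SD of
#' zero contributes a z of zero. These are reconstructions: only the
#' existence and high mutual correlation of the scores is externally
#' specified, not their formulas.
#'
#' @param metric_table data frame with the conjugate metric columns.
#' @param reference output of [boxscore_reference()].
#' @return Data frame of the four score columns, one row per input row.
#' @export
box_scores <- function(metric_table, reference) {
  cons <- box_score_constituents()
  zs <- function(m) {
    s <- reference$sd[[m]]
    x <- metric_table[[m]]
    if (is.na(s) || s == 0) return(ifelse(is.na(x), NA_real_, 0)) else
      (x - reference$mean[[m]]) / s
  }
  out <- lapply(cons, function(members) {
    z <- vapply(members, zs, numeric(nrow(metric_table)))
    if (nrow(metric_table) == 1L) z <- matrix(z, nrow = 1L)
    rowMeans(z)
  })
  as.data.frame(out, check.names = FALSE)
}

#' Add BOX scores to a metric table
#'
#' @param metric_table data frame with subject rows and metric columns.
#' @param reference_ids subject ids of the z-scoring reference population
#'   (normally the controls); `NULL` uses all rows.
#' @return The table with the four BOX-score columns filled in.
#' @export
add_box_scores <- function(metric_table, reference_ids = NULL) {
  ref_rows <- if (is.null(reference_ids)) metric_table else
    metric_table[metric_table$subject_id %in% reference_ids, ]
  ref <- boxscore_reference(ref_rows)
  sc <- box_scores(metric_table, ref)
  for (m in names(sc)) metric_table[[m]] <- sc[[m]]
  metric_table
}

#' Compute the per-subject metric table for a cohort
#'
#' Runs preprocessing and metric extraction for every recording and fills in
#' the BOX scores z-referenced on the cohort's control subjects.
#'
#' @param recordings list of `raw_recording` objects.
#' @param cohort cohort data frame with `subject_id` and `group`; used to
#'   identify the control reference for the BOX scores. `NULL` uses all
#'   subjects as reference.
#' @param ... passed to [compute_metric_vector()].
#' @return Data frame: `subject_id` plus the 89 metric columns.
#' @export
compute_metric_table <- function(recordings, cohort = NULL, ...) {
  rows <- lapply(recordings, function(r) {
    v <- compute_metric_vector(r, ...)
    cbind(data.frame(subject_id = r$subject_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ref_ids <- NULL
  if (!is.null(cohort)) {
    ref_ids <- cohort$subject_id[cohort$group == "control"]
  }
  add_box_scores(tab, ref_ids)
}
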