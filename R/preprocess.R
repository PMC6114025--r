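#' Trim the lead-in and lead-out of a recording
#'
#' Discards the first and last `trim_margin` seconds, retaining the central
#' window that contains exactly `n_cycles` whole stimulus cycles (200 s /
#' 100,000 samples at protocol defaults).
#'
#' @param recording a `raw_recording` of full protocol length.
#' @param protocol the matching [stimulus_protocol()].
#' @return A `raw_recording` restricted to the retained window.
#' @export
trim_recording <- function(recording, protocol = recording$protocol) {
  stopifnot(inherits(recording, "raw_recording"))
  n <- n_samples(recording)
  if (n != n_samples_total(protocol)) {
    stop("recording length (", n, ") does not match protocol (",
         n_samples_total(protocol), " samples)", call. = FALSE)
  }
  m <- as.integer(round(protocol$trim_margin * protocol$sampling_rate))
  keep <- seq(m + 1L, n - m)
  out <- recording
  for (f in c("timestamps", "left_x", "left_y", "right_x", "right_y",
              "valid_left", "valid_right")) {
    out[[f]] <- recording[[f]][keep]
  }
  attr(out, "trimmed") <- TRUE
  out
}

#' Detect blink / track-loss intervals
#'
#' A blink is a maximal run of samples where either eye's validity flag is
#' false. Intervals are reported 0-based and half-open: `[start, end)`.
#'
#' @param recording a `raw_recording`.
#' @return A `blink_set`: data frame with integer columns `start`, `end`,
#'   carrying the sample count as attribute `n_samples`.
#' @export
detect_blinks <- function(recording) {
  invalid <- !(recording$valid_left & recording$valid_right)
  n <- length(invalid)
  if (!any(invalid)) {
    out <- data.frame(start = integer(0), end = integer(0))
  } else {
    r <- rle(invalid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    out <- data.frame(start = starts[r$values], end = ends[r$values])
  }
  attr(out, "n_samples") <- n
  class(out) <- c("blink_set", "data.frame")
  out
}

#' Widen blink intervals and build an inclusion mask
#'
#' Marks as excluded every sample inside a blink interval widened by `margin`
#' samples on both ends (clipped to the recording bounds). The default margin
#' of 200 samples corresponds to 400 ms at 500 Hz.
#'
#' @param mask logical inclusion mask (TRUE = usable), one entry per sample.
#' @param blinks a `blink_set` from [detect_blinks()].
#' @param margin non-negative integer margin, in samples.
#' @return The updated logical mask.
#' @export
apply_blink_margins <- function(mask, blinks, margin = 200L) {
  stopifnot(is.logical(mask), margin >= 0)
  n <- length(mask)
  for (i in seq_len(nrow(blinks))) {
    a <- max(0L, blinks$start[i] - margin)
    b <- min(n, blinks$end[i] + margin)
    if (b > a) mask[(a + 1L):b] <- FALSE
  }
  mask
}

#' Center each eye on its own position statistic
#'
#' Applies the per-eye transformation: for each eye independently, subtract
#' that eye's own center (median by default) of (x, y) over included samples.
#' No information crosses between eyes and the degree scale is unchanged, so
#' conjugate differences are preserved up to a constant.
#'
#' @param recording a (typically trimmed) `raw_recording`.
#' @param include_mask logical mask of samples allowed to influence the center
#'   and all downstream statistics.
#' @param center `"median"` (robust default) or `"mean"`.
#' @return A `clean_recording`: the recording with centered coordinates and an
#'   `include_mask` element.
#' @export
transform_per_eye <- function(recording, include_mask = NULL,
                              center = c("median", "mean")) {
  center <- match.arg(center)
  cfun <- if (center == "median") stats::median else mean
  n <- n_samples(recording)
  if (is.null(include_mask)) {
    include_mask <- recording$valid_left & recording$valid_right
  }
  stopifnot(length(include_mask) == n)
  out <- recording
  for (eye in c("left", "right")) {
    ok <- include_mask & recording[[paste0("valid_", eye)]]
    if (!any(ok)) {
      stop("eye '", eye, "' has no valid samples; cannot transform",
           call. = FALSE)
    }
    for (ax in c("x", "y")) {
      f <- paste0(eye, "_", ax)
      out[[f]] <- recording[[f]] - cfun(recording[[f]][ok])
    }
  }
  out$include_mask <- include_mask
  class(out) <- c("clean_recording", "raw_recording")
  out
}

#' Assign each sample to its cycle, side, and phase
#'
#' For a trimmed recording: the cycle clock starts at the first retained
#' sample, so each cycle holds exactly `4 * side_duration * sampling_rate`
#' samples. Sides follow the protocol's `side_order`; phase is seconds within
#' the cycle, in `[0, 4 * side_duration)`. Assignment is computed from sample
#' indices, not floating-point timestamps, so side boundaries are exact.
#'
#' @param recording a trimmed `raw_recording` or `clean_recording`.
#' @param protocol the matching [stimulus_protocol()].
#' @return A data frame with columns `cycle` (0-based), `side`, `phase`.
#' @export
segment_recording <- function(recording, protocol = recording$protocol) {
  n <- n_samples(recording)
  spc <- samples_per_cycle(protocol)
  sps <- samples_per_side(protocol)
  if (n != n_samples_trimmed(protocol)) {
    stop("segment_recording expects a trimmed recording (",
         n_samples_trimmed(protocol), " samples), got ", n, call. = FALSE)
  }
  rel <- seq_len(n) - 1L
  cycle <- rel %/% spc
  within <- rel %% spc
  side <- protocol$side_order[within %/% sps + 1L]
  data.frame(cycle = cycle, side = side,
             phase = within / protocol$sampling_rate,
             stringsAsFactors = FALSE)
}

#' Trial-triggered average over the cycle grid ("box trajectory")
#'
#' Averages (x, y) across repeated stimulus cycles, synchronized by time of
#' cycle start, on a grid of `n_bins_per_cycle` phase bins. Only included
#' samples contribute; bins with zero valid contributions are reported with
#' `n = 0` and missing coordinates, never zero-filled.
#'
#' @param recording a `clean_recording` (or trimmed `raw_recording`; then the
#'   joint validity flags form the mask).
#' @param segments output of [segment_recording()].
#' @param n_bins_per_cycle number of phase bins; must divide evenly into the
#'   four sides (a multiple of 4). Default 2000 gives 20 ms bins at protocol
#'   defaults, ~10 contributing samples per bin per cycle at 500 Hz.
#' @return A `box_trajectory`: data frame with columns `phase_bin` (0-based),
#'   `eye`, `x`, `y`, `n`, plus attributes `n_bins` and `side` (side of each
#'   bin, length `n_bins`).
#' @export
trial_triggered_average <- function(recording, segments,
                                    n_bins_per_cycle = 2000L) {
  stopifnot(n_bins_per_cycle >= 4, n_bins_per_cycle %% 4 == 0)
  n <- n_samples(recording)
  stopifnot(nrow(segments) == n)
  mask <- recording$include_mask
  if (is.null(mask)) mask <- recording$valid_left & recording$valid_right
  protocol <- recording$protocol
  spc <- samples_per_cycle(protocol)
  within <- (seq_len(n) - 1L) %% spc
  bin <- as.integer(floor(within * (n_bins_per_cycle / spc)))

  bin_side <- protocol$side_order[
    (seq_len(n_bins_per_cycle) - 1L) %/% (n_bins_per_cycle %/% 4L) + 1L]

  lev <- seq_len(n_bins_per_cycle) - 1L
  fbin <- factor(bin[mask], levels = lev)
  res <- list()
  for (eye in c("left", "right")) {
    xs <- recording[[paste0(eye, "_x")]][mask]
    ys <- recording[[paste0(eye, "_y")]][mask]
    cnt <- as.integer(table(fbin))
    mx <- as.numeric(tapply(xs, fbin, mean))
    my <- as.numeric(tapply(ys, fbin, mean))
    mx[cnt == 0L] <- NA_real_
    my[cnt == 0L] <- NA_real_
    res[[eye]] <- data.frame(phase_bin = lev, eye = eye, x = mx, y = my,
                             n = cnt, stringsAsFactors = FALSE)
  }
  out <- rbind(res$left, res$right)
  rownames(out) <- NULL
  attr(out, "n_bins") <- as.integer(n_bins_per_cycle)
  attr(out, "side") <- bin_side
  class(out) <- c("box_trajectory", "data.frame")
  out
}

#' Full preprocessing of one raw recording
#'
#' Convenience wrapper: trim, detect blinks, widen them by `blink_margin`
#' samples, center each eye on its own median, segment into cycles/sides, and
#' compute the box trajectory. Eyes are masked jointly (either-eye invalidity
#' excludes the sample for both), since conjugate metrics need simultaneous
#' valid pairs.
#'
#' @param recording a full-length `raw_recording`.
#' @param protocol the matching [stimulus_protocol()].
#' @param blink_margin samples removed before and after each blink; `NULL`
#'   (default) uses 0.4 s worth of samples, i.e. 200 samples at the 500 Hz
#'   reference rate, scaling with the protocol's sampling rate.
#' @param n_bins_per_cycle phase bins for the box trajectory; `NULL` uses
#'   2000 (10 ms bins at 500 Hz), capped at one bin per grid sample for
#'   coarser rates.
#' @param center per-eye centering statistic, `"median"` or `"mean"`.
#' @return A list with elements `recording` (`clean_recording`), `blinks`,
#'   `segments`, `trajectory`.
#' @export
preprocess_recording <- function(recording, protocol = recording$protocol,
                                 blink_margin = NULL,
                                 n_bins_per_cycle = NULL,
                                 center = "median") {
  if (is.null(blink_margin)) {
    blink_margin <- as.integer(round(0.4 * protocol$sampling_rate))
  }
  if (is.null(n_bins_per_cycle)) {
    n_bins_per_cycle <- min(2000L, samples_per_cycle(protocol))
    n_bins_per_cycle <- n_bins_per_cycle - n_bins_per_cycle %% 4L
  }
  trimmed <- trim_recording(recording, protocol)
  blinks <- detect_blinks(trimmed)
  mask <- rep(TRUE, n_samples(trimmed))
  mask <- apply_blink_margins(mask, blinks, blink_margin)
  clean <- transform_per_eye(trimmed, include_mask = mask, center = center)
  segments <- segment_recording(clean, protocol)
  trajectory <- trial_triggered_average(clean, segments, n_bins_per_cycle)
  list(recording = clean, blinks = blinks, segments = segments,
       trajectory = trajectory)
}
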