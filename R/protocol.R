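#' Stimulus protocol description
#'
#' Describes the aperture-on-monitor-edge pursuit protocol: an aperture moves
#' clockwise along the outer edges of a 4:3 monitor at a fixed number of
#' seconds per side, repeating for several full cycles, while both pupils are
#' sampled at a fixed rate. The defaults describe a 220 s recording at 500 Hz
#' with five 40 s cycles (10 s per side) and a 10 s lead-in/lead-out on either
#' end that is discarded before analysis, leaving 100,000 retained samples.
#'
#' The traverse extents are expressed in degrees of visual angle: the pupil
#' travels `horizontal_traverse` degrees along the top/bottom sides and
#' `vertical_traverse` degrees along the left/right sides. `viewing_distance`
#' is retained as metadata only; no computation depends on it.
#'
#' @param sampling_rate samples per second (Hz).
#' @param total_duration total recording length in seconds, including the
#'   trimmed margins.
#' @param trim_margin seconds discarded at each end of the recording.
#' @param side_duration seconds the aperture spends on each monitor side.
#' @param n_cycles number of complete cycles in the retained window.
#' @param horizontal_traverse horizontal path extent, degrees.
#' @param vertical_traverse vertical path extent, degrees.
#' @param viewing_distance subject-to-monitor distance in cm (metadata only).
#' @param side_order order in which the four sides are traversed; the default
#'   starts at the top-left corner moving along the top edge, i.e. clockwise.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' p <- stimulus_protocol()
#' stimulus_position(p, c(0, 40, 80))
#' @export
stimulus_protocol <- function(sampling_rate = 500,
                              total_duration = 220,
                              trim_margin = 10,
                              side_duration = 10,
                              n_cycles = 5,
                              horizontal_traverse = 34,
                              vertical_traverse = 23,
                              viewing_distance = 55,
                              side_order = c("top", "right", "bottom", "left")) {
  stopifnot(
    sampling_rate > 0, total_duration > 0, trim_margin >= 0,
    side_duration > 0, n_cycles >= 1,
    horizontal_traverse > 0, vertical_traverse > 0,
    length(side_order) == 4,
    setequal(side_order, c("top", "right", "bottom", "left"))
  )
  if (!isTRUE(all.equal(n_cycles * 4 * side_duration + 2 * trim_margin,
                        total_duration))) {
    stop("protocol timing inconsistent: n_cycles * 4 * side_duration + ",
         "2 * trim_margin must equal total_duration", call. = FALSE)
  }
  structure(
    list(
      sampling_rate = sampling_rate,
      total_duration = total_duration,
      trim_margin = trim_margin,
      side_duration = side_duration,
      n_cycles = n_cycles,
      horizontal_traverse = horizontal_traverse,
      vertical_traverse = vertical_traverse,
      viewing_distance = viewing_distance,
      side_order = side_order
    ),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("Stimulus protocol:\n")
  cat(sprintf("  %g s at %g Hz (%d samples), trim %g s each end\n",
              x$total_duration, x$sampling_rate, n_samples_total(x),
              x$trim_margin))
  cat(sprintf("  %d cycles of %g s (%g s/side), order %s\n",
              x$n_cycles, cycle_duration(x), x$side_duration,
              paste(x$side_order, collapse = " > ")))
  cat(sprintf("  traverse %g deg horizontal x %g deg vertical\n",
              x$horizontal_traverse, x$vertical_traverse))
  invisible(x)
}

cycle_duration <- function(protocol) 4 * protocol$side_duration

n_samples_total <- function(protocol) {
  as.integer(round(protocol$sampling_rate * protocol$total_duration))
}

n_samples_trimmed <- function(protocol) {
  as.integer(round(protocol$sampling_rate *
                     (protocol$total_duration - 2 * protocol$trim_margin)))
}

samples_per_cycle <- function(protocol) {
  as.integer(round(protocol$sampling_rate * cycle_duration(protocol)))
}

samples_per_side <- function(protocol) {
  as.integer(round(protocol$sampling_rate * protocol$side_duration))
}

# Corner reached at the START of each side when traversed clockwise starting
# top-left. x in [-h/2, h/2], y in [-v/2, v/2], screen center at origin.
side_start_corner <- function(side, h, v) {
  switch(side,
    top    = c(-h / 2,  v / 2),
    right  = c( h / 2,  v / 2),
    bottom = c( h / 2, -v / 2),
    left   = c(-h / 2, -v / 2),
    stop("unknown side: ", side)
  )
}

side_end_corner <- function(side, h, v) {
  switch(side,
    top    = c( h / 2,  v / 2),
    right  = c( h / 2, -v / 2),
    bottom = c(-h / 2, -v / 2),
    left   = c(-h / 2,  v / 2),
    stop("unknown side: ", side)
  )
}

#' Aperture position along the box path
#'
#' Piecewise-linear closed rectangular path, periodic with period
#' `4 * side_duration`. Phase is referenced to the trimmed window so that the
#' retained portion of the recording contains exactly `n_cycles` whole cycles:
#' the cycle clock reads zero at `t = trim_margin`.
#'
#' @param protocol a [stimulus_protocol()].
#' @param t time in seconds, vectorized; must lie within `[0, total_duration]`.
#' @return A data frame with columns `x`, `y` in degrees.
#' @export
stimulus_position <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (any(t < 0 | t > protocol$total_duration)) {
    stop("t outside the recording window [0, ", protocol$total_duration, "]",
         call. = FALSE)
  }
  h <- protocol$horizontal_traverse
  v <- protocol$vertical_traverse
  period <- cycle_duration(protocol)
  phase <- (t - protocol$trim_margin) %% period
  side_idx <- pmin(floor(phase / protocol$side_duration) + 1L, 4L)
  frac <- (phase - (side_idx - 1L) * protocol$side_duration) /
    protocol$side_duration

  x <- numeric(length(t))
  y <- numeric(length(t))
  for (k in seq_len(4L)) {
    sel <- side_idx == k
    if (!any(sel)) next
    a <- side_start_corner(protocol$side_order[k], h, v)
    b <- side_end_corner(protocol$side_order[k], h, v)
    x[sel] <- a[1] + frac[sel] * (b[1] - a[1])
    y[sel] <- a[2] + frac[sel] * (b[2] - a[2])
  }
  data.frame(x = x, y = y)
}
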