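#' Per-subject simulation parameters
#'
#' Describes one simulated subject's oculomotor behaviour during pursuit of the
#' box-path aperture. Each eye follows the stimulus scaled by `pursuit_gain`
#' with additive white tracking noise; in addition, one eye (the left, by
#' convention) carries a slowly varying disconjugacy offset whose empirical
#' standard deviation over the recording equals `disconjugacy_sd`, so that the
#' injected disconjugacy magnitude is directly recoverable from the variance
#' of the left-minus-right position difference. Blinks are Poisson events that
#' flag both eyes invalid and blank the coordinates.
#'
#' @param group `"control"` or `"case"`; a label only, the dynamics are fully
#'   determined by the numeric parameters.
#' @param pursuit_gain unitless gain of each eye on the stimulus (~1).
#' @param tracking_noise_sd SD of white tracking noise per coordinate, degrees.
#' @param disconjugacy_sd SD (degrees) of the slow additive offset applied to
#'   the left eye only; 0 gives perfectly conjugate pursuit up to noise.
#' @param blink_rate expected blinks per minute.
#' @param blink_duration_mean mean blink duration, milliseconds.
#' @param seed integer RNG seed; required for any stochastic simulation.
#' @return An object of class `sim_subject_params`.
#' @export
sim_subject_params <- function(group = c("control", "case"),
                               pursuit_gain = 1.0,
                               tracking_noise_sd = 0.5,
                               disconjugacy_sd = if (group[1] == "case") 1.5 else 0,
                               blink_rate = 12,
                               blink_duration_mean = 150,
                               seed = 1L) {
  group <- match.arg(group)
  if (tracking_noise_sd < 0 || disconjugacy_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (blink_rate < 0) stop("blink_rate must be >= 0", call. = FALSE)
  if (blink_duration_mean <= 0) {
    stop("blink_duration_mean must be > 0", call. = FALSE)
  }
  structure(
    list(group = group, pursuit_gain = pursuit_gain,
         tracking_noise_sd = tracking_noise_sd,
         disconjugacy_sd = disconjugacy_sd,
         blink_rate = blink_rate,
         blink_duration_mean = blink_duration_mean,
         seed = as.integer(seed)),
    class = "sim_subject_params"
  )
}

new_raw_recording <- function(subject_id, timestamps, left_x, left_y,
                              right_x, right_y, valid_left, valid_right,
                              protocol) {
  n <- length(timestamps)
  stopifnot(
    length(left_x) == n, length(left_y) == n,
    length(right_x) == n, length(right_y) == n,
    length(valid_left) == n, length(valid_right) == n
  )
  structure(
    list(subject_id = subject_id, timestamps = timestamps,
         left_x = left_x, left_y = left_y,
         right_x = right_x, right_y = right_y,
         valid_left = valid_left, valid_right = valid_right,
         protocol = protocol),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("Binocular recording '%s': %d samples, %.1f s, %.1f%% valid\n",
              x$subject_id, length(x$timestamps),
              diff(range(x$timestamps)) + 1 / x$protocol$sampling_rate,
              100 * mean(x$valid_left & x$valid_right)))
  invisible(x)
}

#' Number of samples in a recording
#' @param recording a `raw_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(recording) length(recording$timestamps)

# Slow offset process: a Gaussian random walk low-pass filtered with a moving
# average whose width corresponds to ~0.5 Hz, then standardized so the
# empirical SD over the recording equals `sd_target` exactly (making the
# parameter recoverable from the conjugate variance metrics).
slow_offset_process <- function(n, sd_target, sampling_rate) {
  if (sd_target == 0 || n < 2) return(numeric(n))
  w <- max(3L, as.integer(round(sampling_rate / 0.5)))
  walk <- cumsum(stats::rnorm(n + w))
  sm <- stats::filter(walk, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)[seq(ceiling(w / 2), length.out = n)]
  sm[is.na(sm)] <- 0
  s <- stats::sd(sm)
  if (s == 0) return(numeric(n))
  sd_target * (sm - mean(sm)) / s
}

# Poisson blink process: returns 0-based half-open sample intervals.
draw_blinks <- function(n, sampling_rate, blink_rate, blink_duration_mean) {
  duration_min <- n / sampling_rate / 60
  k <- stats::rpois(1, blink_rate * duration_min)
  if (k == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  starts <- sort(sample.int(n, k, replace = FALSE) - 1L)
  dur_s <- stats::rexp(k, rate = 1 / (blink_duration_mean / 1000))
  lens <- pmax(1L, as.integer(round(dur_s * sampling_rate)))
  ends <- pmin(starts + lens, n)
  data.frame(start = starts, end = ends)
}

#' Simulate one binocular recording
#'
#' Each eye's trace is `pursuit_gain * stimulus + white noise`, with a slowly
#' varying disconjugacy offset (independent x and y components) added to the
#' left eye only, and Poisson blink events during which validity is false and
#' coordinates are missing. Deterministic for a fixed `params$seed`.
#'
#' @param params a [sim_subject_params()].
#' @param protocol a [stimulus_protocol()].
#' @param subject_id identifier stored in the recording.
#' @return A `raw_recording`.
#' @examples
#' rec <- simulate_recording(sim_subject_params("control", seed = 7),
#'                           stimulus_protocol())
#' n_samples(rec)  # 110000
#' @export
simulate_recording <- function(params, protocol = stimulus_protocol(),
                               subject_id = "sim") {
  stopifnot(inherits(params, "sim_subject_params"),
            inherits(protocol, "stimulus_protocol"))
  set.seed(params$seed)
  n <- n_samples_total(protocol)
  t <- (seq_len(n) - 1L) / protocol$sampling_rate
  stim <- stimulus_position(protocol, t)

  noise <- function() {
    if (params$tracking_noise_sd > 0) {
      stats::rnorm(n, 0, params$tracking_noise_sd)
    } else numeric(n)
  }
  g <- params$pursuit_gain
  left_x <- g * stim$x + noise()
  left_y <- g * stim$y + noise()
  right_x <- g * stim$x + noise()
  right_y <- g * stim$y + noise()

  left_x <- left_x + slow_offset_process(n, params$disconjugacy_sd,
                                         protocol$sampling_rate)
  left_y <- left_y + slow_offset_process(n, params$disconjugacy_sd,
                                         protocol$sampling_rate)

  valid <- rep(TRUE, n)
  blinks <- draw_blinks(n, protocol$sampling_rate, params$blink_rate,
                        params$blink_duration_mean)
  for (i in seq_len(nrow(blinks))) {
    idx <- (blinks$start[i] + 1L):blinks$end[i]
    valid[idx] <- FALSE
  }
  left_x[!valid] <- NA_real_
  left_y[!valid] <- NA_real_
  right_x[!valid] <- NA_real_
  right_y[!valid] <- NA_real_

  new_raw_recording(subject_id, t, left_x, left_y, right_x, right_y,
                    valid_left = valid, valid_right = valid,
                    protocol = protocol)
}

#' Simulate a labeled cohort with recordings
#'
#' Draws `n_control + n_case` subjects with ages uniform on `age_range`, sex
#' by `male_fraction`, SCAT3 scores consistent with the case definition
#' (cases: symptom severity > 40 and cognitive subscore <= 24; controls below
#' / above those bounds), and CT status for cases positive with probability
#' `ct_positive_fraction` (controls carry `"none"`). Per-subject simulation
#' seeds are derived reproducibly from `master_seed`, and per-subject effect
#' sizes are jittered around the profile values by a lognormal factor with
#' coefficient of variation `between_subject_cv` to emulate biological
#' heterogeneity.
#'
#' @param n_control,n_case group sizes; their sum must be positive.
#' @param control_params,case_params [sim_subject_params()] profiles.
#' @param protocol a [stimulus_protocol()].
#' @param age_range inclusive age bounds, years.
#' @param male_fraction probability a subject is male.
#' @param ct_positive_fraction probability a case is CT positive.
#' @param between_subject_cv coefficient of variation of the per-subject
#'   lognormal jitter on `disconjugacy_sd` and `tracking_noise_sd`; 0 disables.
#' @param master_seed integer master seed; all randomness derives from it.
#' @return A list with `cohort` (data frame: subject_id, age, sex, group,
#'   ct_status, sss, sac) and `recordings` (list of `raw_recording`).
#' @export
simulate_cohort <- function(n_control, n_case,
                            control_params = sim_subject_params("control"),
                            case_params = sim_subject_params("case"),
                            protocol = stimulus_protocol(),
                            age_range = c(18, 60),
                            male_fraction = 0.5,
                            ct_positive_fraction = 13 / 34,
                            between_subject_cv = 0.3,
                            master_seed = 1L) {
  stopifnot(n_control >= 0, n_case >= 0)
  if (n_control + n_case == 0) {
    stop("cohort must contain at least one subject", call. = FALSE)
  }
  set.seed(master_seed)
  n <- n_control + n_case
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  group <- c(rep("control", n_control), rep("case", n_case))
  age <- round(stats::runif(n, age_range[1], age_range[2]), 1)
  sex <- ifelse(stats::runif(n) < male_fraction, "male", "female")
  sss <- ifelse(group == "case",
                41L + as.integer(stats::runif(n, 0, 60)),
                as.integer(stats::runif(n, 0, 21)))
  sac <- ifelse(group == "case",
                10L + as.integer(stats::runif(n, 0, 15)),
                25L + as.integer(stats::runif(n, 0, 6)))
  ct_status <- ifelse(group == "case",
                      ifelse(stats::runif(n) < ct_positive_fraction,
                             "positive", "negative"),
                      "none")
  jitter_factor <- function(k) {
    if (between_subject_cv <= 0) return(rep(1, k))
    sdlog <- sqrt(log(1 + between_subject_cv^2))
    stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  jit_noise <- jitter_factor(n)
  jit_disc <- jitter_factor(n)

  subject_id <- sprintf("S%03d", seq_len(n))
  cohort <- data.frame(
    subject_id = subject_id, age = age, sex = sex, group = group,
    ct_status = ct_status, sss = sss, sac = sac,
    stringsAsFactors = FALSE
  )

  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- if (group[i] == "case") case_params else control_params
    p_i <- sim_subject_params(
      group = prof$group,
      pursuit_gain = prof$pursuit_gain,
      tracking_noise_sd = prof$tracking_noise_sd * jit_noise[i],
      disconjugacy_sd = prof$disconjugacy_sd * jit_disc[i],
      blink_rate = prof$blink_rate,
      blink_duration_mean = prof$blink_duration_mean,
      seed = subject_seeds[i]
    )
    recordings[[i]] <- simulate_recording(p_i, protocol, subject_id[i])
  }
  names(recordings) <- subject_id
  list(cohort = cohort, recordings = recordings)
}
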