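# Shared fixtures. Simulated cohorts are cached per parameter key so the
# expensive ones are built once per test run. Reduced sampling rates keep
# the suite fast; the protocol's temporal structure (220 s, 5 x 40 s cycles,
# 10 s trim) is never changed.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

quick_protocol <- function(rate = 50) stimulus_protocol(sampling_rate = rate)

noiseless_params <- function(seed = 1L) {
  sim_subject_params("control", tracking_noise_sd = 0, disconjugacy_sd = 0,
                     blink_rate = 0, seed = seed)
}

# Hand-built recording on a quick protocol grid.
toy_recording <- function(left_x, left_y = left_x, right_x = left_x,
                          right_y = left_y, valid = NULL,
                          protocol = quick_protocol(),
                          trimmed = FALSE) {
  n <- length(left_x)
  if (is.null(valid)) valid <- rep(TRUE, n)
  t0 <- if (trimmed) protocol$trim_margin else 0
  rec <- oculobox:::new_raw_recording(
    "toy", t0 + (seq_len(n) - 1L) / protocol$sampling_rate,
    left_x, left_y, right_x, right_y, valid, valid, protocol)
  if (trimmed) attr(rec, "trimmed") <- TRUE
  rec
}

# Cohort of simulated recordings reduced to a metric table plus cohort frame.
simulated_metric_cohort <- function(n_control, n_case, rate = 50,
                                    case_disc = 1.5, seed = 42L) {
  key <- paste("mc", n_control, n_case, rate, case_disc, seed, sep = "_")
  cached(key, {
    protocol <- quick_protocol(rate)
    sim <- simulate_cohort(
      n_control, n_case,
      control_params = sim_subject_params("control"),
      case_params = sim_subject_params("case", disconjugacy_sd = case_disc),
      protocol = protocol, master_seed = seed)
    tab <- compute_metric_table(sim$recordings, sim$cohort)
    list(cohort = sim$cohort, metrics = tab,
         labels = ifelse(sim$cohort$group == "case", "case", "control"))
  })
}

# Synthetic metric-table-shaped data with known signal structure, for the
# model-fitting tests (no recordings involved).
synthetic_design <- function(n, p_signal = 2, p_noise = 10, beta = 2,
                             seed = 1L) {
  set.seed(seed)
  p <- p_signal + p_noise
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- sprintf("m%02d_value", seq_len(p))
  eta <- x[, seq_len(p_signal), drop = FALSE] %*% rep(beta, p_signal)
  y <- rbinom(n, 1, plogis(drop(eta)))
  tab <- data.frame(subject_id = sprintf("D%03d", seq_len(n)), x,
                    check.names = FALSE)
  signal <- if (p_signal > 0) colnames(x)[seq_len(p_signal)] else character(0)
  list(table = tab, labels = ifelse(y == 1, "case", "control"),
       signal = signal, noise = setdiff(colnames(x), signal))
}
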