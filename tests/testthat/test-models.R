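test_that("best-subset search finds the signal and rejects pure noise", {
  d <- synthetic_design(150, p_signal = 2, p_noise = 4, beta = 2, seed = 21L)
  m <- fit_best_subset(d$table, d$labels,
                       candidates = c(d$signal, d$noise),
                       max_subset_size = 3)
  expect_true(all(d$signal %in% m$selected))
  expect_gt(m$apparent_auc, 0.8)

  # single candidate: that model is returned
  m1 <- fit_best_subset(d$table, d$labels, candidates = d$signal[1])
  expect_equal(m1$selected, d$signal[1])

  # candidates exactly orthogonal to the labels: the logistic MLE for each
  # is exactly zero, so the intercept-only model wins AIC deterministically
  set.seed(22)
  n <- 400
  y <- rep(c(0, 1), each = n / 2)
  ortho <- sapply(1:3, function(j) {
    x <- rnorm(n)
    x - (y - mean(y)) * sum(x * (y - mean(y))) / sum((y - mean(y))^2)
  })
  colnames(ortho) <- sprintf("o%d_value", 1:3)
  dn_tab <- data.frame(subject_id = sprintf("O%03d", 1:n), ortho,
                       check.names = FALSE)
  mn <- fit_best_subset(dn_tab, ifelse(y == 1, "case", "control"),
                        candidates = colnames(ortho))
  expect_length(mn$selected, 0)

  expect_error(fit_best_subset(d$table, d$labels, character(0)),
               "no candidate")
})

test_that("missing-data policies drop rows or columns as requested", {
  d <- synthetic_design(80, p_signal = 2, p_noise = 2, seed = 23L)
  tab <- d$table
  tab[[d$noise[1]]][5] <- NA
  m_rows <- fit_best_subset(tab, d$labels, c(d$signal, d$noise),
                            missing = "drop_rows")
  expect_equal(length(m_rows$training_ids), 79)
  m_cols <- fit_best_subset(tab, d$labels, c(d$signal, d$noise),
                            missing = "drop_columns")
  expect_equal(length(m_cols$training_ids), 80)
  expect_false(d$noise[1] %in% m_cols$selected)
})

test_that("lasso recovers sparse signal; limiting penalties behave", {
  d <- synthetic_design(200, p_signal = 2, p_noise = 10, beta = 2, seed = 24L)
  cand <- c(d$signal, d$noise)
  m <- fit_lasso(d$table, d$labels, cand, seed = 5L)
  expect_true(all(d$signal %in% m$selected))
  expect_lte(length(m$selected), 8)

  # penalty -> infinity: full shrinkage to the intercept
  m_inf <- fit_lasso(d$table, d$labels, cand, lambda = 1e6)
  expect_length(m_inf$selected, 0)

  # penalty 0 approximates the unpenalized maximum-likelihood fit
  d2 <- synthetic_design(300, p_signal = 2, p_noise = 1, beta = 1, seed = 25L)
  m0 <- fit_lasso(d2$table, d2$labels, c(d2$signal, d2$noise), lambda = 0)
  glm_fit <- glm(
    I(d2$labels == "case") ~ .,
    data = d2$table[, c(d2$signal, d2$noise)], family = binomial())
  expect_equal(unname(m0$coefficients[names(coef(glm_fit))[-1]]),
               unname(coef(glm_fit)[-1]), tolerance = 0.02)

  # reproducibility under seed
  m_b <- fit_lasso(d$table, d$labels, cand, seed = 5L)
  expect_identical(m$coefficients, m_b$coefficients)
})

test_that("bagged forest: separable, null, and deterministic behaviour", {
  set.seed(30)
  n <- 60
  x <- data.frame(subject_id = sprintf("F%02d", 1:n),
                  a_value = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                  b_value = rnorm(n))
  labs <- rep(c("control", "case"), each = n / 2)
  m <- fit_random_forest(x, labs, c("a_value", "b_value"),
                         n_trees = 100, seed = 2L)
  expect_lt(m$oob_error, 10)  # separable limit: near-zero OOB error

  # permuted labels: OOB error near the 50% chance level
  labs_perm <- sample(labs)
  m_null <- fit_random_forest(x, labs_perm, c("a_value", "b_value"),
                              n_trees = 100, seed = 2L)
  expect_gt(m_null$oob_error, 30)
  expect_lt(m_null$oob_error, 70)

  m2 <- fit_random_forest(x, labs, c("a_value", "b_value"),
                          n_trees = 100, seed = 2L)
  expect_identical(m2$oob_error, m$oob_error)
  expect_identical(predict_oculobox(m2, x), predict_oculobox(m, x))

  expect_error(fit_random_forest(x, rep("case", n), "a_value"),
               "single-class")
})

test_that("repeated CV is honest on null data and tracks apparent AUC", {
  # null: no signal anywhere
  dn <- synthetic_design(48, p_signal = 0, p_noise = 4, seed = 26L)
  cvn <- repeated_cv(dn$table, dn$labels, "best_subset", dn$noise,
                     n_repeats = 25, seed = 7L, max_subset_size = 2)
  expect_gt(cvn$mean_auc, 0.35)
  expect_lt(cvn$mean_auc, 0.65)

  # strong signal: cross-validated AUC below apparent, within 0.1
  d <- synthetic_design(80, p_signal = 2, p_noise = 2, beta = 2, seed = 27L)
  cand <- c(d$signal, d$noise)
  m <- fit_best_subset(d$table, d$labels, cand, max_subset_size = 2)
  cv <- repeated_cv(d$table, d$labels, "best_subset", cand,
                    n_repeats = 25, seed = 7L, max_subset_size = 2)
  expect_lte(cv$mean_auc, m$apparent_auc + 0.02)
  expect_gte(cv$mean_auc, m$apparent_auc - 0.1)

  # determinism and error handling
  cv2 <- repeated_cv(d$table, d$labels, "best_subset", cand,
                     n_repeats = 25, seed = 7L, max_subset_size = 2)
  expect_identical(cv$auc, cv2$auc)
  expect_error(repeated_cv(d$table[1:6, ], d$labels[1:6], "best_subset",
                           cand, n_folds = 4),
               "n_folds")
})

test_that("selection leakage inflates cross-validated AUC on null data", {
  dn <- synthetic_design(48, p_signal = 0, p_noise = 15, seed = 28L)
  honest <- repeated_cv(dn$table, dn$labels, "best_subset", dn$noise,
                        n_repeats = 15, seed = 9L, max_subset_size = 2)
  leaky <- repeated_cv(dn$table, dn$labels, "best_subset", dn$noise,
                       n_repeats = 15, seed = 9L, max_subset_size = 2,
                       leak_selection = TRUE)
  expect_gt(leaky$mean_auc, honest$mean_auc)
  # with 15 noise candidates the leaked selection is optimistic by far more
  # than 2 SE of the repeat means
  se <- sd(leaky$auc) / sqrt(length(leaky$auc))
  expect_gt(leaky$mean_auc, 0.5 + 2 * se)
})
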