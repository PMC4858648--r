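test_that("intercept-only fit is the closed-form log-odds of prevalence", {
  tab <- planted_table(43, 73, planted = NULL)
  fit <- fit_logistic(tab, character(0))
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(43 / 73),
               tolerance = 1e-8)
  expect_equal(fit$aic, 2 - 2 * fit$loglik)
})

test_that("degenerate designs are caught", {
  set.seed(21)
  tab <- planted_table(20, 20, planted = NULL)
  tab$energy <- 1  # constant feature
  expect_error(fit_logistic(tab, "energy"), "singular")

  # one perfectly separating feature raises a separation warning
  tab2 <- planted_table(20, 20, planted = NULL)
  tab2$entropy <- ifelse(tab2$label == "E", 1, -1)
  expect_warning(fit_logistic(tab2, "entropy"), "separation")

  one_class <- planted_table(10, 10, planted = NULL)
  one_class$label <- "E"
  expect_error(fit_logistic(one_class, "entropy"), "both classes")
})

test_that("stepwise selection finds a strongly separated feature first", {
  set.seed(22)
  hits <- vapply(1:25, function(i) {
    tab <- planted_table(43, 73, shift = 2, planted = "sum_variance")
    m <- suppressWarnings(stepwise_select(tab))
    adds <- m$step_log[m$step_log$action == "add", ]
    nrow(adds) >= 1 && adds$feature[1] == "sum_variance"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("stepwise selection is deterministic and AIC-monotone", {
  set.seed(23)
  tab <- planted_table(43, 73, shift = 1.2, planted = "entropy")
  m1 <- suppressWarnings(stepwise_select(tab))
  m2 <- suppressWarnings(stepwise_select(tab))
  expect_identical(m1$step_log, m2$step_log)
  expect_identical(m1$coefficients, m2$coefficients)

  # the AIC trace never increases over accepted additions
  adds <- m1$step_log[m1$step_log$action == "add", ]
  expect_true(all(diff(c(m1$aic_trace[1], adds$aic)) <= 1e-9))
  # every selected term's final Wald p is below the removal threshold
  w <- m1$wald_stats[m1$wald_stats$term %in% m1$selected_features, ]
  expect_true(all(w$p <= 0.15))
})

test_that("threshold contract and empty-selection path behave", {
  tab <- planted_table(30, 30, planted = NULL)
  expect_error(stepwise_select(tab, p_enter = 0.2, p_remove = 0.1), "p_remove")
  expect_error(stepwise_select(tab[0, ]), "empty")

  # with an impossible entry threshold nothing is ever selected
  m <- stepwise_select(tab, p_enter = 1e-12, p_remove = 1e-11)
  expect_length(m$selected_features, 0)
  expect_equal(unname(m$coefficients["(Intercept)"]), 0, tolerance = 1e-6)
})

test_that("likelihood-ratio entry agrees with Wald on a strong signal", {
  set.seed(24)
  tab <- planted_table(43, 73, shift = 2, planted = "sum_average")
  mw <- suppressWarnings(stepwise_select(tab, entry_test = "wald", max_steps = 1))
  ml <- suppressWarnings(stepwise_select(tab, entry_test = "lr", max_steps = 1))
  expect_equal(mw$selected_features[1], "sum_average")
  expect_equal(ml$selected_features[1], "sum_average")
})

test_that("selection recovers a known two-feature logistic model", {
  set.seed(25)
  active <- c("dissimilarity", "sum_entropy")
  n <- 500
  recovered <- 0
  for (rep in 1:15) {
    X <- matrix(rnorm(n * 20), n, 20)
    colnames(X) <- texture_feature_names
    eta <- 1.2 * X[, "dissimilarity"] - 1.4 * X[, "sum_entropy"]
    y <- rbinom(n, 1, plogis(eta))
    tab <- data.frame(subject_id = sprintf("S%02d", rep_len(1:15, n)),
                      roi_id = sprintf("R%03d", 1:n),
                      label = ifelse(y == 1, "E", "NE"))
    tab <- cbind(tab, as.data.frame(X))
    m <- suppressWarnings(stepwise_select(tab))
    if (all(active %in% m$selected_features)) recovered <- recovered + 1
    # coefficient signs always match the generating model when selected
    if ("dissimilarity" %in% m$selected_features)
      expect_gt(m$coefficients[["dissimilarity"]], 0)
    if ("sum_entropy" %in% m$selected_features)
      expect_lt(m$coefficients[["sum_entropy"]], 0)
  }
  expect_gt(recovered / 15, 0.9)
})

test_that("prediction is the inverse logit of the linear predictor", {
  set.seed(26)
  tab <- planted_table(40, 60, shift = 2, planted = "contrast")
  m <- suppressWarnings(stepwise_select(tab, max_steps = 2))
  rows <- planted_table(10, 10, planted = NULL)
  p <- predict(m, rows)
  # independent recomputation of the inverse logit
  eta <- m$coefficients[["(Intercept)"]]
  for (f in m$selected_features) eta <- eta + m$coefficients[[f]] * rows[[f]]
  expect_equal(p, 1 / (1 + exp(-eta)), tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))

  # zero-coefficient model predicts 0.5 everywhere
  m0 <- m; m0$coefficients[] <- 0
  expect_equal(predict(m0, rows), rep(0.5, nrow(rows)))

  expect_error(predict(m, rows[setdiff(names(rows), m$selected_features)]),
               "missing selected feature")
})

test_that("odds ratios exponentiate coefficients and flag significance", {
  set.seed(27)
  tab <- planted_table(43, 73, shift = 2, planted = "sum_variance")
  m <- suppressWarnings(stepwise_select(tab))
  or <- odds_ratios(m)
  expect_equal(or$odds_ratio,
               unname(exp(m$coefficients[or$feature])), tolerance = 1e-12)
  # entry at p < 0.05 implies every retained term is flagged significant
  expect_true(all(or$significant))

  m0 <- m
  m0$wald_stats <- data.frame(term = "x", estimate = log(2), se = 1, z = 1,
                              p = 0.5)
  m0$selected_features <- "x"
  expect_equal(odds_ratios(m0)$odds_ratio, 2)
  expect_false(odds_ratios(m0)$significant)
})

test_that("stepwise models serialize to JSON and back", {
  set.seed(28)
  tab <- planted_table(30, 40, shift = 2, planted = "energy")
  m <- suppressWarnings(stepwise_select(tab, max_steps = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_stepwise_model(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$selected_features, m$selected_features)
  expect_equal(unlist(back$coefficients), unlist(m$coefficients),
               tolerance = 1e-12)
})
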