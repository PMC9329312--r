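test_that("fitting is deterministic under a fixed seed", {
  sd <- small_signal_data(n = 60, p_noise = 4, seed = 1)
  f1 <- fit_survival_forest(sd$features, sd$outcome, n_trees = 10, seed = 42)
  f2 <- fit_survival_forest(sd$features, sd$outcome, n_trees = 10, seed = 42)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$oob, f2$oob)
  expect_identical(permutation_vimp(f1), permutation_vimp(f2))
  expect_identical(predict_survival(f1), predict_survival(f2))
  f3 <- fit_survival_forest(sd$features, sd$outcome, n_trees = 10, seed = 43)
  expect_false(identical(f1$trees, f3$trees))
})

test_that("a single-leaf tree stores the full-sample Nelson-Aalen hazard", {
  sd <- small_signal_data(n = 30, p_noise = 2, seed = 2)
  f <- fit_survival_forest(sd$features, sd$outcome, n_trees = 1,
                           min_node_size = 1e6, bootstrap = FALSE, seed = 1)
  expect_equal(nrow(f$trees[[1]]$chf), 1) # no split happened
  na <- nelson_aalen(sd$outcome$time_days, sd$outcome$event)
  grid_na <- na$cumhaz[match(f$time_grid, na$time)]
  expect_equal(as.vector(f$trees[[1]]$chf[1, ]), grid_na, tolerance = 1e-10)
  # any input predicts the training-sample curve
  pred <- predict_survival(f, sd$features[3, ])
  expect_equal(pred$cumhaz, grid_na, tolerance = 1e-10)
})

test_that("ensemble hazard is the exact mean of member-tree hazards", {
  sd <- small_signal_data(n = 50, p_noise = 3, seed = 3)
  f <- fit_survival_forest(sd$features, sd$outcome, n_trees = 2, seed = 7)
  chf <- kinomescreen:::ensemble_chf_matrix(f)
  per_tree <- lapply(f$trees, function(tr) {
    idx <- kinomescreen:::ensemble_chf_cpp(list(tr), f$X)
    idx
  })
  expect_equal(chf, (per_tree[[1]] + per_tree[[2]]) / 2, tolerance = 1e-12)
})

test_that("predicted survival starts at 1 and never increases", {
  sd <- small_signal_data(n = 80, p_noise = 4, seed = 4)
  f <- fit_survival_forest(sd$features, sd$outcome, n_trees = 25, seed = 5)
  pred <- predict_survival(f, times = c(0, sort(sample(1:200, 20))))
  by_pat <- split(pred, pred$patient_id)
  for (pp in by_pat[1:10]) {
    expect_equal(pp$survival[pp$time == 0], 1)
    expect_true(all(diff(pp$survival[order(pp$time)]) <= 1e-12))
    expect_true(all(pp$survival > 0 & pp$survival <= 1))
  }
})

test_that("out-of-bag fraction matches the bootstrap expectation", {
  sd <- small_signal_data(n = 100, p_noise = 3, seed = 5)
  f <- fit_survival_forest(sd$features, sd$outcome, n_trees = 200, seed = 11)
  frac <- mean(vapply(f$oob, length, integer(1))) / 100
  expect_equal(frac, (1 - 1 / 100)^100, tolerance = 0.02)
})

test_that("the root splits on a perfectly separating predictor", {
  # one predictor cleanly orders early vs late events; competitors are noise
  withr::with_seed(6, {
    n <- 60
    x <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
    t <- c(sample(1:20, n / 2, TRUE), sample(100:120, n / 2, TRUE))
    feats <- tibble::tibble(patient_id = sprintf("s%02d", 1:n),
                            strong = x, noise = rnorm(n))
    out <- tibble::tibble(patient_id = feats$patient_id, ae_term = "ae",
                          time_days = as.numeric(t), event = 1L)
    f <- fit_survival_forest(feats, out, n_trees = 30, mtry = 2, seed = 3)
    root_vars <- vapply(f$trees, function(tr) tr$split_var[1], integer(1))
    expect_true(mean(f$predictors[root_vars + 1L] == "strong") > 0.9)
    # exhaustive check on one in-bag sample: no threshold of either
    # predictor beats the chosen root split
    tr <- f$trees[[1]]
    chosen <- logrank_split_statistic(
      out$time_days, out$event, feats[[f$predictors[tr$split_var[1] + 1L]]] <=
        tr$split_val[1])
    for (v in c("strong", "noise")) {
      xs <- sort(unique(feats[[v]]))
      thr <- (head(xs, -1) + xs[-1]) / 2
      best <- max(vapply(thr, function(th) {
        logrank_split_statistic(out$time_days, out$event, feats[[v]] <= th)
      }, numeric(1)))
      if (v == "strong") expect_gte(chosen, best * 0.999)
    }
  })
})

test_that("forest refuses to fit without events", {
  sd <- small_signal_data(n = 20, p_noise = 2, seed = 7)
  sd$outcome$event <- 0L
  sd$outcome$time_days <- 200
  expect_error(fit_survival_forest(sd$features, sd$outcome), "no events")
})

test_that("OOB concordance is near 1/2 when outcomes are independent of features", {
  withr::with_seed(31, {
    n <- 200
    x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
    ids <- sprintf("s%03d", 1:n)
    t <- ceiling(150 * rexp(n) / log(2))
    ev <- as.integer(t < 150)
    t[ev == 0] <- 150
    feats <- dplyr::bind_cols(tibble::tibble(patient_id = ids),
                              tibble::as_tibble(x))
    out <- tibble::tibble(patient_id = ids, ae_term = "ae",
                          time_days = as.numeric(t), event = ev)
    f <- fit_survival_forest(feats, out, n_trees = 100, seed = 17)
    expect_equal(oob_concordance(f), 0.5, tolerance = 0.05)
  })
})

test_that("risk ordering follows a strong single feature", {
  sd <- small_signal_data(n = 120, p_noise = 2, hr = 4, seed = 8)
  f <- fit_survival_forest(sd$features, sd$outcome, n_trees = 60, seed = 19)
  mort <- predict_mortality(f)
  expect_gt(cor(mort$mortality, sd$features$signal, method = "spearman"),
            0.7)
})

test_that("permutation importance is exactly zero for an unused predictor", {
  sd <- small_signal_data(n = 60, p_noise = 3, seed = 9)
  sd$features$constant <- 5 # constant column can never be split on
  f <- fit_survival_forest(sd$features, sd$outcome, n_trees = 20, seed = 23)
  vi <- permutation_vimp(f, predictors = "constant")
  expect_identical(vi$vimp, 0)
})

test_that("importance separates causal from noise predictors", {
  sd <- small_signal_data(n = 150, p_noise = 9, hr = 3, seed = 10)
  f <- fit_survival_forest(sd$features, sd$outcome, n_trees = 100, seed = 29)
  vi <- permutation_vimp(f, n_repeats = 5)
  noise <- vi$vimp[vi$predictor != "signal"]
  expect_gt(vi$vimp[vi$predictor == "signal"],
            quantile(noise, 0.95))
  # pure-noise importance centred at zero
  expect_lt(abs(mean(noise)), 0.01)
})

test_that("minimal depth follows the stated conventions", {
  # predictor that splits every root has minimal depth 0
  withr::with_seed(11, {
    n <- 80
    feats <- tibble::tibble(patient_id = sprintf("s%02d", 1:n),
                            strong = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                            weak = rnorm(n))
    t <- c(sample(1:15, n / 2, TRUE), sample(80:100, n / 2, TRUE))
    out <- tibble::tibble(patient_id = feats$patient_id, ae_term = "ae",
                          time_days = as.numeric(t), event = 1L)
    f <- fit_survival_forest(feats, out, n_trees = 25, mtry = 2, seed = 31)
    md <- minimal_depth(f)
    expect_lt(md$minimal_depth[md$predictor == "strong"], 0.5)
    # unused predictor gets max depth + 1 in every tree
    feats$constant <- 1
    f2 <- fit_survival_forest(feats, out, n_trees = 10, mtry = 3, seed = 37)
    md2 <- minimal_depth(f2)
    max_depths <- vapply(f2$trees, function(tr) max(tr$depth) + 1, numeric(1))
    expect_equal(md2$minimal_depth[md2$predictor == "constant"],
                 mean(max_depths))
  })
})

test_that("forest concordance is comparable to an established implementation", {
  skip_if_not_installed("ranger")
  sd <- small_signal_data(n = 150, p_noise = 9, hr = 3, seed = 12)
  f <- fit_survival_forest(sd$features, sd$outcome, n_trees = 100, seed = 41)
  df <- as.data.frame(sd$features[-1])
  df$time <- sd$outcome$time_days
  df$status <- sd$outcome$event
  rf <- ranger::ranger(survival::Surv(time, status) ~ ., data = df,
                       num.trees = 100, seed = 1, num.threads = 1)
  ours <- oob_concordance(f)
  theirs <- 1 - rf$prediction.error
  expect_lt(abs(ours - theirs), 0.05)
})
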