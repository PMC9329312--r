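test_that("Harrell's C matches exhaustive pair enumeration", {
  # 6 subjects, 2 censored
  times <- c(2, 5, 3, 8, 4, 9)
  events <- c(1, 1, 0, 1, 1, 0)
  risk <- c(0.9, 0.3, 0.5, 0.1, 0.8, 0.2)
  expect_equal(harrell_c(times, events, risk),
               oracle_harrell_c(times, events, risk), tolerance = 1e-10)
  withr::with_seed(5, {
    for (rep in 1:40) {
      inst <- random_tiny_instance()
      risk <- round(rnorm(length(inst$times)), 1) # ties happen
      got <- tryCatch(harrell_c(inst$times, inst$events, risk),
                      error = function(e) NA_real_)
      if (!is.na(got)) {
        expect_equal(got, oracle_harrell_c(inst$times, inst$events, risk),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("C-index hits the boundary and null anchors", {
  # risk perfectly ordering uncensored times -> 1
  times <- 1:6
  expect_equal(harrell_c(times, rep(1, 6), rev(times) / 10), 1)
  # flipping risk gives the complement when no ties
  risk <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(harrell_c(times, c(1, 1, 0, 1, 0, 1), risk) +
                 harrell_c(times, c(1, 1, 0, 1, 0, 1), -risk), 1)
  # invariance under strictly monotone transforms
  expect_equal(harrell_c(times, rep(1, 6), risk),
               harrell_c(times, rep(1, 6), exp(2 * risk)))
  # undefined without permissible pairs
  expect_error(harrell_c(c(5, 5), c(1, 1), c(1, 2)), "permissible")
  # random scores on simulated outcomes average near 1/2
  withr::with_seed(21, {
    cs <- replicate(60, {
      t <- rexp(80)
      cen <- rexp(80, 0.5)
      harrell_c(pmin(t, cen), as.integer(t <= cen), runif(80))
    })
    expect_equal(mean(cs), 0.5, tolerance = 0.02)
  })
})

test_that("reporting odds ratio follows ad/bc with zero-cell correction", {
  expect_equal(ror(10, 90, 10, 90)$ror, 1)
  expect_equal(ror(20, 80, 10, 90)$ror, 2.25)
  # scale invariance
  expect_equal(ror(40, 160, 20, 180)$ror, 2.25)
  # zero cell: Haldane-Anscombe correction, flagged
  r0 <- ror(0, 50, 5, 45)
  expect_true(r0$corrected)
  expect_equal(r0$ror, (0.5 * 45.5) / (50.5 * 5.5))
  expect_true(r0$lower < r0$ror & r0$ror < r0$upper)
  expect_error(ror(0, 0, 0, 0), "undefined")
})

test_that("ror_from_events builds the 2x2 table from patient-level data", {
  pts <- tibble::tibble(patient_id = sprintf("p%d", 1:8),
                        drug_id = rep(c("a", "b"), each = 4))
  out <- tibble::tibble(patient_id = pts$patient_id, ae_term = "rash",
                        event = c(1, 1, 1, 0, 1, 0, 0, 0))
  r <- ror_from_events(out, pts, "a", "rash")
  expect_equal(unlist(r[c("a", "b", "c", "d")]),
               c(a = 3, b = 1, c = 1, d = 3))
  expect_equal(r$ror, 9)
})

test_that("bootstrap CV draws disjoint covering splits and returns B values", {
  sd <- small_signal_data(n = 60, p_noise = 3, seed = 3)
  cv <- bootstrap_cv(sd$features, sd$outcome, "ae", B = 2, n_trees = 20,
                     seed = 9, keep_splits = TRUE)
  expect_equal(nrow(cv$iterations), 2)
  expect_true(all(cv$iterations$c_index >= 0 & cv$iterations$c_index <= 1))
  for (sp in cv$splits) {
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_len(60))
    expect_equal(length(sp$train), floor(0.8 * 60))
  }
  expect_lte(cv$lower, cv$upper)
  expect_error(bootstrap_cv(sd$features, sd$outcome, "ae", B = 0), "B")
})

test_that("bootstrap CV detects a strong single-feature signal", {
  sd <- small_signal_data(n = 150, p_noise = 9, hr = 3, seed = 4)
  cv <- bootstrap_cv(sd$features, sd$outcome, "ae", B = 10, n_trees = 50,
                     seed = 10)
  expect_gt(cv$mean, 0.65)
})

test_that("bootstrap CV stays near 1/2 under pure noise", {
  # averaged over replicate datasets: a single noise dataset carries its
  # own pseudo-signal and its CV mean scatters around 1/2 by several
  # hundredths even at B = 50
  means <- vapply(1:3, function(r) {
    withr::with_seed(77 + r, {
      n <- 200
      x <- matrix(rnorm(n * 5), n, 5,
                  dimnames = list(NULL, paste0("x", 1:5)))
      ids <- sprintf("s%03d", 1:n)
      t <- ceiling(100 * rexp(n) / log(2))
      ev <- as.integer(t < 100)
      t[ev == 0] <- 100
      feats <- dplyr::bind_cols(tibble::tibble(patient_id = ids),
                                tibble::as_tibble(x))
      out <- tibble::tibble(patient_id = ids, ae_term = "ae",
                            time_days = as.numeric(t), event = ev)
      bootstrap_cv(feats, out, "ae", B = 50, n_trees = 30, seed = 123)$mean
    })
  }, numeric(1))
  expect_gte(mean(means), 0.45)
  expect_lte(mean(means), 0.55)
})

test_that("leave-one-out CV holds each patient out exactly once", {
  sd <- small_signal_data(n = 40, p_noise = 3, hr = 3, seed = 6)
  # structural check at small n: n predictions, ids preserved
  loo <- loo_cv(sd$features, sd$outcome, "ae", n_trees = 15, seed = 2)
  expect_equal(nrow(loo$predictions), 40)
  expect_setequal(loo$predictions$patient_id, sd$features$patient_id)
  expect_true(loo$c_index >= 0 && loo$c_index <= 1)
})

test_that("leave-one-out CV recovers signal on informative data", {
  sd <- small_signal_data(n = 150, p_noise = 4, hr = 3, seed = 8)
  loo <- loo_cv(sd$features, sd$outcome, "ae", n_trees = 25, seed = 3)
  expect_gt(loo$c_index, 0.6)
})

test_that("validation metrics cover the boundary cases", {
  # predictions equal to incidences: perfect
  obs <- c(0.02, 0.05, 0.12, 0.2, 0.4, 0.15)
  m <- validation_metrics(obs, obs, threshold = 0.10)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$pearson_r, 1)
  # all-zero predictions with some frequent AEs
  m0 <- validation_metrics(rep(0, 6), obs, threshold = 0.10)
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$specificity, 1)
})

test_that("external validation on a same-mechanism cohort is specific", {
  # training cohort with one real signal AE and many rare null AEs
  make_cohort <- function(seed, n = 150) {
    withr::with_seed(seed, {
      x <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(NULL, paste0("k", 1:6)))
      ids <- sprintf("c%03d", 1:n)
      feats <- dplyr::bind_cols(tibble::tibble(patient_id = ids),
                                tibble::as_tibble(x))
      terms <- c("common_ae", paste0("rare_ae_", 1:8))
      frac <- c(0.45, rep(0.04, 8))
      out <- purrr::map2(terms, frac, function(tm, f) {
        eta <- if (tm == "common_ae") log(2.5) * x[, 1] else 0
        t <- 365 * rexp(n) / (-log(1 - f) * exp(eta - mean(eta)))
        days <- ceiling(t)
        ev <- as.integer(days < 365)
        days[ev == 0] <- 365
        tibble::tibble(patient_id = ids, ae_term = tm,
                       time_days = as.numeric(days), event = ev)
      })
      list(features = feats, outcomes = dplyr::bind_rows(out))
    })
  }
  train <- make_cohort(1)
  ext <- make_cohort(2)
  models <- fit_ae_models(train$features, train$outcomes, n_trees = 40,
                          seed = 5)
  rep <- suppressWarnings( # horizon may sit past the training event grid
    external_validate(models, ext$features, ext$outcomes, threshold = 0.10))
  expect_gt(rep$metrics$specificity, 0.95)
  expect_equal(rep$metrics$sensitivity, 1)
  expect_true(all(rep$table$predicted >= 0 & rep$table$predicted <= 1))
})

test_that("external validation clips horizons beyond the model grid", {
  sd <- small_signal_data(n = 60, p_noise = 2, seed = 12)
  models <- list(ae = fit_survival_forest(sd$features, sd$outcome,
                                          n_trees = 20, seed = 1))
  expect_warning(
    external_validate(models, sd$features, sd$outcome, horizon = 10000),
    "clipped"
  )
})
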