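test_that("kinome simulation honours sparsity extremes and the seed", {
  cfg <- simulation_config(n_drugs = 4, n_kinases = 30,
                           patients_per_drug = 5)
  p1 <- simulate_kinome(cfg, seed = 3)
  p2 <- simulate_kinome(cfg, seed = 3)
  expect_identical(p1, p2)
  expect_false(identical(p1, simulate_kinome(cfg, seed = 4)))
  validate_kinome_panel(p1)
  # sparsity 1: fully missing panel
  cfg1 <- simulation_config(n_drugs = 4, n_kinases = 30,
                            patients_per_drug = 5, kd_sparsity = 1)
  expect_true(all(is.na(as.matrix(simulate_kinome(cfg1, 1)[-1]))))
  # sparsity 0: fully observed panel
  cfg0 <- simulation_config(n_drugs = 4, n_kinases = 30,
                            patients_per_drug = 5, kd_sparsity = 0)
  expect_false(anyNA(as.matrix(simulate_kinome(cfg0, 1)[-1])))
})

test_that("exposures are positive log-normals with the configured CV", {
  cfg <- simulation_config(n_drugs = 2, n_kinases = 10,
                           patients_per_drug = 250, exposure_cv = 0.5)
  pts <- simulate_exposures(cfg, seed = 5)
  expect_true(all(pts$cave_ss > 0))
  emp_cv <- pts |>
    dplyr::group_by(drug_id) |>
    dplyr::summarise(cv = sd(cave_ss) / mean(cave_ss))
  expect_true(all(abs(emp_cv$cv - 0.5) < 0.1)) # within 20% of configured
  # zero variability: every patient at the drug median
  cfg0 <- simulation_config(n_drugs = 2, n_kinases = 10,
                            patients_per_drug = 20, exposure_cv = 0)
  pts0 <- simulate_exposures(cfg0, seed = 5)
  expect_equal(as.numeric(tapply(pts0$cave_ss, pts0$drug_id,
                                 function(x) length(unique(x)))), c(1, 1))
})

test_that("administrative censoring at day 1 censors everyone", {
  cfg <- simulation_config(
    n_drugs = 2, n_kinases = 10, patients_per_drug = 20,
    ae_terms = list(ae_1 = list(n_causal = 2, hr_per_sd = 2,
                                causal_kinases = NULL,
                                baseline = list(family = "exponential",
                                                event_fraction = 0.5),
                                censor_day = 1)))
  ds <- simulate_dataset(cfg, seed = 2)
  expect_true(all(ds$outcomes$event == 0L))
  expect_true(all(ds$outcomes$time_days == 1))
})

test_that("event fraction shrinks as censoring comes earlier", {
  frac <- vapply(c(50, 150, 365), function(cd) {
    cfg <- simulation_config(
      n_drugs = 4, n_kinases = 20, patients_per_drug = 50,
      ae_terms = list(ae_1 = list(n_causal = 2, hr_per_sd = 2,
                                  causal_kinases = NULL,
                                  baseline = list(family = "exponential",
                                                  event_fraction = 0.5),
                                  censor_day = cd)))
    ds <- simulate_dataset(cfg, seed = 7)
    mean(ds$outcomes$event)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("doubling a causal feature shortens simulated event times", {
  withr::with_seed(13, {
    n <- 1000
    feats <- tibble::tibble(patient_id = sprintf("p%04d", 1:n),
                            KINA = rep(10, n), KINB = rnorm(n, 5, 1))
    cfg <- simulation_config(
      n_drugs = 1, n_kinases = 2, patients_per_drug = n,
      ae_terms = list(ae_1 = list(n_causal = 1, hr_per_sd = 3,
                                  causal_kinases = "KINA",
                                  baseline = list(family = "exponential",
                                                  event_fraction = 0.5),
                                  censor_day = 10000)))
    # KINA constant at 10 vs constant at 20: beta is resolved on pooled sd,
    # so simulate the two cohorts jointly
    feats2 <- feats
    feats2$KINA <- 20
    both <- dplyr::bind_rows(feats, feats2)
    both$patient_id <- sprintf("p%04d", seq_len(2 * n))
    sim <- simulate_outcomes(both, cfg, seed = 3)
    t_lo <- sim$outcomes$time_days[1:n]
    t_hi <- sim$outcomes$time_days[(n + 1):(2 * n)]
    expect_lt(median(t_hi), median(t_lo))
  })
})

test_that("a lone strong causal kinase anti-correlates with event times", {
  cfg <- simulation_config(
    n_drugs = 4, n_kinases = 20, patients_per_drug = 50,
    ae_terms = list(ae_1 = list(n_causal = 1, hr_per_sd = 4,
                                causal_kinases = NULL,
                                baseline = list(family = "exponential",
                                                event_fraction = 0.6),
                                censor_day = 365)))
  ds <- simulate_dataset(cfg, seed = 11)
  causal <- ds$ground_truth$ae_1$causal_kinases
  ev <- ds$outcomes$event == 1
  tau <- cor(ds$features[[causal]][ev], ds$outcomes$time_days[ev],
             method = "kendall")
  expect_lt(tau, 0)
})

test_that("no-signal configurations yield chance-level forests", {
  cfg <- simulation_config(
    n_drugs = 4, n_kinases = 20, patients_per_drug = 50,
    ae_terms = list(ae_1 = list(n_causal = 2, hr_per_sd = 1, # HR 1 = no effect
                                causal_kinases = NULL,
                                baseline = list(family = "exponential",
                                                event_fraction = 0.5),
                                censor_day = 365)))
  ds <- simulate_dataset(cfg, seed = 19)
  f <- fit_survival_forest(ds$features,
                           dplyr::filter(ds$outcomes, ae_term == "ae_1"),
                           n_trees = 100, seed = 5)
  expect_lt(abs(oob_concordance(f) - 0.5), 0.06)
})

test_that("ground truth lists exactly the configured causal kinases", {
  cfg <- simulation_config(n_drugs = 3, n_kinases = 15,
                           patients_per_drug = 10,
                           ae_terms = list(ae_1 = list(
                             n_causal = 2, hr_per_sd = 2,
                             causal_kinases = c("KIN003", "KIN007"),
                             baseline = list(family = "exponential",
                                             event_fraction = 0.4),
                             censor_day = 180)))
  ds <- simulate_dataset(cfg, seed = 1)
  expect_equal(ds$ground_truth$ae_1$causal_kinases, c("KIN003", "KIN007"))
  expect_length(ds$ground_truth$ae_1$beta, 2)
})

test_that("dataset directories are byte-stable and round-trip losslessly", {
  cfg <- simulation_config(n_drugs = 3, n_kinases = 12,
                           patients_per_drug = 15)
  d1 <- file.path(tempdir(), "ds1")
  d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  ds <- generate_dataset(cfg, d1, seed = 21)
  generate_dataset(cfg, d2, seed = 21)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  back <- read_dataset(d1)
  expect_equal(as.data.frame(back$patients), as.data.frame(ds$patients),
               tolerance = 1e-9)
  expect_equal(as.data.frame(back$outcomes), as.data.frame(ds$outcomes),
               tolerance = 1e-9)
  expect_equal(as.data.frame(back$panel), as.data.frame(ds$panel),
               tolerance = 1e-9)
  expect_equal(back$ground_truth$ae_1$causal_kinases,
               ds$ground_truth$ae_1$causal_kinases)
  unlink(c(d1, d2), recursive = TRUE)
})
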