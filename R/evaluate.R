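#' Harrell's concordance index
#'
#' Fraction of permissible pairs whose predicted risk ordering agrees with
#' the observed event-time ordering. A pair (i, j) is permissible when the
#' earlier observed time belongs to a subject with an event and the times
#' differ (the shorter survivor is then known to have failed first despite
#' censoring). Ties in risk score count 1/2. C = 0.5 is a random model,
#' 1 a perfect ranking.
#'
#' @param times Observed times.
#' @param events 0/1 event indicators.
#' @param risk Risk scores; higher = earlier predicted event.
#' @return Scalar in `[0, 1]`.
#' @export
harrell_c <- function(times, events, risk) {
  n <- length(times)
  stopifnot(length(events) == n, length(risk) == n,
            all(events %in% c(0, 1)), all(is.finite(risk)))
  permissible <- outer(times, times, "<") & matrix(events == 1, n, n)
  np <- sum(permissible)
  if (np == 0) {
    stop("no permissible pairs: C-index is undefined", call. = FALSE)
  }
  conc <- sum(outer(risk, risk, ">") & permissible)
  ties <- sum(outer(risk, risk, "==") & permissible)
  (conc + 0.5 * ties) / np
}

has_permissible_pair <- function(times, events) {
  any(outer(times, times, "<") & matrix(events == 1, length(times),
                                        length(times)))
}

#' Bootstrap cross-validation of predictive concordance
#'
#' Repeated split-sample validation: in each of `B` iterations a fraction
#' `train_frac` of the patients is drawn *without replacement* as the
#' training set, a forest is fitted on it, and Harrell's C of the ensemble
#' mortality on the held-out remainder is recorded. Iterations whose split
#' leaves either side without events (or the test side without a
#' permissible pair) are redrawn. The summary reports the mean C and the
#' empirical central 90% interval (5th-95th percentiles) of the C
#' distribution.
#'
#' @param features Feature table.
#' @param outcomes Long outcome table `patient_id`, `ae_term`, `time_days`,
#'   `event`.
#' @param ae_term Customized AE term to evaluate.
#' @param B Number of iterations (default 500).
#' @param train_frac Training fraction (default 0.8).
#' @param n_trees,mtry,min_node_size,min_node_events Forest configuration
#'   per iteration.
#' @param seed Master seed; every iteration's seed descends from it and is
#'   recorded for replay.
#' @param keep_splits Record train/test indices per iteration.
#' @return Object of class `cv_result`.
#' @export
bootstrap_cv <- function(features, outcomes, ae_term, B = 500,
                         train_frac = 0.8, n_trees = 150, mtry = NULL,
                         min_node_size = 15, min_node_events = 3, seed = 1L,
                         keep_splits = FALSE) {
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  stopifnot(train_frac > 0, train_frac < 1)
  out <- dplyr::filter(outcomes, .data$ae_term == !!ae_term)
  if (nrow(out) == 0) stop("unknown AE term: ", ae_term, call. = FALSE)
  d <- align_features_outcome(features, out)
  n <- length(d$time)
  n_train <- floor(train_frac * n)
  stopifnot(n_train >= 2, n - n_train >= 2)
  iter_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, B))
  rows <- vector("list", B)
  splits <- if (keep_splits) vector("list", B) else NULL
  for (b in seq_len(B)) {
    split <- with_seed(iter_seeds[b], {
      for (attempt in seq_len(100L)) {
        tr <- sort(sample.int(n, n_train))
        te <- setdiff(seq_len(n), tr)
        if (sum(d$event[tr]) >= 1 &&
            has_permissible_pair(d$time[te], d$event[te])) {
          break
        }
        tr <- NULL
      }
      if (is.null(tr)) {
        stop("could not draw a usable train/test split for '", ae_term, "'",
             call. = FALSE)
      }
      list(train = tr, test = te)
    })
    forest <- fit_survival_forest(
      features[split$train, , drop = FALSE], out,
      n_trees = n_trees, mtry = mtry, min_node_size = min_node_size,
      min_node_events = min_node_events, seed = iter_seeds[b]
    )
    mort <- predict_mortality(forest, features[split$test, , drop = FALSE])
    ci <- harrell_c(d$time[split$test], d$event[split$test], mort$mortality)
    rows[[b]] <- tibble::tibble(iteration = b, seed = iter_seeds[b],
                                n_train = length(split$train),
                                n_test = length(split$test), c_index = ci)
    if (keep_splits) splits[[b]] <- split
  }
  iters <- dplyr::bind_rows(rows)
  structure(
    list(ae_term = ae_term, iterations = iters,
         mean = mean(iters$c_index),
         lower = unname(quantile(iters$c_index, 0.05)),
         upper = unname(quantile(iters$c_index, 0.95)),
         B = B, train_frac = train_frac, seed = as.integer(seed),
         splits = splits),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Bootstrap cross-validation for '%s' (B = %d, train %.0f%%)\n",
              x$ae_term, x$B, 100 * x$train_frac))
  cat(sprintf("  C-index %.3f (90%% interval %.3f, %.3f)\n",
              x$mean, x$lower, x$upper))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$iterations

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(ae_term = x$ae_term, B = x$B, mean_c = x$mean,
                 lower_90 = x$lower, upper_90 = x$upper)
}

#' Leave-one-out cross-validation
#'
#' Fits one forest per patient, each time leaving that patient out, scores
#' the left-out patient by ensemble mortality, and pools all held-out
#' scores into a single Harrell's C. This is the patient-level counterpart
#' of [bootstrap_cv()].
#'
#' @inheritParams bootstrap_cv
#' @param n_trees Trees per left-out fit.
#' @return Object of class `loo_result`: `$predictions` (per-patient
#'   held-out mortality) and `$c_index` (pooled C).
#' @export
loo_cv <- function(features, outcomes, ae_term, n_trees = 100, mtry = NULL,
                   min_node_size = 15, min_node_events = 3, seed = 1L) {
  out <- dplyr::filter(outcomes, .data$ae_term == !!ae_term)
  if (nrow(out) == 0) stop("unknown AE term: ", ae_term, call. = FALSE)
  d <- align_features_outcome(features, out)
  n <- length(d$time)
  if (n < 3) stop("leave-one-out needs at least 3 patients", call. = FALSE)
  fold_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  mort <- numeric(n)
  for (i in seq_len(n)) {
    forest <- fit_survival_forest(
      features[-i, , drop = FALSE], out,
      n_trees = n_trees, mtry = mtry, min_node_size = min_node_size,
      min_node_events = min_node_events, seed = fold_seeds[i]
    )
    mort[i] <- predict_mortality(forest, features[i, , drop = FALSE])$mortality
  }
  preds <- tibble::tibble(patient_id = d$patient_id, mortality = mort,
                          time_days = d$time, event = d$event)
  structure(
    list(ae_term = ae_term, predictions = preds,
         c_index = harrell_c(d$time, d$event, mort), seed = as.integer(seed)),
    class = "loo_result"
  )
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation for '%s' (n = %d)\n",
              x$ae_term, nrow(x$predictions)))
  cat(sprintf("  pooled C-index %.3f\n", x$c_index))
  invisible(x)
}

#' @export
tidy.loo_result <- function(x, ...) x$predictions

#' @export
glance.loo_result <- function(x, ...) {
  tibble::tibble(ae_term = x$ae_term, n = nrow(x$predictions),
                 c_index = x$c_index)
}

#' Threshold classification metrics for external validation
#'
#' Given per-AE model-predicted probabilities and observed incidences,
#' classifies each AE as predicted-frequent (`predicted >= threshold`) vs
#' observed-frequent (`observed >= threshold`) and reports sensitivity,
#' specificity, and the Pearson correlation (with two-sided p value)
#' between predicted probability and observed incidence among the
#' observed-frequent ("frequently reported") AEs.
#'
#' @param predicted Predicted probabilities, one per AE term.
#' @param observed Observed incidences, one per AE term.
#' @param threshold Frequent-AE threshold (default 0.10).
#' @return One-row tibble: `sensitivity`, `specificity`, `pearson_r`,
#'   `pearson_p`, `n_positive`, `n_negative`.
#' @export
validation_metrics <- function(predicted, observed, threshold = 0.10) {
  stopifnot(length(predicted) == length(observed),
            all(predicted >= 0 & predicted <= 1),
            all(observed >= 0 & observed <= 1))
  pred_pos <- predicted >= threshold
  obs_pos <- observed >= threshold
  sens <- if (any(obs_pos)) mean(pred_pos[obs_pos]) else NA_real_
  spec <- if (any(!obs_pos)) mean(!pred_pos[!obs_pos]) else NA_real_
  r <- p <- NA_real_
  if (sum(obs_pos) >= 3 && sd(predicted[obs_pos]) > 0 &&
      sd(observed[obs_pos]) > 0) {
    ct <- cor.test(predicted[obs_pos], observed[obs_pos])
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  tibble::tibble(sensitivity = sens, specificity = spec,
                 pearson_r = r, pearson_p = p,
                 n_positive = sum(obs_pos), n_negative = sum(!obs_pos))
}

#' External validation on an independent cohort
#'
#' Applies per-AE forests trained on one population to an external cohort
#' that shares the kinase feature space. For every AE term the predicted
#' probability is the mean over external patients of `1 - S(horizon)` from
#' the ensemble survival curve; it is compared with the observed incidence
#' (events with onset on or before the horizon) at the frequent-AE
#' threshold, yielding sensitivity, specificity, and the Pearson
#' correlation among frequently reported AEs.
#'
#' @param models Named list of fitted `survival_forest` objects, names =
#'   AE terms (see [fit_ae_models()]).
#' @param features External-cohort feature table (same kinase columns).
#' @param outcomes External-cohort outcome table.
#' @param threshold Frequent-AE threshold (default 0.10; 0.15 and 0.20 are
#'   common sensitivity analyses).
#' @param horizon Probability horizon in days; default the external
#'   cohort's maximum follow-up. Horizons beyond a model's event-time grid
#'   are clipped to the grid maximum with a warning.
#' @return Object of class `external_validation`.
#' @export
external_validate <- function(models, features, outcomes, threshold = 0.10,
                              horizon = NULL) {
  stopifnot(is.list(models), !is.null(names(models)))
  terms <- intersect(names(models), unique(outcomes$ae_term))
  if (length(terms) == 0) {
    stop("no model AE term present in the external outcomes", call. = FALSE)
  }
  horizon <- horizon %||% max(outcomes$time_days)
  rows <- purrr::map(terms, function(tm) {
    forest <- models[[tm]]
    hz <- horizon
    gmax <- max(forest$time_grid)
    if (hz > gmax) {
      warning(sprintf("horizon %s beyond model grid for '%s'; clipped to %s",
                      hz, tm, gmax), call. = FALSE)
      hz <- gmax
    }
    chf <- ensemble_chf_matrix(forest, features)
    idx <- findInterval(hz, forest$time_grid)
    h_at <- if (idx > 0) chf[, idx] else rep(0, nrow(chf))
    out <- outcomes[outcomes$ae_term == tm, , drop = FALSE]
    tibble::tibble(
      ae_term = tm,
      predicted = mean(1 - exp(-h_at)),
      observed = mean(out$event == 1 & out$time_days <= hz)
    )
  })
  tab <- dplyr::bind_rows(rows)
  metrics <- validation_metrics(tab$predicted, tab$observed, threshold)
  structure(
    list(table = dplyr::mutate(tab,
                               predicted_positive = .data$predicted >= threshold,
                               observed_positive = .data$observed >= threshold),
         metrics = metrics, threshold = threshold, horizon = horizon),
    class = "external_validation"
  )
}

#' @export
print.external_validation <- function(x, ...) {
  cat(sprintf("External validation (%d AE terms, threshold %.0f%%, horizon %s days)\n",
              nrow(x$table), 100 * x$threshold, x$horizon))
  cat(sprintf("  sensitivity %.3f   specificity %.3f   Pearson r %.3f (p %.3g)\n",
              x$metrics$sensitivity, x$metrics$specificity,
              x$metrics$pearson_r, x$metrics$pearson_p))
  invisible(x)
}

#' @export
tidy.external_validation <- function(x, ...) x$table

#' @export
glance.external_validation <- function(x, ...) {
  dplyr::mutate(x$metrics, threshold = x$threshold, horizon = x$horizon)
}

#' Reporting odds ratio for a drug-AE 2x2 table
#'
#' Disproportionality statistic `(a/b) / (c/d) = ad / bc` from reporting
#' counts: `a` AE reports with the drug of interest, `b` non-AE reports
#' with the drug, `c` AE reports with the comparator drugs, `d` non-AE
#' reports with the comparators. A ROR above 1 means the AE is reported
#' more frequently with the drug of interest than with the comparators.
#' When any cell is zero, 0.5 is added to all four cells
#' (Haldane-Anscombe) and the result is flagged `corrected`. The 95%
#' confidence interval uses the usual log-scale standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' @param a,b,c,d Non-negative counts (see above).
#' @return One-row tibble `ror`, `lower`, `upper`, `corrected`.
#' @examples
#' ror(20, 80, 10, 90) # 2.25
#' @export
ror <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(is.finite(counts)), all(counts >= 0))
  if (all(counts == 0)) {
    stop("all four cells are zero: ROR is undefined", call. = FALSE)
  }
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  est <- (counts["a"] * counts["d"]) / (counts["b"] * counts["c"])
  se <- sqrt(sum(1 / counts))
  tibble::tibble(
    ror = unname(est),
    lower = unname(exp(log(est) - 1.96 * se)),
    upper = unname(exp(log(est) + 1.96 * se)),
    corrected = corrected
  )
}

#' Reporting odds ratio from patient-level outcomes
#'
#' Convenience wrapper building the 2x2 table from the integrated data: AE
#' reporters among patients on the drug of interest vs among patients on
#' the comparator drugs (by default, all other drugs in the table).
#'
#' @param outcomes Outcome table `patient_id`, `ae_term`, `event`.
#' @param patients Patient table with `patient_id`, `drug_id`.
#' @param drug_id Drug of interest.
#' @param ae_term AE term of interest.
#' @param comparators Comparator drug identifiers; default all other drugs.
#' @return One-row tibble as [ror()], plus the four counts.
#' @export
ror_from_events <- function(outcomes, patients, drug_id, ae_term,
                            comparators = NULL) {
  comparators <- comparators %||% setdiff(unique(patients$drug_id), drug_id)
  out <- dplyr::filter(outcomes, .data$ae_term == !!ae_term) |>
    dplyr::inner_join(patients[c("patient_id", "drug_id")], by = "patient_id")
  on_drug <- out$drug_id == drug_id
  on_comp <- out$drug_id %in% comparators
  a <- sum(on_drug & out$event == 1)
  b <- sum(on_drug & out$event == 0)
  c <- sum(on_comp & out$event == 1)
  d <- sum(on_comp & out$event == 0)
  dplyr::bind_cols(ror(a, b, c, d), tibble::tibble(a = a, b = b, c = c, d = d))
}
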