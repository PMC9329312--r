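#' Fit a random survival forest
#'
#' Grows an ensemble of binary survival trees for the time to first
#' occurrence of one adverse event. Each tree is grown on a bootstrap sample
#' of the patients (with replacement); at every node, `mtry` candidate
#' predictors are drawn uniformly without replacement and the (predictor,
#' threshold) pair maximizing the standardized log-rank statistic splits the
#' node, candidate thresholds being midpoints between consecutive distinct
#' observed values within the node. A node becomes terminal when its size or
#' event count falls below the configured minima or no admissible split
#' exists; terminal nodes store the Nelson-Aalen cumulative hazard of their
#' members on the shared grid of distinct training event times. The ensemble
#' cumulative hazard is the arithmetic mean of the member-tree hazards.
#'
#' Determinism: identical data, configuration and `seed` give a
#' bit-identical forest. Tie-breaks are deterministic -- among
#' equal-statistic splits the first candidate in the seeded random draw
#' order wins, and within a predictor the smallest qualifying threshold.
#'
#' @param features Feature table: `patient_id` plus numeric predictor
#'   columns (see [compute_inhibition_features()]). No missing values.
#' @param outcome Single-term outcome table: `patient_id`, `time_days`,
#'   `event`. At least one event is required.
#' @param n_trees Number of trees (default 500).
#' @param mtry Candidate predictors per node; default `ceiling(sqrt(p))`.
#' @param min_node_size Minimum (weighted) node size to attempt a split
#'   (default 15).
#' @param min_node_events Minimum (weighted) node events to attempt a split
#'   (default 3).
#' @param bootstrap Draw a with-replacement bootstrap per tree (default
#'   `TRUE`). With `FALSE` every tree sees all patients and no out-of-bag
#'   sets exist (importance becomes unavailable).
#' @param seed Integer master seed for the fit.
#' @return Object of class `survival_forest`.
#' @export
fit_survival_forest <- function(features, outcome, n_trees = 500, mtry = NULL,
                                min_node_size = 15, min_node_events = 3,
                                bootstrap = TRUE, seed = 1L) {
  stopifnot(n_trees >= 1)
  d <- align_features_outcome(features, outcome)
  if (sum(d$event) < 1) {
    stop("cannot fit a survival forest: the outcome has no events",
         call. = FALSE)
  }
  p <- length(d$predictors)
  mtry <- as.integer(mtry %||% ceiling(sqrt(p)))
  stopifnot(mtry >= 1)
  grid <- sort(unique(d$time[d$event == 1]))
  n <- nrow(d$X)
  trees <- vector("list", n_trees)
  oob <- vector("list", n_trees)
  with_seed(seed, {
    tree_seeds <- sample.int(.Machine$integer.max - 1L, n_trees)
    for (t in seq_len(n_trees)) {
      set.seed(tree_seeds[t])
      w <- if (bootstrap) {
        tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      } else {
        rep(1L, n)
      }
      trees[[t]] <- grow_tree_cpp(d$X, d$time, as.integer(d$event),
                                  as.integer(w), grid, mtry,
                                  min_node_size, min_node_events,
                                  tree_seeds[t])
      oob[[t]] <- which(w == 0L)
    }
  })
  structure(
    list(trees = trees, oob = oob, time_grid = grid,
         predictors = d$predictors, patient_id = d$patient_id,
         X = d$X, time = d$time, event = as.integer(d$event),
         config = list(n_trees = as.integer(n_trees), mtry = mtry,
                       min_node_size = min_node_size,
                       min_node_events = min_node_events,
                       bootstrap = bootstrap, seed = as.integer(seed))),
    class = "survival_forest"
  )
}

#' @export
print.survival_forest <- function(x, ...) {
  cat("Random survival forest\n")
  cat(sprintf("  trees: %d   mtry: %d   min node size: %s   min node events: %s\n",
              x$config$n_trees, x$config$mtry, x$config$min_node_size,
              x$config$min_node_events))
  cat(sprintf("  patients: %d   events: %d   predictors: %d   seed: %d\n",
              length(x$time), sum(x$event), length(x$predictors),
              x$config$seed))
  invisible(x)
}

# New-data matrix aligned to the forest's predictor columns.
forest_feature_matrix <- function(forest, features) {
  missing <- setdiff(forest$predictors, names(features))
  if (length(missing) > 0) {
    stop("new data lacks predictor(s): ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(features[forest$predictors])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) {
    stop("missing or non-finite feature values; impute upstream",
         call. = FALSE)
  }
  X
}

# Ensemble CHF matrix (rows = patients, cols = forest grid).
ensemble_chf_matrix <- function(forest, features = NULL) {
  X <- if (is.null(features)) forest$X else forest_feature_matrix(forest, features)
  ensemble_chf_cpp(forest$trees, X)
}

#' Predict ensemble survival and cumulative hazard
#'
#' Drops each patient down every tree, averages the terminal-node
#' Nelson-Aalen cumulative hazards, and converts to survival
#' `S(t) = exp(-H(t))`. Between grid points the curve is a right-continuous
#' step function; requested `times` are looked up accordingly (0 hazard
#' before the first training event time).
#'
#' @param forest A fitted [fit_survival_forest()] object.
#' @param features Feature table with the forest's predictor columns and a
#'   `patient_id` column; default the training data.
#' @param times Evaluation times (days); default the forest's event-time
#'   grid.
#' @return Tibble `patient_id`, `time`, `cumhaz`, `survival`.
#' @export
predict_survival <- function(forest, features = NULL, times = NULL) {
  stopifnot(inherits(forest, "survival_forest"))
  chf <- ensemble_chf_matrix(forest, features)
  ids <- if (is.null(features)) forest$patient_id else features$patient_id
  ids <- ids %||% as.character(seq_len(nrow(chf)))
  tt <- times %||% forest$time_grid
  idx <- findInterval(tt, forest$time_grid)
  H <- cbind(0, chf)[, idx + 1L, drop = FALSE]
  tibble::tibble(
    patient_id = rep(ids, each = length(tt)),
    time = rep(tt, times = nrow(chf)),
    cumhaz = as.vector(t(H)),
    survival = exp(-as.vector(t(H)))
  )
}

#' Ensemble mortality risk score
#'
#' The scalar risk score used throughout evaluation: the ensemble
#' cumulative hazard summed over the event-time grid. Higher mortality =
#' earlier predicted event.
#'
#' @inheritParams predict_survival
#' @return Tibble `patient_id`, `mortality`.
#' @export
predict_mortality <- function(forest, features = NULL) {
  stopifnot(inherits(forest, "survival_forest"))
  chf <- ensemble_chf_matrix(forest, features)
  ids <- if (is.null(features)) forest$patient_id else features$patient_id
  ids <- ids %||% as.character(seq_len(nrow(chf)))
  tibble::tibble(patient_id = ids, mortality = rowSums(chf))
}

# Out-of-bag mortality per training patient (NA when never OOB), plus the
# baseline OOB prediction error 1 - C.
oob_state <- function(forest) {
  mort <- oob_mortality_cpp(forest$trees, forest$oob, forest$X)
  ok <- !is.na(mort)
  if (sum(ok) < 2L) {
    stop("no usable out-of-bag predictions (was the forest fitted with bootstrap = TRUE?)",
         call. = FALSE)
  }
  err <- 1 - harrell_c(forest$time[ok], forest$event[ok], mort[ok])
  list(ok = ok, mortality = mort, error = err)
}

#' Out-of-bag concordance of a forest
#'
#' Harrell's C computed from out-of-bag ensemble mortality: each patient is
#' scored only by the trees whose bootstrap sample excluded them.
#'
#' @param forest A fitted forest (with `bootstrap = TRUE`).
#' @return Scalar C-index.
#' @export
oob_concordance <- function(forest) {
  1 - oob_state(forest)$error
}

#' Permutation variable importance
#'
#' The importance of a predictor is the increase in out-of-bag prediction
#' error (1 minus Harrell's C of tree mortality on the tree's out-of-bag
#' patients) when the predictor's out-of-bag values are randomly permuted,
#' averaged over trees -- the standard Breiman-Cutler scheme for random
#' survival forests. Permuting a predictor the forest relies on degrades
#' the OOB ranking; a predictor never used in any split changes nothing and
#' scores exactly 0. Because every tree contributes its own permutation and
#' error difference, a single importance value already averages over as
#' many permutations as there are trees.
#'
#' @param forest A fitted forest (with `bootstrap = TRUE`).
#' @param predictors Predictors to score; default all.
#' @param n_repeats Rounds of per-tree permutations averaged per predictor
#'   (default 1).
#' @param seed Seed for the permutations; default derived from the forest's
#'   seed.
#' @return Tibble `predictor`, `vimp` in the forest's predictor order.
#' @export
permutation_vimp <- function(forest, predictors = NULL, n_repeats = 1,
                             seed = NULL) {
  stopifnot(inherits(forest, "survival_forest"), n_repeats >= 1)
  if (!forest$config$bootstrap) {
    stop("importance needs out-of-bag sets; refit with bootstrap = TRUE",
         call. = FALSE)
  }
  preds <- predictors %||% forest$predictors
  bad <- setdiff(preds, forest$predictors)
  if (length(bad) > 0) {
    stop("unknown predictor(s): ", paste(head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  seed <- seed %||% derive_seed(forest$config$seed, "vimp")
  cols <- match(preds, forest$predictors) - 1L
  vals <- tree_vimp_cpp(forest$trees, forest$oob, forest$X, forest$time,
                        forest$event, as.integer(cols),
                        as.integer(n_repeats), as.integer(seed))
  tibble::tibble(predictor = preds, vimp = as.numeric(vals))
}

#' Minimal depth of predictors
#'
#' For each tree, the depth (root = 0) of the first node that splits on the
#' predictor; trees that never split on it contribute the tree's maximal
#' depth plus one. The reported value is the average over trees: small
#' minimal depth means the forest uses the predictor early and often, i.e. a
#' strong association.
#'
#' @param forest A fitted forest.
#' @param predictors Predictors to score; default all.
#' @return Tibble `predictor`, `minimal_depth`.
#' @export
minimal_depth <- function(forest, predictors = NULL) {
  stopifnot(inherits(forest, "survival_forest"))
  preds <- predictors %||% forest$predictors
  p <- length(forest$predictors)
  totals <- numeric(p)
  for (tr in forest$trees) {
    sv <- tr$split_var
    dp <- tr$depth
    md <- rep(max(dp) + 1, p)
    used <- sv >= 0L
    if (any(used)) {
      mins <- tapply(dp[used], sv[used], min)
      md[as.integer(names(mins)) + 1L] <- as.numeric(mins)
    }
    totals <- totals + md
  }
  avg <- totals / length(forest$trees)
  tibble::tibble(predictor = preds,
                 minimal_depth = avg[match(preds, forest$predictors)])
}

#' @export
tidy.survival_forest <- function(x, ...) {
  p <- length(x$predictors)
  counts <- numeric(p)
  for (tr in x$trees) {
    used <- tr$split_var[tr$split_var >= 0L]
    if (length(used) > 0) {
      tab <- tabulate(used + 1L, nbins = p)
      counts <- counts + tab
    }
  }
  md <- minimal_depth(x)
  tibble::tibble(predictor = x$predictors, n_splits = counts,
                 minimal_depth = md$minimal_depth)
}

#' @export
glance.survival_forest <- function(x, ...) {
  oob_c <- tryCatch(oob_concordance(x), error = function(e) NA_real_)
  tibble::tibble(
    n_patients = length(x$time),
    n_events = sum(x$event),
    n_predictors = length(x$predictors),
    n_trees = x$config$n_trees,
    mtry = x$config$mtry,
    oob_c_index = oob_c
  )
}
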