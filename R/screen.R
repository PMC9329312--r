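#' Screen one adverse event against the kinome
#'
#' Fits a survival forest for the time to first occurrence of one
#' customized AE term and ranks every predictor by permutation variable
#' importance, with minimal depth reported alongside as a second importance
#' measure. Ranks are by VIMP, descending; ties keep the forest's predictor
#' order, so a re-run with the same seed reproduces the table exactly.
#'
#' @param features Feature table (see [compute_inhibition_features()]).
#' @param outcomes Long outcome table `patient_id`, `ae_term`, `time_days`,
#'   `event`.
#' @param ae_term Customized AE term to screen.
#' @param top_k Size of the headline extract (default 25); stored as an
#'   attribute and used by [top_predictors()] and `autoplot()`.
#' @param n_trees,mtry,min_node_size,min_node_events Forest configuration.
#' @param vimp_repeats Permutations averaged per predictor.
#' @param seed Seed for the forest and the permutations.
#' @param keep_forest Attach the fitted forest as an attribute (needed for
#'   [stratify_survival()] afterwards).
#' @return Tibble of class `vimp_table`: `ae_term`, `predictor`, `vimp`,
#'   `minimal_depth`, `rank`, `fitted`. For a term with no events a one-row
#'   placeholder flagged `fitted = FALSE` is returned with a warning.
#' @export
screen_ae <- function(features, outcomes, ae_term, top_k = 25, n_trees = 150,
                      mtry = NULL, min_node_size = 15, min_node_events = 3,
                      vimp_repeats = 1, seed = 1L, keep_forest = FALSE) {
  out <- dplyr::filter(outcomes, .data$ae_term == !!ae_term)
  if (nrow(out) == 0) stop("unknown AE term: ", ae_term, call. = FALSE)
  if (sum(out$event) < 1) {
    warning("no events for AE term '", ae_term, "'; not fitted",
            call. = FALSE)
    return(unfitted_vimp_table(ae_term, top_k))
  }
  forest <- fit_survival_forest(features, out, n_trees = n_trees,
                                mtry = mtry, min_node_size = min_node_size,
                                min_node_events = min_node_events,
                                seed = seed)
  vi <- permutation_vimp(forest, n_repeats = vimp_repeats,
                         seed = derive_seed(seed, "vimp"))
  md <- minimal_depth(forest)
  tbl <- vi |>
    dplyr::left_join(md, by = "predictor") |>
    dplyr::arrange(dplyr::desc(.data$vimp)) |>
    dplyr::mutate(ae_term = !!ae_term, rank = dplyr::row_number(),
                  fitted = TRUE) |>
    dplyr::select("ae_term", "predictor", "vimp", "minimal_depth", "rank",
                  "fitted")
  class(tbl) <- c("vimp_table", class(tbl))
  attr(tbl, "top_k") <- top_k
  if (keep_forest) attr(tbl, "forest") <- forest
  tbl
}

unfitted_vimp_table <- function(ae_term, top_k) {
  tbl <- tibble::tibble(ae_term = ae_term, predictor = NA_character_,
                        vimp = NA_real_, minimal_depth = NA_real_,
                        rank = NA_integer_, fitted = FALSE)
  class(tbl) <- c("vimp_table", class(tbl))
  attr(tbl, "top_k") <- top_k
  tbl
}

#' Top predictors of a screening table
#'
#' @param table A `vimp_table` from [screen_ae()].
#' @param k Number of predictors (default the table's `top_k` attribute).
#' @return The first `k` rows by VIMP rank.
#' @export
top_predictors <- function(table, k = NULL) {
  stopifnot(inherits(table, "vimp_table"))
  k <- k %||% attr(table, "top_k") %||% 25
  tbl <- table[table$fitted & !is.na(table$rank), , drop = FALSE]
  tbl[order(tbl$rank), , drop = FALSE] |> head(k)
}

#' Kinome-wide screening over many adverse events
#'
#' Runs [screen_ae()] for every requested customized AE term, skipping (but
#' counting) terms with no events, and reports the total number of
#' kinase-AE pairs evaluated: `n_kinases x n_ae_terms`, kinase features
#' only -- demographic covariates are predictors in every forest but are
#' not kinase-AE pairs.
#'
#' @inheritParams screen_ae
#' @param ae_terms Terms to screen; default all terms in `outcomes`.
#' @param kinases Kinase feature names; default from the feature table's
#'   `kinases` attribute (see [kinase_features()]).
#' @param seed Master seed; each term's forest seed descends from it.
#' @return Object of class `screen_result`: `$tables` (row-bound
#'   `vimp_table`s with a `fitted` flag) and `$summary` (one row:
#'   `n_kinases`, `n_ae_terms`, `n_pairs`, `n_fitted`, `n_skipped`).
#' @export
screen_all <- function(features, outcomes, ae_terms = NULL, top_k = 25,
                       n_trees = 150, mtry = NULL, min_node_size = 15,
                       min_node_events = 3, vimp_repeats = 1, seed = 1L,
                       kinases = NULL) {
  terms <- ae_terms %||% sort(unique(outcomes$ae_term))
  kinases <- kinases %||% kinase_features(features)
  counts <- outcomes |>
    dplyr::filter(.data$ae_term %in% terms) |>
    dplyr::group_by(.data$ae_term) |>
    dplyr::summarise(n_events = sum(.data$event), .groups = "drop")
  n_events <- setNames(counts$n_events, counts$ae_term)
  tables <- purrr::map(terms, function(tm) {
    if (!tm %in% names(n_events) || n_events[[tm]] < 1) {
      return(unfitted_vimp_table(tm, top_k))
    }
    screen_ae(features, outcomes, tm, top_k = top_k, n_trees = n_trees,
              mtry = mtry, min_node_size = min_node_size,
              min_node_events = min_node_events,
              vimp_repeats = vimp_repeats, seed = derive_seed(seed, tm))
  })
  skipped <- terms[vapply(tables, function(t) !any(t$fitted), logical(1))]
  if (length(skipped) > 0) {
    message(length(skipped), " AE term(s) had no events and were not fitted")
  }
  tbl <- dplyr::bind_rows(tables)
  structure(
    list(
      tables = tbl,
      summary = tibble::tibble(
        n_kinases = length(kinases),
        n_ae_terms = length(terms),
        n_pairs = length(kinases) * length(terms),
        n_fitted = length(terms) - length(skipped),
        n_skipped = length(skipped)
      ),
      top_k = top_k, seed = as.integer(seed)
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Kinome-wide screen: %d kinases x %d AE terms = %d KI-AE pairs evaluated\n",
              s$n_kinases, s$n_ae_terms, s$n_pairs))
  cat(sprintf("  %d term(s) fitted, %d skipped (no events)\n",
              s$n_fitted, s$n_skipped))
  invisible(x)
}

#' @export
tidy.screen_result <- function(x, ...) x$tables

#' @export
glance.screen_result <- function(x, ...) x$summary

#' Fit one forest per adverse-event term
#'
#' Companion to [external_validate()]: fits a named list of survival
#' forests, one per term with at least one event.
#'
#' @inheritParams screen_all
#' @return Named list of `survival_forest` objects.
#' @export
fit_ae_models <- function(features, outcomes, ae_terms = NULL, n_trees = 150,
                          mtry = NULL, min_node_size = 15,
                          min_node_events = 3, seed = 1L) {
  terms <- ae_terms %||% sort(unique(outcomes$ae_term))
  models <- list()
  for (tm in terms) {
    out <- dplyr::filter(outcomes, .data$ae_term == !!tm)
    if (nrow(out) == 0 || sum(out$event) < 1) next
    models[[tm]] <- fit_survival_forest(
      features, out, n_trees = n_trees, mtry = mtry,
      min_node_size = min_node_size, min_node_events = min_node_events,
      seed = derive_seed(seed, tm)
    )
  }
  models
}

#' Median-split stratified ensemble survival curves
#'
#' Splits the patients at the median of one kinase-inhibition feature --
#' "higher inhibition" strictly above the median, "lower inhibition" at or
#' below it (ties go to the lower stratum) -- and averages the
#' forest-predicted ensemble survival curves pointwise within each stratum.
#' The 95% pointwise band is the normal approximation
#' `mean +/- 1.96 * se` across the stratum's patients, clamped to `[0, 1]`.
#' Diverging strata indicate that predicted event onset tracks the degree
#' of inhibition of that kinase.
#'
#' @param forest Forest fitted for the AE term of interest.
#' @param kinase Kinase feature to stratify on.
#' @param features Feature table; default the forest's training data.
#' @return Tibble of class `stratified_curves`: `time`, `stratum`,
#'   `mean_survival`, `lower`, `upper`; attributes `kinase` and `sizes`.
#' @export
stratify_survival <- function(forest, kinase, features = NULL) {
  stopifnot(inherits(forest, "survival_forest"))
  if (!kinase %in% forest$predictors) {
    stop("'", kinase, "' is not a predictor of this forest", call. = FALSE)
  }
  X <- if (is.null(features)) forest$X else forest_feature_matrix(forest, features)
  x <- X[, kinase]
  med <- median(x)
  high <- x > med
  if (!any(high) || all(high)) {
    stop("cannot median-split '", kinase,
         "': feature is constant (or effectively so) across patients",
         call. = FALSE)
  }
  surv <- exp(-ensemble_chf_cpp(forest$trees, X))
  strata <- list("higher inhibition" = which(high),
                 "lower inhibition" = which(!high))
  rows <- purrr::imap(strata, function(idx, label) {
    s <- surv[idx, , drop = FALSE]
    m <- colMeans(s)
    se <- apply(s, 2, sd) / sqrt(length(idx))
    tibble::tibble(time = forest$time_grid, stratum = label,
                   mean_survival = m,
                   lower = pmax(0, m - 1.96 * se),
                   upper = pmin(1, m + 1.96 * se))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stratified_curves", class(out))
  attr(out, "kinase") <- kinase
  attr(out, "sizes") <- vapply(strata, length, integer(1))
  out
}
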