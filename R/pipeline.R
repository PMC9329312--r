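#' Run the integrated screening pipeline
#'
#' Executes the full workflow -- obtain data (simulate, or read the CSV
#' layout), integrate features, screen AE terms kinome-wide, stratify the
#' top kinase per term, cross-validate -- and writes every result plus a
#' run manifest to an output directory. Every random draw descends from
#' the single master `seed` through a documented hierarchical scheme
#' (master seed, then per-stage seeds, then per-term / per-tree seeds), so
#' a rerun with the same configuration and seed reproduces the output
#' directory byte for byte; wall-clock stage timings go to `run.log`,
#' outside the deterministic manifest.
#'
#' @param config Either a path to a YAML/JSON file or a list with
#'   elements: `simulation` (arguments for [simulation_config()]) *or*
#'   `inputs` (a dataset directory path, see [read_dataset()]); optional
#'   `screen` (`ae_terms`, `top_k`, `n_trees`, `vimp_repeats`, ...),
#'   `stratify` (`"auto"`, the default, strata on each fitted term's
#'   top-VIMP kinase; or a list of `list(ae_term =, kinase =)`), and
#'   `evaluate` (`B`, `train_frac`, `n_trees`; `NULL` skips
#'   cross-validation).
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return Invisibly, a list with the in-memory results (`dataset`,
#'   `screen`, `curves`, `cv`) and the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  config <- load_pipeline_config(config)
  if (is.null(config$simulation) && is.null(config$inputs)) {
    stop("config must provide either a `simulation` block or an `inputs` path",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("pipeline start, master seed %d\n", as.integer(seed)),
      file = log_path)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    cat(sprintf("stage %-10s %8.2fs\n", name, timings[[name]]),
        file = log_path, append = TRUE)
    res
  }

  dataset <- stage("data", {
    if (!is.null(config$simulation)) {
      sim_cfg <- do.call(simulation_config, config$simulation)
      ds <- simulate_dataset(sim_cfg, derive_seed(seed, "simulate"))
      write_dataset(ds, file.path(out_dir, "dataset"))
      ds
    } else {
      if (!dir.exists(config$inputs)) {
        stop("input dataset directory not found: ", config$inputs,
             call. = FALSE)
      }
      read_dataset(config$inputs)
    }
  })

  sc <- config$screen %||% list()
  screen <- stage("screen", {
    screen_all(dataset$features, dataset$outcomes,
               ae_terms = sc$ae_terms, top_k = sc$top_k %||% 25,
               n_trees = sc$n_trees %||% 150, mtry = sc$mtry,
               min_node_size = sc$min_node_size %||% 15,
               min_node_events = sc$min_node_events %||% 3,
               vimp_repeats = sc$vimp_repeats %||% 1,
               seed = derive_seed(seed, "screen"))
  })
  readr::write_csv(screen$tables, file.path(out_dir, "vimp.csv"))
  readr::write_csv(screen$summary, file.path(out_dir, "screen_summary.csv"))

  strat_cfg <- config$stratify %||% "auto"
  curves <- stage("stratify", {
    pairs <- if (identical(strat_cfg, "auto")) {
      fitted_terms <- unique(screen$tables$ae_term[screen$tables$fitted])
      purrr::map(fitted_terms, function(tm) {
        top <- screen$tables |>
          dplyr::filter(.data$ae_term == tm, .data$fitted,
                        .data$predictor %in% kinase_features(dataset$features)) |>
          dplyr::arrange(.data$rank)
        list(ae_term = tm, kinase = top$predictor[1L])
      })
    } else {
      strat_cfg
    }
    out <- purrr::map(pairs, function(pr) {
      forest <- fit_survival_forest(
        dataset$features,
        dplyr::filter(dataset$outcomes, .data$ae_term == pr$ae_term),
        n_trees = sc$n_trees %||% 150,
        seed = derive_seed(seed, paste0("stratify:", pr$ae_term))
      )
      cv <- stratify_survival(forest, pr$kinase)
      dplyr::mutate(cv, ae_term = pr$ae_term, kinase = pr$kinase)
    })
    dplyr::bind_rows(out)
  })
  readr::write_csv(curves, file.path(out_dir, "stratified_curves.csv"))

  ev <- config$evaluate
  cv <- NULL
  if (!is.null(ev)) {
    cv <- stage("evaluate", {
      terms <- ev$ae_terms %||%
        unique(screen$tables$ae_term[screen$tables$fitted])
      purrr::map(terms, function(tm) {
        bootstrap_cv(dataset$features, dataset$outcomes, tm,
                     B = ev$B %||% 20, train_frac = ev$train_frac %||% 0.8,
                     n_trees = ev$n_trees %||% 50,
                     seed = derive_seed(seed, paste0("cv:", tm)))
      })
    })
    iters <- dplyr::bind_rows(purrr::map(cv, function(r) {
      dplyr::mutate(tidy(r), ae_term = r$ae_term)
    }))
    readr::write_csv(iters, file.path(out_dir, "cv.csv"))
    readr::write_csv(dplyr::bind_rows(purrr::map(cv, glance)),
                     file.path(out_dir, "cv_summary.csv"))
  }

  outputs <- setdiff(list.files(out_dir, recursive = TRUE),
                     c("run.log", "manifest.json"))
  manifest <- list(
    package = "kinomescreen",
    version = as.character(utils::packageVersion("kinomescreen")),
    master_seed = as.integer(seed),
    stage_seeds = list(simulate = derive_seed(seed, "simulate"),
                       screen = derive_seed(seed, "screen")),
    config = config,
    checksums = as.list(tools::md5sum(file.path(out_dir, outputs))) |>
      setNames(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dataset = dataset, screen = screen, curves = curves,
                 cv = cv, manifest = manifest))
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the yaml package", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  config
}

#' Summarise a completed pipeline run
#'
#' Reads the CSV outputs of [run_pipeline()] and prints, per AE term, the
#' event count, the cross-validated C-index summary and the top kinases by
#' permutation importance. Values are read back from the run directory, so
#' the summary always matches the CSVs exactly.
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @param top_n Kinases listed per term (default 10).
#' @return Tibble, one row per fitted AE term, invisibly `NULL` with a
#'   message when the directory holds no run.
#' @export
report_summary <- function(out_dir, top_n = 10) {
  vimp_path <- file.path(out_dir, "vimp.csv")
  if (!dir.exists(out_dir) || !file.exists(vimp_path)) {
    message("no runs found in '", out_dir, "'")
    return(invisible(NULL))
  }
  vimp <- readr::read_csv(vimp_path, show_col_types = FALSE)
  outcomes_path <- file.path(out_dir, "dataset", "outcomes.csv")
  events <- if (file.exists(outcomes_path)) {
    readr::read_csv(outcomes_path, show_col_types = FALSE) |>
      dplyr::group_by(.data$ae_term) |>
      dplyr::summarise(n_events = sum(.data$event), .groups = "drop")
  } else {
    tibble::tibble(ae_term = character(), n_events = integer())
  }
  cv_path <- file.path(out_dir, "cv_summary.csv")
  cv <- if (file.exists(cv_path)) {
    readr::read_csv(cv_path, show_col_types = FALSE)
  } else {
    tibble::tibble(ae_term = character(), mean_c = numeric(),
                   lower_90 = numeric(), upper_90 = numeric())
  }
  out <- vimp |>
    dplyr::filter(.data$fitted) |>
    dplyr::group_by(.data$ae_term) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::summarise(
      top_kinases = paste(head(.data$predictor, top_n), collapse = ", "),
      .groups = "drop"
    ) |>
    dplyr::left_join(events, by = "ae_term") |>
    dplyr::left_join(cv[intersect(names(cv),
                                  c("ae_term", "mean_c", "lower_90",
                                    "upper_90"))],
                     by = "ae_term")
  for (i in seq_len(nrow(out))) {
    cat(sprintf("%s: %s events", out$ae_term[i], out$n_events[i]))
    if ("mean_c" %in% names(out) && !is.na(out$mean_c[i])) {
      cat(sprintf(", C-index %.3f (90%% CI %.3f-%.3f)", out$mean_c[i],
                  out$lower_90[i], out$upper_90[i]))
    }
    cat("\n  top kinases: ", out$top_kinases[i], "\n", sep = "")
  }
  invisible(out)
}
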