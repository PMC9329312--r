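#' Write / read the integrated dataset CSV layout
#'
#' The serialized form of an integrated dataset is a directory of
#' plain-text CSVs -- `kinome.csv`, `patients.csv`, `outcomes.csv`,
#' `ae_records.csv`, `term_map.csv` -- plus `metadata.json` (units and
#' encodings: K_d and C_ave,ss in nM, times in integer days 1-based from
#' treatment start, sex coded 0 = female / 1 = male, the master seed) and,
#' for synthetic data, `ground_truth.json`.
#'
#' @param dataset A `ki_dataset` (see [simulate_dataset()]) or a list with
#'   the same elements.
#' @param dir Directory to write to (created if needed).
#' @return `write_dataset()`: the directory path, invisibly.
#'   `read_dataset()`: a `ki_dataset` list (with `features` rebuilt from
#'   the imputed panel).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_kinome_panel(dataset$panel, file.path(dir, "kinome.csv"))
  readr::write_csv(dataset$patients, file.path(dir, "patients.csv"))
  readr::write_csv(dataset$outcomes, file.path(dir, "outcomes.csv"))
  records <- dataset$outcomes |>
    dplyr::filter(.data$event == 1L) |>
    dplyr::transmute(patient_id = .data$patient_id, ae_term = .data$ae_term,
                     onset_day = as.integer(.data$time_days),
                     grade = .data$grade)
  readr::write_csv(records, file.path(dir, "ae_records.csv"))
  terms <- sort(unique(dataset$outcomes$ae_term))
  readr::write_csv(tibble::tibble(raw_term = terms, customized_term = terms),
                   file.path(dir, "term_map.csv"))
  meta <- list(
    units = list(kd = "nM", cave_ss = "nM", time = "days"),
    encodings = list(sex = "0 = female, 1 = male",
                     time_origin = "day 1 = first day of treatment"),
    seed = dataset$seed
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(dataset$ground_truth)) {
    jsonlite::write_json(dataset$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  need <- c("kinome.csv", "patients.csv", "outcomes.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    stop("dataset directory '", dir, "' lacks: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  panel <- read_kinome_panel(file.path(dir, "kinome.csv"))
  patients <- readr::read_csv(
    file.path(dir, "patients.csv"), show_col_types = FALSE,
    col_types = readr::cols(patient_id = "c", drug_id = "c",
                            followup_days = "i", .default = "d"))
  outcomes <- readr::read_csv(
    file.path(dir, "outcomes.csv"), show_col_types = FALSE,
    col_types = readr::cols(patient_id = "c", ae_term = "c",
                            time_days = "d", event = "i", grade = "i"))
  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_path)) {
    jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  meta_path <- file.path(dir, "metadata.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
  structure(
    list(panel = panel, patients = patients,
         features = compute_inhibition_features(patients, impute_kd(panel)),
         outcomes = outcomes, ground_truth = ground_truth,
         metadata = meta, seed = meta$seed %||% NA_integer_),
    class = "ki_dataset"
  )
}
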