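#' Consolidate raw adverse-event terms into customized preferred terms
#'
#' Clinical AE records use fine-grained dictionary preferred terms; analyses
#' group related terms under one customized preferred term (e.g. "mouth
#' ulceration" under "stomatitis", "nausea" under "vomiting/nausea"). The
#' map is data supplied by the analyst, not code: a two-column table
#' `raw_term` -> `customized_term` (many-to-one). Raw terms absent from the
#' map pass through unchanged as their own customized term.
#'
#' With `merge = TRUE`, records of one patient whose raw terms collapse onto
#' the same customized term are merged, keeping the earliest onset (and the
#' maximum severity grade among the merged records, when a `grade` column is
#' present). Merging can therefore only move a patient's first onset of a
#' customized term earlier, never later. Use `merge = FALSE` when a
#' downstream step still needs the individual records, e.g. grade filtering.
#'
#' @param records Data frame of raw AE records with columns `patient_id`,
#'   `ae_term`, `onset_day` (integer days, 1-based from treatment start) and
#'   optionally `grade` (1-5).
#' @param term_map Data frame with columns `raw_term`, `customized_term`.
#' @param merge Merge same-patient records sharing a customized term.
#' @return Tibble of records with `ae_term` replaced by customized terms.
#' @export
map_ae_terms <- function(records, term_map, merge = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("patient_id", "ae_term", "onset_day") %in% names(records)))
  stopifnot(is.data.frame(term_map),
            all(c("raw_term", "customized_term") %in% names(term_map)))
  if (anyDuplicated(term_map$raw_term) > 0) {
    stop("term map must be a function of raw_term (duplicated raw terms)",
         call. = FALSE)
  }
  if (any(is.na(term_map$customized_term) | term_map$customized_term == "")) {
    stop("customized terms must be non-empty", call. = FALSE)
  }
  out <- tibble::as_tibble(records)
  hit <- match(out$ae_term, term_map$raw_term)
  out$ae_term <- ifelse(is.na(hit), out$ae_term,
                        term_map$customized_term[hit])
  if (!merge) return(out)
  has_grade <- "grade" %in% names(out)
  out <- out |>
    dplyr::group_by(.data$patient_id, .data$ae_term) |>
    dplyr::summarise(
      onset_day = min(.data$onset_day),
      grade = if (has_grade) suppressWarnings(max(.data$grade, na.rm = TRUE)) else NA_integer_,
      .groups = "drop"
    )
  if (!has_grade) out$grade <- NULL
  if (has_grade) out$grade[!is.finite(out$grade)] <- NA_integer_
  out
}

#' Time to first adverse-event occurrence for one patient
#'
#' The response of the survival model: time from treatment start to the
#' first occurrence of the customized AE term. A patient with no occurrence
#' is censored at the end of follow-up (event indicator 0, time equal to the
#' follow-up duration).
#'
#' @param records Mapped AE records (see [map_ae_terms()]).
#' @param patient One-row data frame with `patient_id` and `followup_days`.
#' @param ae_term Customized preferred term of interest.
#' @param min_grade Optional minimum severity grade; records below it are
#'   ignored (e.g. `min_grade = 4` for life-threatening events).
#' @return Named list `time_days`, `event`.
#' @export
extract_time_to_event <- function(records, patient, ae_term, min_grade = NULL) {
  stopifnot(is.data.frame(patient), nrow(patient) == 1L,
            all(c("patient_id", "followup_days") %in% names(patient)))
  fu <- as.numeric(patient$followup_days)
  stopifnot(is.finite(fu), fu >= 1)
  hits <- records[records$patient_id == patient$patient_id &
                    records$ae_term == ae_term, , drop = FALSE]
  if (!is.null(min_grade) && nrow(hits) > 0) {
    stopifnot("grade" %in% names(hits))
    hits <- hits[!is.na(hits$grade) & hits$grade >= min_grade, , drop = FALSE]
  }
  if (nrow(hits) == 0L) {
    return(list(time_days = fu, event = 0L))
  }
  onset <- min(hits$onset_day)
  if (onset > fu) {
    stop(sprintf("onset day %s after end of follow-up (%s) for patient '%s'",
                 onset, fu, patient$patient_id), call. = FALSE)
  }
  list(time_days = as.numeric(onset), event = 1L)
}

#' Build the patient-by-term time-to-event table
#'
#' Vectorised companion of [extract_time_to_event()]: for every patient and
#' every requested customized term, the time to first occurrence and the
#' event indicator. Patients without a record of a term are censored at
#' their follow-up.
#'
#' @param records Mapped AE records.
#' @param patients Patient table with `patient_id`, `followup_days`.
#' @param ae_terms Terms to tabulate; default all terms in `records`.
#' @param min_grade Optional minimum grade filter (see
#'   [extract_time_to_event()]).
#' @return Tibble `patient_id`, `ae_term`, `time_days`, `event`.
#' @export
build_ae_outcomes <- function(records, patients, ae_terms = NULL,
                              min_grade = NULL) {
  stopifnot(all(c("patient_id", "followup_days") %in% names(patients)))
  terms <- ae_terms %||% sort(unique(records$ae_term))
  recs <- tibble::as_tibble(records)
  if (!is.null(min_grade)) {
    stopifnot("grade" %in% names(recs))
    recs <- recs[!is.na(recs$grade) & recs$grade >= min_grade, , drop = FALSE]
  }
  recs <- recs[recs$ae_term %in% terms, , drop = FALSE]
  first <- recs |>
    dplyr::group_by(.data$patient_id, .data$ae_term) |>
    dplyr::summarise(onset_day = min(.data$onset_day), .groups = "drop")
  grid <- tidyr::expand_grid(patient_id = patients$patient_id,
                             ae_term = terms)
  out <- grid |>
    dplyr::left_join(first, by = c("patient_id", "ae_term")) |>
    dplyr::left_join(patients[c("patient_id", "followup_days")],
                     by = "patient_id")
  bad <- !is.na(out$onset_day) & out$onset_day > out$followup_days
  if (any(bad)) {
    stop(sprintf("onset after follow-up for patient '%s', term '%s'",
                 out$patient_id[bad][1L], out$ae_term[bad][1L]), call. = FALSE)
  }
  out |>
    dplyr::mutate(
      event = as.integer(!is.na(.data$onset_day)),
      time_days = as.numeric(ifelse(.data$event == 1L, .data$onset_day,
                                    .data$followup_days))
    ) |>
    dplyr::select("patient_id", "ae_term", "time_days", "event")
}
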