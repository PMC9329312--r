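#' Per-patient kinase-inhibition features
#'
#' Builds the drug-agnostic feature matrix that drives the whole analysis:
#' for patient i on drug j, the inhibition feature against kinase k is the
#' dimensionless ratio `cave_ss_i / kd_{j,k}` of the patient's steady-state
#' average plasma concentration to the drug's dissociation constant, both in
#' nM. Because every patient is represented only by this ratio vector (plus
#' demographics), the drug identity itself drops out of the model: two
#' patients on different drugs with identical ratio vectors are
#' indistinguishable.
#'
#' @param patients Data frame with columns `patient_id`, `drug_id`,
#'   `cave_ss` (nM, positive) and the demographic columns named in
#'   `covariates` (by default `age` in years and `sex` coded 0 = female,
#'   1 = male).
#' @param panel Imputed kinome panel (no missing entries; see [impute_kd()]).
#' @param covariates Character vector of demographic columns to append.
#' @return Tibble: `patient_id`, one column per kinase, then the covariates.
#'   Attributes `kinases` and `covariates` record the split between the two
#'   predictor groups.
#' @examples
#' panel <- impute_kd(tibble::tibble(drug = "a", KIT = 10, ABL1 = NA))
#' pts <- tibble::tibble(patient_id = "p1", drug_id = "a", cave_ss = 100,
#'                       age = 61, sex = 1)
#' compute_inhibition_features(pts, panel)
#' @export
compute_inhibition_features <- function(patients, panel,
                                        covariates = c("age", "sex")) {
  validate_kinome_panel(panel)
  stopifnot(is.data.frame(patients),
            all(c("patient_id", "drug_id", "cave_ss") %in% names(patients)))
  missing_cov <- setdiff(covariates, names(patients))
  if (length(missing_cov) > 0) {
    stop("patients table lacks covariate column(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(patients$patient_id) > 0) {
    stop("duplicated patient_id", call. = FALSE)
  }
  if (any(!is.finite(patients$cave_ss)) || any(patients$cave_ss <= 0)) {
    stop("cave_ss must be positive and finite", call. = FALSE)
  }
  kin <- kinase_columns(panel)
  kd <- as.matrix(panel[kin])
  if (anyNA(kd)) {
    stop("panel has missing K_d entries; run impute_kd() first", call. = FALSE)
  }
  row <- match(patients$drug_id, panel$drug)
  if (anyNA(row)) {
    stop("drug(s) absent from kinome panel: ",
         paste(unique(patients$drug_id[is.na(row)]), collapse = ", "),
         call. = FALSE)
  }
  feat <- patients$cave_ss / kd[row, , drop = FALSE]
  dimnames(feat) <- list(NULL, kin)
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = patients$patient_id),
    tibble::as_tibble(feat),
    tibble::as_tibble(patients[covariates])
  )
  attr(out, "kinases") <- kin
  attr(out, "covariates") <- covariates
  out
}

#' Kinase feature names of a feature table
#'
#' Returns the kinase-feature columns recorded by
#' [compute_inhibition_features()], falling back to "all predictors except
#' `age`/`sex`" when the attribute has been stripped by data wrangling.
#'
#' @param features Feature table.
#' @return Character vector of kinase column names.
#' @export
kinase_features <- function(features) {
  attr(features, "kinases") %||%
    setdiff(predictor_columns(features), c("age", "sex"))
}
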