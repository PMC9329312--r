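#' Validate a kinome dissociation-constant panel
#'
#' A kinome panel is a data frame with a `drug` column of unique drug
#' identifiers and one numeric column per kinase holding dissociation
#' constants (K_d) in nanomolar. Missing entries (`NA`) mean the drug was not
#' profiled against that kinase, or bound too weakly to quantify. All
#' non-missing values must be strictly positive.
#'
#' @param panel Data frame, first column `drug`, remaining columns kinases.
#' @return The panel, invisibly, after validation.
#' @export
validate_kinome_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  if (!"drug" %in% names(panel)) {
    stop("kinome panel must have a `drug` column", call. = FALSE)
  }
  if (anyDuplicated(panel$drug) > 0) {
    stop("drug identifiers must be unique", call. = FALSE)
  }
  kin <- kinase_columns(panel)
  if (length(kin) == 0L) stop("kinome panel has no kinase columns", call. = FALSE)
  if (anyDuplicated(kin) > 0) {
    stop("kinase identifiers must be unique", call. = FALSE)
  }
  for (k in kin) {
    bad <- which(!is.na(panel[[k]]) & panel[[k]] <= 0)
    if (length(bad) > 0) {
      stop(sprintf("non-positive K_d for drug '%s', kinase '%s'",
                   panel$drug[bad[1L]], k), call. = FALSE)
    }
  }
  invisible(panel)
}

kinase_columns <- function(panel) setdiff(names(panel), "drug")

#' Impute missing dissociation constants
#'
#' Replaces every missing K_d entry with a fixed weak-binding constant,
#' 1e4 by default, in the same unit as the panel (nM). A missing entry is
#' read as "no measurable binding at assay concentrations", so the imputed
#' value encodes near-zero inhibition at therapeutic exposures. Observed
#' entries are never changed, and imputation is idempotent.
#'
#' @param panel Kinome panel data frame (see [validate_kinome_panel()]).
#' @param value Imputation constant, nM. Default `1e4`.
#' @return The panel as a tibble with no missing kinase entries.
#' @examples
#' panel <- tibble::tibble(drug = c("a", "b"), KIT = c(NA, 3.2), ABL1 = c(12, NA))
#' impute_kd(panel)
#' @export
impute_kd <- function(panel, value = 1e4) {
  validate_kinome_panel(panel)
  stopifnot(is.numeric(value), length(value) == 1L, value > 0)
  out <- tibble::as_tibble(panel)
  for (k in kinase_columns(out)) {
    out[[k]][is.na(out[[k]])] <- value
  }
  out
}

#' Read / write a kinome panel CSV
#'
#' The on-disk layout is one row per drug: first column `drug`, remaining
#' columns kinase identifiers; an empty cell is a missing K_d.
#'
#' @param path CSV file path.
#' @return [read_kinome_panel()] returns a validated tibble.
#' @export
read_kinome_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                           col_types = readr::cols(drug = "c",
                                                   .default = "d"))
  validate_kinome_panel(panel)
  tibble::as_tibble(panel)
}

#' @rdname read_kinome_panel
#' @param panel Kinome panel data frame.
#' @export
write_kinome_panel <- function(panel, path) {
  validate_kinome_panel(panel)
  readr::write_csv(panel, path, na = "")
  invisible(path)
}
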