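# Internal helpers shared across modules.

# Deterministic child seed from a master seed and a stage label, so every
# random draw in a pipeline descends from one master seed regardless of the
# order stages run in. Plain polynomial string hash folded into [1, 2^31 - 2].
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid 32-bit integers
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer((abs(seed) %% m * 7919 + h) %% (m - 1) + 1)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's
# .Random.seed afterwards so exported functions do not disturb user state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Column names of a feature table that hold predictors (everything numeric
# except the patient identifier).
predictor_columns <- function(features) {
  nm <- setdiff(names(features), "patient_id")
  keep <- vapply(features[nm], is.numeric, logical(1))
  nm[keep]
}

# Align a feature table and a single-term outcome table into matrices/vectors
# ordered as the feature rows. Errors on missing patients or non-finite
# values: imputation is an upstream responsibility.
align_features_outcome <- function(features, outcome) {
  stopifnot("patient_id" %in% names(features), "patient_id" %in% names(outcome))
  if (anyDuplicated(features$patient_id) > 0) {
    stop("duplicated patient_id in `features`", call. = FALSE)
  }
  if (anyDuplicated(outcome$patient_id) > 0) {
    stop("duplicated patient_id in `outcome`; filter to a single AE term first",
         call. = FALSE)
  }
  idx <- match(features$patient_id, outcome$patient_id)
  if (anyNA(idx)) {
    stop("no outcome record for patient(s): ",
         paste(head(features$patient_id[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  preds <- predictor_columns(features)
  X <- as.matrix(features[preds])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) {
    stop("feature matrix contains missing or non-finite values; ",
         "impute upstream (see impute_kd())", call. = FALSE)
  }
  time <- as.numeric(outcome$time_days[idx])
  event <- as.integer(outcome$event[idx])
  stopifnot(all(is.finite(time)), all(time > 0), all(event %in% c(0L, 1L)))
  list(X = X, time = time, event = event,
       patient_id = features$patient_id, predictors = preds)
}

# Step-function lookup of a cumulative quantity on a grid: value at the
# largest grid time <= t, 0 before the first grid point.
step_lookup <- function(grid, values, t) {
  idx <- findInterval(t, grid)
  out <- numeric(length(t))
  out[idx > 0] <- values[idx[idx > 0]]
  out
}
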