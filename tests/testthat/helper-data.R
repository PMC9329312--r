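# Small in-code fixtures shared across test files.

toy_panel <- function() {
  tibble::tibble(
    drug = c("drugA", "drugB", "drugC"),
    KIT  = c(NA, 10, 250),
    ABL1 = c(3.2, NA, 40),
    KDR  = c(25, 5, NA)
  )
}

toy_patients <- function() {
  tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4"),
    drug_id = c("drugA", "drugA", "drugB", "drugC"),
    age = c(55, 61, 48, 70),
    sex = c(0, 1, 1, 0),
    cave_ss = c(100, 50, 200, 500),
    followup_days = c(100L, 100L, 200L, 150L)
  )
}

toy_records <- function() {
  tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p3", "p3"),
    ae_term = c("mouth ulceration", "nausea", "stomatitis",
                "vomiting", "headache"),
    onset_day = c(12L, 5L, 30L, 7L, 40L),
    grade = c(2L, 1L, 3L, 4L, 1L)
  )
}

toy_term_map <- function() {
  tibble::tibble(
    raw_term = c("mouth ulceration", "oral mucosal eruption", "stomatitis",
                 "vomiting", "nausea"),
    customized_term = c("stomatitis", "stomatitis", "stomatitis",
                        "vomiting/nausea", "vomiting/nausea")
  )
}

# A small single-signal survival dataset: one informative feature with a
# configurable hazard ratio per SD, several pure-noise features.
small_signal_data <- function(n = 150, p_noise = 9, hr = 3, censor = 200,
                              seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * (p_noise + 1)), n, p_noise + 1,
                dimnames = list(NULL, c("signal",
                                        paste0("noise", seq_len(p_noise)))))
    eta <- log(hr) * x[, "signal"]
    t_cont <- censor * rexp(n) / (log(2) * exp(eta - mean(eta)))
    days <- ceiling(t_cont)
    event <- as.integer(days < censor)
    days[event == 0L] <- censor
    ids <- sprintf("s%03d", seq_len(n))
    list(
      features = dplyr::bind_cols(tibble::tibble(patient_id = ids),
                                  tibble::as_tibble(x)),
      outcome = tibble::tibble(patient_id = ids, ae_term = "ae",
                               time_days = as.numeric(days), event = event)
    )
  })
}
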