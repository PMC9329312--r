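#' Nelson-Aalen cumulative hazard estimator
#'
#' Nonparametric cumulative hazard `H(t) = sum_{t_k <= t} d_k / n_k` over
#' the distinct event times, with `d_k` events and `n_k` subjects at risk at
#' `t_k`; tied event times are aggregated (Breslow convention). This is the
#' estimator stored in every terminal node of a survival tree.
#'
#' @param times Positive event/censoring times.
#' @param events 0/1 event indicators.
#' @param weights Optional non-negative case weights (bootstrap
#'   multiplicities); default 1.
#' @return Tibble `time`, `cumhaz`, `survival` (`exp(-cumhaz)`), one row per
#'   distinct event time, preceded by the `time = 0` anchor row
#'   (`cumhaz = 0`, `survival = 1`).
#' @examples
#' nelson_aalen(c(1, 2), c(1, 1)) # H(1) = 1/2, H(2) = 1/2 + 1/1
#' @export
nelson_aalen <- function(times, events, weights = NULL) {
  ht <- hazard_table(times, events, weights)
  h <- c(0, cumsum(ht$d / ht$n))
  tibble::tibble(time = c(0, ht$time), cumhaz = h, survival = exp(-h))
}

#' Kaplan-Meier product-limit survival curve
#'
#' `S(t) = prod_{t_k <= t} (1 - d_k / n_k)` over distinct event times, tied
#' events aggregated.
#'
#' @inheritParams nelson_aalen
#' @return Tibble `time`, `survival`, with the `time = 0` anchor row.
#' @export
kaplan_meier <- function(times, events, weights = NULL) {
  ht <- hazard_table(times, events, weights)
  surv <- cumprod(1 - ht$d / ht$n)
  tibble::tibble(time = c(0, ht$time), survival = c(1, surv))
}

# Distinct event times with weighted event counts and at-risk counts.
hazard_table <- function(times, events, weights = NULL) {
  stopifnot(length(times) == length(events), length(times) >= 1,
            all(is.finite(times)), all(events %in% c(0, 1)))
  w <- weights %||% rep(1, length(times))
  stopifnot(length(w) == length(times), all(w >= 0))
  et <- sort(unique(times[events == 1 & w > 0]))
  d <- vapply(et, function(t) sum(w[times == t & events == 1]), numeric(1))
  n <- vapply(et, function(t) sum(w[times >= t]), numeric(1))
  list(time = et, d = d, n = n)
}

#' Standardized log-rank statistic for a proposed node split
#'
#' The node-splitting criterion of the survival trees: the absolute
#' standardized log-rank statistic `|O - E| / sqrt(V)` comparing the
#' proposed left and right daughter groups, with the usual hypergeometric
#' expectation and variance accumulated over distinct event times (tied
#' events aggregated, Breslow convention). Degenerate proposals -- no
#' events, or a grouping with zero variance -- score 0.
#'
#' @inheritParams nelson_aalen
#' @param left Logical vector: membership of the proposed left daughter.
#' @return Non-negative scalar; larger means better survival separation.
#' @export
logrank_split_statistic <- function(times, events, left, weights = NULL) {
  stopifnot(is.logical(left), length(left) == length(times))
  if (!any(left) || all(left)) {
    stop("both sides of a split must be non-empty", call. = FALSE)
  }
  w <- weights %||% rep(1, length(times))
  ht <- hazard_table(times, events, w)
  if (length(ht$time) == 0L) return(0)
  num <- 0
  v <- 0
  for (k in seq_along(ht$time)) {
    t_k <- ht$time[k]
    n_k <- ht$n[k]
    d_k <- ht$d[k]
    n1 <- sum(w[left & times >= t_k])
    d1 <- sum(w[left & times == t_k & events == 1])
    num <- num + d1 - n1 * d_k / n_k
    if (n_k > 1) {
      v <- v + d_k * (n_k - d_k) / (n_k - 1) * n1 * (n_k - n1) / n_k^2
    }
  }
  if (v <= 0) return(0)
  abs(num) / sqrt(v)
}
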