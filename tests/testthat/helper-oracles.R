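# Independent brute-force oracles for the survival primitives. These are
# deliberately naive direct evaluations of the defining formulas, kept free
# of any code path they are used to check.

# Nelson-Aalen: H(t) = sum over distinct event times t_k <= t of d_k / n_k.
oracle_nelson_aalen <- function(times, events, at) {
  vapply(at, function(t) {
    h <- 0
    for (tk in sort(unique(times[events == 1]))) {
      if (tk <= t) {
        d <- sum(times == tk & events == 1)
        n <- sum(times >= tk)
        h <- h + d / n
      }
    }
    h
  }, numeric(1))
}

# Kaplan-Meier: S(t) = prod over distinct event times t_k <= t of (1 - d/n).
oracle_kaplan_meier <- function(times, events, at) {
  vapply(at, function(t) {
    s <- 1
    for (tk in sort(unique(times[events == 1]))) {
      if (tk <= t) {
        d <- sum(times == tk & events == 1)
        n <- sum(times >= tk)
        s <- s * (1 - d / n)
      }
    }
    s
  }, numeric(1))
}

# Standardized log-rank: |sum (d1k - n1k dk/nk)| / sqrt(sum Vk) with the
# hypergeometric variance, accumulated over distinct event times.
oracle_logrank <- function(times, events, left) {
  num <- 0
  v <- 0
  for (tk in sort(unique(times[events == 1]))) {
    n <- sum(times >= tk)
    d <- sum(times == tk & events == 1)
    n1 <- sum(times >= tk & left)
    d1 <- sum(times == tk & events == 1 & left)
    num <- num + (d1 - n1 * d / n)
    if (n > 1) v <- v + d * (n - d) / (n - 1) * n1 * (n - n1) / n^2
  }
  if (v <= 0) return(0)
  abs(num) / sqrt(v)
}

# Harrell's C by exhaustive pair enumeration: pair (i, j) permissible when
# t_i < t_j and subject i had the event; ties in risk score 1/2.
oracle_harrell_c <- function(times, events, risk) {
  conc <- 0
  perm <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (times[i] < times[j] && events[i] == 1) {
        perm <- perm + 1
        if (risk[i] > risk[j]) conc <- conc + 1
        if (risk[i] == risk[j]) conc <- conc + 0.5
      }
    }
  }
  conc / perm
}

# Random tiny survival instance (n <= 10) for oracle-equivalence sweeps.
random_tiny_instance <- function(n = NULL) {
  n <- n %||% sample(3:10, 1)
  times <- sample(1:8, n, replace = TRUE)
  events <- rbinom(n, 1, 0.7)
  if (sum(events) == 0) events[sample(n, 1)] <- 1L
  list(times = as.numeric(times), events = as.integer(events))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
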