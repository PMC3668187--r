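# Independent reference computations used as oracles. These are written
# from first principles (risk-set definitions, hypergeometric
# enumeration) and deliberately do not call the code paths they check.

# Product-limit estimator by hand: S(t) = prod over event times u <= t
# of (1 - d_u / n_u), subjects censored at an event time still at risk.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_u <- sum(time >= ts[i])
    d_u <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_u / n_u)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Mantel-Cox log-rank statistic from the risk-set definition: at each
# event time, observed vs hypergeometric-expected events per group with
# the hypergeometric covariance; statistic = u' V^{-1} u on the first
# k - 1 groups.
oracle_logrank <- function(time, event, group) {
  group <- as.character(group)
  gl <- sort(unique(group))
  k <- length(gl)
  ts <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ts) {
    at <- time >= t
    n <- sum(at)
    d <- sum(event == 1 & time == t)
    ni <- vapply(gl, function(g) sum(at & group == g), numeric(1))
    di <- vapply(gl, function(g) sum(event == 1 & time == t & group == g),
                 numeric(1))
    O <- O + di
    E <- E + d * ni / n
    if (n > 1) {
      mult <- d * (n - d) / (n - 1)
      for (i in seq_len(k)) {
        for (j in seq_len(k)) {
          V[i, j] <- V[i, j] +
            mult * ni[i] * ((i == j) * n - ni[j]) / n^2
        }
      }
    }
  }
  u <- (O - E)[-k]
  drop(t(u) %*% solve(V[-k, -k, drop = FALSE]) %*% u)
}

# Two-sided Fisher p for a 2x2 table by full enumeration of the
# hypergeometric support: sum the probabilities of all tables (with the
# observed margins) whose probability does not exceed the observed
# table's, with a small relative tolerance for float ties.
oracle_fisher2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
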