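# Shared stationarity diagnostic for trailing steady-state windows.
#
# Splits the window in halves and compares their means against a pooled
# standard error. Trajectory samples are autocorrelated (the relaxation
# time typically spans many sampling intervals), so a naive iid SE would
# reject genuinely stationary windows; the variance of each half-mean is
# therefore scaled by an AR(1) effective sample size,
# n_eff = n (1 - rho) / (1 + rho) with rho the lag-1 autocorrelation.
# Returns TRUE when the window is consistent with stationarity.
.is_stationary <- function(w, n_se = 2) {
  n <- length(w)
  if (n < 6L) return(TRUE)
  h1 <- w[seq_len(n %/% 2)]
  h2 <- w[(n %/% 2 + 1L):n]
  ess <- function(x) {
    m <- length(x)
    if (stats::var(x) == 0) return(m)
    rho <- stats::cor(x[-m], x[-1])
    if (!is.finite(rho)) return(m)
    rho <- min(max(rho, 0), 0.99)
    max(2, m * (1 - rho) / (1 + rho))
  }
  se <- sqrt(stats::var(h1) / ess(h1) + stats::var(h2) / ess(h2))
  drift <- abs(mean(h1) - mean(h2))
  # a drift below 2% of the level is negligible regardless of the SE
  # (deterministic saturating tails drift by ever-smaller amounts that a
  # variance-based test would otherwise flag)
  drift <= 0.02 * abs(mean(w)) || !is.finite(se) || se == 0 || drift <= n_se * se
}
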