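# Independent oracles used across the suite. Deliberately naive: plain
# loops and closed forms, sharing no code with the implementation paths
# they check.

# Best attainable pinball loss over all lines through point pairs,
# evaluated with a scalar double loop.
oracle_pinball_best <- function(bw, sf, tau) {
  n <- length(bw)
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(bw[i] - bw[j]) < 1e-12) next
      b <- (sf[j] - sf[i]) / (bw[j] - bw[i])
      a <- sf[i] - b * bw[i]
      loss <- 0
      for (k in seq_len(n)) {
        r <- sf[k] - a - b * bw[k]
        loss <- loss + r * (tau - (r < 0))
      }
      if (loss < best) best <- loss
    }
  }
  best
}

# Logistic log-likelihood maximised by a generic numeric optimizer.
oracle_logistic_loglik <- function(sf, y) {
  nll <- function(b) {
    eta <- b[1] + b[2] * sf
    -sum(y * eta - log1p(exp(eta)))
  }
  f1 <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-14))
  f2 <- stats::optim(f1$par, nll, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-14))
  -min(f1$value, f2$value)
}

# Relative risk from unit-weight 2x2 cell counts by direct probability
# arithmetic.
oracle_rr <- function(poor_poor, good_poor, poor_good, good_good) {
  (poor_poor / (poor_poor + good_poor)) /
    (poor_good / (poor_good + good_good))
}

# Flags table for a given unit-weight 2x2 cell count vector.
flags_from_cells <- function(poor_poor, good_poor, poor_good, good_good) {
  data.frame(
    sf_status = rep(c("poor", "poor", "good", "good"),
                    c(poor_poor, good_poor, poor_good, good_good)),
    bio_status = rep(c("poor", "good", "poor", "good"),
                     c(poor_poor, good_poor, poor_good, good_good)),
    weight = 1)
}

# Small simulated dataset under study-like conditions, shared by several
# suites.
sim_small <- function(seed, n = 400, compute_truth = FALSE, ...) {
  cfg <- simulation_config(n_sites = n, seed = seed, ...)
  simulate_events(cfg, compute_truth = compute_truth)
}
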