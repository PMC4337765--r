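# Independent oracles, deliberately brute-force and written against the
# definitions, not against the implementation.

# O(n^2) discrete Fourier transform applying the Gaussian spectral
# envelope term by term: X_k = sum_t x_t exp(-2*pi*i*k*t/n), multiply by
# exp(-omega_k^2 / (2 sigma^2)) with omega the signed frequency index,
# invert with the conjugate double sum.
dft_lowpass_oracle <- function(x, cutoff_period) {
  n <- length(x)
  sigma <- n / cutoff_period
  ks <- 0:(n - 1)
  X <- vapply(ks, function(k) {
    sum(x * exp(-2i * pi * k * ks / n))
  }, complex(1))
  omega <- ifelse(ks <= n / 2, ks, ks - n)
  X <- X * exp(-omega^2 / (2 * sigma^2))
  out <- vapply(ks, function(t) {
    sum(X * exp(2i * pi * ks * t / n)) / n
  }, complex(1))
  Re(out)
}

# Exhaustive double loop over lags and time indices for the directional
# correlation delay; same tie-break contract (smallest |tau|, then
# positive).
delay_oracle <- function(psi_i, psi_j, max_lag) {
  n <- length(psi_i)
  best_tau <- NA_integer_
  best_corr <- -Inf
  for (tau in -max_lag:max_lag) {
    acc <- 0
    cnt <- 0
    for (t in 1:n) {
      u <- t + tau
      if (u >= 1 && u <= n && !is.na(psi_i[t]) && !is.na(psi_j[u])) {
        acc <- acc + cos(psi_i[t] - psi_j[u])
        cnt <- cnt + 1
      }
    }
    corr <- acc / cnt
    better <- corr > best_corr ||
      (corr == best_corr &&
         (abs(tau) < abs(best_tau) ||
            (abs(tau) == abs(best_tau) && tau > best_tau)))
    if (better) {
      best_corr <- corr
      best_tau <- tau
    }
  }
  best_tau
}

# Per-observation loop recomputing a cell mean of a polar map.
polar_cell_mean_oracle <- function(obs, r_lo, r_hi, th_lo, th_hi,
                                   response = "turn") {
  acc <- 0
  cnt <- 0
  for (i in seq_len(nrow(obs))) {
    if (obs$d[i] > r_lo && obs$d[i] <= r_hi &&
        obs$theta[i] > th_lo && obs$theta[i] <= th_hi) {
      acc <- acc + obs[[response]][i]
      cnt <- cnt + 1
    }
  }
  if (cnt == 0) NA_real_ else acc / cnt
}

# Lag-k sample autocorrelation without stats::acf conventions getting in
# the way of an exact definitional check.
lag_autocor <- function(x, k) {
  n <- length(x)
  stats::cor(x[1:(n - k)], x[(1 + k):n])
}
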