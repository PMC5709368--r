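# Fixture builders shared across the test files. Everything is generated
# in code; no data files.

# small symmetric connectome with uniform lengths
toy_connectome <- function(n = 4, weight = 1, length_mm = 60) {
  w <- matrix(weight, n, n); diag(w) <- 0
  l <- matrix(length_mm, n, n); diag(l) <- 0
  structural_connectome(w, l)
}

# deterministic multiregion sinusoid series
sinusoid_ts <- function(freqs_hz, T = 512, dt = 1, phase = 0) {
  tt <- (seq_len(T) - 1) * dt
  data <- t(vapply(freqs_hz, function(f) cos(2 * pi * f * tt + phase),
                   numeric(T)))
  regional_timeseries(data, dt_sample = dt)
}

# the deterministic series the frozen external oracles were computed on
oracle_series <- function() {
  t <- 0:63
  round(sin(0.3 * t) + 0.5 * cos(0.11 * t), 6)
}

# three series whose pairwise Pearson correlations are exactly 1, 0.5, 0.5
correlated_triplet <- function(T = 32) {
  z1 <- sin(2 * pi * (0:(T - 1)) / T)
  z2 <- cos(2 * pi * (0:(T - 1)) / T)      # orthogonal, equal norm
  z1 <- (z1 - mean(z1)) / sd(z1)
  z2 <- (z2 - mean(z2)) / sd(z2)
  rbind(a = z1, b = z1, c = z1 + sqrt(3) * z2)
}

# two-module partition over explicit ids
toy_partition <- function(ids, sizes = c(2, 2),
                          labels = c("NetA", "NetB")) {
  network_partition(
    stats::setNames(rep(labels, sizes), ids[seq_len(sum(sizes))]), ids)
}

# Monte-Carlo oracle for the generative phase model: the time-averaged
# resultant of n von Mises phasors, averaged over n_indep effectively
# independent offset configurations (a 390-s window holds about
# T / (2 * offset_timescale) of them). Returns the finite-network mean
# (upward-biased relative to I1/I0 for small n) and its sampling SD.
resultant_oracle <- function(kappa, n, n_indep, n_mc = 3000, seed = 99) {
  set.seed(seed)
  qf <- netdyn:::.vm_quantile_fun(kappa)
  rbar <- vapply(seq_len(n_mc), function(i)
    mean(vapply(seq_len(n_indep), function(j)
      Mod(mean(exp(1i * qf(runif(n))))), numeric(1))), numeric(1))
  c(mean = mean(rbar), sd = sd(rbar))
}
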