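# Independent oracles used to cross-check the estimators. These deliberately
# avoid the package's own code paths.

# Bennett acceptance ratio for two states, solved from its implicit equation.
# w_f: u2 - u1 evaluated on samples from state 1; w_r: u1 - u2 on samples
# from state 2. Returns the dimensionless free-energy difference f2 - f1.
bar_oracle <- function(w_f, w_r, interval = c(-50, 50)) {
  n_f <- length(w_f)
  n_r <- length(w_r)
  m <- log(n_f / n_r)
  # two-state self-consistency summed over both sample sets:
  # sum_n [1 + (N1/N2) exp(w_n - df)]^-1 = N2, with w = u2 - u1 per sample
  h <- function(df) {
    sum(1 / (1 + exp(m + w_f - df))) +
      sum(1 / (1 + exp(m - w_r - df))) - n_r
  }
  stats::uniroot(h, interval, tol = 1e-12)$root
}

# plain log-sum-exp with max shift, written independently of the package
lse_oracle <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# product-moment correlation from the raw definition
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

kT_at <- function(temperature_K) 0.0019872041 * temperature_K

# coarse desk-scale schedules used by the sampling tests
coarse_complex_schedule <- function() {
  build_lambda_schedule("complex", dlam_coul = 0.25, dlam_vdw = 0.2,
                        restraint_lambdas = c(0, 0.01, 0.05, 0.15, 0.3, 0.6, 1))
}
coarse_solvent_schedule <- function() {
  build_lambda_schedule("solvent", dlam_coul = 0.25, dlam_vdw = 0.2)
}
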