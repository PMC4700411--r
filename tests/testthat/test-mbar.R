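test_that("reduced-potential container enforces its invariants", {
  u <- matrix(rnorm(20), ncol = 2)
  rp <- reduced_potentials(u, n_k = c(5, 5))
  expect_identical(rp$n_k, c(5L, 5L))
  expect_identical(rp$origin, rep(1:2, each = 5))
  expect_error(reduced_potentials(u[, 1, drop = FALSE], n_k = 10),
               class = "abfe_invalid_input")
  expect_error(reduced_potentials(u, n_k = c(4, 5)),
               class = "abfe_invalid_input")
  u[1, 1] <- Inf
  expect_error(reduced_potentials(u, n_k = c(5, 5)),
               class = "abfe_invalid_input")
})

test_that("identical states give zero free-energy difference", {
  set.seed(11)
  x <- rnorm(400)^2
  rp <- reduced_potentials(cbind(x, x), n_k = c(200, 200))
  fit <- mbar_solve(rp)
  expect_equal(mbar_delta_f(fit, 1, 2), 0, tolerance = 1e-9)
})

test_that("two-state Gaussian problem recovers the analytic -ln(2)", {
  rp <- sample_gaussian_states(sigma = c(1, 2), n = 20000, seed = 33)
  fit <- mbar_solve(rp)
  expect_lt(abs(mbar_delta_f(fit, 1, 2) - (-log(2))), 0.03)
})

test_that("a three-state ladder is exactly additive and antisymmetric", {
  rp <- sample_gaussian_states(sigma = c(1, 1.5, 2.5), n = 2000, seed = 5)
  fit <- mbar_solve(rp)
  d12 <- mbar_delta_f(fit, 1, 2)
  d23 <- mbar_delta_f(fit, 2, 3)
  d13 <- mbar_delta_f(fit, 1, 3)
  expect_equal(d13, d12 + d23, tolerance = 1e-12)
  expect_equal(mbar_delta_f(fit, 3, 1), -d13, tolerance = 1e-12)
})

test_that("per-sample weights are a proper distribution reproducing N_k", {
  rp <- sample_gaussian_states(sigma = c(1, 1.4, 2), n = c(300, 500, 400),
                               seed = 9)
  fit <- mbar_solve(rp)
  W <- mbar_weights(fit)
  expect_true(all(W >= 0))
  expect_lt(max(abs(rowSums(W) - 1)), 1e-10)
  expect_lt(max(abs(colSums(W) - rp$n_k)), 1e-6)
})

test_that("the two-state solution satisfies the BAR implicit equation", {
  rp <- sample_gaussian_states(sigma = c(1, 2), n = c(1500, 900), seed = 21)
  fit <- mbar_solve(rp)
  u <- rp$u
  w_f <- u[rp$origin == 1L, 2L] - u[rp$origin == 1L, 1L]
  w_r <- u[rp$origin == 2L, 1L] - u[rp$origin == 2L, 2L]
  expect_lt(abs(mbar_delta_f(fit, 1, 2) - bar_oracle(w_f, w_r)), 1e-8)
})

test_that("the solution is independent of sample ordering", {
  rp <- sample_gaussian_states(sigma = c(1, 2, 3), n = 500, seed = 14)
  fit1 <- mbar_solve(rp)
  set.seed(1)
  perm <- sample.int(nrow(rp$u))
  rp2 <- reduced_potentials(rp$u[perm, ], origin = rp$origin[perm])
  fit2 <- mbar_solve(rp2)
  expect_equal(unname(fit1$f), unname(fit2$f), tolerance = 1e-8)
})

test_that("pathologies are reported: non-convergence and missing overlap", {
  rp <- sample_gaussian_states(sigma = c(1, 1.3), mu = c(0, 4), n = 2000,
                               seed = 3)
  expect_error(mbar_solve(rp, max_iterations = 2L),
               class = "abfe_convergence_error")
  far <- sample_gaussian_states(sigma = c(0.05, 0.05), mu = c(0, 60),
                                n = 400, seed = 4)
  expect_warning(fit <- mbar_solve(far), "overlap")
  expect_true(fit$low_overlap)
})

test_that("subsampled IID data agree with the full estimate", {
  rp <- sample_gaussian_states(sigma = c(1, 2), n = 8000, seed = 17)
  fit_full <- mbar_solve(rp)
  keep <- unlist(lapply(1:2, function(k) which(rp$origin == k)[seq(1, 8000, by = 4)]))
  rp_sub <- reduced_potentials(rp$u[keep, ], origin = rp$origin[keep])
  b_full <- bootstrap_free_energy(rp, n_boot = 40, seed = 2)
  b_sub <- bootstrap_free_energy(rp_sub, n_boot = 40, seed = 2)
  se <- sqrt(b_full$sd^2 + b_sub$sd^2)
  expect_lt(abs(b_full$value - b_sub$value), 3 * se)
})

test_that("tidiers summarize the fit", {
  rp <- sample_gaussian_states(sigma = c(1, 2), n = 200, seed = 1)
  fit <- mbar_solve(rp)
  td <- tidy(fit)
  expect_identical(nrow(td), 2L)
  expect_equal(td$f[1], 0)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_identical(gl$n_states, 2L)
})

test_that("estimator errors shrink with sample size and are covered by bootstrap", {
  err_at <- function(n, seeds) {
    vapply(seeds, function(s) {
      rp <- sample_gaussian_states(sigma = c(1, 2), n = n, seed = 5000 + s)
      abs(mbar_delta_f(mbar_solve(rp), 1, 2) - (-log(2)))
    }, numeric(1))
  }
  expect_lt(mean(err_at(2000, 1:12)), mean(err_at(100, 1:12)))

  hits <- vapply(1:100, function(s) {
    rp <- sample_gaussian_states(sigma = c(1, 2), n = 400, seed = 7000 + s)
    est <- bootstrap_free_energy(rp, n_boot = 30, seed = s)
    kT <- kT_at(rp$temperature_K)
    abs(est$value / kT - (-log(2))) <= 3 * est$sd / kT
  }, logical(1))
  expect_gte(sum(hits), 95L)
})

test_that("the information-matrix covariance is a sane diagnostic", {
  rp <- sample_gaussian_states(sigma = c(1, 2), n = 3000, seed = 55)
  fit <- mbar_solve(rp)
  V <- mbar_covariance(fit)
  expect_equal(V[1, 1], 0)
  expect_gt(V[2, 2], 0)
  est <- bootstrap_free_energy(rp, n_boot = 60, seed = 2)
  kT <- kT_at(rp$temperature_K)
  sd_boot <- est$sd / kT
  expect_gt(sqrt(V[2, 2]), sd_boot / 3)
  expect_lt(sqrt(V[2, 2]), sd_boot * 3)
})
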