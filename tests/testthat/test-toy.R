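test_that("soft-core pair energy has the stated limits", {
  expect_equal(softcore_lj(3, 0.3, 3, 1), 0)  # LJ zero crossing at sigma
  expect_equal(softcore_lj(0, 1, 3, 0.5), 24)  # finite at the core
  r <- seq(2.5, 8, by = 0.1)
  # reduces to plain LJ at full coupling
  lj <- 4 * 0.3 * ((3 / r)^12 - (3 / r)^6)
  expect_equal(softcore_lj(r, 0.3, 3, 1), lj, tolerance = 1e-12)
  expect_error(softcore_lj(1, 0.3, 3, 1.2), class = "abfe_invalid_input")
})

test_that("the toy potential vanishes when fully decoupled and is continuous in lambda", {
  m <- toy_model()
  conf <- list(translation = c(12, 12, 14), quaternion = c(1, 0, 0, 0))
  expect_equal(toy_potential(conf, 0, 0, 0, m), 0)

  lams <- seq(0, 1, by = 0.05)
  e <- vapply(lams, function(l) toy_potential(conf, 0, 0, l, m), numeric(1))
  expect_true(all(is.finite(e)))
  expect_lt(max(abs(diff(e))), 0.5)  # no jumps on a fine lambda grid

  expect_error(toy_potential(conf, -0.1, 0, 0, m),
               class = "abfe_invalid_input")
})

test_that("the restraint reference pose has zero restraint energy", {
  m <- toy_model()
  ic <- internal_coordinates(m, m$reference_pose)
  expect_equal(restraint_energy(as.list(ic), m$restraint), 0,
               tolerance = 1e-10)
  expect_equal(toy_potential(m$reference_pose, 1, 0, 0, m), 0,
               tolerance = 1e-10)
})

test_that("stored reduced potentials are reproducible from stored configurations", {
  m <- toy_model()
  sched <- coarse_complex_schedule()
  res <- run_hrex(m, sched, hrex_config(n_sweeps = 600, seed = 5))
  kT <- m$thermo$kT
  set.seed(99)
  rows <- sample.int(nrow(res$u), 100)
  for (i in rows) {
    conf <- list(translation = res$configs[i, 1:3],
                 quaternion = res$configs[i, 4:7])
    k <- sample.int(nrow(sched), 1)
    u_expected <- toy_potential(conf, sched$lambda_restraint[k],
                                sched$lambda_coulomb[k], sched$lambda_vdw[k],
                                m) / kT
    expect_equal(res$u[i, k], u_expected, tolerance = 1e-9)
  }
})

test_that("the exactly sampled Gaussian ladder matches its analytic truth", {
  same <- sample_gaussian_states(sigma = c(1.3, 1.3), n = 100, seed = 2)
  expect_equal(attr(same, "analytic_f")[2], 0)

  two <- sample_gaussian_states(sigma = c(1, 2), n = 4000, seed = 6)
  expect_equal(attr(two, "analytic_f")[2], -log(2))
  est <- bootstrap_free_energy(two, n_boot = 50, seed = 3)
  kT <- kT_at(two$temperature_K)
  expect_lt(abs(est$value / kT - (-log(2))), 3 * est$sd / kT)
  expect_error(sample_gaussian_states(sigma = c(1, 2), n = 1),
               class = "abfe_invalid_input")
})

test_that("identical Hamiltonians swap freely and replicas visit states uniformly", {
  m <- toy_model()
  sched <- coarse_solvent_schedule()  # solvent legs are non-interacting
  res <- run_hrex(m, sched, hrex_config(n_sweeps = 8000, seed = 11))
  expect_true(all(res$neighbour_acceptance$acceptance > 0.999))
  expect_gt(res$jump_probability, 0.8)

  # replica 1 visit counts, in units of exchange rounds, against uniform
  K <- nrow(sched)
  counts <- res$occupancy[1, ] / 100  # swap_interval sweeps per round
  p <- suppressWarnings(chisq.test(counts, p = rep(1 / K, K)))$p.value
  expect_gt(p, 0.01)
})

test_that("a stiff restrained distance obeys equipartition", {
  m <- toy_model()
  # restraint-only ladder: two fully restrained, decoupled states
  sched <- build_lambda_schedule("complex", dlam_coul = 1, dlam_vdw = 1,
                                 restraint_lambdas = c(0, 1))
  sched <- sched[sched$lambda_restraint == 1 & sched$lambda_coulomb == 0 &
                   sched$lambda_vdw %in% c(0, 1), ]
  class(sched) <- c("lambda_schedule", class(tibble::tibble()))
  attr(sched, "environment") <- "complex"
  res <- run_hrex(m, sched, hrex_config(n_sweeps = 12000, seed = 21,
                                        swap_interval = 1e9))
  rows <- which(res$origin == 2L)[200:1200]  # restraint-only state, burn-in dropped
  r_dev <- vapply(rows, function(i) {
    conf <- list(translation = res$configs[i, 1:3],
                 quaternion = res$configs[i, 4:7])
    internal_coordinates(m, conf)[["r"]] - m$restraint$r0
  }, numeric(1))
  kT <- m$thermo$kT
  expected <- kT / m$restraint$k_r
  msd <- mean(r_dev^2)
  se <- sd(r_dev^2) / sqrt(length(r_dev) / 10)  # generous correlation factor
  expect_lt(abs(msd - expected), 3 * se + 0.2 * expected)
})

test_that("coarser ladders overlap less: neighbour acceptance drops", {
  m <- toy_model()
  fine <- build_lambda_schedule("solvent", dlam_coul = 1, dlam_vdw = 0.05)
  coarse <- build_lambda_schedule("solvent", dlam_coul = 1, dlam_vdw = 0.25)
  # make the vdw ladder interacting by sampling the complex environment
  attr(fine, "environment") <- "complex"
  attr(coarse, "environment") <- "complex"
  rf <- run_hrex(m, fine, hrex_config(n_sweeps = 2500, seed = 31))
  rc <- run_hrex(m, coarse, hrex_config(n_sweeps = 2500, seed = 31))
  expect_gt(mean(rf$neighbour_acceptance$acceptance),
            mean(rc$neighbour_acceptance$acceptance))
})

test_that("the quadrature oracle has exact limits and monotone depth", {
  uncoupled <- toy_model(
    guest = tibble::tibble(x = c(0, 1.5, 1.5), y = c(0, 0, 1.5), z = 0,
                           epsilon = 0, sigma = 3, charge = 0),
    host = tibble::tibble(x = c(10, 8.5, 8.5), y = c(10, 10, 8.5), z = 10,
                          epsilon = 0, sigma = 3, charge = 0))
  q0 <- quadrature_binding_dG(uncoupled, n_cells = 4, n_per_cell = 50,
                              seed = 1)
  kT <- uncoupled$thermo$kT
  expect_equal(q0$value, -kT * log(8000 / 1660.539), tolerance = 1e-9)
  expect_equal(q0$se, 0, tolerance = 1e-12)

  m <- toy_model()
  q1 <- quadrature_binding_dG(m, seed = 2)
  # doubling the standard-state volume shifts the result by +kT ln 2
  m2 <- m
  m2$thermo <- thermo_state(298.15, v_standard = 2 * 1660.539)
  q2 <- quadrature_binding_dG(m2, seed = 2)
  expect_equal(q2$value - q1$value, kT * log(2), tolerance = 1e-9)

  deep <- toy_model(guest = dplyr::mutate(m$guest, epsilon = epsilon * 4))
  qd <- quadrature_binding_dG(deep, n_per_cell = 10000, seed = 2)
  expect_lt(qd$value, q1$value)
})
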