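test_that("charge correction applies the mean and flags large spreads", {
  set.seed(12)
  vals <- rnorm(11, mean = 0.31, sd = 0.02)
  cc <- apply_charge_correction(vals)
  expect_equal(cc$mean, mean(vals))
  expect_false(cc$flagged)

  same <- apply_charge_correction(rep(0.2, 5))
  expect_equal(same$mean, 0.2)
  expect_equal(same$sd, 0)

  set.seed(13)
  wide <- rnorm(11, mean = 0.3, sd = 0.12)
  expect_warning(cc2 <- apply_charge_correction(wide), "threshold")
  expect_true(cc2$flagged)

  expect_error(apply_charge_correction(numeric(0)),
               class = "abfe_invalid_input")
})

test_that("cycle assembly sums signed legs and combines sds in quadrature", {
  zero <- assemble_cycle(0, 0, 0, 0)
  expect_equal(zero$dG_bind, 0)
  expect_equal(zero$sd, 0)

  est <- function(v, s) free_energy_estimate(value = v, sd = s)
  cyc <- assemble_cycle(
    dG_solv_elec_vdw = est(3.2, 0.3), dG_solv_restr = 6.83,
    dG_prot_elec_vdw = est(-12.1, 0.4), dG_prot_restr = est(-4.0, 0)
  )
  expect_equal(cyc$dG_bind, 3.2 + 6.83 - 12.1 - 4.0)
  expect_equal(cyc$sd, 0.5)  # rss of 0.3 and 0.4

  with_corr <- assemble_cycle(est(0, 0.3), 0, est(0, 0.4), 0,
                              corrections = list(charge = 0.25,
                                                 dispersion = -0.1))
  expect_equal(with_corr$dG_bind, 0.15)
  expect_equal(with_corr$sd, 0.5)

  cc <- apply_charge_correction(rep(0.2, 3))
  expect_equal(assemble_cycle(0, 0, 0, 0,
                              corrections = list(rip = cc))$dG_bind, 0.2)

  expect_error(assemble_cycle(NULL, 0, 0, 0), class = "abfe_invalid_input")
  expect_error(assemble_cycle(0, 0, 0, 0, corrections = list(0.2)),
               class = "abfe_invalid_input")
})

test_that("cycle tidiers expose legs and totals", {
  est <- function(v, s) free_energy_estimate(value = v, sd = s)
  cyc <- assemble_cycle(est(1, 0.1), 2, est(-3, 0.2), est(-0.5, 0.1),
                        corrections = list(charge = 0.1))
  td <- tidy(cyc)
  expect_identical(nrow(td), 5L)
  expect_equal(sum(td$value_kcal_mol), glance(cyc)$dG_bind_kcal_mol)
})

test_that("multimode combination follows the log-sum-exp of binding constants", {
  kT <- kT_at(298.15)
  one <- combine_binding_modes(-7.3)
  expect_equal(one$value, -7.3, tolerance = 1e-10)

  two <- combine_binding_modes(c(-8, -8))
  expect_equal(two$value, -8 - kT * log(2), tolerance = 1e-9)

  # five reported poses of one ligand; oracle via independent log-sum-exp
  poses <- c(-10.8, -10.5, -7.3, -6.5, -6.2)
  expected <- -kT * lse_oracle(-poses / kT)
  comb <- combine_binding_modes(poses)
  expect_equal(comb$value, expected, tolerance = 1e-9)
  expect_equal(comb$value, -11.0809, tolerance = 1e-4)
})

test_that("multimode combination is permutation-invariant and bounded by the best mode", {
  set.seed(31)
  for (i in 1:20) {
    v <- -runif(sample(2:6, 1), 2, 12)
    comb <- combine_binding_modes(v)$value
    expect_lte(comb, min(v) + 1e-12)
    expect_equal(combine_binding_modes(sample(v))$value, comb,
                 tolerance = 1e-12)
    # adding a mode can only strengthen the combined affinity
    expect_lte(combine_binding_modes(c(v, -3))$value, comb + 1e-12)
  }
  # a dominant mode swamps the others
  dom <- combine_binding_modes(c(-15, -3))$value
  expect_equal(dom, -15, tolerance = 1e-8)
  expect_error(combine_binding_modes(list()), class = "abfe_invalid_input")
})

test_that("multimode uncertainty is propagated from bootstrap samples", {
  set.seed(77)
  m1 <- free_energy_estimate(boot = rnorm(200, -8.0, 0.3))
  m2 <- free_energy_estimate(boot = rnorm(200, -7.5, 0.2))
  a <- combine_binding_modes(list(m1, m2), n_resample = 2000, seed = 10)
  b <- combine_binding_modes(list(m1, m2), n_resample = 2000, seed = 10)
  expect_identical(a$boot, b$boot)
  expect_gt(a$sd, 0.05)
  expect_lt(a$sd, 0.5)
  # combined distribution sits below the stronger mode on average
  expect_lt(a$value, -8.0)
})
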