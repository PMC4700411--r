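test_that("the packaged benchmark tables have the expected shape", {
  both <- brd4_benchmark("both")
  expect_identical(nrow(both), 22L)
  t1 <- brd4_benchmark(1)
  expect_identical(t1$ligand, 1:11)
  expect_true(all(t1$dG_calc < 0) && all(t1$dG_exp < 0))
  # single-measurement ligand: missing experimental sd, not zero
  expect_true(is.na(t1$dG_exp_sd[t1$ligand == 11]))
  expect_true(all(is.na(t1$docking_dG)))
  expect_true(all(!is.na(brd4_benchmark(2)$docking_dG)))
})

test_that("error metrics reproduce the crystal-structure campaign summary", {
  t1 <- brd4_benchmark(1)
  expect_equal(round(mae(t1$dG_calc, t1$dG_exp), 1), 0.6)
  expect_equal(round(rmse(t1$dG_calc, t1$dG_exp), 1), 0.8)
  expect_equal(mae(t1$dG_exp, t1$dG_exp), 0)
  expect_equal(rmse(t1$dG_exp, t1$dG_exp), 0)
})

test_that("error metrics reproduce the docking campaign summary", {
  t2 <- brd4_benchmark(2)
  expect_equal(round(mae(t2$dG_calc, t2$dG_exp), 1), 1.0)
  expect_equal(round(rmse(t2$dG_calc, t2$dG_exp), 1), 1.4)
  expect_equal(round(rmse(t2$docking_dG, t2$dG_exp), 1), 4.2)
})

test_that("correlations behave on exact and fixture data", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(spearman(exp(x), x), 1)   # monotone transform
  expect_equal(spearman(-x, x), -1)
  expect_error(pearson(rep(1, 5), x), class = "abfe_undefined_correlation")
  expect_error(pearson(x[1:2], x[1:2]), class = "abfe_invalid_input")

  t1 <- brd4_benchmark(1)
  # plug-in values from the one-decimal table, against an independent
  # hand-rolled product-moment computation
  expect_equal(pearson(t1$dG_calc, t1$dG_exp),
               pearson_oracle(t1$dG_calc, t1$dG_exp), tolerance = 1e-12)
  expect_equal(pearson(t1$dG_calc, t1$dG_exp), 0.875, tolerance = 0.005)
  expect_equal(spearman(t1$dG_calc, t1$dG_exp),
               pearson_oracle(rank(t1$dG_calc), rank(t1$dG_exp)),
               tolerance = 1e-12)
  expect_equal(spearman(t1$dG_calc, t1$dG_exp), 0.861, tolerance = 0.005)
})

test_that("metrics are invariant under shifts; mae never exceeds rmse", {
  set.seed(44)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    p <- rnorm(n, -8, 2)
    o <- p + rnorm(n, 0, 1.5)
    expect_lte(mae(p, o), rmse(p, o) + 1e-12)
    expect_equal(mae(p + 3, o + 3), mae(p, o), tolerance = 1e-12)
    expect_equal(rmse(p - 1, o - 1), rmse(p, o), tolerance = 1e-12)
    if (sd(p) > 0 && sd(o) > 0) {
      expect_equal(pearson(2 * p + 1, o), pearson(p, o), tolerance = 1e-12)
      expect_equal(spearman(3 * p - 2, o), spearman(p, o), tolerance = 1e-12)
    }
  }
})

test_that("the paired metric bootstrap is seeded and calibrated", {
  t1 <- brd4_benchmark(1)
  a <- bootstrap_metric(mae, t1$dG_calc, t1$dG_exp, n_boot = 500, seed = 9)
  b <- bootstrap_metric(mae, t1$dG_calc, t1$dG_exp, n_boot = 500, seed = 9)
  expect_identical(a$boot, b$boot)

  # ligand-resampling spread of the crystal-structure MAE (frozen value;
  # an over-ligand bootstrap measures the sensitivity to the compound set)
  big <- bootstrap_metric(mae, t1$dG_calc, t1$dG_exp, n_boot = 5000, seed = 1)
  expect_equal(round(big$sd, 1), 0.2)

  perfect <- bootstrap_metric(mae, t1$dG_exp, t1$dG_exp, n_boot = 100, seed = 2)
  expect_equal(perfect$sd, 0)

  # the bootstrap mean converges to the plug-in statistic
  huge <- bootstrap_metric(mae, t1$dG_calc, t1$dG_exp, n_boot = 1e5, seed = 3)
  expect_lt(abs(huge$mean - mae(t1$dG_calc, t1$dG_exp)), 0.01)
})

test_that("benchmark_summary assembles plug-in and bootstrap columns", {
  summ <- benchmark_summary(brd4_benchmark(1), n_boot = 1000, seed = 4)
  expect_identical(summ$metric, c("mae", "rmse", "pearson_r", "spearman_rho"))
  expect_true(all(summ$boot_sd > 0))
  expect_lte(summ$value[summ$metric == "mae"],
             summ$value[summ$metric == "rmse"])
  gl <- glance(summ)
  expect_identical(gl$n, 11L)
  # docking scores correlate poorly with experiment
  dock <- benchmark_summary(brd4_benchmark(2), pred = "docking_dG",
                            n_boot = 200, seed = 4)
  expect_lt(glance(dock)$pearson_r, 0.3)
})
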