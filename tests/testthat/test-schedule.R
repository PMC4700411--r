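test_that("default protocol yields 42 complex and 31 solvent windows", {
  expect_identical(nrow(build_lambda_schedule("complex")), 42L)
  expect_identical(nrow(build_lambda_schedule("solvent")), 31L)
})

test_that("endpoints are physical and boundary states are deduplicated", {
  cs <- build_lambda_schedule("complex")
  # first state: fully interacting, unrestrained complex
  expect_equal(unlist(cs[1, c("lambda_restraint", "lambda_coulomb",
                              "lambda_vdw")], use.names = FALSE), c(0, 1, 1))
  # last state: restrained, fully decoupled
  expect_equal(unlist(cs[42, c("lambda_restraint", "lambda_coulomb",
                               "lambda_vdw")], use.names = FALSE), c(1, 0, 0))
  # no duplicated lambda triples anywhere
  expect_identical(anyDuplicated(cs[, c("lambda_restraint", "lambda_coulomb",
                                        "lambda_vdw")]), 0L)

  ss <- build_lambda_schedule("solvent")
  expect_true(all(ss$lambda_restraint == 0))
  expect_equal(unlist(ss[1, c("lambda_coulomb", "lambda_vdw")],
                      use.names = FALSE), c(1, 1))
  expect_equal(unlist(ss[31, c("lambda_coulomb", "lambda_vdw")],
                      use.names = FALSE), c(0, 0))
})

test_that("state counts follow the deduplication rule for any valid spacing", {
  # hand-counted toy case: 2 restraint values, dlam 0.5 -> 2 + 3 + 3 - 2
  toy <- build_lambda_schedule("complex", dlam_coul = 0.5, dlam_vdw = 0.5,
                               restraint_lambdas = c(0, 1))
  expect_identical(nrow(toy), 6L)

  for (dc in c(0.5, 0.25, 0.2, 0.1)) {
    for (dv in c(0.5, 0.25, 0.1, 0.05)) {
      n_r <- 4L
      sc <- build_lambda_schedule("complex", dlam_coul = dc, dlam_vdw = dv,
                                  restraint_lambdas = c(0, 0.1, 0.4, 1))
      expect_identical(nrow(sc), n_r + as.integer(1 / dc) + as.integer(1 / dv))
      sv <- build_lambda_schedule("solvent", dlam_coul = dc, dlam_vdw = dv)
      expect_identical(nrow(sv),
                       as.integer(1 / dc) + as.integer(1 / dv) + 1L)
    }
  }
})

test_that("invalid spacings and restraint ladders are rejected", {
  expect_error(build_lambda_schedule("complex", dlam_coul = 0.3),
               class = "abfe_invalid_input")
  expect_error(build_lambda_schedule("solvent", dlam_vdw = 0.7),
               class = "abfe_invalid_input")
  expect_error(build_lambda_schedule("complex",
                                     restraint_lambdas = c(0.1, 0.5, 1)),
               class = "abfe_invalid_input")
  expect_error(build_lambda_schedule("complex",
                                     restraint_lambdas = c(0, 0.5)),
               class = "abfe_invalid_input")
})

test_that("leg boundaries are reported in schedule order", {
  ends <- schedule_leg_ends(build_lambda_schedule("complex"))
  expect_identical(names(ends), c("restraint_on", "coulomb_off", "vdw_off"))
  expect_identical(unname(ends), c(12L, 22L, 42L))
})
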