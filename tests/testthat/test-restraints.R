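example_restraint <- function(k = 10, ...) {
  boresch_restraint(r0 = 5, theta_A0 = 90, theta_B0 = 90,
                    phi_A0 = 0, phi_B0 = 0, phi_C0 = 0,
                    k_r = k, k_theta_A = k, k_theta_B = k,
                    k_phi_A = k, k_phi_B = k, k_phi_C = k, ...)
}

ref_coords <- list(r = 5, theta_A = 90, theta_B = 90,
                   phi_A = 0, phi_B = 0, phi_C = 0)

test_that("restraint energy is harmonic with periodic dihedrals", {
  br <- example_restraint()
  expect_equal(restraint_energy(ref_coords, br), 0)

  co <- ref_coords
  co$r <- 6
  expect_equal(restraint_energy(co, br), 5)  # 1/2 * 10 * 1^2

  # a 350-degree dihedral excursion is a 10-degree deviation
  a <- ref_coords; a$phi_A <- 350
  b <- ref_coords; b$phi_A <- -10
  expect_equal(restraint_energy(a, br), restraint_energy(b, br))
  expect_gt(restraint_energy(a, br), 0)

  bad <- ref_coords; bad$r <- -1
  expect_error(restraint_energy(bad, br), class = "abfe_invalid_input")
})

test_that("constructor validates geometry and converts per-degree constants", {
  expect_error(example_restraint(k = -1), class = "abfe_invalid_input")
  expect_error(boresch_restraint(5, 0, 90, 0, 0, 0, 10, 10, 10, 10, 10, 10),
               class = "abfe_invalid_input")
  deg <- example_restraint(k = 10, angle_k_unit = "kcal/mol/deg2")
  expect_equal(deg$k_theta_A, 10 * (180 / pi)^2)
  expect_equal(deg$k_r, 10)  # distance constant is unaffected
  # stiffer angular springs -> larger restraining cost
  expect_gt(boresch_analytic_dG(deg), boresch_analytic_dG(example_restraint()))
})

test_that("analytic restraining free energy matches the closed form", {
  br <- example_restraint()
  th <- thermo_state(298.15)
  # frozen closed-form arithmetic: kT ln(8 pi^2 V0 sqrt(10^6) / (25 (2 pi kT)^3))
  expect_equal(boresch_analytic_dG(br, th), 6.830958, tolerance = 1e-6)

  # doubling all six force constants adds 3 kT ln 2
  expect_equal(boresch_analytic_dG(example_restraint(k = 20), th) -
                 boresch_analytic_dG(br, th),
               3 * th$kT * log(2), tolerance = 1e-10)

  # doubling the standard-state volume adds kT ln 2
  th2 <- thermo_state(298.15, v_standard = 2 * 1660.539)
  expect_equal(boresch_analytic_dG(br, th2) - boresch_analytic_dG(br, th),
               th$kT * log(2), tolerance = 1e-10)
})

test_that("the analytic value is monotone in force constants and singular at the poles", {
  base <- boresch_analytic_dG(example_restraint())
  for (arg in c("k_r", "k_theta_A", "k_phi_C")) {
    br <- example_restraint()
    br[[arg]] <- br[[arg]] * 1.5
    expect_gt(boresch_analytic_dG(br), base)
  }
  near_pole <- boresch_restraint(5, 1e-9, 90, 0, 0, 0, 10, 10, 10, 10, 10, 10,
                                 anchors = NULL)
  expect_error(boresch_analytic_dG(near_pole), class = "abfe_singularity_error")
})

test_that("quadrature agrees with the stiff-spring formula as springs stiffen", {
  th <- thermo_state(298.15)
  # exact integral differs from the stiff limit by O(kT^2/K) per bending angle
  err10 <- abs(boresch_quadrature_dG(example_restraint(10), th) -
                 boresch_analytic_dG(example_restraint(10), th))
  err100 <- abs(boresch_quadrature_dG(example_restraint(100), th) -
                  boresch_analytic_dG(example_restraint(100), th))
  err400 <- abs(boresch_quadrature_dG(example_restraint(400), th) -
                  boresch_analytic_dG(example_restraint(400), th))
  expect_lt(err100, err10)
  expect_lt(err400, 0.01)
  expect_lt(err100, 0.01)
  # the K = 10 deviation is the predicted 2 kT^2/K Jacobian correction
  predicted <- 2 * th$kT * (th$kT / (2 * 10)) - th$kT * (th$kT / 10) / 25
  expect_lt(abs(err10 - predicted), 0.005)
})
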