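#' Boresch-style orientational restraint
#'
#' Defines the six-degree-of-freedom harmonic restraint — one distance, two
#' angles and three dihedrals between three receptor anchors (P1, P2, P3) and
#' three ligand anchors (L1, L2, L3) — that fixes the position and
#' orientation of a bound ligand. The internal coordinates are: distance
#' `r = |P1-L1|`, angles `theta_A = P2-P1-L1` and `theta_B = P1-L1-L2`, and
#' dihedrals `phi_A = P3-P2-P1-L1`, `phi_B = P2-P1-L1-L2`,
#' `phi_C = P1-L1-L2-L3`.
#'
#' Angular force constants may be declared per square degree; they are
#' converted to the internal canonical unit of kcal/mol/rad^2 with the factor
#' `(180/pi)^2`.
#'
#' @param r0 Reference distance in angstroms (> 0).
#' @param theta_A0,theta_B0 Reference angles in degrees, strictly between 0
#'   and 180.
#' @param phi_A0,phi_B0,phi_C0 Reference dihedrals in degrees.
#' @param k_r Distance force constant, kcal/mol/A^2.
#' @param k_theta_A,k_theta_B,k_phi_A,k_phi_B,k_phi_C Angular force
#'   constants, in the unit named by `angle_k_unit`.
#' @param angle_k_unit `"kcal/mol/rad2"` (default) or `"kcal/mol/deg2"`.
#' @param anchors Optional character vector of six anchor-atom labels
#'   (P1, P2, P3, L1, L2, L3), metadata only.
#'
#' @return A `boresch_restraint` object (angular constants stored in
#'   kcal/mol/rad^2).
#' @examples
#' br <- boresch_restraint(r0 = 5, theta_A0 = 90, theta_B0 = 90,
#'                         phi_A0 = 0, phi_B0 = 0, phi_C0 = 0,
#'                         k_r = 10, k_theta_A = 10, k_theta_B = 10,
#'                         k_phi_A = 10, k_phi_B = 10, k_phi_C = 10)
#' boresch_analytic_dG(br)
#' @export
boresch_restraint <- function(r0, theta_A0, theta_B0,
                              phi_A0, phi_B0, phi_C0,
                              k_r, k_theta_A, k_theta_B,
                              k_phi_A, k_phi_B, k_phi_C,
                              angle_k_unit = c("kcal/mol/rad2",
                                               "kcal/mol/deg2"),
                              anchors = NULL) {
  angle_k_unit <- match.arg(angle_k_unit)
  conv <- if (angle_k_unit == "kcal/mol/deg2") (180 / pi)^2 else 1
  ks <- c(k_theta_A, k_theta_B, k_phi_A, k_phi_B, k_phi_C) * conv
  if (r0 <= 0) abort("`r0` must be positive.", class = "abfe_invalid_input")
  if (k_r <= 0 || any(ks <= 0)) {
    abort("All force constants must be positive.",
          class = "abfe_invalid_input")
  }
  if (theta_A0 <= 0 || theta_A0 >= 180 || theta_B0 <= 0 || theta_B0 >= 180) {
    abort("Reference angles must lie strictly between 0 and 180 degrees.",
          class = "abfe_invalid_input")
  }
  structure(
    list(r0 = r0, theta_A0 = theta_A0, theta_B0 = theta_B0,
         phi_A0 = phi_A0, phi_B0 = phi_B0, phi_C0 = phi_C0,
         k_r = k_r,
         k_theta_A = ks[1L], k_theta_B = ks[2L],
         k_phi_A = ks[3L], k_phi_B = ks[4L], k_phi_C = ks[5L],
         anchors = anchors),
    class = "boresch_restraint"
  )
}

#' @export
print.boresch_restraint <- function(x, ...) {
  cat("<boresch_restraint>\n")
  cat(sprintf("  r0 = %.2f A (k = %.3g kcal/mol/A^2)\n", x$r0, x$k_r))
  cat(sprintf("  theta_A0 = %.1f, theta_B0 = %.1f deg (k = %.3g, %.3g kcal/mol/rad^2)\n",
              x$theta_A0, x$theta_B0, x$k_theta_A, x$k_theta_B))
  cat(sprintf("  phi_A0 = %.1f, phi_B0 = %.1f, phi_C0 = %.1f deg (k = %.3g, %.3g, %.3g kcal/mol/rad^2)\n",
              x$phi_A0, x$phi_B0, x$phi_C0, x$k_phi_A, x$k_phi_B, x$k_phi_C))
  invisible(x)
}

# wrap an angular deviation in degrees to (-180, 180]
wrap_deg <- function(d) {
  w <- d - 360 * floor(d / 360 + 0.5)
  w[w == -180] <- 180
  w
}

#' Harmonic restraint energy at given internal coordinates
#'
#' Evaluates `E = 1/2 sum K (deviation)^2` for the six restrained internal
#' coordinates, with dihedral deviations wrapped to `(-180, 180]` degrees
#' before squaring. Zero at the reference geometry.
#'
#' @param coords Named list or vector with elements `r` (angstroms),
#'   `theta_A`, `theta_B`, `phi_A`, `phi_B`, `phi_C` (degrees).
#' @param restraint A [boresch_restraint()].
#' @return Energy in kcal/mol.
#' @export
restraint_energy <- function(coords, restraint) {
  co <- as.list(coords)
  need <- c("r", "theta_A", "theta_B", "phi_A", "phi_B", "phi_C")
  if (!all(need %in% names(co))) {
    abort(paste("`coords` must contain:", paste(need, collapse = ", ")),
          class = "abfe_invalid_input")
  }
  if (co$r <= 0) {
    abort("Distance `r` must be positive.", class = "abfe_invalid_input")
  }
  deg2rad <- pi / 180
  e <- 0.5 * restraint$k_r * (co$r - restraint$r0)^2 +
    0.5 * restraint$k_theta_A * ((co$theta_A - restraint$theta_A0) * deg2rad)^2 +
    0.5 * restraint$k_theta_B * ((co$theta_B - restraint$theta_B0) * deg2rad)^2 +
    0.5 * restraint$k_phi_A * (wrap_deg(co$phi_A - restraint$phi_A0) * deg2rad)^2 +
    0.5 * restraint$k_phi_B * (wrap_deg(co$phi_B - restraint$phi_B0) * deg2rad)^2 +
    0.5 * restraint$k_phi_C * (wrap_deg(co$phi_C - restraint$phi_C0) * deg2rad)^2
  e
}

#' Analytic free energy of restraining a non-interacting ligand
#'
#' Closed-form (stiff-spring) free-energy cost of imposing the six-dimensional
#' Boresch restraint on a non-interacting ligand at standard concentration,
#' including the standard-state volume term:
#' `dG = kT * ln( 8 pi^2 V0 sqrt(prod K) / (r0^2 sin(thetaA0) sin(thetaB0) (2 pi kT)^3) )`.
#' This is the `B -> C` leg of the thermodynamic cycle and is positive for
#' stiff restraints: confining the free ligand costs entropy.
#'
#' @param restraint A [boresch_restraint()].
#' @param thermo A [thermo_state()] (or a temperature in kelvin).
#' @return Free energy in kcal/mol.
#' @export
boresch_analytic_dG <- function(restraint, thermo = thermo_state()) {
  thermo <- as_thermo_state(thermo)
  deg2rad <- pi / 180
  tA <- restraint$theta_A0 * deg2rad
  tB <- restraint$theta_B0 * deg2rad
  if (min(abs(c(tA, tB, pi - tA, pi - tB))) < 1e-6) {
    abort("Reference angles too close to 0 or 180 degrees: the restraint Jacobian is singular.",
          class = "abfe_singularity_error")
  }
  kT <- thermo$kT
  prodK <- restraint$k_r * restraint$k_theta_A * restraint$k_theta_B *
    restraint$k_phi_A * restraint$k_phi_B * restraint$k_phi_C
  kT * log(8 * pi^2 * thermo$v_standard * sqrt(prodK) /
             (restraint$r0^2 * sin(tA) * sin(tB) * (2 * pi * kT)^3))
}

#' Numerical-quadrature free energy of the restrained ligand
#'
#' Independent check of [boresch_analytic_dG()]: the configurational integral
#' of the restrained, non-interacting ligand factorizes over the six internal
#' coordinates with Jacobian `r^2 sin(theta_A) sin(theta_B)`, so each factor
#' is evaluated by one-dimensional adaptive quadrature over its full domain
#' (no stiff-spring approximation) and
#' `dG = kT * ln(8 pi^2 V0 / Z_restr)`.
#'
#' @inheritParams boresch_analytic_dG
#' @param rel_tol Relative tolerance passed to [stats::integrate()].
#' @return Free energy in kcal/mol.
#' @export
boresch_quadrature_dG <- function(restraint, thermo = thermo_state(),
                                  rel_tol = 1e-10) {
  thermo <- as_thermo_state(thermo)
  kT <- thermo$kT
  beta <- 1 / kT
  deg2rad <- pi / 180
  r0 <- restraint$r0

  int1 <- function(f, lower, upper) {
    stats::integrate(f, lower, upper, rel.tol = rel_tol,
                     subdivisions = 2000L)$value
  }
  z_r <- int1(function(r) r^2 * exp(-beta * 0.5 * restraint$k_r * (r - r0)^2),
              0, r0 + 30 / sqrt(beta * restraint$k_r))
  z_theta <- function(t0_deg, k) {
    t0 <- t0_deg * deg2rad
    int1(function(t) sin(t) * exp(-beta * 0.5 * k * (t - t0)^2), 0, pi)
  }
  z_phi <- function(k) {
    # periodic domain: reference shifts away, integrate deviation over (-pi, pi]
    int1(function(p) exp(-beta * 0.5 * k * p^2), -pi, pi)
  }
  z <- z_r *
    z_theta(restraint$theta_A0, restraint$k_theta_A) *
    z_theta(restraint$theta_B0, restraint$k_theta_B) *
    z_phi(restraint$k_phi_A) * z_phi(restraint$k_phi_B) *
    z_phi(restraint$k_phi_C)
  kT * log(8 * pi^2 * thermo$v_standard / z)
}
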