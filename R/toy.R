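#' Soft-core parameters for van der Waals decoupling
#'
#' Beutler-type soft core: the pair interaction
#' `lambda^p * 4 eps * (sigma^12 / (alpha sigma^6 (1 - lambda) + r^6)^2 -
#' sigma^6 / (alpha sigma^6 (1 - lambda) + r^6))`
#' stays finite at `r = 0` for every `lambda < 1` and reduces to plain
#' Lennard-Jones at `lambda = 1`.
#'
#' @param alpha Soft-core alpha (> 0).
#' @param lambda_power Integer power `p` on the lambda prefactor.
#' @return A `softcore_params` object.
#' @export
softcore_params <- function(alpha = 0.5, lambda_power = 1L) {
  if (!is.numeric(alpha) || alpha <= 0) {
    abort("`alpha` must be positive.", class = "abfe_invalid_input")
  }
  structure(list(alpha = alpha, lambda_power = as.integer(lambda_power)),
            class = "softcore_params")
}

#' Soft-core Lennard-Jones pair energy
#'
#' @param r Distance(s) in angstroms (>= 0).
#' @param epsilon Well depth, kcal/mol.
#' @param sigma LJ diameter, angstroms.
#' @param lambda Coupling in `[0, 1]`; 1 is plain LJ.
#' @param softcore A [softcore_params()].
#' @return Energy in kcal/mol (vectorized over `r`).
#' @examples
#' softcore_lj(3, 0.3, 3, 1)   # zero at r = sigma
#' softcore_lj(0, 1, 3, 0.5)   # 24 kcal/mol: finite at the core
#' @export
softcore_lj <- function(r, epsilon, sigma, lambda,
                        softcore = softcore_params()) {
  if (any(lambda < 0 | lambda > 1)) {
    abort("`lambda` must lie in [0, 1].", class = "abfe_invalid_input")
  }
  s6 <- sigma^6
  denom <- softcore$alpha * s6 * (1 - lambda) + r^6
  t <- s6 / denom
  lambda^softcore$lambda_power * 4 * epsilon * (t^2 - t)
}

#' Desk-scale host-guest toy model
#'
#' A rigid triatomic guest interacting with three fixed host sites through
#' Lennard-Jones and Coulomb terms inside a cubic box, restrained by a
#' Boresch-style 6-DOF restraint. Only rigid-body translation and rotation of
#' the guest are sampled, so the model is small enough for exact quadrature
#' oracles while exhibiting the statistical structure of an alchemical
#' binding calculation.
#'
#' @param guest Tibble/data frame with columns `x, y, z, epsilon, sigma,
#'   charge` for the three guest sites (reference geometry; site 1 is the
#'   rotation pivot and first restraint anchor).
#' @param host Same columns for the three fixed host sites (absolute
#'   positions in the box).
#' @param box_edge Cubic box edge in angstroms.
#' @param restraint A [boresch_restraint()], or `NULL` to derive one with
#'   force constants `k` from the reference bound pose.
#' @param reference_pose List with `translation` (position of guest site 1)
#'   and `quaternion` (w, x, y, z) defining the bound pose used to derive
#'   restraint reference values.
#' @param k Force constant used when deriving the restraint (kcal/mol/A^2 for
#'   the distance, kcal/mol/rad^2 for angles and dihedrals).
#' @param thermo A [thermo_state()].
#' @param softcore A [softcore_params()].
#'
#' @return A `toy_model` object.
#' @export
toy_model <- function(guest = NULL, host = NULL, box_edge = 20,
                      restraint = NULL,
                      reference_pose = list(translation = c(10, 10, 13.2),
                                            quaternion = c(1, 0, 0, 0)),
                      k = 10,
                      thermo = thermo_state(),
                      softcore = softcore_params()) {
  if (is.null(guest)) {
    guest <- tibble(
      x = c(0, 1.5, 1.5), y = c(0, 0, 1.5), z = c(0, 0, 0),
      epsilon = c(0.5, 0.4, 0.3), sigma = c(3.0, 3.0, 3.0),
      charge = c(0.12, -0.06, -0.06)
    )
  }
  if (is.null(host)) {
    host <- tibble(
      x = c(10, 8.5, 8.5), y = c(10, 10, 8.5), z = c(10, 10, 10),
      epsilon = c(0.5, 0.4, 0.3), sigma = c(3.0, 3.0, 3.0),
      charge = c(-0.12, 0.06, 0.06)
    )
  }
  guest <- as_tibble(guest)
  host <- as_tibble(host)
  need <- c("x", "y", "z", "epsilon", "sigma", "charge")
  if (!all(need %in% names(guest)) || !all(need %in% names(host))) {
    abort(paste("`guest` and `host` need columns:", paste(need, collapse = ", ")),
          class = "abfe_invalid_input")
  }
  if (nrow(guest) != 3L || nrow(host) != 3L) {
    abort("The toy model uses exactly 3 guest sites and 3 host sites.",
          class = "abfe_invalid_input")
  }
  if (box_edge <= 4 * max(guest$sigma, host$sigma)) {
    abort("`box_edge` must exceed 4 * max(sigma).",
          class = "abfe_invalid_input")
  }
  # shift the guest reference geometry so site 1 sits at the origin
  guest$x <- guest$x - guest$x[1L]
  guest$y <- guest$y - guest$y[1L]
  guest$z <- guest$z - guest$z[1L]

  model <- structure(
    list(guest = guest, host = host, box_edge = box_edge,
         restraint = restraint, reference_pose = reference_pose,
         thermo = as_thermo_state(thermo), softcore = softcore),
    class = "toy_model"
  )
  if (is.null(restraint)) {
    ic <- internal_coordinates(model, reference_pose)
    model$restraint <- boresch_restraint(
      r0 = ic[["r"]], theta_A0 = ic[["theta_A"]], theta_B0 = ic[["theta_B"]],
      phi_A0 = ic[["phi_A"]], phi_B0 = ic[["phi_B"]], phi_C0 = ic[["phi_C"]],
      k_r = k, k_theta_A = k, k_theta_B = k,
      k_phi_A = k, k_phi_B = k, k_phi_C = k
    )
  }
  model
}

#' @export
print.toy_model <- function(x, ...) {
  cat(sprintf("<toy_model> 3-site guest / 3-site host, box %.1f A, T = %.2f K\n",
              x$box_edge, x$thermo$temperature_K))
  invisible(x)
}

quat_rotate <- function(q, v) {
  # v: n x 3 matrix; q = (w, x, y, z)
  w <- q[1L]
  u <- q[2:4]
  uv <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
              u[3] * v[, 1] - u[1] * v[, 3],
              u[1] * v[, 2] - u[2] * v[, 1])
  uuv <- cbind(u[2] * uv[, 3] - u[3] * uv[, 2],
               u[3] * uv[, 1] - u[1] * uv[, 3],
               u[1] * uv[, 2] - u[2] * uv[, 1])
  v + 2 * (w * uv + uuv)
}

guest_site_positions <- function(model, configuration) {
  ref <- as.matrix(model$guest[, c("x", "y", "z")])
  q <- configuration$quaternion
  q <- q / sqrt(sum(q^2))
  rot <- quat_rotate(q, ref)
  sweep(rot, 2L, configuration$translation, `+`)
}

vec_angle <- function(a, b) {
  c_ <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, c_))) * 180 / pi
}

vec_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  atan2(sum(m1 * n2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
}

#' Boresch internal coordinates of a guest configuration
#'
#' @param model A [toy_model()].
#' @param configuration List with `translation` (length 3) and `quaternion`
#'   (length 4, w first).
#' @return Named numeric vector `r` (angstrom), `theta_A`, `theta_B`,
#'   `phi_A`, `phi_B`, `phi_C` (degrees).
#' @export
internal_coordinates <- function(model, configuration) {
  pos <- guest_site_positions(model, configuration)
  hp <- as.matrix(model$host[, c("x", "y", "z")])
  P1 <- hp[1L, ]; P2 <- hp[2L, ]; P3 <- hp[3L, ]
  L1 <- pos[1L, ]; L2 <- pos[2L, ]; L3 <- pos[3L, ]
  c(r = sqrt(sum((L1 - P1)^2)),
    theta_A = vec_angle(P2 - P1, L1 - P1),
    theta_B = vec_angle(P1 - L1, L2 - L1),
    phi_A = vec_dihedral(P3, P2, P1, L1),
    phi_B = vec_dihedral(P2, P1, L1, L2),
    phi_C = vec_dihedral(P1, L1, L2, L3))
}

#' Toy-system potential energy at given couplings
#'
#' Total potential `U = lambda_restraint * E_restraint + lambda_coulomb *
#' E_coulomb + E_vdw_softcore(lambda_vdw)` of the guest in the host box, in
#' kcal/mol. Pure-R reference implementation; the Monte Carlo sampler uses an
#' equivalent compiled kernel.
#'
#' @inheritParams internal_coordinates
#' @param lambda_restraint,lambda_coulomb,lambda_vdw Couplings in `[0, 1]`.
#' @return Energy in kcal/mol.
#' @export
toy_potential <- function(configuration, lambda_restraint, lambda_coulomb,
                          lambda_vdw, model,
                          softcore = model$softcore) {
  lams <- c(lambda_restraint, lambda_coulomb, lambda_vdw)
  if (any(lams < 0 | lams > 1)) {
    abort("All lambda values must lie in [0, 1].",
          class = "abfe_invalid_input")
  }
  pos <- guest_site_positions(model, configuration)
  hp <- as.matrix(model$host[, c("x", "y", "z")])
  e <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      d <- sqrt(sum((pos[i, ] - hp[j, ])^2))
      epsij <- sqrt(model$guest$epsilon[i] * model$host$epsilon[j])
      sigij <- (model$guest$sigma[i] + model$host$sigma[j]) / 2
      if (lambda_vdw > 0) {
        e <- e + softcore_lj(d, epsij, sigij, lambda_vdw, softcore)
      }
      if (lambda_coulomb > 0) {
        e <- e + lambda_coulomb * .coulomb_const *
          model$guest$charge[i] * model$host$charge[j] / d
      }
    }
  }
  if (lambda_restraint > 0 && !is.null(model$restraint)) {
    ic <- internal_coordinates(model, configuration)
    e <- e + lambda_restraint * restraint_energy(as.list(ic), model$restraint)
  }
  e
}

# flatten a toy model into the list consumed by the C++ kernel
toy_system_list <- function(model, environment = "complex") {
  g <- model$guest
  h <- model$host
  eps <- outer(g$epsilon, h$epsilon, function(a, b) sqrt(a * b))
  sig <- outer(g$sigma, h$sigma, function(a, b) (a + b) / 2)
  qq <- outer(g$charge, h$charge) * .coulomb_const
  deg2rad <- pi / 180
  r <- model$restraint
  has_host <- environment == "complex"
  list(
    guest_ref = as.matrix(g[, c("x", "y", "z")]),
    host = as.matrix(h[, c("x", "y", "z")]),
    eps_pair = eps, sigma_pair = sig, qq_pair = qq,
    box_edge = model$box_edge,
    has_host = has_host,
    has_restraint = has_host && !is.null(r),
    restraint = if (is.null(r)) numeric(12) else
      c(r$r0, r$theta_A0 * deg2rad, r$theta_B0 * deg2rad,
        r$phi_A0 * deg2rad, r$phi_B0 * deg2rad, r$phi_C0 * deg2rad,
        r$k_r, r$k_theta_A, r$k_theta_B, r$k_phi_A, r$k_phi_B, r$k_phi_C),
    kT = model$thermo$kT,
    alpha = model$softcore$alpha,
    lam_power = model$softcore$lambda_power
  )
}

#' Hamiltonian-exchange Monte Carlo run configuration
#'
#' @param n_sweeps Sweeps per replica (one translation and one rotation
#'   attempt per replica per sweep).
#' @param swap_interval Sweeps between exchange rounds.
#' @param swap_attempts_per_round Random state-pair swap attempts per
#'   exchange round; defaults to `2 * K^2` for `K` states (Gibbs-style
#'   mixing).
#' @param sample_interval Sweeps between retained samples.
#' @param translation_step Maximum translation displacement, angstroms.
#' @param rotation_step_deg Maximum rotation angle, degrees.
#' @param seed Integer RNG seed.
#' @return A `hrex_config` object.
#' @export
hrex_config <- function(n_sweeps = 20000L, swap_interval = 100L,
                        swap_attempts_per_round = NULL,
                        sample_interval = 10L, translation_step = 0.75,
                        rotation_step_deg = 25, seed = 1L) {
  counts <- c(n_sweeps, swap_interval, sample_interval)
  if (any(counts < 1)) {
    abort("Sweep, swap and sample intervals must be positive.",
          class = "abfe_invalid_input")
  }
  structure(
    list(n_sweeps = as.integer(n_sweeps),
         swap_interval = as.integer(swap_interval),
         swap_attempts_per_round = swap_attempts_per_round,
         sample_interval = as.integer(sample_interval),
         translation_step = translation_step,
         rotation_step_deg = rotation_step_deg,
         seed = as.integer(seed)),
    class = "hrex_config"
  )
}

#' Run Hamiltonian-exchange Monte Carlo on the toy system
#'
#' Simulates one replica per lambda state with Metropolis rigid-body moves;
#' every `swap_interval` sweeps an exchange round performs many random
#' state-pair swap attempts accepted on reduced-potential differences, which
#' approximates Gibbs-sampling state mixing. Retained samples have their
#' reduced potential evaluated at every state of the schedule.
#'
#' @param model A [toy_model()].
#' @param schedule A [build_lambda_schedule()] result; its `environment`
#'   attribute decides whether host interactions and the restraint are
#'   present (`"solvent"` turns both off).
#' @param config A [hrex_config()].
#' @return An `hrex_result`: list with the reduced-potential matrix `u`
#'   (samples by states), `origin` state of each sample, stored `configs`,
#'   acceptance statistics (`move_acceptance`, `neighbour_acceptance` tibble,
#'   `jump_probability`), the replica-state `occupancy` matrix, and the
#'   inputs.
#' @export
run_hrex <- function(model, schedule, config = hrex_config()) {
  stopifnot(inherits(model, "toy_model"), inherits(schedule, "lambda_schedule"))
  if (nrow(schedule) < 2L) {
    abort("The schedule must contain at least 2 states.",
          class = "abfe_invalid_input")
  }
  env <- attr(schedule, "environment")
  sys <- toy_system_list(model, environment = env)
  lam <- as.matrix(schedule[, c("lambda_restraint", "lambda_coulomb",
                                "lambda_vdw")])
  K <- nrow(lam)
  swaps <- config$swap_attempts_per_round %||% (2L * K * K)
  raw <- with_seed(config$seed, {
    .cpp_run_hrex(sys, lam, config$n_sweeps, config$swap_interval,
                  as.integer(swaps), config$sample_interval,
                  config$translation_step,
                  config$rotation_step_deg * pi / 180)
  })
  if (any(raw$move_acceptance <= 0, na.rm = TRUE)) {
    abort("A state accepted no Monte Carlo moves; step sizes or the model are pathological.",
          class = "abfe_diagnostics_error")
  }
  neighbour <- tibble(
    pair = if (K > 1) paste(seq_len(K - 1L), seq(2L, K), sep = "-") else character(),
    attempts = as.numeric(raw$neighbour_attempts),
    acceptance = as.numeric(raw$neighbour_acceptance)
  )
  structure(
    list(u = raw$u, origin = as.integer(raw$origin), configs = raw$configs,
         move_acceptance = as.numeric(raw$move_acceptance),
         neighbour_acceptance = neighbour,
         jump_probability = raw$jump_probability,
         occupancy = raw$occupancy,
         n_exchange_rounds = raw$n_exchange_rounds,
         schedule = schedule, model = model, config = config,
         environment = env),
    class = "hrex_result"
  )
}

#' @export
print.hrex_result <- function(x, ...) {
  cat(sprintf("<hrex_result> %s, %d states, %d samples/state\n",
              x$environment, nrow(x$schedule),
              sum(x$origin == 1L)))
  cat(sprintf("  mean neighbour swap acceptance: %.3f; any-state jump probability: %.3f\n",
              mean(x$neighbour_acceptance$acceptance, na.rm = TRUE),
              x$jump_probability))
  invisible(x)
}

#' Decorrelate an HREX run into a reduced-potential container
#'
#' Applies the equilibration discard and statistical-inefficiency subsampling
#' of [prepare_samples()] to each state's own-state reduced-potential series,
#' then assembles the retained cross-evaluated rows into a
#' [reduced_potentials()] object.
#'
#' @param x An `hrex_result` (or a data frame in energy-table layout: a
#'   `state` column then one reduced-potential column per evaluated state).
#' @param discard_fraction Fraction of each state's series discarded from the
#'   front as equilibration.
#' @param temperature_K Temperature for data-frame input.
#' @param ... Unused.
#' @return A [reduced_potentials()] with attribute `decorrelation` (the
#'   per-state subsampling summary tibble).
#' @export
as_reduced_potentials <- function(x, ...) UseMethod("as_reduced_potentials")

#' @rdname as_reduced_potentials
#' @export
as_reduced_potentials.hrex_result <- function(x, discard_fraction = 0.1, ...) {
  K <- nrow(x$schedule)
  series <- lapply(seq_len(K), function(k) x$u[x$origin == k, k])
  plan <- prepare_samples(series, discard_fraction = discard_fraction)
  keep <- integer(0)
  for (k in seq_len(K)) {
    rows_k <- which(x$origin == k)
    keep <- c(keep, rows_k[plan$indices[[k]]])
  }
  out <- reduced_potentials(x$u[keep, , drop = FALSE],
                            origin = x$origin[keep],
                            temperature_K = x$model$thermo$temperature_K)
  attr(out, "decorrelation") <- plan$info
  attr(out, "rows_kept") <- keep
  out
}

#' @rdname as_reduced_potentials
#' @export
as_reduced_potentials.data.frame <- function(x, temperature_K = 298.15, ...) {
  if (!"state" %in% names(x)) {
    abort("Energy-table data frames need a `state` column.",
          class = "abfe_invalid_input")
  }
  u <- as.matrix(x[, setdiff(names(x), "state"), drop = FALSE])
  reduced_potentials(u, origin = as.integer(x$state),
                     temperature_K = temperature_K)
}

#' Exactly sampled Gaussian ladder for estimator validation
#'
#' Draws independent samples from K harmonic (Gaussian) states and evaluates
#' every sample's reduced potential `u_l(x) = (x - mu_l)^2 / (2 sigma_l^2)`
#' at all states. The analytic dimensionless free energies
#' `f_l = -ln(sigma_l sqrt(2 pi))` (normalized to state 1) are attached, so
#' estimator error can be measured against exact ground truth.
#'
#' @param sigma Numeric vector of state standard deviations (> 0).
#' @param mu State means (recycled to `length(sigma)`).
#' @param n Samples per state (scalar or vector, >= 2).
#' @param seed Integer seed.
#' @param temperature_K Nominal temperature stored on the container.
#' @return A [reduced_potentials()] with attribute `analytic_f`.
#' @examples
#' rp <- sample_gaussian_states(sigma = c(1, 2), n = 100, seed = 1)
#' attr(rp, "analytic_f")[2]  # -log(2)
#' @export
sample_gaussian_states <- function(sigma, mu = 0, n = 1000L, seed = 1L,
                                   temperature_K = 298.15) {
  sigma <- as.numeric(sigma)
  K <- length(sigma)
  if (K < 2L || any(sigma <= 0)) {
    abort("`sigma` must give at least two positive state widths.",
          class = "abfe_invalid_input")
  }
  mu <- rep_len(as.numeric(mu), K)
  n <- rep_len(as.integer(n), K)
  if (any(n < 2L)) {
    abort("At least 2 samples per state are required.",
          class = "abfe_invalid_input")
  }
  x <- with_seed(seed, {
    unlist(lapply(seq_len(K), function(k) stats::rnorm(n[k], mu[k], sigma[k])))
  })
  u <- vapply(seq_len(K),
              function(l) (x - mu[l])^2 / (2 * sigma[l]^2),
              numeric(length(x)))
  out <- reduced_potentials(u, n_k = n, temperature_K = temperature_K)
  f <- -log(sigma * sqrt(2 * pi))
  attr(out, "analytic_f") <- f - f[1L]
  out
}

#' Exact standard binding free energy of the toy model by quadrature
#'
#' Independent oracle for the whole cycle: estimates the configurational
#' integral of the fully coupled, unrestrained guest over the box and all
#' orientations by stratified Monte Carlo (uniform positions within a
#' translation grid, uniform random orientations) and returns
#' `dG = -kT ln( V_box <exp(-U/kT)> / V0 )` with its standard error.
#'
#' @param model A [toy_model()].
#' @param n_cells Translation strata per box dimension.
#' @param n_per_cell Samples per stratum.
#' @param seed Integer seed.
#' @param max_rel_error Maximum tolerated relative standard error of the
#'   integral; exceeding it raises an oracle-precision error.
#' @return List with `value` (kcal/mol), `se` (kcal/mol), `z_mean`,
#'   `z_se`, `n_total`.
#' @export
quadrature_binding_dG <- function(model, n_cells = 10L, n_per_cell = 2000L,
                                  seed = 1L, max_rel_error = 0.01) {
  stopifnot(inherits(model, "toy_model"))
  sys <- toy_system_list(model, environment = "complex")
  raw <- with_seed(seed, {
    .cpp_quadrature_z(sys, as.integer(n_cells), as.integer(n_per_cell))
  })
  rel <- raw$se / raw$mean
  if (!is.finite(rel) || rel > max_rel_error) {
    abort(sprintf(
      "Quadrature oracle too imprecise (relative error %.2g > %.2g); increase n_cells or n_per_cell.",
      rel, max_rel_error),
      class = "abfe_oracle_precision_error")
  }
  kT <- model$thermo$kT
  vbox <- model$box_edge^3
  value <- -kT * log(vbox * raw$mean / model$thermo$v_standard)
  list(value = value, se = kT * rel, z_mean = raw$mean, z_se = raw$se,
       n_total = raw$n_total)
}
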