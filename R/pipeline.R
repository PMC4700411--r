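# shared bootstrap machinery: one resampling pass, several endpoint pairs
bootstrap_multi <- function(data, pairs, n_boot = 200L, seed = 1L,
                            tolerance = 1e-10, max_iterations = 10000L) {
  kT <- .kB * data$temperature_K
  fit0 <- mbar_solve(data, tolerance = tolerance,
                     max_iterations = max_iterations)
  reps <- matrix(0, n_boot, length(pairs))
  reps[1L, ] <- vapply(pairs, function(p) {
    mbar_delta_f(fit0, p[1L], p[2L])
  }, numeric(1))
  with_seed(seed, {
    for (b in 2:n_boot) {
      rows <- resample_within_states(data)
      db <- data
      db$u <- data$u[rows, , drop = FALSE]
      db$origin <- data$origin[rows]
      fitb <- suppressWarnings(
        mbar_solve(db, tolerance = tolerance,
                   max_iterations = max_iterations, f_init = fit0$f,
                   check_overlap = FALSE))
      reps[b, ] <- vapply(pairs, function(p) {
        mbar_delta_f(fitb, p[1L], p[2L])
      }, numeric(1))
    }
  })
  ests <- lapply(seq_along(pairs), function(j) {
    est <- free_energy_estimate(boot = reps[, j] * kT,
                                method = "mbar_bootstrap",
                                seed = as.integer(seed), n_boot = n_boot,
                                temperature_K = data$temperature_K)
    est$endpoints <- pairs[[j]]
    est
  })
  names(ests) <- names(pairs)
  list(estimates = ests, fit = fit0)
}

#' Run the complete alchemical cycle on the toy system
#'
#' End-to-end pipeline: samples the solvent and complex lambda ladders with
#' Hamiltonian-exchange Monte Carlo, discards equilibration and decorrelates
#' each window, estimates every sampled leg with bootstrapped MBAR, adds the
#' analytic restraint/standard-state term, and assembles the standard binding
#' free energy with root-sum-square uncertainty. The result can be compared
#' against [quadrature_binding_dG()], which computes the same quantity by
#' direct integration.
#'
#' @param model A [toy_model()].
#' @param complex_schedule,solvent_schedule Lambda schedules from
#'   [build_lambda_schedule()]; the defaults are the full 42/31-window
#'   protocol. Coarser ladders run faster at some precision cost.
#' @param hrex A [hrex_config()]; its `seed` is ignored in favour of `seed`.
#' @param discard_fraction Equilibration fraction discarded per window.
#' @param n_boot Bootstrap replicates per sampled leg.
#' @param seed Integer master seed; per-stage streams are derived from it by
#'   fixed offsets.
#' @param corrections Named list of additive corrections (numbers or
#'   [apply_charge_correction()] objects).
#' @return A `cycle_result` with an extra `details` element (HREX acceptance
#'   statistics, decorrelation summaries, schedules, seeds).
#' @export
run_full_toy_pipeline <- function(model,
                                  complex_schedule = build_lambda_schedule("complex"),
                                  solvent_schedule = build_lambda_schedule("solvent"),
                                  hrex = hrex_config(),
                                  discard_fraction = 0.1,
                                  n_boot = 200L, seed = 1L,
                                  corrections = list()) {
  stopifnot(inherits(model, "toy_model"))
  if (attr(complex_schedule, "environment") != "complex" ||
      attr(solvent_schedule, "environment") != "solvent") {
    abort("Schedules must be a complex and a solvent schedule.",
          class = "abfe_invalid_input")
  }
  seed <- as.integer(seed)
  seeds <- list(solvent = seed + 101L, complex = seed + 202L,
                boot_solvent = seed + 303L, boot_complex = seed + 404L)

  cfg_s <- hrex
  cfg_s$seed <- seeds$solvent
  hrex_solv <- run_hrex(model, solvent_schedule, cfg_s)
  rp_solv <- as_reduced_potentials(hrex_solv,
                                   discard_fraction = discard_fraction)
  Ks <- nrow(solvent_schedule)
  est_solv <- bootstrap_multi(rp_solv,
                              pairs = list(solv_elec_vdw = c(1L, Ks)),
                              n_boot = n_boot, seed = seeds$boot_solvent)

  cfg_c <- hrex
  cfg_c$seed <- seeds$complex
  hrex_comp <- run_hrex(model, complex_schedule, cfg_c)
  rp_comp <- as_reduced_potentials(hrex_comp,
                                   discard_fraction = discard_fraction)
  ends <- schedule_leg_ends(complex_schedule)
  if (!"restraint_on" %in% names(ends)) {
    abort("The complex schedule must contain a restraint_on leg.",
          class = "abfe_invalid_input")
  }
  iE <- unname(ends[["restraint_on"]])  # restrained, fully coupled state
  Kc <- nrow(complex_schedule)
  est_comp <- bootstrap_multi(
    rp_comp,
    pairs = list(prot_elec_vdw = c(Kc, iE),  # D -> E: recoupling
                 prot_restr = c(iE, 1L)),    # E -> F: restraint release
    n_boot = n_boot, seed = seeds$boot_complex)

  dG_restr <- boresch_analytic_dG(model$restraint, model$thermo)

  result <- assemble_cycle(
    dG_solv_elec_vdw = est_solv$estimates$solv_elec_vdw,
    dG_solv_restr = dG_restr,
    dG_prot_elec_vdw = est_comp$estimates$prot_elec_vdw,
    dG_prot_restr = est_comp$estimates$prot_restr,
    corrections = corrections,
    thermo = model$thermo
  )
  result$details <- list(
    seeds = seeds,
    solvent = list(
      neighbour_acceptance = hrex_solv$neighbour_acceptance,
      jump_probability = hrex_solv$jump_probability,
      decorrelation = attr(rp_solv, "decorrelation")
    ),
    complex = list(
      neighbour_acceptance = hrex_comp$neighbour_acceptance,
      jump_probability = hrex_comp$jump_probability,
      decorrelation = attr(rp_comp, "decorrelation"),
      mbar = glance(est_comp$fit)
    ),
    schedules = list(complex = complex_schedule, solvent = solvent_schedule),
    n_boot = n_boot, seed = seed,
    discard_fraction = discard_fraction
  )
  result
}
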